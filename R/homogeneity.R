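#' Territory map: assign every pixel to its nearest pore
#'
#' Generalised Voronoi partition of the image by the pore pixel sets:
#' each pixel is labelled with the pore whose nearest pore *pixel* is
#' closest in Euclidean distance (distance to the pixel set, not to the
#' centroid -- centroid-based Voronoi diagrams fail for elongated or
#' irregular pores). A pore's own pixels trivially map to itself. The
#' territory is the free space "owned" by each pore and normalises its
#' local area fraction.
#'
#' Computed with an exact Euclidean nearest-site distance transform;
#' pixels equidistant to several pores are assigned deterministically by
#' the transform's scan order (smallest site column, then smallest site
#' row), so runs are bit-reproducible.
#'
#' @param mask A [binary_mask()].
#' @param contours Result of [extract_contours()] on that mask (supplies
#'   the component labels and pore ids).
#' @return A `territory_map`: list with `labels` (integer matrix of pore
#'   ids, NA if the image has no pores), `territory_area` (named vector,
#'   px^2 per pore id), `pore_area` (filled px^2 per id), `scale`.
#' @export
territory_map <- function(mask, contours) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- attr(contours, "labels")
  if (is.null(lab)) stop("`contours` must come from extract_contours()")
  if (length(contours) == 0L) {
    warning("no pores: territory map is empty")
    empty <- matrix(NA_integer_, nrow(mask), ncol(mask))
    return(structure(list(labels = empty, territory_area = numeric(0),
                          pore_area = numeric(0), scale = attr(mask, "scale")),
                     class = "territory_map"))
  }
  # keep only components that survived min_area filtering, renumbered to
  # pore ids (offset indexing: background label 0 maps to 0)
  remap <- integer(max(lab) + 1L)
  for (pc in contours) remap[pc$label + 1L] <- pc$id
  lab_kept <- matrix(remap[lab + 1L], nrow(lab), ncol(lab))

  nl <- .nearest_label_cpp(lab_kept)
  ids <- vapply(contours, `[[`, integer(1), "id")
  ta <- tabulate(nl$label, nbins = max(ids))[ids]
  pa <- vapply(contours, `[[`, numeric(1), "area_px")
  structure(list(labels = nl$label, dist2 = nl$dist2,
                 territory_area = setNames(as.numeric(ta), ids),
                 pore_area = setNames(pa, ids),
                 scale = attr(mask, "scale")),
            class = "territory_map")
}

#' @export
print.territory_map <- function(x, ...) {
  cat(sprintf("territory_map: %d x %d px, %d territories\n",
              ncol(x$labels), nrow(x$labels), length(x$territory_area)))
  invisible(x)
}

#' Local area fraction (homogeneity metric)
#'
#' Pore area divided by territory area: the fraction of its own
#' neighbourhood a pore fills. Uniformly dispersed pores of equal size
#' share a common local area fraction; agglomeration and sparse regions
#' show up as high and low values respectively.
#'
#' @param pore_area Pore area, px^2 (> 0).
#' @param territory_area Territory area, px^2 (>= pore_area).
#' @return Ratio in (0, 1]. Vectorised.
#' @export
local_area_fraction <- function(pore_area, territory_area) {
  if (any(pore_area <= 0)) stop("pore area must be positive")
  if (any(territory_area < pore_area))
    stop("territory smaller than pore: inconsistent labelling")
  pore_area / territory_area
}

#' Per-pore local area fractions of a territory map
#'
#' @param tm A `territory_map`.
#' @return data.frame with columns `id`, `pore_area_px`,
#'   `territory_area_px`, `local_af`.
#' @export
homogeneity_records <- function(tm) {
  stopifnot(inherits(tm, "territory_map"))
  ids <- as.integer(names(tm$territory_area))
  data.frame(id = ids,
             pore_area_px = unname(tm$pore_area),
             territory_area_px = unname(tm$territory_area),
             local_af = local_area_fraction(unname(tm$pore_area),
                                            unname(tm$territory_area)))
}

#' Radial ring-band profile
#'
#' Splits the image into concentric annuli of width `step` about the
#' image centre and aggregates pore metrics per band. Each pore is
#' assigned whole to the band containing its centroid (with a feature to
#' step ratio of at least 1:10, features divided between bands have a
#' negligible effect on band means). Band porosity uses the pore pixel
#' areas of the assigned pores over the annulus area inside the frame.
#'
#' @param image_dims c(height, width) in px.
#' @param step Band width in px (> 0).
#' @param pores data.frame from [measure_pores()], optionally carrying a
#'   `local_af` column.
#' @param centre c(x, y) of the band centre; defaults to the image
#'   centre (W/2, H/2).
#' @param scale Micrometres per pixel for the reported radii.
#' @return data.frame with one row per band: band_index, r_inner_um,
#'   r_outer_um, n_pores, mean_pore_size_um (mean LSTP radius), mean
#'   metrics, porosity, mean_local_af. Bands with no pores carry NA
#'   statistics.
#' @export
ring_bands <- function(image_dims, step, pores, centre = NULL, scale = 1) {
  if (step <= 0) stop("band step must be positive")
  H <- image_dims[1]; W <- image_dims[2]
  if (is.null(centre)) centre <- c(W / 2, H / 2)

  # annulus areas inside the frame, by pixel count
  rpix <- sqrt(outer((seq_len(H) - centre[2])^2, (seq_len(W) - centre[1])^2, `+`))
  max_r <- max(rpix)
  nb <- max(1L, ceiling(max_r / step))
  band_px <- tabulate(pmin(floor(rpix / step), nb - 1L) + 1L, nbins = nb)

  if (nrow(pores) > 0L) {
    rc <- sqrt((pores$centroid_x - centre[1])^2 + (pores$centroid_y - centre[2])^2)
    band <- pmin(floor(rc / step), nb - 1L) + 1L
  } else band <- integer(0)

  agg <- function(v, b) {
    out <- rep(NA_real_, nb)
    if (length(v)) {
      m <- tapply(v, factor(b, levels = seq_len(nb)), mean, na.rm = TRUE)
      out[as.integer(names(m))] <- as.numeric(m)
    }
    out
  }
  n_pores <- tabulate(band, nbins = nb)
  area_sum <- rep(0, nb)
  if (nrow(pores) > 0L) {
    s <- tapply(pores$area_um2 / scale^2, factor(band, levels = seq_len(nb)), sum)
    area_sum[!is.na(s)] <- s[!is.na(s)]
  }
  out <- data.frame(
    band_index = seq_len(nb) - 1L,
    r_inner_um = (seq_len(nb) - 1L) * step * scale,
    r_outer_um = seq_len(nb) * step * scale,
    n_pores = n_pores,
    mean_pore_size_um = agg(pores$lstp_radius_um, band),
    mean_eq_diameter_um = agg(pores$eq_diameter_um, band),
    mean_circularity = agg(pores$circularity, band),
    mean_waviness = agg(pores$waviness, band),
    mean_aspect_ratio = agg(pores$aspect_ratio, band),
    porosity = ifelse(band_px > 0, area_sum / band_px, NA_real_),
    mean_local_af = if ("local_af" %in% names(pores)) agg(pores$local_af, band)
                    else rep(NA_real_, nb)
  )
  out
}

#' Render a homogeneity colour map
#'
#' Paints every territory with a colour encoding its pore's local area
#' fraction and overlays the pore pixels in a distinct colour, giving the
#' at-a-glance dispersion map: sparse regions (low local af) read dark
#' blue, agglomerated regions read red under the default viridis-like
#' scale.
#'
#' @param tm A `territory_map`.
#' @param records data.frame from [homogeneity_records()] (computed if
#'   NULL).
#' @param colour_range Local-af range mapped onto the colour scale;
#'   default c(0, 0.5), fixed so maps of different samples share a
#'   colour bar. Values outside are clamped.
#' @param palette Colour palette name for [grDevices::hcl.colors()]
#'   (default "Spectral", reversed: blue = low, red = high).
#' @param pore_colour Overlay colour for pore interiors.
#' @param mask Optional [binary_mask()]; when given, its pore pixels are
#'   overlaid.
#' @param file Optional PNG path to write.
#' @return An H x W x 3 RGB array in \[0, 1\] (invisibly if written to
#'   file).
#' @export
render_homogeneity_map <- function(tm, records = NULL, colour_range = c(0, 0.5),
                                   palette = "Spectral", pore_colour = "black",
                                   mask = NULL, file = NULL) {
  stopifnot(inherits(tm, "territory_map"))
  if (is.null(records)) records <- homogeneity_records(tm)
  n_col <- 256L
  cols <- rev(hcl.colors(n_col, palette))
  af <- setNames(records$local_af, records$id)
  lab <- tm$labels
  idx <- matrix(NA_integer_, nrow(lab), ncol(lab))
  ok <- !is.na(lab) & lab > 0
  v <- af[as.character(lab[ok])]
  v <- pmin(pmax((v - colour_range[1]) / diff(colour_range), 0), 1)
  idx[ok] <- as.integer(round(v * (n_col - 1L))) + 1L
  rgb_cols <- col2rgb(cols) / 255
  img <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(lab), ncol(lab))
    plane[ok] <- rgb_cols[ch, idx[ok]]
    img[, , ch] <- plane
  }
  if (!is.null(mask)) {
    pc <- col2rgb(pore_colour)[, 1] / 255
    pore <- as.logical(mask)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[pore] <- pc[ch]
      img[, , ch] <- plane
    }
  }
  if (!is.null(file)) {
    png::writePNG(img, file)
    return(invisible(img))
  }
  img
}

#' Write a territory label image (16-bit PNG)
#'
#' @param tm A `territory_map`.
#' @param path Output PNG path.
#' @export
write_territory_png <- function(tm, path) {
  lab <- tm$labels
  lab[is.na(lab)] <- 0L
  png::writePNG(lab / max(1L, max(lab)), path)
  invisible(path)
}
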