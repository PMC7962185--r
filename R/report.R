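#' Pipeline configuration
#'
#' Collects every tunable of the measurement pipeline in one validated
#' record. The measurement path contains no randomness: identical input
#' and configuration always reproduce identical outputs.
#'
#' @param input Path to a PNG/TIFF micrograph, or NULL when `mask` is
#'   given.
#' @param mask Path to a pre-binarised PNG mask, or a [binary_mask()]
#'   object; bypasses segmentation.
#' @param threshold Binarisation threshold (required with `input`).
#' @param invert TRUE when pores image bright.
#' @param scale_um_per_px Physical scale, um/px.
#' @param fft_small_px,fft_large_px Band-pass feature-size cutoffs in px;
#'   set `fft_small_px = NA` to skip the filter (thresholding then applies
#'   to the unfiltered image).
#' @param min_area Minimum pore size kept, px^2.
#' @param band_step Ring-band width, px; NA disables banding.
#' @param refine_step LSTP final grid pitch, px.
#' @param angle_step Aspect-ratio sweep step, degrees.
#' @param colour_range Local-af range of the homogeneity colour scale.
#' @param out_dir Output directory for [run_pipeline()] artifacts; NULL
#'   returns results without writing.
#' @param exclude_border_pores Drop border-touching pores from the
#'   summary statistics (they still count towards porosity and
#'   territories).
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, mask = NULL, threshold = NULL,
                       invert = FALSE, scale_um_per_px = 1,
                       fft_small_px = NA, fft_large_px = NA,
                       min_area = 5, band_step = NA, refine_step = 0.1,
                       angle_step = 0.5, colour_range = c(0, 0.5),
                       out_dir = NULL, exclude_border_pores = FALSE) {
  if (is.null(input) && is.null(mask))
    stop("provide `input` (micrograph) or `mask`")
  if (!is.null(input) && is.null(threshold))
    stop("a threshold is required when segmenting a micrograph")
  for (p in c(scale_um_per_px, min_area, refine_step, angle_step))
    if (!is.na(p) && p < 0) stop("numeric parameters must be positive")
  if (scale_um_per_px <= 0) stop("scale must be positive")
  structure(list(input = input, mask = mask, threshold = threshold,
                 invert = invert, scale_um_per_px = scale_um_per_px,
                 fft_small_px = fft_small_px, fft_large_px = fft_large_px,
                 min_area = min_area, band_step = band_step,
                 refine_step = refine_step, angle_step = angle_step,
                 colour_range = colour_range, out_dir = out_dir,
                 exclude_border_pores = exclude_border_pores),
            class = "run_config")
}

#' Run the full measurement pipeline
#'
#' Segmentation (optional FFT band-pass + threshold) -> contour
#' extraction -> per-pore morphometrics -> territory/homogeneity ->
#' ring banding, with per-stage timing logged via `message()`. With
#' `out_dir` set, writes `pores.csv`, `bands.csv`, `summary.json`,
#' `homogeneity_map.png`, `territory.png` and `mask.png`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return List with `summary` (a `sample_summary`), `pores`
#'   (per-pore data.frame incl. `local_af`), `bands`, `territory`,
#'   `mask`, and `paths` of written files (if any).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[3]
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(lab, t_prev) {
    t <- proc.time()[3]; say("[%s] %.2f s", lab, t - t_prev); t
  }

  # --- segmentation ----------------------------------------------------
  if (!is.null(config$mask)) {
    mask <- if (inherits(config$mask, "binary_mask")) config$mask
            else read_mask(config$mask, scale = config$scale_um_per_px)
  } else {
    img <- read_micrograph(config$input, scale = config$scale_um_per_px)
    if (!is.na(config$fft_small_px)) {
      large <- if (is.na(config$fft_large_px)) NULL else config$fft_large_px
      img <- fft_bandpass(img, config$fft_small_px, large)
    }
    mask <- binarize(img, config$threshold, config$invert)
  }
  t1 <- stage("segmentation", t0)

  # --- contours --------------------------------------------------------
  poro <- porosity(mask)
  contours <- extract_contours(mask, min_area = config$min_area)
  say("[contours] %d pores, porosity %.4f", length(contours), poro)
  t2 <- stage("contours", t1)

  if (length(contours) == 0L) {
    warning("no pores found")
    summary <- sample_summary(empty_metrics(), poro, runtime = proc.time()[3] - t0)
    res <- list(summary = summary, pores = empty_metrics(), bands = NULL,
                territory = NULL, mask = mask, paths = character(0))
    if (!is.null(config$out_dir)) res$paths <- write_outputs(res, config)
    return(res)
  }

  # --- morphometrics ---------------------------------------------------
  smoothed <- lapply(contours, smooth_contour)
  pores <- do.call(rbind, Map(function(pc, sc)
    measure_pore(pc, sc, scale = config$scale_um_per_px,
                 angle_step = config$angle_step,
                 refine_step = config$refine_step),
    contours, smoothed))
  t3 <- stage("morphometrics", t2)

  # --- homogeneity -----------------------------------------------------
  tm <- territory_map(mask, contours)
  rec <- homogeneity_records(tm)
  pores$local_af <- rec$local_af[match(pores$id, rec$id)]
  t4 <- stage("homogeneity", t3)

  # --- banding ---------------------------------------------------------
  bands <- NULL
  if (!is.na(config$band_step))
    bands <- ring_bands(dim(mask), config$band_step, pores,
                        scale = config$scale_um_per_px)
  t5 <- stage("banding", t4)

  stat_pores <- if (config$exclude_border_pores) pores[!pores$touches_border, , drop = FALSE] else pores
  summary <- sample_summary(stat_pores, poro, runtime = proc.time()[3] - t0)
  res <- list(summary = summary, pores = pores, bands = bands,
              territory = tm, mask = mask, paths = character(0))
  if (!is.null(config$out_dir)) res$paths <- write_outputs(res, config)
  res
}

#' Per-sample summary statistics
#'
#' Mean and standard deviation of each pore metric, pores weighted
#' equally. "Mean pore size" conventionally refers to the LSTP radius;
#' the equivalent-circle diameter is reported separately.
#'
#' @param pores Per-pore data.frame.
#' @param porosity Total porosity of the mask.
#' @param runtime Elapsed seconds.
#' @return A `sample_summary` list.
#' @export
sample_summary <- function(pores, porosity, runtime = NA_real_) {
  ms <- function(v) if (length(v) == 0L || all(is.na(v))) c(mean = NA_real_, sd = NA_real_)
                    else c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  structure(list(
    n_pores = nrow(pores),
    porosity = porosity,
    lstp_radius_um = ms(pores$lstp_radius_um),
    eq_diameter_um = ms(pores$eq_diameter_um),
    circularity = ms(pores$circularity),
    waviness = ms(pores$waviness),
    aspect_ratio = ms(pores$aspect_ratio),
    local_af = if ("local_af" %in% names(pores)) ms(pores$local_af) else c(mean = NA_real_, sd = NA_real_),
    runtime_s = unname(runtime)
  ), class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample_summary: %d pores, porosity %.4f\n", x$n_pores, x$porosity))
  f <- function(nm, lab) cat(sprintf("  %-22s %8.4f +/- %.4f\n", lab, x[[nm]]["mean"], x[[nm]]["sd"]))
  f("lstp_radius_um", "mean pore size (LSTP)")
  f("eq_diameter_um", "eq. diameter (um)")
  f("circularity", "circularity")
  f("waviness", "waviness")
  f("aspect_ratio", "aspect ratio")
  f("local_af", "local area fraction")
  invisible(x)
}

#' Write pipeline artifacts
#'
#' CSV files are UTF-8 with a header row and fixed column order; the
#' summary is JSON. Re-running with an identical configuration reproduces
#' byte-identical CSV/JSON.
#'
#' @param res Result list from [run_pipeline()].
#' @param config The [run_config()] used.
#' @return Named character vector of written paths.
#' @export
write_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$out_dir)) stop("cannot create output directory: ", config$out_dir)
  paths <- c()
  p <- file.path(config$out_dir, "pores.csv")
  write.csv(res$pores, p, row.names = FALSE)
  paths["pores"] <- p
  if (!is.null(res$bands)) {
    p <- file.path(config$out_dir, "bands.csv")
    write.csv(res$bands, p, row.names = FALSE)
    paths["bands"] <- p
  }
  p <- file.path(config$out_dir, "summary.json")
  s <- res$summary
  jsonlite::write_json(list(
    n_pores = s$n_pores, porosity = s$porosity,
    lstp_radius_um = as.list(s$lstp_radius_um),
    eq_diameter_um = as.list(s$eq_diameter_um),
    circularity = as.list(s$circularity),
    waviness = as.list(s$waviness),
    aspect_ratio = as.list(s$aspect_ratio),
    local_af = as.list(s$local_af)
  ), p, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  paths["summary"] <- p
  p <- file.path(config$out_dir, "mask.png")
  write_mask(res$mask, p)
  paths["mask"] <- p
  if (!is.null(res$territory)) {
    p <- file.path(config$out_dir, "territory.png")
    write_territory_png(res$territory, p)
    paths["territory"] <- p
    p <- file.path(config$out_dir, "homogeneity_map.png")
    render_homogeneity_map(res$territory, colour_range = config$colour_range,
                           mask = res$mask, file = p)
    paths["homogeneity_map"] <- p
  }
  paths
}

#' Relative-frequency histogram with least-squares Gaussian fit
#'
#' Bins the values (Freedman--Diaconis rule by default), normalises bin
#' heights to relative frequency (summing to 1), and fits
#' `A * exp(-(x - mu)^2 / (2 sigma^2))` to the bin centres by
#' least squares -- the conventional way pore-size distributions from
#' different measurement methods are overlaid and compared.
#'
#' @param values Numeric vector (>= 3 values).
#' @param bins Number of bins, or "fd" for Freedman--Diaconis.
#' @return List with `table` (data.frame mid, count, rel_freq), `mean`,
#'   `sd`, `amplitude`, `fit` ("gaussian" or "degenerate"). All-equal
#'   input yields a degenerate delta-like summary with no fit.
#' @export
gaussian_histogram <- function(values, bins = "fd") {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 values")
  if (diff(range(values)) == 0)
    return(list(table = data.frame(mid = values[1], count = length(values), rel_freq = 1),
                mean = values[1], sd = 0, amplitude = 1, fit = "degenerate"))
  nb <- if (identical(bins, "fd")) max(3L, grDevices::nclass.FD(values)) else as.integer(bins)
  brk <- seq(min(values), max(values), length.out = nb + 1L)
  cnt <- tabulate(findInterval(values, brk, rightmost.closed = TRUE), nbins = nb)
  mids <- (brk[-1] + brk[-(nb + 1L)]) / 2
  rel <- cnt / sum(cnt)

  m0 <- mean(values); s0 <- stats::sd(values); a0 <- max(rel)
  obj <- function(p) sum((rel - p[3] * exp(-(mids - p[1])^2 / (2 * p[2]^2)))^2)
  fit <- optim(c(m0, s0, a0), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  par <- fit$par
  rng <- range(values)
  # few-bin or strongly non-Gaussian samples can drive the least-squares
  # fit to a degenerate flat optimum; report moment estimates instead
  if (!all(is.finite(par)) || par[1] < rng[1] || par[1] > rng[2] ||
      abs(par[2]) > 10 * diff(rng)) {
    par <- c(m0, s0, a0)
  }
  list(table = data.frame(mid = mids, count = cnt, rel_freq = rel),
       mean = par[1], sd = abs(par[2]), amplitude = par[3],
       fit = "gaussian")
}
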