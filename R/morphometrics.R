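#' Largest sphere through pore (LSTP): maximal inscribed circle
#'
#' Two-stage grid search for the largest circle fully inscribed in a pore
#' cross-section -- a proxy for the largest particle that could pass the
#' pore, and a far better size measure than the equivalent-circle
#' diameter for irregular pores. A coarse point grid spans the contour
#' bounding box; points inside the contour are kept and the minimum
#' distance from each to the smoothed boundary is computed, the maximum
#' of which seeds progressively finer local grids until the pitch reaches
#' `refine_step`.
#'
#' Distances are measured to the band-limited smoothed boundary (not the
#' raw pixel staircase), which places the boundary at sub-pixel accuracy,
#' and carry a +0.5 px digitisation correction: traced contours pass
#' through the centres of boundary pixels, while the physical pore edge
#' lies half a pixel beyond them.
#'
#' @param contour A `pore_contour` (interior test polygon).
#' @param smoothed The `smoothed_contour` used as the distance target.
#'   If NULL (recommended), a dedicated light smoothing band (cutoff
#'   wavelength 8 px of arc) is built: just enough to suppress the
#'   half-pixel staircase without rounding concave notches outward.
#' @param coarse_step Coarse grid pitch in px; default
#'   `max(1, ceil(min(bbox)/64))`.
#' @param refine_step Final grid pitch in px (default 0.1).
#' @return List with `radius` (px), `centre` (x, y), `method`
#'   ("grid" or "distance-transform fallback").
#' @export
lstp <- function(contour, smoothed = NULL, coarse_step = NULL, refine_step = 0.1) {
  stopifnot(inherits(contour, "pore_contour"))
  if (is.null(smoothed))
    smoothed <- smooth_contour(contour,
      kept_harmonics = max(8L, as.integer(ceiling(contour$perimeter / 8))))
  if (!is.null(coarse_step) && (refine_step <= 0 || coarse_step < refine_step))
    stop("need coarse_step >= refine_step > 0")
  pts <- contour$points
  bb <- c(min(pts[, 1]), max(pts[, 1]), min(pts[, 2]), max(pts[, 2]))
  if (is.null(coarse_step))
    coarse_step <- max(1, ceiling(min(bb[2] - bb[1], bb[4] - bb[3]) / 64))
  poly <- smoothed_points(smoothed)

  inside_grid <- function(step) {
    gx <- seq(bb[1], bb[2], by = step)
    gy <- seq(bb[3], bb[4], by = step)
    g <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    g[point_in_polygon(g, pts), , drop = FALSE]
  }

  g <- inside_grid(coarse_step)
  if (nrow(g) == 0L && coarse_step > 1) g <- inside_grid(1)
  if (nrow(g) == 0L) g <- inside_grid(0.25)   # sub-pixel-thin pore
  if (nrow(g) == 0L) {
    # thinner than a quarter pixel everywhere: report the half-width bound
    return(list(radius = 0.25, centre = contour$centroid, method = "thin-pore bound"))
  }
  d <- .min_dist_to_polyline_cpp(g, poly)
  best <- which.max(d)
  centre <- g[best, ]; radius <- d[best]

  step <- coarse_step
  while (step > refine_step) {
    new_step <- max(refine_step, step / 8)
    gx <- seq(centre[1] - 2 * step, centre[1] + 2 * step, by = new_step)
    gy <- seq(centre[2] - 2 * step, centre[2] + 2 * step, by = new_step)
    g <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    g <- g[point_in_polygon(g, pts), , drop = FALSE]
    if (nrow(g) > 0L) {
      d <- .min_dist_to_polyline_cpp(g, poly)
      b <- which.max(d)
      if (d[b] > radius) { radius <- d[b]; centre <- g[b, ] }
    }
    step <- new_step
  }
  # contour points sit on boundary-pixel centres, half a pixel inside
  # the physical pore edge
  list(radius = radius + 0.5, centre = unname(centre), method = "grid")
}

# even-odd rule point-in-polygon, vectorised over query points
point_in_polygon <- function(q, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- logical(nrow(q))
  qx <- q[, 1]; qy <- q[, 2]
  for (i in seq_along(x)) {
    crosses <- ((y[i] > qy) != (yn[i] > qy))
    if (any(crosses)) {
      xint <- x[i] + (qy[crosses] - y[i]) / (yn[i] - y[i]) * (xn[i] - x[i])
      inside[crosses] <- xor(inside[crosses], qx[crosses] < xint)
    }
  }
  inside
}

#' Circularity (ISO 9276-6)
#'
#' `4 * pi * A / P^2`: 1 for a perfect circle, decreasing with boundary
#' irregularity and elongation.
#'
#' @param A Area (> 0), any unit.
#' @param P Perimeter (> 0), consistent unit.
#' @return Dimensionless circularity.
#' @export
circularity <- function(A, P) {
  if (any(A <= 0) || any(P <= 0)) stop("area and perimeter must be positive")
  4 * pi * A / P^2
}

#' Waviness: convex fraction of the boundary
#'
#' The fraction of the contour's arc length that is locally convex, i.e.
#' where the centre of curvature lies inside the shape. Signed curvature
#' is evaluated on the band-limited smoothed contour as
#' `kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)`; with the
#' counter-clockwise orientation enforced at contour extraction, convex
#' arcs have positive kappa. Waviness is 1 for any convex shape and drops
#' as concave re-entrants occupy more of the boundary -- a property tied
#' to cell adhesion and tissue in-growth on scaffold pore walls.
#'
#' @param smoothed A `smoothed_contour`.
#' @param turn_tol Hysteresis threshold on the tangent turning angle, in
#'   radians (default 0.2): a boundary stretch counts as concave only
#'   when the tangent direction reverses by more than `turn_tol`.
#'   Pointwise curvature signs flicker wherever residual pixel noise
#'   rivals a shallow arc's true curvature; the accumulated turning
#'   angle is dimensionless and scale-free, so thresholding its
#'   reversals classifies shallow concave arcs correctly while flat
#'   runs (zero net turning) count as convex -- a straight edge being
#'   the limit of a convex arc, convex polygons score exactly 1.
#' @return Waviness in (0, 1].
#' @export
waviness <- function(smoothed, turn_tol = 0.2) {
  stopifnot(inherits(smoothed, "smoothed_contour"))
  speed2 <- smoothed$dx^2 + smoothed$dy^2
  ok <- speed2 > 1e-12
  if (!all(ok)) message(sum(!ok), " zero-speed contour samples excluded from waviness")
  dx <- smoothed$dx[ok]; dy <- smoothed$dy[ok]
  ddx <- smoothed$ddx[ok]; ddy <- smoothed$ddy[ok]
  sp <- sqrt(speed2[ok])
  kappa <- (dx * ddy - dy * ddx) / sp^3
  # orientation safeguard: positive enclosed area = CCW = convex kappa > 0
  if (signed_area(smoothed_points(smoothed)) < 0) kappa <- -kappa
  n <- length(kappa)
  w <- sp / sum(sp)                 # arc-length weight per sample
  dtheta <- kappa * sp              # turning per sample (d theta = kappa ds)

  # hysteresis walk over two laps; classifications taken from the second,
  # so the wrap-around start phase cannot bias the result
  theta <- cumsum(rep(dtheta, 2L))
  concave <- logical(2L * n)
  segs <- list()
  state_concave <- FALSE
  ref <- theta[1]; ref_i <- 1L
  seg_start <- 1L
  for (i in seq_along(theta)) {
    th <- theta[i]
    if (!state_concave) {
      if (th > ref) { ref <- th; ref_i <- i }
      else if (ref - th > turn_tol) {         # genuine reversal: concave from the peak
        state_concave <- TRUE
        seg_start <- ref_i
        ref <- th; ref_i <- i
      }
    } else {
      if (th < ref) { ref <- th; ref_i <- i }
      else if (th - ref > turn_tol) {         # reversal back: concave ended at the trough
        segs[[length(segs) + 1L]] <- c(seg_start, ref_i)
        state_concave <- FALSE
        ref <- th; ref_i <- i
      }
    }
  }
  if (state_concave) segs[[length(segs) + 1L]] <- c(seg_start, ref_i)

  if (length(segs)) {
    # Endpoint refinement. On a shallow concave arc the position of the
    # peak/trough of theta jitters by (noise amplitude / trend slope),
    # clipping the segment; a circular running median of the turning
    # rate is immune to the sharp positive spikes at cusps and corners,
    # so extending each core while the median turning rate stays
    # negative recovers the true transition points.
    kwin <- max(5L, 2L * (n %/% 30L) + 1L)
    med3 <- stats::runmed(rep(dtheta, 3L), kwin, endrule = "constant")
    med <- rep(med3[(n + 1L):(2L * n)], 2L)
    for (sg in segs) {
      a <- sg[1]; b <- sg[2]
      while (a > 1L && med[a - 1L] < 0 && b - a < 2L * n) a <- a - 1L
      while (b < 2L * n && med[b + 1L] < 0 && b - a < 2L * n) b <- b + 1L
      concave[a:b] <- TRUE
    }
  }
  conc <- concave[(n + 1L):(2L * n)] | concave[seq_len(n)]
  sum(w[!conc])
}

#' Aspect ratio by rotating-extent sweep (ISO 9276-6)
#'
#' `AR = d_min / d_max`: the minimum width over all orientations divided
#' by the extent perpendicular to that orientation. The contour is swept
#' through (-90, 90] degrees (extents have period 180 deg, so this covers
#' the full rotation); `d_min` is the smallest directional extent and
#' `d_max` the extent at right angles to it -- note `d_max` is not the
#' global maximum Feret diameter, which differs for skewed shapes.
#'
#' @param contour A `pore_contour` (raw boundary points are used).
#' @param angle_step Sweep step in degrees (default 0.5, must be <= 5).
#' @return List with `aspect_ratio`, `d_min`, `d_max`, `angle_min`
#'   (degrees, orientation of the minimum extent; ties take the smallest
#'   angle).
#' @export
aspect_ratio <- function(contour, angle_step = 0.5) {
  stopifnot(inherits(contour, "pore_contour"))
  if (!(angle_step > 0 && angle_step <= 5)) stop("need 0 < angle_step <= 5 degrees")
  pts <- contour$points
  th <- seq(-90 + angle_step, 90, by = angle_step) * pi / 180
  proj <- pts %*% rbind(cos(th), sin(th))            # n_points x n_angles
  width <- apply(proj, 2, max) - apply(proj, 2, min)
  i <- which.min(width)                              # which.min takes the first (smallest angle) tie
  perp <- pts %*% c(cos(th[i] + pi / 2), sin(th[i] + pi / 2))
  d_min <- width[i]
  d_max <- max(perp) - min(perp)
  list(aspect_ratio = d_min / d_max, d_min = d_min, d_max = d_max,
       angle_min = th[i] * 180 / pi)
}

#' Measure one pore: full metric record
#'
#' Aggregates size and shape metrics for a single pore. All geometry is
#' computed in pixels and converted to micrometres via `scale` at the
#' end. Area and perimeter for circularity come from the smoothed
#' contour (consistent sub-pixel pair); the equivalent-circle diameter
#' uses the filled pixel area; LSTP uses the two-stage grid search.
#' A failing component metric is reported as NA rather than dropping the
#' pore.
#'
#' @param contour A `pore_contour`.
#' @param smoothed Its `smoothed_contour` (computed if NULL).
#' @param scale Micrometres per pixel.
#' @param angle_step,refine_step,turn_tol Passed to the component
#'   operations.
#' @return One-row data.frame with columns id, centroid_x, centroid_y,
#'   area_um2, perimeter_um, eq_diameter_um, lstp_radius_um, circularity,
#'   waviness, aspect_ratio, d_min_um, d_max_um, touches_border.
#' @export
measure_pore <- function(contour, smoothed = NULL, scale = 1,
                         angle_step = 0.5, refine_step = 0.1, turn_tol = 0.2) {
  stopifnot(inherits(contour, "pore_contour"))
  if (is.null(smoothed)) smoothed <- smooth_contour(contour)
  sp <- smoothed_points(smoothed)
  A_sm <- shoelace_area(sp)
  P_sm <- perimeter_length(sp)
  circ <- tryCatch(circularity(A_sm, P_sm), error = function(e) NA_real_)
  # waviness uses a stronger smoothing band (cutoff wavelength ~40 px of
  # arc) than the geometric contour: curvature-sign classification needs
  # the staircase fully suppressed, where perimeter/area need detail kept
  wav <- tryCatch({
    K_w <- max(8L, as.integer(ceiling(contour$perimeter / 40)))
    waviness(smooth_contour(contour, kept_harmonics = K_w), turn_tol)
  }, error = function(e) NA_real_)
  ar <- tryCatch(aspect_ratio(contour, angle_step),
                 error = function(e) list(aspect_ratio = NA_real_, d_min = NA_real_, d_max = NA_real_))
  ls <- tryCatch(lstp(contour, refine_step = refine_step),
                 error = function(e) list(radius = NA_real_))
  data.frame(
    id = contour$id,
    centroid_x = contour$centroid[1],
    centroid_y = contour$centroid[2],
    area_um2 = contour$area_px * scale^2,
    perimeter_um = P_sm * scale,
    eq_diameter_um = equivalent_circular_diameter(contour$area_px, scale),
    lstp_radius_um = ls$radius * scale,
    circularity = circ,
    waviness = wav,
    aspect_ratio = ar$aspect_ratio,
    d_min_um = ar$d_min * scale,
    d_max_um = ar$d_max * scale,
    touches_border = contour$touches_border
  )
}

#' Measure all pores of a contour set
#'
#' @param contours Result of [extract_contours()].
#' @param scale Micrometres per pixel; defaults to the scale recorded on
#'   the contour set.
#' @param ... Passed to [measure_pore()].
#' @return data.frame with one row per pore (see [measure_pore()]).
#' @export
measure_pores <- function(contours, scale = NULL, ...) {
  if (is.null(scale)) scale <- attr(contours, "scale")
  if (is.null(scale)) scale <- 1
  if (length(contours) == 0L) return(empty_metrics())
  rows <- lapply(contours, function(pc) measure_pore(pc, scale = scale, ...))
  do.call(rbind, rows)
}

empty_metrics <- function() {
  data.frame(id = integer(), centroid_x = numeric(), centroid_y = numeric(),
             area_um2 = numeric(), perimeter_um = numeric(),
             eq_diameter_um = numeric(), lstp_radius_um = numeric(),
             circularity = numeric(), waviness = numeric(),
             aspect_ratio = numeric(), d_min_um = numeric(),
             d_max_um = numeric(), touches_border = logical())
}
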