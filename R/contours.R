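#' Total porosity of a mask
#'
#' Area fraction of pore pixels: pore pixel count divided by total pixel
#' count.
#'
#' @param mask A [binary_mask()].
#' @return Fraction in \[0, 1\].
#' @export
porosity <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  mean(mask)
}

#' Shoelace polygon area
#'
#' @param points Two-column matrix of (x, y) vertices of a closed polygon
#'   (first vertex not repeated); at least 3 vertices.
#' @return Unsigned area, px^2.
#' @export
shoelace_area <- function(points) {
  abs(signed_area(points))
}

signed_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("a polygon needs at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a closed polygon
#'
#' Sum of segment lengths including the closing segment.
#'
#' @inheritParams shoelace_area
#' @return Length, px.
#' @export
perimeter_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("a polygon needs at least 3 points")
  dx <- diff(c(points[, 1], points[1, 1]))
  dy <- diff(c(points[, 2], points[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

#' Polygon centroid (area-weighted)
#' @inheritParams shoelace_area
#' @return c(x, y)
#' @keywords internal
polygon_centroid <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- signed_area(points)
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Equivalent circular diameter from pore area
#'
#' Diameter of the circle with the same area as the pore:
#' d = 2 * scale * sqrt(A / pi).
#'
#' @param A Pore area in px^2 (> 0).
#' @param scale Micrometres per pixel.
#' @return Diameter in micrometres.
#' @export
equivalent_circular_diameter <- function(A, scale = 1) {
  if (any(!is.finite(A)) || any(A <= 0)) stop("area must be positive and finite")
  2 * scale * sqrt(A / pi)
}

#' Extract external pore contours from a binary mask
#'
#' Labels 8-connected pore components (4-connected background), drops
#' components below `min_area` pixels, and traces the ordered external
#' boundary of each with a Moore-neighbour walk. Interior solid islands
#' (pores within pores) are ignored: only the external contour is kept,
#' and the pore area includes any enclosed holes. Ids follow row-major
#' scan order of the topmost-leftmost boundary pixel, so numbering is
#' identical across platforms.
#'
#' @param mask A [binary_mask()].
#' @param min_area Minimum component pixel count to keep (default 5;
#'   features under 12--15 px across are unreliable, 5 px^2 removes
#'   speckle while keeping that regime measurable).
#' @return A list of `pore_contour` objects, each with elements `points`
#'   (n x 2 matrix of (x, y) pixel-centre coordinates, counter-clockwise),
#'   `id`, `area_px` (filled pixel count), `area_shoelace`, `perimeter`,
#'   `centroid`, `touches_border`. The label matrix is attached as
#'   attribute `labels`, the mask scale as `scale`.
#' @export
extract_contours <- function(mask, min_area = 5) {
  stopifnot(inherits(mask, "binary_mask"))
  lab <- .label8_cpp(matrix(as.logical(mask), nrow(mask), ncol(mask)))
  n <- max(lab)
  if (n == 0L) {
    out <- list()
    attr(out, "labels") <- lab
    attr(out, "scale") <- attr(mask, "scale")
    return(out)
  }
  filled <- .filled_areas_cpp(lab, n)
  H <- nrow(lab); W <- ncol(lab)

  # topmost-leftmost pixel per label (row-major scan: y, then x)
  keep <- which(filled >= max(min_area, 1))
  contours <- vector("list", length(keep))
  kept <- 0L
  for (id in keep) {
    idx <- which(lab == id)
    r <- (idx - 1L) %% H + 1L
    c0 <- (idx - 1L) %/% H + 1L
    o <- order(r, c0)[1]
    pts <- .trace_contour_cpp(lab, id, r[o] - 1L, c0[o] - 1L)
    pts <- unique_consecutive(pts)
    if (nrow(pts) < 3L) next  # degenerate 1-2 px components
    if (signed_area(pts) < 0) pts <- pts[c(1L, nrow(pts):2L), , drop = FALSE]
    kept <- kept + 1L
    contours[[kept]] <- structure(list(
      points = pts,
      id = kept,
      label = id,
      area_px = filled[id],
      area_shoelace = shoelace_area(pts),
      perimeter = perimeter_length(pts),
      centroid = polygon_centroid(pts),
      touches_border = any(r == 1L | r == H) || any(c0 == 1L | c0 == W)
    ), class = "pore_contour")
  }
  contours <- contours[seq_len(kept)]
  attr(contours, "labels") <- lab
  attr(contours, "scale") <- attr(mask, "scale")
  contours
}

unique_consecutive <- function(pts) {
  if (nrow(pts) < 2L) return(pts)
  dup <- c(FALSE, pts[-1, 1] == pts[-nrow(pts), 1] & pts[-1, 2] == pts[-nrow(pts), 2])
  pts <- pts[!dup, , drop = FALSE]
  if (nrow(pts) > 1L && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  pts
}

#' @export
print.pore_contour <- function(x, ...) {
  cat(sprintf("pore_contour #%d: %d boundary points, area %.0f px^2, perimeter %.1f px%s\n",
              x$id, nrow(x$points), x$area_px, x$perimeter,
              if (x$touches_border) " (touches border)" else ""))
  invisible(x)
}

#' Band-limited smoothing of a pore contour
#'
#' Resamples the traced boundary at uniform arc length with `density`
#' times the original point count, then low-pass filters the periodic
#' x(t) and y(t) signals in the Fourier domain, yielding a continuous,
#' differentiable closed curve. Discrete pixel boundaries have unusable
#' derivatives; the band-limited curve makes curvature (and hence
#' convexity classification) well posed, and places boundary samples at
#' sub-pixel positions for the inscribed-circle search.
#'
#' The number of retained harmonics adapts to how much of the boundary is
#' axis-aligned straight runs: per axis, straightness is the fraction of
#' segments with zero first-difference, and K = max(10, ceil(N * (0.02 +
#' 0.08 * straightness))). Straight edges need many harmonics to avoid
#' corner rounding; smoothly curved boundaries need few to suppress the
#' half-pixel staircase.
#'
#' @param contour A `pore_contour`.
#' @param density Resampling factor over the original point count
#'   (default 20).
#' @param kept_harmonics Optional fixed harmonic count per axis,
#'   overriding the adaptive rule (length 1 or 2).
#' @return A `smoothed_contour`: list with `x`, `y` (sample positions),
#'   `dx`, `dy`, `ddx`, `ddy` (exact derivatives of the band-limited
#'   curve w.r.t. arc-length parameter), `kept_harmonics`, `source_id`,
#'   `n`. Contours with fewer than 8 points fall back to plain linear
#'   interpolation (with finite-difference derivatives).
#' @export
smooth_contour <- function(contour, density = 20, kept_harmonics = NULL) {
  stopifnot(inherits(contour, "pore_contour"))
  pts <- contour$points
  n0 <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  L <- sum(seg)
  N <- max(16L, as.integer(density) * n0)
  tt <- cumsum(c(0, seg))
  s_out <- seq(0, L, length.out = N + 1L)[-(N + 1L)]
  xi <- approx(tt, closed[, 1], xout = s_out, rule = 2)$y
  yi <- approx(tt, closed[, 2], xout = s_out, rule = 2)$y

  if (n0 < 8L) {
    message("contour #", contour$id, " has fewer than 8 points; linear interpolation only")
    dx <- fd_periodic(xi); dy <- fd_periodic(yi)
    ddx <- fd_periodic(dx); ddy <- fd_periodic(dy)
    return(structure(list(x = xi, y = yi, dx = dx, dy = dy, ddx = ddx, ddy = ddy,
                          kept_harmonics = c(NA_integer_, NA_integer_),
                          source_id = contour$id, n = N, smoothing = "linear"),
                     class = "smoothed_contour"))
  }

  if (is.null(kept_harmonics)) {
    # Cutoff wavelength (px of arc) adapts to the fraction of the
    # boundary made of genuinely straight runs: straight edges are the
    # hardest to reproduce and need a short cutoff, while curved
    # boundaries carry only half-pixel staircase at short wavelengths
    # and tolerate a long one. A run only counts as straight when it is
    # longer than the longest staircase tread a circle of the same
    # perimeter would produce (~ 2 sqrt(L/pi)).
    s <- straight_fraction(pts)
    lambda <- 12 - 8 * s
    K <- rep(pmax(8L, as.integer(ceiling(L / lambda))), 2L)
  } else {
    K <- as.integer(rep_len(kept_harmonics, 2L))
  }
  K <- pmin(K, N %/% 2L - 1L)

  sm_x <- fourier_lowpass(xi, K[1])
  sm_y <- fourier_lowpass(yi, K[2])
  h <- L / N  # arc-length step of the parameter grid
  structure(list(x = sm_x$f, y = sm_y$f,
                 dx = sm_x$d1 / h, dy = sm_y$d1 / h,
                 ddx = sm_x$d2 / h^2, ddy = sm_y$d2 / h^2,
                 kept_harmonics = K, source_id = contour$id, n = N,
                 smoothing = "fourier"),
            class = "smoothed_contour")
}

# low-pass a periodic signal with a Gaussian roll-off at harmonic K
# (hard truncation rings on straight runs, which corrupts curvature
# signs); returns the filtered signal and its exact first/second
# derivatives w.r.t. sample index
fourier_lowpass <- function(v, K) {
  N <- length(v)
  X <- fft(v)
  k <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1))    # signed harmonic index
  X <- X * exp(-0.5 * (k / K)^2)
  X[abs(k) > 3 * K] <- 0
  om <- 2i * pi * k / N
  if (N %% 2L == 0L) om[N %/% 2 + 1L] <- 0        # drop unpaired Nyquist in derivatives
  f  <- Re(fft(X, inverse = TRUE)) / N
  d1 <- Re(fft(X * om, inverse = TRUE)) / N
  d2 <- Re(fft(X * om^2, inverse = TRUE)) / N
  list(f = f, d1 = d1, d2 = d2)
}

# fraction of the closed chain's length lying in maximal same-direction
# runs longer than the staircase-tread bound 2*sqrt(L/pi)
straight_fraction <- function(pts) {
  closed <- rbind(pts, pts[1, ])
  d <- cbind(diff(closed[, 1]), diff(closed[, 2]))
  len <- sqrt(d[, 1]^2 + d[, 2]^2)
  L <- sum(len)
  r <- rle(paste(d[, 1], d[, 2]))
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  runlen <- vapply(seq_along(starts),
                   function(i) sum(len[starts[i]:ends[i]]), numeric(1))
  thr <- max(8, 2 * sqrt(L / pi))
  sum(runlen[runlen >= thr]) / L
}

fd_periodic <- function(v) {
  n <- length(v)
  (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / 2
}

#' @export
print.smoothed_contour <- function(x, ...) {
  cat(sprintf("smoothed_contour of pore #%d: %d samples, harmonics (%s, %s), %s smoothing\n",
              x$source_id, x$n, x$kept_harmonics[1], x$kept_harmonics[2], x$smoothing))
  invisible(x)
}

#' Sampled points of a smoothed contour
#' @param sc A `smoothed_contour`.
#' @return n x 2 matrix of (x, y).
#' @export
smoothed_points <- function(sc) cbind(x = sc$x, y = sc$y)
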