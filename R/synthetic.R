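#' Rasterise a region defined by an inside test
#'
#' A pixel belongs to the shape iff its centre lies inside the continuous
#' region -- the unbiased rasterisation rule used by all generators, which
#' keeps pixel-count areas centred on the analytic area. Generators are
#' fully deterministic: rasterisations are bit-stable across runs.
#'
#' @param canvas c(height, width) px.
#' @param inside function(x, y) -> logical, vectorised over pixel-centre
#'   coordinates.
#' @param scale Micrometres per pixel recorded on the mask.
#' @return A [binary_mask()].
#' @keywords internal
rasterise <- function(canvas, inside, scale = 1) {
  H <- canvas[1]; W <- canvas[2]
  x <- matrix(rep(seq_len(W), each = H), H, W)
  y <- matrix(rep(seq_len(H), times = W), H, W)
  binary_mask(matrix(inside(as.numeric(x), as.numeric(y)), H, W),
              scale = scale, provenance = "synthetic")
}

#' Synthetic pore from overlapping circles
#'
#' Builds complex pore shapes as the rasterised union of filled circles,
#' emulating irregular pores while retaining an exact ground truth: as
#' long as no satellite circle overlap enlarges the maximal inscribed
#' disc, the true largest-inscribed-circle radius equals the largest
#' constituent radius.
#'
#' @param circles data.frame or matrix with columns cx, cy, r (px).
#' @param canvas c(height, width) px.
#' @param scale Micrometres per pixel.
#' @return List with `mask` (a [binary_mask()]) and `truth` (list with
#'   `max_inscribed_radius` = largest constituent radius and its
#'   derivation).
#' @export
make_overlapping_circles <- function(circles, canvas, scale = 1) {
  circles <- as.data.frame(circles)
  stopifnot(nrow(circles) >= 1L, all(c("cx", "cy", "r") %in% names(circles)))
  if (any(circles$r <= 0)) stop("circle radii must be positive")
  margin_ok <- circles$cx - circles$r >= 2 & circles$cx + circles$r <= canvas[2] - 1 &
               circles$cy - circles$r >= 2 & circles$cy + circles$r <= canvas[1] - 1
  if (!all(margin_ok)) stop("all circles must fit inside the canvas with a 2 px margin")
  mask <- rasterise(canvas, function(x, y) {
    inside <- rep(FALSE, length(x))
    for (i in seq_len(nrow(circles)))
      inside <- inside | ((x - circles$cx[i])^2 + (y - circles$cy[i])^2 <= circles$r[i]^2)
    inside
  }, scale)
  list(mask = mask,
       truth = list(max_inscribed_radius = max(circles$r),
                    derivation = "largest constituent circle radius (overlaps do not enlarge the inscribed disc)"))
}

#' The eight reference overlapping-circle pore configurations
#'
#' Fixture specs whose largest constituent radii are 27, 37, 40, 55, 63,
#' 70, 100 and 200 px; satellites overlap the main circle at 60--80% of
#' the radius sum in centre distance, placed so the union never enlarges
#' the maximal inscribed disc. Ground truth for each is the largest
#' radius.
#'
#' @return Named list of specs, each with `circles` and `canvas` suitable
#'   for [make_overlapping_circles()].
#' @export
reference_pore_specs <- function() {
  mk <- function(R, sats) {
    cx <- 2 * R + 10; cy <- 2 * R + 10
    circles <- data.frame(cx = cx, cy = cy, r = R)
    for (s in sats) {
      d <- (R + s$r) * s$f
      circles <- rbind(circles, data.frame(cx = cx + d * cos(s$th),
                                           cy = cy + d * sin(s$th), r = s$r))
    }
    side <- ceiling(2 * (2 * R + 10))
    list(circles = circles, canvas = c(side, side))
  }
  radii <- c(27, 37, 40, 55, 63, 70, 100, 200)
  sats_of <- function(R) list(
    list(r = 0.45 * R, th = 0.3, f = 0.75),
    list(r = 0.35 * R, th = 2.2, f = 0.70),
    list(r = 0.5 * R,  th = 4.1, f = 0.80)
  )
  out <- lapply(radii, function(R) mk(R, sats_of(R)))
  names(out) <- paste0("r", radii)
  out
}

#' Filled regular polygon, rectangle or circle with analytic truths
#'
#' Generates the validation shapes for the circularity and aspect-ratio
#' shape factors. Ground truths from closed forms: circularity
#' `4*pi*A/P^2` with exact A and P; aspect ratio 1 for circle and square,
#' 0.5 for the 1 x 2 rectangle, sqrt(3)/2 for the equilateral triangle
#' and the regular hexagon.
#'
#' @param shape One of "circle", "square", "rectangle", "triangle",
#'   "hexagon", or an integer n >= 3 for a regular n-gon.
#' @param size Circle radius; polygon side length; for "rectangle" the
#'   short side (long side is `2 * size`), px.
#' @param canvas c(height, width); default sized to fit.
#' @param rotation Rotation of the shape in degrees (default 0).
#' @param scale Micrometres per pixel.
#' @return List with `mask` and `truth` (circularity, aspect_ratio,
#'   area, perimeter, derivation).
#' @export
make_polygon <- function(shape, size, canvas = NULL, rotation = 0, scale = 1) {
  tr <- polygon_truth(shape, size)
  if (is.character(shape) && shape == "circle") {
    R <- size
    if (is.null(canvas)) canvas <- rep(ceiling(2 * R + 8), 2L)
    mask <- rasterise(canvas, function(x, y)
      (x - canvas[2] / 2)^2 + (y - canvas[1] / 2)^2 <= R^2, scale)
    return(list(mask = mask, truth = tr))
  }
  v <- polygon_vertices(shape, size)
  th <- rotation * pi / 180
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  v <- v %*% t(Rm)
  ext <- apply(v, 2, function(z) diff(range(z)))
  if (is.null(canvas)) canvas <- ceiling(rev(ext) + 10)
  ctr <- c(canvas[2] / 2, canvas[1] / 2)
  bb_mid <- apply(v, 2, function(z) mean(range(z)))   # centre the bounding box
  v <- sweep(v, 2, bb_mid) + matrix(ctr, nrow(v), 2, byrow = TRUE)
  mask <- rasterise(canvas, function(x, y) point_in_polygon(cbind(x, y), v), scale)
  list(mask = mask, truth = tr)
}

polygon_vertices <- function(shape, size) {
  if (is.numeric(shape)) {             # regular n-gon with side `size`
    n <- as.integer(shape)
    if (n < 3L) stop("a polygon needs n >= 3")
    Rc <- size / (2 * sin(pi / n))     # circumradius from side length
    th <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(Rc * cos(th), Rc * sin(th)))
  }
  switch(shape,
    square = cbind(c(0, size, size, 0), c(0, 0, size, size)),
    rectangle = cbind(c(0, 2 * size, 2 * size, 0), c(0, 0, size, size)),
    triangle = polygon_vertices(3L, size),
    hexagon = polygon_vertices(6L, size),
    stop("unknown shape: ", shape))
}

#' Closed-form shape-factor truths for the validation shapes
#'
#' @inheritParams make_polygon
#' @return List with `circularity`, `aspect_ratio`, `area`, `perimeter`,
#'   `derivation`.
#' @export
polygon_truth <- function(shape, size = 1) {
  s <- size
  if (is.numeric(shape)) {
    n <- as.integer(shape)
    A <- n * s^2 / (4 * tan(pi / n)); P <- n * s
    # closed-form AR is only quoted for the named validation shapes
    ar <- switch(as.character(n), "3" = sqrt(3) / 2, "4" = 1, "6" = sqrt(3) / 2, NA_real_)
    return(list(circularity = 4 * pi * A / P^2, aspect_ratio = ar,
                area = A, perimeter = P,
                derivation = sprintf("regular %d-gon closed form", n)))
  }
  switch(shape,
    circle = list(circularity = 1, aspect_ratio = 1,
                  area = pi * s^2, perimeter = 2 * pi * s,
                  derivation = "circle: 4*pi*(pi r^2)/(2 pi r)^2 = 1"),
    square = list(circularity = pi / 4, aspect_ratio = 1,
                  area = s^2, perimeter = 4 * s,
                  derivation = "square: 4*pi*s^2/(4s)^2 = pi/4 = 0.785"),
    rectangle = list(circularity = 4 * pi * 2 * s^2 / (6 * s)^2, aspect_ratio = 0.5,
                     area = 2 * s^2, perimeter = 6 * s,
                     derivation = "1x2 rectangle: 8*pi*s^2/(6s)^2 = 2*pi/9 = 0.698"),
    triangle = list(circularity = 4 * pi * (sqrt(3) / 4) / 9, aspect_ratio = sqrt(3) / 2,
                    area = sqrt(3) / 4 * s^2, perimeter = 3 * s,
                    derivation = "equilateral triangle: pi*sqrt(3)/9 = 0.605; AR = height/side = sqrt(3)/2"),
    hexagon = list(circularity = pi * sqrt(3) / 6, aspect_ratio = sqrt(3) / 2,
                   area = 3 * sqrt(3) / 2 * s^2, perimeter = 6 * s,
                   derivation = "regular hexagon: pi*sqrt(3)/6 = 0.907; AR = across-flats/across-corners = sqrt(3)/2"),
    stop("unknown shape: ", shape))
}

#' Half perimeter of an ellipse by the binomial infinite series
#'
#' Half the complete elliptic perimeter of an ellipse with semi-axes a
#' and b, from the hypergeometric series
#' `P = pi (a+b) * sum_n [ C(1/2, n) h^n ]^2`, `h = ((a-b)/(a+b))^2`,
#' truncated when the term drops below 1e-10 relative.
#'
#' @param a,b Semi-axes (> 0), px.
#' @return Half perimeter, px.
#' @export
ellipse_half_perimeter <- function(a, b) {
  if (a <= 0 || b <= 0) stop("semi-axes must be positive")
  h <- ((a - b) / (a + b))^2
  total <- 1
  coef <- 1       # C(1/2, n) running product
  term <- 1
  n <- 0
  while (abs(term) > 1e-10 * total) {
    n <- n + 1
    coef <- coef * (1.5 - n) / n
    term <- (coef^2) * h^n
    total <- total + term
    if (n > 10000) break
  }
  pi * (a + b) * total / 2
}

#' Analytic waviness of the horseshoe validation shape
#'
#' The horseshoe is the region between an outer semicircle of radius `a`
#' and an inner half-ellipse with semi-axes (a, b) on the same flat edge.
#' Its boundary is the convex outer arc (length pi*a) plus the concave
#' inner arc (the ellipse half perimeter), so
#' `waviness = pi*a / (pi*a + ellipse_half_perimeter(a, b))`.
#'
#' @inheritParams ellipse_half_perimeter
#' @return Waviness in (0.5, 1).
#' @export
horseshoe_waviness <- function(a, b) {
  if (!(b < a)) stop("need inner semi-axis b < outer radius a")
  pi * a / (pi * a + ellipse_half_perimeter(a, b))
}

#' Rasterised horseshoe (half-ellipse annulus)
#'
#' The waviness validation geometry: simple polygons have no concave
#' arcs, so waviness is exercised on the region between an outer
#' semicircle of radius `a` and an inner half-ellipse with semi-axes
#' (a, b). The inner arc is the concave portion of the boundary, the
#' outer arc the convex portion.
#'
#' @param a Outer radius, px.
#' @param b Inner half-ellipse semi-minor axis, px (0 < b < a).
#' @param canvas c(height, width); default sized to fit.
#' @param rotation Rotation of the shape in degrees (default 0).
#' @param scale Micrometres per pixel.
#' @return List with `mask` and `truth` (`waviness` from
#'   [horseshoe_waviness()]).
#' @export
make_horseshoe <- function(a, b, canvas = NULL, rotation = 0, scale = 1) {
  if (!(b > 0 && b < a)) stop("need 0 < b < a")
  if (is.null(canvas)) {
    side <- ceiling(2 * a + 10)
    canvas <- if (rotation == 0) c(ceiling(a + 10), side) else c(side, side)
  }
  cx <- canvas[2] / 2
  cy <- if (rotation == 0) canvas[1] - 4.5 else canvas[1] / 2
  th <- rotation * pi / 180
  mask <- rasterise(canvas, function(x, y) {
    x0 <- x - cx; y0 <- cy - y                 # y up, origin at arc centre
    u <- cos(th) * x0 + sin(th) * y0
    v <- -sin(th) * x0 + cos(th) * y0          # v >= 0 above the flat edge
    v >= 0 & (u^2 + v^2 <= a^2) & (u^2 / a^2 + v^2 / b^2 >= 1)
  }, scale)
  list(mask = mask,
       truth = list(waviness = horseshoe_waviness(a, b),
                    derivation = "pi*a / (pi*a + half ellipse perimeter(a, b))"))
}

#' Square mesh grid of square holes
#'
#' Analogue of a TEM support grid: a square lattice of square holes of
#' side `pitch - bar_width` separated by bars of width `bar_width`. Used
#' to validate size statistics on a field of identical pores.
#'
#' @param pitch Lattice pitch, px.
#' @param bar_width Bar width, px (< pitch).
#' @param canvas c(height, width) px.
#' @param scale Micrometres per pixel.
#' @return List with `mask` and `truth` (`hole_side`,
#'   `eq_diameter = 2 * side / sqrt(pi) * scale`).
#' @export
make_mesh_grid <- function(pitch, bar_width, canvas, scale = 1) {
  if (!(bar_width > 0 && bar_width < pitch)) stop("need 0 < bar_width < pitch")
  hole <- pitch - bar_width
  mask <- rasterise(canvas, function(x, y) {
    ((x - 1) %% pitch) >= bar_width & ((y - 1) %% pitch) >= bar_width &
      x <= (canvas[2] %/% pitch) * pitch & y <= (canvas[1] %/% pitch) * pitch
  }, scale)
  list(mask = mask,
       truth = list(hole_side = hole,
                    eq_diameter_um = 2 * hole / sqrt(pi) * scale,
                    derivation = "square hole: d_eq = 2*side/sqrt(pi)"))
}
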