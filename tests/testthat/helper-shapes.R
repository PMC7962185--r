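# Shared fixtures, built once per test run and memoised: rasterisation and
# contour extraction of the large validation shapes dominate the suite's
# cost otherwise.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# contour of a generated shape
shape_contour <- function(name, gen) {
  fixture(paste0("contour_", name), function() extract_contours(gen()$mask)[[1]])
}

circle_contour <- function(r) {
  shape_contour(paste0("circle", r), function() make_polygon("circle", r))
}

horseshoe_contour <- function(b, a = 240) {
  shape_contour(paste0("hs", a, "_", b), function() make_horseshoe(a, b))
}

# a pore_contour built directly from analytic polygon vertices (continuous
# input, no rasterisation)
analytic_contour <- function(pts) {
  if (poremorph:::signed_area(pts) < 0) pts <- pts[c(1, nrow(pts):2), ]
  structure(list(points = pts, id = 1L, label = 1L,
                 area_px = shoelace_area(pts),
                 area_shoelace = shoelace_area(pts),
                 perimeter = perimeter_length(pts),
                 centroid = poremorph:::polygon_centroid(pts),
                 touches_border = FALSE),
            class = "pore_contour")
}

# dense analytic circle boundary
analytic_circle <- function(R, n = 720, centre = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  analytic_contour(cbind(centre[1] + R * cos(th), centre[2] + R * sin(th)))
}

# printed reference values (algorithm-measured) for the validation shapes
printed_table2 <- list(
  circle = list(circ = 0.999, ar = 1),
  square = list(circ = 0.790, ar = 1),
  rectangle = list(circ = 0.702, ar = 0.5),
  triangle = list(circ = 0.610, ar = 0.8696),
  hexagon = list(circ = 0.90981, ar = 0.86635)
)
table3_calculated <- c("2" = 0.6094, "5" = 0.6023, "10" = 0.5851, "15" = 0.5647,
                       "20" = 0.5430, "25" = 0.5212, "28" = 0.5084)
table3_measured <- c("2" = 0.6226, "5" = 0.5977, "10" = 0.5906, "15" = 0.5693,
                     "20" = 0.5447, "25" = 0.5239, "28" = 0.5112)

# waviness exactly as measure_pore computes it (dedicated smoothing band)
measure_pore_waviness <- function(pc) {
  K_w <- max(8L, as.integer(ceiling(pc$perimeter / 40)))
  waviness(smooth_contour(pc, kept_harmonics = K_w))
}
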