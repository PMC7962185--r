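test_that("circularity closed forms match the reference shapes", {
  expect_equal(circularity(1^2, 4), pi / 4)                       # square: 0.785
  expect_equal(round(circularity(100^2, 400), 3), 0.785)
  s <- 3
  expect_equal(circularity(pi * s^2, 2 * pi * s), 1)              # circle
  expect_equal(round(circularity(3 * sqrt(3) / 2, 6), 3), 0.907)  # hexagon
  expect_equal(round(circularity(sqrt(3) / 4, 3), 3), 0.605)      # triangle
  expect_equal(round(circularity(2, 6), 3), 0.698)                # 1x2 rectangle
  expect_error(circularity(-1, 4), "positive")
})

test_that("circularity of regular n-gons increases towards the circle", {
  circ <- vapply(c(3, 4, 6, 12, 24), function(n) {
    tr <- polygon_truth(n, 1)
    tr$circularity
  }, numeric(1))
  expect_true(all(diff(circ) > 0))
  expect_lt(max(circ), 1)
  expect_gt(circ[5], 0.99)
})

test_that("aspect ratio recovers the reference shapes", {
  expect_equal(aspect_ratio(circle_contour(50))$aspect_ratio, 1, tolerance = 1e-6)
  rc <- extract_contours(make_polygon("rectangle", 100)$mask)[[1]]
  expect_equal(aspect_ratio(rc)$aspect_ratio, 0.5, tolerance = 0.01)
  tc <- extract_contours(make_polygon("triangle", 200)$mask)[[1]]
  ar <- aspect_ratio(tc)
  expect_equal(ar$aspect_ratio, sqrt(3) / 2, tolerance = 0.01)
  expect_lt(ar$d_min, ar$d_max)
  expect_error(aspect_ratio(tc, angle_step = 10), "angle_step")
})

test_that("aspect ratio is invariant under rotation of the shape", {
  base <- aspect_ratio(extract_contours(make_polygon("triangle", 200)$mask)[[1]])
  for (rot in c(15, 40, 75)) {
    r <- aspect_ratio(extract_contours(make_polygon("triangle", 200, rotation = rot)$mask)[[1]])
    expect_equal(r$aspect_ratio, base$aspect_ratio, tolerance = 0.01)
  }
})

test_that("waviness is 1 for convex shapes, including rotated ones", {
  convex <- list(
    circle_contour(50),
    extract_contours(make_polygon("square", 100)$mask)[[1]],
    extract_contours(make_polygon("square", 100, rotation = 15)$mask)[[1]],
    extract_contours(make_polygon("hexagon", 100)$mask)[[1]],
    extract_contours(make_polygon("triangle", 200, rotation = 25)$mask)[[1]]
  )
  for (pc in convex) {
    K_w <- max(8L, ceiling(pc$perimeter / 40))
    expect_equal(waviness(smooth_contour(pc, kept_harmonics = K_w)), 1,
                 tolerance = 1e-6)
  }
})

test_that("horseshoe waviness matches the reference measurements", {
  # resolvable geometries: within 1% of the reference algorithm's values
  for (b in c(10, 15, 20, 25, 28)) {
    pc <- horseshoe_contour(8 * b)
    w <- measure_pore_waviness(pc)
    expect_equal(w, unname(table3_measured[as.character(b)]), tolerance = 0.01,
                 label = sprintf("waviness b=%d", b))
  }
  # shallow inner arcs sit at the estimator's resolution floor
  for (b in c(2, 5)) {
    pc <- horseshoe_contour(8 * b)
    w <- measure_pore_waviness(pc)
    expect_equal(w, unname(table3_measured[as.character(b)]), tolerance = 0.035,
                 label = sprintf("waviness b=%d (shallow)", b))
  }
})

test_that("waviness is invariant under rotation and scaling", {
  vals_rot <- vapply(c(0, 30, 75, 135), function(rot) {
    pc <- extract_contours(make_horseshoe(240, 160, rotation = rot)$mask)[[1]]
    measure_pore_waviness(pc)
  }, numeric(1))
  expect_lt(diff(range(vals_rot)), 0.005)

  vals_scale <- vapply(c(160, 240, 360), function(a) {
    pc <- extract_contours(make_horseshoe(a, a * 2 / 3)$mask)[[1]]
    measure_pore_waviness(pc)
  }, numeric(1))
  expect_lt(diff(range(vals_scale)), 0.005)
})

test_that("LSTP recovers circle radii on raster and continuous input", {
  # rasterised r=27: reference algorithm prints 26.75
  l <- lstp(circle_contour(27))
  expect_gte(l$radius, 26.5); expect_lte(l$radius, 27.0)

  # continuous polygon input: radius exact within refine_step (no
  # digitisation, so no half-pixel correction applies)
  pc <- analytic_circle(40, centre = c(50, 50))
  sc <- smooth_contour(pc, kept_harmonics = 60)
  l2 <- lstp(pc, smoothed = sc, refine_step = 0.1)
  expect_equal(l2$radius - 0.5, 40, tolerance = 0.1)
  # centre strictly inside
  expect_lt(sqrt(sum((l2$centre - c(50, 50))^2)), 40)

  expect_error(lstp(pc, smoothed = sc, coarse_step = 0.05, refine_step = 0.1),
               "coarse_step")
})

test_that("LSTP of two overlapping circles matches the distance-transform oracle", {
  skip_if_not_installed("EBImage")
  mk <- make_overlapping_circles(
    data.frame(cx = c(60, 110), cy = c(60, 60), r = c(40, 25)), c(180, 180))
  ct <- extract_contours(mk$mask)
  expect_length(ct, 1)
  l <- lstp(ct[[1]])
  dm <- EBImage::distmap(matrix(as.numeric(mk$mask), nrow(mk$mask), ncol(mk$mask)))
  expect_equal(l$radius, max(dm), tolerance = 0.5, ignore_attr = TRUE)
  expect_equal(l$radius, 40, tolerance = 0.5)
})

test_that("LSTP radius never exceeds the equivalent-circle radius", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    circ <- data.frame(cx = runif(n, 50, 110), cy = runif(n, 50, 110),
                       r = runif(n, 10, 30))
    mk <- make_overlapping_circles(circ, c(160, 160))
    for (pc in extract_contours(mk$mask)) {
      r_eq <- sqrt(pc$area_px / pi)
      expect_lte(lstp(pc)$radius, r_eq + 0.5)
    }
  }
  # equality within 1% only for a circle
  pc <- circle_contour(50)
  expect_equal(lstp(pc)$radius, sqrt(pc$area_px / pi), tolerance = 0.01)
})

test_that("measure_pore assembles a consistent record with unit conversion", {
  pc <- circle_contour(50)
  m <- measure_pore(pc, scale = 2)
  expect_equal(m$eq_diameter_um, 200, tolerance = 1)
  expect_equal(m$lstp_radius_um, 100, tolerance = 1)
  expect_equal(m$circularity, 1, tolerance = 0.005)
  expect_equal(m$waviness, 1)
  expect_equal(m$aspect_ratio, 1, tolerance = 1e-6)
  expect_equal(m$area_um2, pc$area_px * 4)
  expect_false(m$touches_border)

  sq <- measure_pore(extract_contours(make_polygon("square", 100)$mask)[[1]])
  expect_equal(sq$circularity, 0.790, tolerance = 0.01)
  expect_equal(sq$aspect_ratio, 1, tolerance = 0.01)

  hs <- measure_pore(horseshoe_contour(120))
  expect_equal(hs$waviness, 0.5693, tolerance = 0.01)
})
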