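test_that("shoelace area and perimeter match closed forms and a triangulation oracle", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(shoelace_area(sq), 1)
  expect_equal(perimeter_length(sq), 4)
  rect <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  expect_equal(shoelace_area(rect), 2)
  expect_equal(perimeter_length(rect), 6)
  expect_error(shoelace_area(sq[1:2, ]), "3 points")

  # random star-convex polygons: fan triangulation from the centre is exact
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    # jittered regular angles keep every gap < pi, so the polygon is
    # star-shaped about the origin and the fan from the origin is exact
    th <- 2 * pi * (0:(n - 1)) / n + runif(n, 0, pi / n)
    r <- runif(n, 1, 4)
    pts <- cbind(r * cos(th), r * sin(th))
    fan <- sum(vapply(seq_len(n), function(i) {
      j <- i %% n + 1
      abs(pts[i, 1] * pts[j, 2] - pts[j, 1] * pts[i, 2]) / 2
    }, numeric(1)))
    expect_equal(shoelace_area(pts), fan, tolerance = 1e-12)
  }
})

test_that("porosity is the exact pore-pixel fraction", {
  m <- matrix(FALSE, 10, 10); m[1:5, ] <- TRUE
  expect_equal(porosity(binary_mask(m)), 0.5)
  expect_equal(porosity(binary_mask(matrix(TRUE, 3, 3))), 1)
  set.seed(22)
  k <- 37
  m2 <- matrix(FALSE, 15, 20); m2[sample(300, k)] <- TRUE
  expect_equal(porosity(binary_mask(m2)), k / 300)
})

test_that("equivalent circular diameter follows d = 2 s sqrt(A/pi)", {
  expect_equal(equivalent_circular_diameter(pi * 100, 1), 20)
  expect_equal(equivalent_circular_diameter(pi * 100, 0.5), 10)
  expect_error(equivalent_circular_diameter(-1), "positive")
  pc <- circle_contour(27)
  expect_equal(equivalent_circular_diameter(pc$area_px, 1), 54, tolerance = 0.01)
})

test_that("contour extraction finds external contours with areas matching pixel counts", {
  p <- make_polygon("circle", 50)
  ct <- extract_contours(p$mask)
  expect_length(ct, 1)
  expect_equal(ct[[1]]$area_px, sum(p$mask), tolerance = 1e-12)
  expect_equal(ct[[1]]$area_px, pi * 50^2, tolerance = 0.01)

  # two disjoint 10x10 squares
  m <- matrix(FALSE, 40, 40)
  m[5:14, 5:14] <- TRUE; m[25:34, 25:34] <- TRUE
  ct2 <- extract_contours(binary_mask(m))
  expect_length(ct2, 2)
  expect_equal(vapply(ct2, `[[`, numeric(1), "area_px"), c(100, 100))
  # deterministic scan-order ids: topmost-leftmost first
  expect_lt(ct2[[1]]$centroid[2], ct2[[2]]$centroid[2])

  # ring: pore with an interior solid island has exactly one external contour
  xs <- outer(rep(1, 60), 1:60); ys <- outer(1:60, rep(1, 60))
  d2 <- (xs - 30)^2 + (ys - 30)^2
  ring <- d2 <= 20^2 & d2 >= 8^2
  ct3 <- extract_contours(binary_mask(ring))
  expect_length(ct3, 1)
  # filled area includes the enclosed hole
  expect_lt(abs(ct3[[1]]$area_px - sum(d2 <= 20^2)), 2)

  expect_length(extract_contours(binary_mask(matrix(FALSE, 5, 5))), 0)
})

test_that("contours are counter-clockwise and consistent with porosity", {
  set.seed(23)
  circ <- data.frame(cx = runif(4, 30, 90), cy = runif(4, 30, 90), r = runif(4, 8, 15))
  mk <- make_overlapping_circles(circ, c(120, 120))
  ct <- extract_contours(mk$mask, min_area = 0)
  for (pc in ct) expect_gt(poremorph:::signed_area(pc$points), 0)
  # total filled pixel area >= pore pixel count (holes), equal if no holes
  expect_gte(sum(vapply(ct, `[[`, numeric(1), "area_px")) + 1e-9,
             sum(mk$mask))
})

test_that("smoothing tracks a rasterised circle to sub-pixel accuracy", {
  pc <- circle_contour(50)
  raw <- pc$points
  ctr <- colMeans(raw)
  r_raw <- sqrt((raw[, 1] - ctr[1])^2 + (raw[, 2] - ctr[2])^2)
  sc <- smooth_contour(pc)
  sp <- smoothed_points(sc)
  r_sm <- sqrt((sp[, 1] - ctr[1])^2 + (sp[, 2] - ctr[2])^2)
  # every smoothed sample within half a pixel of the raster boundary radius
  expect_lt(max(abs(r_sm - mean(r_raw))), 0.5)
  # 20x sample density
  expect_gte(sc$n, 20 * nrow(raw))
})

test_that("smoothing preserves square corners and perimeter", {
  q <- make_polygon("square", 100)
  pc <- extract_contours(q$mask)[[1]]
  sc <- smooth_contour(pc)
  sp <- smoothed_points(sc)
  expect_equal(perimeter_length(sp), 400, tolerance = 0.03)
  raw <- pc$points
  corners <- raw[c(which.min(raw[, 1] + raw[, 2]), which.max(raw[, 1] - raw[, 2]),
                   which.max(raw[, 1] + raw[, 2]), which.min(raw[, 1] - raw[, 2])), ]
  for (i in 1:4) {
    dev <- min(sqrt((sp[, 1] - corners[i, 1])^2 + (sp[, 2] - corners[i, 2])^2))
    expect_lt(dev, 2)
  }
})

test_that("an already-smooth ellipse is a near fixed point of smoothing", {
  th <- 2 * pi * (0:359) / 360
  pc <- analytic_contour(cbind(80 * cos(th), 50 * sin(th)))
  sp <- smoothed_points(smooth_contour(pc, kept_harmonics = 60))
  d <- poremorph:::.min_dist_to_polyline_cpp(sp, pc$points)
  expect_lt(max(d), 0.1)
})

test_that("smoothing preserves area and centroid", {
  for (pc in list(circle_contour(50), horseshoe_contour(160))) {
    sp <- smoothed_points(smooth_contour(pc))
    expect_equal(shoelace_area(sp), pc$area_shoelace, tolerance = 0.02)
    shift <- poremorph:::polygon_centroid(sp) - poremorph:::polygon_centroid(pc$points)
    expect_lt(max(abs(shift)), 0.2)
  }
})

test_that("more harmonics track the raw polygon more closely", {
  pc <- circle_contour(27)
  devs <- vapply(c(8, 16, 32, 64), function(K) {
    sp <- smoothed_points(smooth_contour(pc, kept_harmonics = K))
    max(poremorph:::.min_dist_to_polyline_cpp(sp, pc$points))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("short contours fall back to linear interpolation with a message", {
  m <- matrix(FALSE, 8, 8); m[3:4, 3:5] <- TRUE
  pc <- extract_contours(binary_mask(m), min_area = 1)[[1]]
  expect_message(sc <- smooth_contour(pc), "fewer than 8 points")
  expect_identical(sc$smoothing, "linear")
})
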