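test_that("circle limit has constant curvature and zero excess", {
  curv <- ellipse_curvature(20, 20, 128)
  expect_equal(max(curv$curvature), 1 / 20, tolerance = 1e-6)
  expect_equal(min(curv$curvature), 1 / 20, tolerance = 1e-6)
  prof <- attachment_profile(curv, kon_P = 0.05, alpha = 2)
  expect_equal(prof$kon_P, rep(0.05, 128), tolerance = 1e-9)
})

test_that("ellipse curvature extrema match the closed forms", {
  a <- 25
  b <- 15
  curv <- ellipse_curvature(a, b, 512)
  expect_equal(max(curv$curvature), a / b^2, tolerance = 1e-4)
  expect_equal(min(curv$curvature), b / a^2, tolerance = 1e-4)
  expect_equal(attr(curv, "baseline"), b / a^2)
  # poles sit at 0 and half the circumference
  L <- attr(curv, "circumference")
  peaks <- curv$position[curv$curvature > 0.999 * max(curv$curvature)]
  expect_true(any(abs(peaks) < L / 50 | abs(peaks - L) < L / 50))
  expect_true(any(abs(peaks - L / 2) < L / 50))
})

test_that("total turning of closed convex contours is 2*pi", {
  turn <- function(curv) sum(curv$curvature) * diff(curv$position[1:2])
  # smooth contours integrate to printed precision
  expect_equal(turn(ellipse_curvature(25, 15, 256)), 2 * pi, tolerance = 1e-4)
  expect_equal(turn(ellipse_curvature(30, 10, 256)), 2 * pi, tolerance = 1e-4)
  expect_equal(
    turn(embryo_triangle_curvature(110, c(0.14, 0.13, 0.119), 3, 256)),
    2 * pi,
    tolerance = 1e-4
  )
  # the rounded triangle's curvature is discontinuous: quadrature error is
  # first order in the grid step and shrinks with refinement
  e1 <- abs(turn(triangle_curvature(40, 5, 256)) - 2 * pi)
  e2 <- abs(turn(triangle_curvature(40, 5, 2048)) - 2 * pi)
  expect_lt(e1 / (2 * pi), 5e-3)
  expect_lt(e2, e1)
})

test_that("rounded-triangle geometry follows the closed-form construction", {
  side <- 40
  r <- 5
  curv <- triangle_curvature(side, r, 512)
  # perimeter: three shortened flats plus three arcs of total turning 2*pi
  expect_equal(
    attr(curv, "circumference"),
    3 * (side - 2 * sqrt(3) * r) + 2 * pi * r,
    tolerance = 1e-9
  )
  # each corner arc subtends 2*pi/3: arc length fraction of the perimeter
  on_arc <- mean(curv$curvature > 0)
  expect_equal(on_arc, 2 * pi * r / attr(curv, "circumference"), tolerance = 0.02)
  expect_equal(attr(curv, "baseline"), 0)
  # impossible rounding is rejected
  expect_error(triangle_curvature(40, 12, 128), "too large")
  expect_error(triangle_curvature(40, 0, 128), "positive")
})

test_that("near-maximal rounding degenerates to the inscribed circle", {
  r <- 11.5 # just under side / (2*sqrt(3)) = 11.547
  curv <- triangle_curvature(40, r, 256)
  # the flats have nearly vanished: almost every point lies on an arc, and
  # the perimeter approaches the inscribed-circle circumference
  expect_gt(mean(curv$curvature == 1 / r), 0.98)
  expect_equal(attr(curv, "circumference"), 2 * pi * 40 / (2 * sqrt(3)),
    tolerance = 0.01
  )
})

test_that("attachment profile enhances only high-curvature regions", {
  curv <- ellipse_curvature(25, 15, 256)
  kon <- 0.0474
  alpha <- 0.6
  prof <- attachment_profile(curv, kon, alpha)
  expect_true(all(prof$kon_P >= kon - 1e-12))
  expect_equal(
    max(prof$kon_P) - kon,
    alpha * (25 / 15^2 - 15 / 25^2),
    tolerance = 1e-3
  )
  # exactly two enhanced arcs on the ellipse, three on the triangle profiles
  n_peaks <- function(p, base) {
    length(parpolar:::circular_runs(p$kon_P > base + 0.5 * (max(p$kon_P) - base)))
  }
  expect_equal(n_peaks(prof, kon), 2)
  tri <- attachment_profile(triangle_curvature(40, 5, 256), kon, alpha)
  expect_equal(n_peaks(tri, kon), 3)
  emb <- attachment_profile(
    embryo_triangle_curvature(110, c(0.14, 0.13, 0.119), 3, 256), kon, alpha
  )
  expect_equal(n_peaks(emb, kon), 3)
  # alpha = 0 leaves the base rate untouched
  expect_equal(attachment_profile(curv, kon, 0)$kon_P, rep(kon, 256))
})

test_that("embryo-in-chamber profile is a valid convex contour", {
  curv <- embryo_triangle_curvature(110, c(0.14, 0.13, 0.119), 3, 256)
  expect_gt(attr(curv, "baseline"), 0)
  expect_true(all(curv$curvature > 0))
  expect_error(
    embryo_triangle_curvature(110, c(5, 5, 5), 10, 256),
    "convex"
  )
})
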