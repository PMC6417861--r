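speckle_pair <- function(seed, flow, size = c(64, 64), density = 0.06) {
  make_speckle_movie(
    synthetic_spec(
      seed = seed, flow = flow,
      speckle = list(density = density, sigma = 1.2, size = size, amplitude = 1)
    ),
    n_frames = 2
  )$frames
}

test_that("identical frames give a zero displacement field", {
  f <- speckle_pair(1, list(type = "none", u = 0))
  out <- piv_multipass(f[[1]], f[[2]])
  expect_true(all(out$valid))
  expect_lt(max(abs(out$u)), 1e-12)
  expect_lt(max(abs(out$v)), 1e-12)
})

test_that("pure integer translation is recovered exactly", {
  f <- speckle_pair(3, list(type = "uniform", u = 3))
  out <- piv_multipass(f[[1]], f[[2]])
  expect_lt(max(abs(out$u[out$valid] - 3)), 1e-9)
  expect_lt(max(abs(out$v[out$valid])), 1e-9)
})

test_that("subpixel translation is recovered to better than 0.1 px RMS", {
  f <- speckle_pair(5, list(type = "uniform", u = 0.3))
  out <- piv_multipass(f[[1]], f[[2]])
  expect_lt(sqrt(mean((out$u - 0.3)^2)), 0.1)
})

test_that("sinusoidal displacement field is recovered below 0.2 px RMS", {
  f <- speckle_pair(4, list(type = "sinusoidal", u = 2, wavelength = 128),
    size = c(128, 128)
  )
  out <- piv_multipass(f[[1]], f[[2]])
  truth <- 2 * sin(2 * pi * (out$x - 1) / 128)
  expect_lt(sqrt(mean((out$u - truth)^2)), 0.2)
})

test_that("textureless windows are flagged invalid and filled from neighbors", {
  f <- speckle_pair(6, list(type = "uniform", u = 2))
  a <- f[[1]]
  b <- f[[2]]
  a[, 1:24] <- 0 # blank out a stripe: no texture for the finest windows
  b[, 1:24] <- 0
  out <- piv_multipass(a, b)
  expect_true(any(!out$valid))
  expect_true(all(is.finite(out$u)))
  # valid vectors away from the blanked stripe (and from the frame edge,
  # where blanking breaks the frame's periodic consistency) still see the
  # translation
  ok <- out$valid & out$x > 32 & out$x < 56
  expect_lt(max(abs(out$u[ok] - 2)), 0.1)
})

test_that("frame preconditions are enforced", {
  expect_error(piv_multipass(matrix(0, 32, 32), matrix(0, 32, 32)), "64")
  expect_error(
    piv_multipass(matrix(0, 64, 64), matrix(0, 64, 128)),
    "same shape"
  )
})

test_that("flow kymographs carry physical units and peak summaries", {
  still <- make_speckle_movie(synthetic_spec(seed = 2), n_frames = 3)
  vk0 <- flow_kymograph(still$frames, frame_interval = 10, pixel_size = 0.1)
  expect_equal(vk0$peak_velocity, 0)

  mv <- make_speckle_movie(
    synthetic_spec(
      seed = 5, flow = list(type = "uniform", u = 5),
      speckle = list(density = 0.06, sigma = 1.2, size = c(64, 64), amplitude = 1)
    ),
    n_frames = 3
  )
  vk <- flow_kymograph(mv$frames, frame_interval = 10, pixel_size = 0.1)
  # 5 px/frame * 0.1 um/px / 10 s * 60 = 3 um/min
  expect_equal(mean(vk$values), 3, tolerance = 0.05)
  expect_equal(vk$units, "um/min")
  expect_warning(flow_kymograph(mv$frames), "px/frame")
})

test_that("bipolar inward flow shows antisymmetric sign structure", {
  mv <- make_speckle_movie(
    synthetic_spec(
      seed = 6, flow = list(type = "bipolar", u = 2),
      speckle = list(density = 0.06, sigma = 1.2, size = c(64, 128), amplitude = 1)
    ),
    n_frames = 3
  )
  vk <- flow_kymograph(mv$frames, frame_interval = 10, pixel_size = 0.1)
  mid <- 0.1 * 64 # midline in um
  expect_gt(mean(vk$values[, vk$positions < mid]), 0)
  expect_lt(mean(vk$values[, vk$positions > mid]), 0)
})
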