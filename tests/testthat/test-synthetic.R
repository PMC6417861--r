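test_that("profile generator honors its ground-truth contract", {
  flat <- make_profile(synthetic_spec(domains = NULL, noise = 0))
  expect_true(all(flat$profile$intensity == 0))

  one <- make_profile(synthetic_spec(
    domains = data.frame(center = 60, width = 30, amplitude = 10), noise = 0
  ))
  expect_equal(max(one$profile$intensity), 10)
  # full width at half maximum equals the nominal width
  above <- one$profile$intensity >= 5
  dx <- diff(one$profile$position[1:2])
  expect_equal(sum(above) * dx, 30, tolerance = dx * 2)

  a <- make_profile(synthetic_spec(seed = 99, domains = data.frame(
    center = 40, width = 20, amplitude = 5
  ), noise = 1))
  b <- make_profile(synthetic_spec(seed = 99, domains = data.frame(
    center = 40, width = 20, amplitude = 5
  ), noise = 1))
  expect_identical(a$profile$intensity, b$profile$intensity)
  expect_error(
    synthetic_spec(domains = data.frame(center = 1, width = 200, amplitude = 1)),
    "less than the circumference"
  )
})

test_that("speckle movies advect by the prescribed field", {
  still <- make_speckle_movie(synthetic_spec(seed = 2), n_frames = 3)
  expect_identical(still$frames[[1]], still$frames[[2]])
  expect_identical(still$frames[[1]], still$frames[[3]])

  mv <- make_speckle_movie(
    synthetic_spec(seed = 3, flow = list(type = "uniform", u = 3)),
    n_frames = 2
  )
  # full-frame correlation oracle: global peak at lag (3, 0)
  a <- mv$frames[[1]] - mean(mv$frames[[1]])
  b <- mv$frames[[2]] - mean(mv$frames[[2]])
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  expect_equal(pk[1] - 1, 0) # y lag
  expect_equal(pk[2] - 1, 3) # x lag

  bip <- make_speckle_movie(
    synthetic_spec(seed = 4, flow = list(type = "bipolar", u = 2)),
    n_frames = 2
  )
  nx <- ncol(bip$frames[[1]])
  expect_gt(mean(bip$truth_u[1:(nx / 2)]), 0)
  expect_lt(mean(bip$truth_u[(nx / 2 + 1):nx]), 0)
})

test_that("ground truth round-trips through text files unchanged", {
  sp <- synthetic_spec(
    seed = 17, circumference = 120, n = 256,
    domains = data.frame(center = c(30, 90), width = c(25, 15), amplitude = c(10, 8)),
    noise = 0.5
  )
  pr <- make_profile(sp)
  path <- file.path(withr::local_tempdir(), "profile.tsv")
  write_profile(pr, path)
  back <- read_profile(path)
  expect_equal(back$profile$intensity, pr$profile$intensity, tolerance = 1e-9)
  expect_equal(back$truth$center, pr$truth$center)
  expect_equal(back$truth$width, pr$truth$width)
  expect_equal(back$truth$amplitude, pr$truth$amplitude)
  expect_equal(back$meta$seed, 17)
})
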