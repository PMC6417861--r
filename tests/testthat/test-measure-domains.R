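test_that("a noiseless top-hat is recovered at its exact width", {
  sp <- synthetic_spec(
    seed = 1, circumference = 512, n = 512,
    domains = data.frame(center = 100, width = 60, amplitude = 10), noise = 0
  )
  m <- domain_extent(make_profile(sp)$profile)
  expect_equal(nrow(m$boundaries), 1L)
  expect_equal(m$extent, 60, tolerance = 1) # within one grid step
})

test_that("domain extents are recovered within 5% for SNR >= 5", {
  for (snr in c(5, 8, 12)) {
    sp <- synthetic_spec(
      seed = 11, circumference = 120, n = 512,
      domains = data.frame(
        center = c(30, 90), width = c(25, 15),
        amplitude = c(2 * snr, 2 * snr)
      ),
      noise = 2
    )
    m <- domain_extent(make_profile(sp)$profile)
    expect_equal(nrow(m$boundaries), 2L)
    w <- sort(m$boundaries$width)
    expect_true(all(abs(w - c(15, 25)) / c(15, 25) < 0.05))
    # centers recovered too
    ctr <- sort(m$boundaries$center)
    expect_true(all(abs(ctr - c(30, 90)) < 2))
  }
})

test_that("flat pure-noise traces rarely yield a false domain", {
  fp <- 0L
  for (s in 1:500) {
    sp <- synthetic_spec(seed = s, n = 512, domains = NULL, noise = 1)
    if (domain_extent(make_profile(sp)$profile)$extent > 0) fp <- fp + 1L
  }
  expect_lte(fp / 500, 0.05)
})

test_that("measurement is covariant under intensity rescaling", {
  sp <- synthetic_spec(
    seed = 21, circumference = 120, n = 512,
    domains = data.frame(center = 50, width = 30, amplitude = 12), noise = 1.5
  )
  pr <- make_profile(sp)$profile
  m1 <- domain_extent(pr)
  pr2 <- pr
  pr2$intensity <- pr2$intensity * 37
  m2 <- domain_extent(pr2)
  expect_equal(m1$boundaries$left, m2$boundaries$left, tolerance = 1e-9)
  expect_equal(m1$extent, m2$extent, tolerance = 1e-9)
  expect_equal(m2$intensity, 37 * m1$intensity, tolerance = 1e-9)
})

test_that("in-domain intensity and the invariants hold", {
  sp <- synthetic_spec(
    seed = 31, circumference = 120, n = 512,
    domains = data.frame(center = 50, width = 30, amplitude = 10), noise = 1
  )
  m <- domain_extent(make_profile(sp)$profile)
  expect_equal(m$extent, sum(m$boundaries$width))
  expect_gte(m$extent, 0)
  expect_lte(m$extent_frac, 1)
  expect_equal(m$intensity, 10, tolerance = 1.5)
  expect_error(domain_extent(rnorm(10)), "longer than")
  expect_error(domain_extent(rnorm(100), window = 22), "odd")
})
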