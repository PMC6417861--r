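test_that("domain counting handles trivial and wrapped cases", {
  expect_equal(count_domains(rep(0, 32)), 0L)
  two <- c(rep(0, 8), rep(3, 6), rep(0, 10), rep(2, 6), rep(0, 2))
  expect_equal(count_domains(two, floor = 1), 2L)
  # a domain straddling the periodic seam counts once
  wrapped <- c(rep(4, 5), rep(0, 22), rep(4, 5))
  expect_equal(count_domains(wrapped, floor = 1), 1L)
  expect_equal(count_domains(rep(2, 16), floor = 1), 1L)
  expect_equal(count_domains(rep(0.5, 16), floor = 1), 0L) # below floor
  expect_error(count_domains(rep(NA_real_, 8)), "NA")
})

test_that("domain counting agrees with brute-force labeling on random profiles", {
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(24:96, 1)
    P <- numeric(n)
    for (d in seq_len(sample(0:4, 1))) {
      c0 <- sample(n, 1)
      w <- sample(2:12, 1)
      idx <- ((c0 + 0:(w - 1) - 1) %% n) + 1
      P[idx] <- P[idx] + runif(1, 1, 6)
    }
    expect_equal(
      count_domains(P, floor = 0.5),
      count_domains_bruteforce(P, floor = 0.5)
    )
  }
})

test_that("domain boundaries are interpolated to sub-grid precision", {
  n <- 128
  L <- 64
  x <- seq(0, L, length.out = n + 1)[1:n]
  P <- 5 * exp(-parpolar:::circ_dist(x, 20, L)^2 / (2 * 4^2))
  runs <- domain_runs(P, x, rel = 0.5, floor = 0)
  expect_equal(nrow(runs), 1L)
  # half-maximum of the Gaussian sits at center +- sigma*sqrt(2 ln 2)
  hw <- 4 * sqrt(2 * log(2))
  expect_equal(runs$left, 20 - hw, tolerance = 0.05)
  expect_equal(runs$right, 20 + hw, tolerance = 0.05)
  expect_equal(runs$width, 2 * hw, tolerance = 0.05)
  expect_equal(runs$center, 20, tolerance = 0.05)
})

test_that("a sub-threshold attachment gain produces no domain", {
  lab <- classify_point(0.05, 100, "no-trigger", model_params(),
    grid_n = 64, t_max = 4000
  )
  expect_equal(lab, "0")
})

test_that("phase sweeps label every cell and resume from partial results", {
  p <- model_params()
  d1 <- phase_sweep("no-trigger", c(0.05), c(50, 100), p,
    grid_n = 64, t_max = 4000
  )
  expect_s3_class(d1, "par_phase")
  expect_equal(nrow(d1), 2L)
  expect_true(all(d1$label == "0"))
  expect_true(all(d1$n_uniform == 0L))
  # resuming with a full cache must not recompute (and must keep labels)
  t0 <- proc.time()[3]
  d2 <- phase_sweep("no-trigger", c(0.05), c(50, 100), p,
    resume = d1, grid_n = 64, t_max = 4000
  )
  expect_lt(proc.time()[3] - t0, 1)
  expect_equal(d2$label, d1$label)
  g <- glance(d1)
  expect_equal(sum(g$cells), 2L)
  expect_s3_class(autoplot(d1), "ggplot")
})
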