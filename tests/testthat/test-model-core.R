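test_that("reaction terms reduce to pure attachment on an empty membrane", {
  p <- model_params()
  n <- 16
  st <- cortex_state(
    x = seq(0, 15, by = 1), A = rep(0, n), P = rep(0, n),
    A_cyto = 1.2, P_cyto = 0.8, t = 0
  )
  rt <- reaction_terms(st, rep(p$kon_P, n), p)
  expect_equal(rt$dA, rep(p$kon_A * 1.2, n))
  expect_equal(rt$dP, rep(p$kon_P * 0.8, n))
  expect_true(all(rt$dA > 0))
})

test_that("detailed balance of the pure exchange kinetics is a fixed point", {
  p <- model_params(k_AP = 0, k_PA = 0)
  n <- 16
  A <- 1.3
  P <- 2.1
  st <- cortex_state(
    x = seq(0, 15, by = 1), A = rep(A, n), P = rep(P, n),
    A_cyto = p$koff_A * A / p$kon_A, P_cyto = p$koff_P * P / p$kon_P, t = 0
  )
  rt <- reaction_terms(st, rep(p$kon_P, n), p)
  expect_lt(max(abs(rt$dA)), 1e-12)
  expect_lt(max(abs(rt$dP)), 1e-12)
})

test_that("reaction terms match direct arithmetic and conserve mass", {
  p <- model_params()
  st <- cortex_state(
    x = 0:7, A = rep(1, 8), P = rep(2, 8),
    A_cyto = 0.5, P_cyto = 0.25, t = 0
  )
  rt <- reaction_terms(st, rep(0.06, 8), p)
  # direct evaluation with the printed rate constants
  expect_equal(rt$dA[1], 8.58e-3 * 0.5 - 5.4e-3 * 1 - 0.19 * 2 * 1)
  expect_equal(rt$dP[1], 0.06 * 0.25 - 7.3e-3 * 2 - 2.0 * 1^2 * 2)
  expect_equal(attr(rt, "dA_cyto"), -p$psi * mean(rt$dA))
  expect_equal(attr(rt, "dP_cyto"), -p$psi * mean(rt$dP))
  expect_error(
    cortex_state(
      x = 0:7, A = rep(-1, 8), P = rep(0, 8),
      A_cyto = 1, P_cyto = 1
    ),
    "nonnegative"
  )
  expect_error(reaction_terms(st, rep(0.06, 4), p), "per grid point")
})

test_that("the homogeneous state is a fixed point of the full stepper", {
  p <- set_dials(model_params(), 0, 0)
  sc <- circle_scenario()
  u <- uniform_steady(p)
  n <- 64
  x <- seq(0, 127.6, length.out = n + 1)[1:n]
  st <- cortex_state(
    x = x, A = rep(u[["A"]], n), P = rep(u[["P"]], n),
    A_cyto = u[["A_cyto"]], P_cyto = u[["P_cyto"]], t = 0
  )
  s1 <- step_cortex(st, sc, p, dt = 500, dt_max = 0.25)
  s2 <- step_cortex(s1, sc, p, dt = 500, dt_max = 0.25)
  expect_lt(stats::sd(s1$A), 1e-12) # stays spatially uniform
  expect_lt(stats::sd(s1$P), 1e-12)
  expect_lt(max(abs(s2$A - s1$A)), 1e-9) # and stationary
  expect_lt(max(abs(s2$P - s1$P)), 1e-9)
})

test_that("no spurious symmetry breaking on a uniform-curvature cortex", {
  # full contractility feedback, but no curvature cue and no trigger
  p <- set_dials(model_params(), 0, 100)
  sim <- run_to_steady_state(circle_scenario(), p, grid_n = 128, t_max = 8000)
  u <- uniform_steady(p)
  expect_lt(max(abs(sim$state$A - u[["A"]])), 1e-8)
  expect_lt(max(abs(sim$state$P - u[["P"]])), 1e-8)
  expect_equal(count_domains(sim), 0L)
})

test_that("mirror-symmetric scenarios stay mirror-symmetric", {
  sim <- run_to_steady_state("no-trigger", anchor_params(), grid_n = 128)
  P <- sim$state$P
  n <- length(P)
  expect_lt(max(abs(P - P[c(1, n:2)])), 1e-8)
  v <- sim$state$v
  expect_lt(max(abs(v + v[c(1, n:2)])), 1e-8) # velocity is odd under reflection
})

test_that("total mass of both species is conserved through a full run", {
  sim <- run_to_steady_state("wt", anchor_params(), grid_n = 128)
  g <- glance(sim)
  expect_lt(g$mass_drift_A, 1e-6)
  expect_lt(g$mass_drift_P, 1e-6)
  expect_true(all(sim$state$A >= 0))
  expect_true(all(sim$state$P >= 0))
})

test_that("time stepping converges at first order in dt", {
  p <- anchor_params()
  sc <- scenario_preset("wt")
  n <- 64
  f <- parpolar:::scenario_fields(sc, p, n)
  u <- uniform_steady(p)
  bump <- exp(-parpolar:::circ_dist(f$x, f$L / 2, f$L)^2 / 50)
  st0 <- cortex_state(
    x = f$x, A = rep(u[["A"]], n) * (1 - 0.5 * bump),
    P = rep(u[["P"]], n) + bump,
    A_cyto = u[["A_cyto"]], P_cyto = u[["P_cyto"]], t = 0
  )
  advance <- function(dt_max) step_cortex(st0, sc, p, dt = 50, dt_max = dt_max)$P
  ref <- advance(0.01)
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) max(abs(advance(h) - ref)), numeric(1))
  expect_true(all(diff(errs) < 0)) # error shrinks with dt
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 1.4 & ratios < 3.5)) # ~first order
})

test_that("identical configurations reproduce bit-identical trajectories", {
  p <- anchor_params()
  s1 <- run_to_steady_state("wt", p, grid_n = 64, t_max = 2000)
  s2 <- run_to_steady_state("wt", p, grid_n = 64, t_max = 2000)
  expect_identical(s1$kymo, s2$kymo)
  expect_identical(s1$state$P, s2$state$P)
})
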