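#' Cortex state container
#'
#' Snapshot of the 1D cortex: membrane concentration fields, flow field,
#' well-mixed cytoplasmic pools, and simulation time. The cytoplasmic pools
#' are slaved to mass conservation
#' (`A_cyto = rho_A - psi * mean(A)`, same for P), so total amounts are
#' conserved by construction.
#'
#' @param x arc-length grid, um (uniform, periodic).
#' @param A,P membrane concentrations, um^-2 (nonnegative).
#' @param v cortical flow, um/s.
#' @param A_cyto,P_cyto cytoplasmic concentrations, um^-3.
#' @param t simulation time, s.
#' @return A list of class `cortex_state`.
#' @export
cortex_state <- function(x, A, P, v = rep(0, length(x)), A_cyto, P_cyto, t = 0) {
  n <- length(x)
  stopifnot(length(A) == n, length(P) == n, length(v) == n)
  if (any(A < 0) || any(P < 0) || A_cyto < 0 || P_cyto < 0) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  structure(
    list(x = x, A = A, P = P, v = v, A_cyto = A_cyto, P_cyto = P_cyto, t = t),
    class = "cortex_state"
  )
}

#' @export
print.cortex_state <- function(x, ...) {
  cat(sprintf(
    "<cortex_state> n = %d, t = %.1f s, mean A = %.3f, mean P = %.3f, max |v| = %.4f um/s\n",
    length(x$x), x$t, mean(x$A), mean(x$P), max(abs(x$v))
  ))
  invisible(x)
}

#' @export
as.data.frame.cortex_state <- function(x, ...) {
  as.data.frame(tibble::tibble(x = x$x, A = x$A, P = x$P, v = x$v))
}

#' Local reaction terms of the PAR dynamics
#'
#' Source/sink contributions at each grid point:
#' `dA/dt = kon_A * A_cyto - koff_A * A - k_AP * P * A` and
#' `dP/dt = kon_P(x) * P_cyto - koff_P * P - k_PA * A^2 * P`, where
#' `kon_P(x)` is the (possibly curvature-enhanced) posterior attachment
#' profile. Every membrane exchange is mirrored as a cytoplasmic change
#' scaled by the surface-to-volume factor, so mass is conserved by
#' construction; the antagonism terms return material to the cytoplasm the
#' same way.
#'
#' @param state a [cortex_state()].
#' @param kon_P_profile numeric vector of posterior attachment rates, one
#'   per grid point (see [attachment_profile()]).
#' @param params a [model_params()] object.
#' @return A tibble with columns `x`, `dA`, `dP` (um^-2/s) and attributes
#'   `dA_cyto`, `dP_cyto` (um^-3/s).
#' @export
reaction_terms <- function(state, kon_P_profile, params) {
  stopifnot(inherits(state, "cortex_state"))
  validate_params(params)
  n <- length(state$x)
  if (length(kon_P_profile) != n) {
    stop("kon_P_profile must have one rate per grid point", call. = FALSE)
  }
  if (any(state$A < 0) || any(state$P < 0)) {
    stop("negative concentrations", call. = FALSE)
  }
  p <- params
  dA <- p$kon_A * state$A_cyto - p$koff_A * state$A - p$k_AP * state$P * state$A
  dP <- kon_P_profile * state$P_cyto - p$koff_P * state$P - p$k_PA * state$A^2 * state$P
  out <- tibble::tibble(x = state$x, dA = dA, dP = dP)
  attr(out, "dA_cyto") <- -p$psi * mean(dA)
  attr(out, "dP_cyto") <- -p$psi * mean(dP)
  out
}

#' Advance the cortex state by one time interval
#'
#' One call of the semi-implicit integrator: implicit diffusion, upwind
#' advection in conservative form, positivity-preserving exchange /
#' antagonism kinetics, and a force-balance re-solve. The requested interval
#' is internally sub-stepped to respect the upwind CFL limit.
#'
#' @param state a [cortex_state()].
#' @param scenario a [par_scenario()] (supplies the attachment profile and
#'   the trigger stress patch).
#' @param params a [model_params()] object.
#' @param dt time interval to advance, s.
#' @param dt_max maximum internal step, s.
#' @return The advanced `cortex_state`.
#' @export
step_cortex <- function(state, scenario, params, dt, dt_max = dt) {
  stopifnot(inherits(state, "cortex_state"), dt > 0)
  validate_params(params)
  n <- length(state$x)
  dx <- state$x[2] - state$x[1]
  sc <- scenario_fields(scenario, params, n)
  par <- core_par_list(params, scenario)
  res <- cpp_integrate(
    state$A, state$P, sc$kon_P, sc$trig, par, dx,
    t0 = state$t, t_max = state$t + dt, dt_max = dt_max,
    cfl_frac = 0.2, tol = 0, t_min = Inf, check_every = 50L,
    record_dt = 2 * dt
  )
  cortex_state(
    x = state$x, A = res$A, P = res$P, v = res$v,
    A_cyto = res$A_cyto, P_cyto = res$P_cyto, t = res$t
  )
}

core_par_list <- function(params, scenario) {
  list(
    D_A = params$D_A, D_P = params$D_P, kon_A = params$kon_A,
    koff_A = params$koff_A, koff_P = params$koff_P,
    k_AP = params$k_AP, k_PA = params$k_PA, eta = params$eta,
    gamma = params$gamma, beta = params$beta, psi = params$psi,
    rho_A = params$rho_A, rho_P = params$rho_P,
    t_trig = scenario$t_trig %||% 0
  )
}
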