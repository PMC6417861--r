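#' Reference scales of the model's nondimensional coordinates
#'
#' The two phase-diagram coordinates of the model are the dimensionless
#' curvature-attachment gain `alpha/l` and the dimensionless contractility
#' feedback `beta*tau/(rho*P0)`. These scales convert between the
#' dimensionless dials and the dimensional parameters `alpha` (attachment
#' gain per unit excess curvature) and `beta` (active-stress reduction per
#' unit membrane PAR-2).
#'
#' Defaults are the package's own unit system (see the methods vignette):
#' `l` is the hydrodynamic length of the cortex `sqrt(eta/gamma)`, `tau` the
#' posterior detachment time `1/koff_P`, `P0` the saturated posterior
#' membrane concentration of the uncoupled exchange kinetics, and `rho` a
#' reference density fixed by calibration at the anchor point of the phase
#' diagrams.
#'
#' @param l reference length, um.
#' @param tau reference time, s.
#' @param rho reference density, amount/um^2.
#' @param P0 reference posterior concentration, amount/um^2.
#' @return A list of class `nondim_scales`.
#' @export
nondim_scales <- function(l = 10, tau = 1 / 7.3e-3, rho = 0.0225, P0 = 3.0487) {
  stopifnot(l > 0, tau > 0, rho > 0, P0 > 0)
  structure(list(l = l, tau = tau, rho = rho, P0 = P0), class = "nondim_scales")
}

#' Model parameters for the PAR / cortical-flow system
#'
#' Rate and mechanical constants of the coupled reaction-diffusion-advection
#' equations for the membrane concentrations of anterior (A) and posterior
#' (P) PAR proteins and of the active-gel force balance for the cortical
#' flow velocity. Units: lengths in um, times in s, membrane concentrations
#' in um^-2, cytoplasmic concentrations in um^-3, stress in units of the
#' membrane friction coefficient (`gamma` = 1 defines the stress scale).
#'
#' Kinetic defaults (diffusivities, exchange rates, totals, the
#' surface-to-volume factor `psi`) follow the established PAR
#' reaction-diffusion framework for the *C. elegans* zygote; the mechanical
#' constants and the antagonism strengths are the package's calibration (see
#' the methods vignette for the reasoning).
#'
#' @param D_A,D_P membrane diffusivities, um^2/s.
#' @param kon_A,kon_P base attachment rates, um/s (cytoplasmic concentration
#'   to membrane flux).
#' @param koff_A,koff_P detachment rates, 1/s.
#' @param k_AP antagonism of P on A (term `k_AP * P * A`), um^2/s.
#' @param k_PA antagonism of A on P (term `k_PA * A^2 * P`), um^4/s.
#' @param eta cortex viscosity.
#' @param gamma cortex-membrane friction (stress scale; keep at 1).
#' @param beta active-stress reduction per unit membrane P. Usually set via
#'   [set_dials()] rather than directly.
#' @param alpha curvature-dependent attachment gain (rate per unit excess
#'   curvature, um^2/s). Usually set via [set_dials()].
#' @param pi_active_0 baseline active stress (sets the trigger amplitude;
#'   its constant part drops out of the force balance).
#' @param pi_passive passive (osmotic) stress; spatially constant, so it
#'   does not drive flow.
#' @param rho_A,rho_P total amounts of each species expressed as cytoplasmic
#'   concentrations, um^-3 (conserved).
#' @param psi surface-to-volume conversion factor, 1/um.
#' @param scales a [nondim_scales()] object.
#' @return A list of class `par_params`.
#' @examples
#' p <- model_params()
#' p <- set_dials(p, alpha_over_l = 1.2, beta_scaled = 100)
#' @export
model_params <- function(D_A = 0.28, D_P = 0.15,
                         kon_A = 8.58e-3, kon_P = 4.74e-2,
                         koff_A = 5.4e-3, koff_P = 7.3e-3,
                         k_AP = 0.19, k_PA = 2.0,
                         eta = 196, gamma = 1,
                         beta = 0, alpha = 0,
                         pi_active_0 = 5, pi_passive = 0,
                         rho_A = 1.56, rho_P = 1.0, psi = 0.174,
                         scales = nondim_scales()) {
  p <- list(
    D_A = D_A, D_P = D_P, kon_A = kon_A, kon_P = kon_P,
    koff_A = koff_A, koff_P = koff_P, k_AP = k_AP, k_PA = k_PA,
    eta = eta, gamma = gamma, beta = beta, alpha = alpha,
    pi_active_0 = pi_active_0, pi_passive = pi_passive,
    rho_A = rho_A, rho_P = rho_P, psi = psi, scales = scales
  )
  validate_params(p)
  structure(p, class = "par_params")
}

validate_params <- function(p) {
  num <- c(
    "D_A", "D_P", "kon_A", "kon_P", "koff_A", "koff_P", "k_AP", "k_PA",
    "eta", "gamma", "beta", "alpha", "rho_A", "rho_P", "psi"
  )
  vals <- unlist(p[num])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("model parameters must be finite and nonnegative", call. = FALSE)
  }
  if (p$D_A <= 0 || p$D_P <= 0) stop("diffusivities must be positive", call. = FALSE)
  if (p$rho_A <= 0 || p$rho_P <= 0) stop("total amounts must be positive", call. = FALSE)
  if (p$eta <= 0 && p$gamma <= 0) {
    stop("force balance is singular: need eta > 0 or gamma > 0", call. = FALSE)
  }
  invisible(p)
}

#' Map the nondimensional phase-diagram coordinates onto dimensional parameters
#'
#' Sets `alpha` and `beta` from the dimensionless dials used on the phase
#' diagrams: `alpha = alpha_over_l * l * kon_P` (so that the polar attachment
#' enhancement is `alpha_over_l * l * excess_curvature` in units of the base
#' rate) and `beta = beta_scaled * rho * P0 / tau`.
#'
#' @param params a [model_params()] object.
#' @param alpha_over_l dimensionless curvature-attachment gain.
#' @param beta_scaled dimensionless contractility feedback `beta*tau/(rho*P0)`.
#' @return The parameter object with `alpha` and `beta` set.
#' @export
set_dials <- function(params, alpha_over_l, beta_scaled) {
  stopifnot(inherits(params, "par_params"), alpha_over_l >= 0, beta_scaled >= 0)
  s <- params$scales
  params$alpha <- alpha_over_l * s$l * params$kon_P
  params$beta <- beta_scaled * s$rho * s$P0 / s$tau
  params
}

#' Saturated posterior membrane concentration
#'
#' Uniform steady state of the posterior exchange kinetics alone (no
#' antagonist): `kon_P * (rho_P - psi * P) = koff_P * P`. Used as the
#' concentration yardstick for domain classification.
#'
#' @param params a [model_params()] object.
#' @return Scalar concentration, um^-2.
#' @export
p_saturated <- function(params) {
  params$kon_P * params$rho_P / (params$koff_P + params$kon_P * params$psi)
}

#' Uniform (anterior-dominant) fixed point of the reaction kinetics
#'
#' Damped fixed-point iteration for the spatially uniform steady state in
#' which the anterior species dominates the membrane and the posterior
#' species sits at its antagonism-suppressed coexistence level. This is the
#' pre-polarization cortex and the default initial condition.
#'
#' @param params a [model_params()] object.
#' @param kon_P optional posterior attachment rate overriding the base rate
#'   (used pointwise for curvature-enhanced grids).
#' @return Named vector with components `A`, `P`, `A_cyto`, `P_cyto`.
#' @export
uniform_steady <- function(params, kon_P = params$kon_P) {
  p <- params
  A <- p$kon_A * p$rho_A / (p$koff_A + p$kon_A * p$psi)
  P <- 0
  for (i in 1:400) {
    Acyto <- max(p$rho_A - p$psi * A, 0)
    Pcyto <- max(p$rho_P - p$psi * P, 0)
    Anew <- p$kon_A * Acyto / (p$koff_A + p$k_AP * P)
    Pnew <- kon_P * Pcyto / (p$koff_P + p$k_PA * A^2)
    dA <- Anew - A
    dP <- Pnew - P
    A <- A + 0.5 * dA
    P <- P + 0.5 * dP
    if (max(abs(dA), abs(dP)) < 1e-12) break
  }
  c(
    A = A, P = P,
    A_cyto = max(p$rho_A - p$psi * A, 0),
    P_cyto = max(p$rho_P - p$psi * P, 0)
  )
}

#' @export
print.par_params <- function(x, ...) {
  cat("<par_params>\n")
  flat <- x[setdiff(names(x), "scales")]
  cat(paste0(
    "  ", format(names(flat)), " = ",
    vapply(flat, function(v) format(v, digits = 4), ""), "\n"
  ), sep = "")
  s <- x$scales
  cat(sprintf(
    "  scales: l = %.3g um, tau = %.4g s, rho = %.3g, P0 = %.4g um^-2\n",
    s$l, s$tau, s$rho, s$P0
  ))
  invisible(x)
}
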