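#' Scenario: geometry plus trigger specification
#'
#' A scenario bundles the embryo geometry (which sets the curvature and
#' hence the posterior attachment profile) with the symmetry-breaking
#' trigger: an initial, exponentially decaying multiplicative reduction of
#' the baseline active stress over a Gaussian patch. The wild-type scenario
#' places a full-depth patch at the posterior pole (the centrosome cue);
#' `"none"` models loss of the cue (uniform initial stress, symmetry broken
#' only by curvature); `"lateral"` displaces the patch to a lateral site;
#' `"anterior-weak"` is a quarter-depth patch at the anterior pole
#' (meiotic-arrest cue).
#'
#' @param trigger one of `"posterior"`, `"none"`, `"lateral"`,
#'   `"anterior-weak"`, or a numeric position as a fraction of the
#'   circumference.
#' @param geometry `"ellipse"` or `"triangle"`, or a list with `shape` and
#'   dimensions (`semi_major`/`semi_minor` or `side`/`corner_radius`).
#' @param trigger_depth fractional reduction of the baseline active stress
#'   at the patch center (default 1 for a full trigger, 0.25 for
#'   `"anterior-weak"`).
#' @param trigger_width Gaussian width of the patch, um.
#' @param t_trig decay time of the trigger, s.
#' @return A list of class `par_scenario`.
#' @examples
#' par_scenario("posterior", "ellipse")
#' scenario_preset("triangle-no-trigger")
#' @export
par_scenario <- function(trigger = c("posterior", "none", "lateral", "anterior-weak"),
                         geometry = "ellipse",
                         trigger_depth = NULL, trigger_width = 8, t_trig = 300) {
  if (is.character(trigger)) trigger <- match.arg(trigger)
  if (is.character(geometry)) {
    geometry <- switch(geometry,
      ellipse = list(shape = "ellipse", semi_major = 25, semi_minor = 15),
      triangle = list(
        shape = "embryo_triangle", perimeter = 110,
        peak_excess = c(0.140, 0.130, 0.119), peak_width = 3
      ),
      stop("unknown geometry: ", geometry, call. = FALSE)
    )
  }
  center_frac <- if (is.numeric(trigger)) {
    trigger
  } else {
    switch(trigger,
      posterior = 0.5, none = NA_real_, lateral = 0.35, `anterior-weak` = 0
    )
  }
  depth <- trigger_depth %||%
    (if (identical(trigger, "anterior-weak")) 0.25 else if (is.na(center_frac)) 0 else 1)
  structure(
    list(
      trigger = if (is.numeric(trigger)) "custom" else trigger,
      geometry = geometry, center_frac = center_frac,
      trigger_depth = depth, trigger_width = trigger_width, t_trig = t_trig
    ),
    class = "par_scenario"
  )
}

#' @rdname par_scenario
#' @param name preset name: `"wt"`, `"no-trigger"`, `"lateral"`,
#'   `"weak-anterior"`, `"triangle-wt"`, `"triangle-no-trigger"`.
#' @export
scenario_preset <- function(name) {
  switch(name,
    "wt" = par_scenario("posterior", "ellipse"),
    "no-trigger" = par_scenario("none", "ellipse"),
    "lateral" = par_scenario("lateral", "ellipse"),
    "weak-anterior" = par_scenario("anterior-weak", "ellipse"),
    "triangle-wt" = {
      s <- par_scenario("posterior", "triangle")
      s$center_frac <- 0 # centrosome cue at a corner-contact site
      s
    },
    "triangle-no-trigger" = par_scenario("none", "triangle"),
    stop("unknown scenario preset: ", name, call. = FALSE)
  )
}

#' @export
print.par_scenario <- function(x, ...) {
  g <- x$geometry
  dims <- switch(g$shape,
    ellipse = sprintf("%g x %g um", 2 * g$semi_major, 2 * g$semi_minor),
    triangle = sprintf(
      "side %g um, corners %s um", g$side,
      paste(g$corner_radius, collapse = "/")
    ),
    embryo_triangle = sprintf(
      "perimeter %g um, contact peaks %s /um", g$perimeter,
      paste(g$peak_excess, collapse = "/")
    )
  )
  cat(sprintf(
    "<par_scenario> trigger = %s (depth %.2f), geometry = %s (%s)\n",
    x$trigger, x$trigger_depth, g$shape, dims
  ))
  invisible(x)
}

# curvature profile for a scenario at resolution n
scenario_curvature <- function(scenario, n) {
  g <- scenario$geometry
  switch(g$shape,
    ellipse = ellipse_curvature(g$semi_major, g$semi_minor, n),
    triangle = triangle_curvature(g$side, g$corner_radius, n),
    embryo_triangle = embryo_triangle_curvature(
      g$perimeter, g$peak_excess, g$peak_width, n
    ),
    stop("unknown geometry shape: ", g$shape, call. = FALSE)
  )
}

# grid-level fields: x, kon_P profile, trigger stress patch
scenario_fields <- function(scenario, params, n) {
  curv <- scenario_curvature(scenario, n)
  L <- attr(curv, "circumference")
  kon <- attachment_profile(curv, params$kon_P, params$alpha)$kon_P
  trig <- rep(0, n)
  if (!is.na(scenario$center_frac) && scenario$trigger_depth > 0) {
    x0 <- scenario$center_frac * L
    d <- circ_dist(curv$position, x0, L)
    trig <- params$pi_active_0 * scenario$trigger_depth *
      exp(-d^2 / (2 * scenario$trigger_width^2))
  }
  list(x = curv$position, L = L, curv = curv, kon_P = kon, trig = trig)
}

circ_dist <- function(x, x0, L) {
  d <- abs(x - x0) %% L
  pmin(d, L - d)
}

# arc-length positions of the distinct curvature peaks (preferred sites)
curvature_peak_sites <- function(curv) {
  kap <- curv$curvature
  n <- length(kap)
  base <- attr(curv, "baseline")
  excess <- pmax(kap - base, 0)
  if (max(excess) <= 0) {
    return(numeric(0))
  }
  above <- excess > 0.5 * max(excess)
  runs <- circular_runs(above)
  L <- attr(curv, "circumference")
  vapply(runs, function(r) {
    idx <- if (r[1] <= r[2]) r[1]:r[2] else c(r[1]:n, 1:r[2])
    # circular mean of positions weighted by excess curvature
    ang <- 2 * pi * curv$position[idx] / L
    w <- excess[idx]
    (atan2(sum(w * sin(ang)), sum(w * cos(ang))) %% (2 * pi)) * L / (2 * pi)
  }, numeric(1))
}

#' Integrate a scenario to steady state
#'
#' Runs the coupled PAR reaction-diffusion-advection and force-balance
#' system from a (near-)uniform initial cortex until the posterior field
#' stops changing (max-norm rate below `tol` in nondimensional units) or
#' `t_max` is reached. Returns the final state together with the recorded
#' posterior kymograph; non-convergence is flagged, never silently dropped.
#'
#' @param scenario a [par_scenario()] or preset name.
#' @param params a [model_params()] with dials set (see [set_dials()]).
#' @param grid_n grid resolution (points around the circumference).
#' @param t_max maximum integration time, s.
#' @param dt_max maximum time step, s (the upwind CFL limit may shorten it).
#' @param tol convergence tolerance on `max|dP/dt| * tau / P0`.
#' @param t_min minimum time before convergence may be declared, s; defaults
#'   to `4 * t_trig` for triggered scenarios and 1500 s otherwise, so a
#'   slowly growing instability is not mistaken for steadiness.
#' @param record_dt kymograph recording interval, s (default `t_max / 200`).
#' @param init `"uniform"` or `"bias"` (a posterior-protein bump at
#'   `bias_site`, used for multistability probing).
#' @param bias_site arc-length position of the bias bump, um.
#' @param noise_amp optional relative amplitude of seeded uniform noise on
#'   the initial posterior field.
#' @param seed RNG seed for the noise perturbation.
#' @return A list of class `par_sim`: `state` (a [cortex_state()]),
#'   `kymo` (time x position matrix of P), `times`, `positions`,
#'   `converged`, plus the inputs.
#' @examples
#' \donttest{
#' p <- set_dials(model_params(), 1.2, 100)
#' sim <- run_to_steady_state("wt", p, grid_n = 128, t_max = 4000)
#' count_domains(sim)
#' }
#' @export
run_to_steady_state <- function(scenario, params, grid_n = 256,
                                t_max = 20000, dt_max = 0.25, tol = 1e-6,
                                t_min = NULL, record_dt = NULL,
                                init = c("uniform", "bias"), bias_site = NULL,
                                noise_amp = 0, seed = NULL) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  init <- match.arg(init)
  validate_params(params)
  sc <- scenario_fields(scenario, params, grid_n)
  dx <- sc$L / grid_n
  record_dt <- record_dt %||% (t_max / 200)
  t_min <- t_min %||% (if (scenario$trigger_depth > 0) 4 * scenario$t_trig else 1500)

  u <- uniform_steady(params)
  A <- rep(u[["A"]], grid_n)
  P <- rep(u[["P"]], grid_n)
  if (init == "bias") {
    if (is.null(bias_site)) stop("init = 'bias' needs a bias_site", call. = FALSE)
    bump <- exp(-circ_dist(sc$x, bias_site, sc$L)^2 / (2 * 8^2))
    P <- P + 0.8 * (p_saturated(params) - P) * bump
    A <- A * (1 - 0.9 * bump)
  }
  if (noise_amp > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    P <- pmax(P * (1 + noise_amp * runif(grid_n, -1, 1)), 0)
  }

  s <- params$scales
  res <- cpp_integrate(
    A, P, sc$kon_P, sc$trig, core_par_list(params, scenario), dx,
    t0 = 0, t_max = t_max, dt_max = dt_max, cfl_frac = 0.2,
    tol = tol * s$P0 / s$tau, t_min = t_min, check_every = 200L,
    record_dt = record_dt
  )
  state <- cortex_state(
    x = sc$x, A = res$A, P = res$P, v = res$v,
    A_cyto = res$A_cyto, P_cyto = res$P_cyto, t = res$t
  )
  structure(
    list(
      state = state, kymo = res$kymo, times = as.numeric(res$kymo_times),
      positions = sc$x, converged = isTRUE(res$converged),
      n_steps = res$n_steps, scenario = scenario, params = params,
      grid_n = grid_n, circumference = sc$L
    ),
    class = "par_sim"
  )
}

#' @export
print.par_sim <- function(x, ...) {
  cat(sprintf(
    "<par_sim> %s / %s, n = %d, t = %.0f s, %s, %d domain(s)\n",
    x$scenario$trigger, x$scenario$geometry$shape, x$grid_n, x$state$t,
    if (x$converged) "converged" else "NOT converged", count_domains(x)
  ))
  invisible(x)
}

#' Tidy a simulation into a long kymograph table
#'
#' @param x a `par_sim` object.
#' @param ... unused.
#' @return A tibble with columns `time`, `position`, `P`.
#' @export
tidy.par_sim <- function(x, ...) {
  k <- x$kymo
  tibble::tibble(
    time = rep(x$times, times = ncol(k)),
    position = rep(x$positions, each = nrow(k)),
    P = as.vector(k)
  )
}

#' One-row summary of a simulation
#'
#' Reports the final time, convergence flag, domain count, mass-conservation
#' drift of both species, and the peak flow speed.
#'
#' @param x a `par_sim` object.
#' @param ... unused.
#' @export
glance.par_sim <- function(x, ...) {
  p <- x$params
  st <- x$state
  totA <- p$psi * mean(st$A) + st$A_cyto
  totP <- p$psi * mean(st$P) + st$P_cyto
  tibble::tibble(
    t_final = st$t,
    converged = x$converged,
    n_domains = count_domains(x),
    mass_drift_A = abs(totA - p$rho_A) / p$rho_A,
    mass_drift_P = abs(totP - p$rho_P) / p$rho_P,
    peak_flow = max(abs(st$v))
  )
}

#' @export
autoplot.par_sim <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$time, fill = .data$P)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "P (um^-2)") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "position along cortex (um)", y = "time (s)",
      title = sprintf(
        "%s / %s", object$scenario$trigger, object$scenario$geometry$shape
      )
    ) +
    ggplot2::theme_minimal()
}
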