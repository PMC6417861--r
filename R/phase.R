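#' Count posterior domains on a periodic concentration profile
#'
#' A domain is a maximal contiguous run of grid points (respecting the
#' periodic wrap: a run crossing the seam counts once) where the profile
#' exceeds the classification threshold. The threshold policy is scale-free:
#' a point is in a domain where `P > rel * max(P)`, and the profile counts
#' as having domains at all only if `max(P) > floor` (guarding against flat
#' profiles being split at half their noise level). When called on a
#' simulation, `floor` defaults to a fraction of the saturated posterior
#' concentration [p_saturated()], and a non-converged (oscillatory) run is
#' classified on the time average of the last 10% of its kymograph.
#'
#' @param P numeric profile on a periodic grid, or a `par_sim`.
#' @param rel relative threshold (fraction of the spatial maximum).
#' @param floor absolute significance floor for the maximum.
#' @param ... passed between methods.
#' @return Integer domain count.
#' @examples
#' count_domains(c(0, 0, 3, 3, 0, 0, 2, 2), floor = 1) # 2
#' @export
count_domains <- function(P, ...) UseMethod("count_domains")

#' @rdname count_domains
#' @export
count_domains.default <- function(P, rel = 0.5, floor = 0, ...) {
  P <- as.numeric(P)
  if (all(is.na(P))) stop("all-NA profile", call. = FALSE)
  if (any(P < 0, na.rm = TRUE)) stop("profile must be nonnegative", call. = FALSE)
  mx <- max(P, na.rm = TRUE)
  if (mx <= floor) {
    return(0L)
  }
  above <- P > pmax(rel * mx, floor)
  length(circular_runs(above))
}

#' @rdname count_domains
#' @param floor_frac fraction of [p_saturated()] used as the significance
#'   floor for simulation output.
#' @export
count_domains.par_sim <- function(P, rel = 0.5, floor_frac = 0.35, ...) {
  prof <- classification_profile(P)
  count_domains(prof, rel = rel, floor = floor_frac * p_saturated(P$params))
}

# profile used for classification: final state if converged, otherwise the
# time average of the last 10% of the kymograph (oscillatory tie-break)
classification_profile <- function(sim) {
  if (sim$converged || nrow(sim$kymo) < 3) {
    return(sim$state$P)
  }
  i0 <- max(1, ceiling(0.9 * nrow(sim$kymo)))
  colMeans(sim$kymo[i0:nrow(sim$kymo), , drop = FALSE])
}

# maximal TRUE runs on a circular logical vector; returns list of c(start, end)
# index pairs (end < start means the run wraps the seam)
circular_runs <- function(above) {
  n <- length(above)
  if (!any(above)) {
    return(list())
  }
  if (all(above)) {
    return(list(c(1L, n)))
  }
  prev <- c(above[n], above[-n])
  starts <- which(above & !prev)
  nxt <- c(above[-1], above[1])
  ends <- which(above & !nxt)
  # pair each start with the first end at-or-after it (circularly)
  lapply(starts, function(s) {
    e <- ends[ends >= s]
    c(s, if (length(e)) e[1] else ends[1])
  })
}

#' Domain boundary positions on a periodic profile
#'
#' Returns, for each detected domain, the sub-grid boundary positions found
#' by linear interpolation of the threshold crossing, along with the domain
#' width and peak position.
#'
#' @inheritParams count_domains.default
#' @param x arc-length coordinates (uniform periodic grid).
#' @return A tibble with columns `left`, `right`, `center`, `width` (all in
#'   the units of `x`; `right < left` means the domain wraps the seam).
#' @export
domain_runs <- function(P, x, rel = 0.5, floor = 0) {
  n <- length(P)
  stopifnot(length(x) == n)
  L <- n * (x[2] - x[1])
  mx <- max(P)
  if (mx <= floor) {
    return(tibble::tibble(
      left = numeric(0), right = numeric(0),
      center = numeric(0), width = numeric(0)
    ))
  }
  thr <- max(rel * mx, floor)
  runs <- circular_runs(P > thr)
  cross <- function(i_out, i_in) {
    # threshold crossing between grid points i_out (below) and i_in (above)
    x0 <- x[i_out]
    x1 <- x[i_out] + circ_signed(x[i_in] - x[i_out], L)
    f <- (thr - P[i_out]) / (P[i_in] - P[i_out])
    (x0 + f * (x1 - x0)) %% L
  }
  rows <- lapply(runs, function(r) {
    s <- r[1]
    e <- r[2]
    im <- if (s == 1) n else s - 1
    ip <- if (e == n) 1 else e + 1
    left <- if (length(runs) == 1 && all(P > thr)) 0 else cross(im, s)
    right <- if (length(runs) == 1 && all(P > thr)) L else cross(ip, e)
    width <- (right - left) %% L
    if (width == 0) width <- L
    center <- (left + width / 2) %% L
    c(left = left, right = right, center = center, width = width)
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out
}

circ_signed <- function(d, L) {
  ((d + L / 2) %% L) - L / 2
}

#' Classify one point of the phase diagram
#'
#' Maps the nondimensional coordinates onto dimensional parameters, runs the
#' scenario to steady state from a panel of initial conditions (uniform plus
#' a posterior-protein bias at each preferred high-curvature site), and
#' labels the point with the common domain count, a coexistence label when
#' different initial conditions settle into different counts, or `"nc"` when
#' any run failed to converge.
#'
#' @param alpha_over_l,beta_scaled nondimensional coordinates.
#' @param scenario a [par_scenario()] or preset name.
#' @param params base [model_params()].
#' @param ic_panel `"auto"` probes multistability (biased initial
#'   conditions at each preferred site) only for untriggered scenarios that
#'   develop at least one domain from the uniform start — a triggered
#'   scenario's initial condition is physically determined, and a
#'   pre-seeded domain surviving below the nucleation threshold is not
#'   spontaneous symmetry breaking. `"uniform"` never probes; `"full"`
#'   always does.
#' @param detail if `TRUE`, return a list with both the label and the
#'   uniform-start domain count.
#' @param ... options forwarded to [run_to_steady_state()] (notably
#'   `grid_n`, `t_max`).
#' @return A label string: `"0"`, `"1"`, `"2"`, `"3"`, `"coexist-a/b"`, or
#'   `"nc"`.
#' @export
classify_point <- function(alpha_over_l, beta_scaled, scenario, params,
                           ic_panel = c("auto", "uniform", "full"),
                           detail = FALSE, ...) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  ic_panel <- match.arg(ic_panel)
  p <- set_dials(params, alpha_over_l, beta_scaled)
  dots <- list(...)
  grid_n <- dots$grid_n %||% 96

  run1 <- function(init, site) {
    do.call(run_to_steady_state, c(
      list(
        scenario = scenario, params = p, init = init,
        bias_site = if (init == "bias") site else NULL
      ),
      dots
    ))
  }
  wrap <- function(label, n_uniform) {
    if (detail) list(label = label, n_uniform = n_uniform) else label
  }
  base <- run1("uniform", NULL)
  if (!base$converged) {
    return(wrap("nc", NA_integer_))
  }
  n0 <- count_domains(base)
  probe <- switch(ic_panel,
    uniform = FALSE,
    full = TRUE,
    auto = scenario$trigger_depth == 0 && n0 >= 1
  )
  if (!probe) {
    return(wrap(as.character(n0), n0))
  }
  sites <- curvature_peak_sites(scenario_curvature(scenario, grid_n))
  sims <- lapply(sites, function(s) run1("bias", s))
  if (!all(vapply(sims, function(s) s$converged, logical(1)))) {
    return(wrap("nc", n0))
  }
  counts <- vapply(sims, count_domains, integer(1))
  counts <- sort(unique(c(n0, counts[counts > 0])))
  lab <- if (length(counts) == 1) {
    as.character(counts)
  } else {
    paste0("coexist-", paste(range(counts), collapse = "/"))
  }
  wrap(lab, n0)
}

#' Sweep a phase diagram over the nondimensional parameter plane
#'
#' Classifies every cell of the `(alpha/l, beta*tau/(rho*P0))` grid for one
#' scenario. Cell failures are recorded in place (`"error"`) and the sweep
#' continues; a previous partial result can be passed via `resume` to skip
#' already-classified cells.
#'
#' @param scenario a [par_scenario()] or preset name.
#' @param alpha_grid,beta_grid sorted vectors of nondimensional coordinates.
#' @param params base [model_params()].
#' @param resume optional previous `par_phase` result for the same grids.
#' @param ... forwarded to [classify_point()].
#' @return A tibble of class `par_phase` with columns `alpha_over_l`,
#'   `beta_scaled`, `label` (classification including multistability), and
#'   `n_uniform` (domain count from the uniform standard start alone).
#' @export
phase_sweep <- function(scenario, alpha_grid, beta_grid, params, resume = NULL, ...) {
  stopifnot(length(alpha_grid) > 0, length(beta_grid) > 0)
  if (is.unsorted(alpha_grid) || is.unsorted(beta_grid)) {
    stop("grids must be sorted", call. = FALSE)
  }
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  cells <- tidyr::expand_grid(alpha_over_l = alpha_grid, beta_scaled = beta_grid)
  labels <- character(nrow(cells))
  done <- rep(FALSE, nrow(cells))
  if (!is.null(resume)) {
    key <- paste(cells$alpha_over_l, cells$beta_scaled)
    old <- paste(resume$alpha_over_l, resume$beta_scaled)
    hit <- match(key, old)
    done <- !is.na(hit)
    labels[done] <- resume$label[hit[done]]
  }
  n_uniform <- rep(NA_integer_, nrow(cells))
  if (!is.null(resume) && !is.null(resume$n_uniform)) {
    n_uniform[done] <- resume$n_uniform[hit[done]]
  }
  for (i in which(!done)) {
    res <- tryCatch(
      classify_point(
        cells$alpha_over_l[i], cells$beta_scaled[i], scenario, params,
        detail = TRUE, ...
      ),
      error = function(e) list(label = "error", n_uniform = NA_integer_)
    )
    labels[i] <- res$label
    n_uniform[i] <- res$n_uniform
  }
  out <- dplyr::mutate(cells, label = labels, n_uniform = n_uniform)
  attr(out, "scenario") <- scenario
  class(out) <- c("par_phase", class(out))
  out
}

#' Summarize a phase diagram by label frequencies
#'
#' @param x a `par_phase` tibble.
#' @param ... unused.
#' @return A tibble with one row per label and its cell count.
#' @export
glance.par_phase <- function(x, ...) {
  dplyr::count(tibble::as_tibble(x), .data$label, name = "cells")
}

#' @export
autoplot.par_phase <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    factor(.data$alpha_over_l), factor(.data$beta_scaled),
    fill = .data$label
  )) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::labs(
      x = "alpha / l", y = "beta * tau / (rho * P0)", fill = "domains"
    ) +
    ggplot2::theme_minimal()
}
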