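#' Read and write run configuration files
#'
#' Plain-text YAML configuration covering the model parameters, the
#' nondimensional dials, the scenario, and the numerical grid. Unspecified
#' entries fall back to package defaults, and [write_run_config()] always
#' writes the fully resolved configuration, so a run directory documents
#' exactly what was executed.
#'
#' @param path file path.
#' @return `read_run_config` returns a list of class `run_config` with
#'   elements `params` (a [model_params()]), `scenario` (a
#'   [par_scenario()]), `dials`, `grid`, `noise`, and `raw`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

as_run_config <- function(raw) {
  scales <- do.call(nondim_scales, raw$scales %||% list())
  params <- do.call(model_params, c(raw$params %||% list(), list(scales = scales)))
  dials <- raw$dials %||% list(alpha_over_l = 1.2, beta_scaled = 100)
  params <- set_dials(params, dials$alpha_over_l, dials$beta_scaled)
  scenario <- if (is.character(raw$scenario %||% "wt")) {
    scenario_preset(raw$scenario %||% "wt")
  } else {
    do.call(par_scenario, raw$scenario)
  }
  grid <- modifyList(
    list(n = 256L, t_max = 8000, dt_max = 0.25, tol = 1e-6),
    raw$grid %||% list()
  )
  noise <- modifyList(list(amp = 0, seed = NULL), raw$noise %||% list())
  structure(
    list(
      params = params, scenario = scenario, dials = dials,
      grid = grid, noise = noise, raw = raw
    ),
    class = "run_config"
  )
}

#' @rdname read_run_config
#' @param config a `run_config` (or the raw list form).
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  p <- config$params
  out <- list(
    params = p[setdiff(
      names(p),
      c("scales", "alpha", "beta")
    )],
    scales = unclass(p$scales),
    dials = config$dials,
    scenario = list(
      trigger = config$scenario$trigger,
      geometry = config$scenario$geometry,
      trigger_depth = config$scenario$trigger_depth,
      trigger_width = config$scenario$trigger_width,
      t_trig = config$scenario$t_trig
    ),
    grid = config$grid,
    noise = config$noise
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Simulate from a run configuration
#'
#' @param config a `run_config` from [read_run_config()].
#' @return A `par_sim` (see [run_to_steady_state()]).
#' @export
simulate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  run_to_steady_state(
    config$scenario, config$params,
    grid_n = config$grid$n, t_max = config$grid$t_max,
    dt_max = config$grid$dt_max, tol = config$grid$tol,
    noise_amp = config$noise$amp, seed = config$noise$seed
  )
}

#' Check lateral-trigger relaxation toward the nearest pole
#'
#' Locates the final posterior domain and tests whether its center lies
#' inside the high-curvature arc (excess curvature above half its maximum)
#' of the pole nearest to the trigger site.
#'
#' @param sim a `par_sim` from a lateral-trigger run.
#' @return A list: `center` (domain center, um), `pole` (nearest pole
#'   position, um), `dist` (circular distance center-to-pole, um),
#'   `within_arc` (logical), `arc_halfwidth` (um).
#' @export
lateral_relaxation_check <- function(sim) {
  prof <- classification_profile(sim)
  runs <- domain_runs(prof, sim$positions,
    rel = 0.5,
    floor = 0.35 * p_saturated(sim$params)
  )
  if (nrow(runs) == 0) {
    return(list(
      center = NA_real_, pole = NA_real_, dist = NA_real_,
      within_arc = FALSE, arc_halfwidth = NA_real_
    ))
  }
  center <- runs$center[which.max(runs$width)]
  curv <- scenario_curvature(sim$scenario, sim$grid_n)
  L <- attr(curv, "circumference")
  sites <- curvature_peak_sites(curv)
  dists <- circ_dist(sites, center, L)
  pole <- sites[which.min(dists)]
  # half-width of the high-curvature arc around that pole
  excess <- pmax(curv$curvature - attr(curv, "baseline"), 0)
  above <- excess > 0.5 * max(excess)
  arc <- circular_runs(above)
  widths <- vapply(arc, function(r) {
    n <- length(above)
    len <- if (r[2] >= r[1]) r[2] - r[1] + 1 else n - r[1] + 1 + r[2]
    len * L / n
  }, numeric(1))
  arc_halfwidth <- max(widths) / 2
  list(
    center = center, pole = pole, dist = min(dists),
    within_arc = min(dists) <= arc_halfwidth, arc_halfwidth = arc_halfwidth
  )
}

#' Run the full simulation and phase-diagram suite
#'
#' Executes the four scenario simulations at the phase-diagram anchor point,
#' the lateral-relaxation run, coarse phase diagrams for the five scenarios,
#' and the measurement cross-check (domain-extent detection applied to the
#' wild-type steady profile). Stage failures are recorded and the report is
#' still produced.
#'
#' @param out_dir optional output directory; when given, scenario tables,
#'   phase-diagram label tables, and the resolved configuration are written
#'   there as delimited text.
#' @param params base [model_params()].
#' @param anchor nondimensional anchor point `c(alpha_over_l, beta_scaled)`.
#' @param grid_n grid resolution for the anchor scenario runs.
#' @param t_max maximum integration time for the anchor runs, s.
#' @param phase list of phase-diagram options: `alpha_grid`, `beta_grid`,
#'   `grid_n`, `t_max`, `scenarios`.
#' @param seed seed recorded in the manifest (the default pipeline is
#'   deterministic; the seed only matters for optional noise studies).
#' @return A list of class `paper_suite`: `scenarios` (tibble of per-run
#'   summaries), `lateral` (relaxation check), `diagrams` (named list of
#'   `par_phase`), `measurement` (cross-check summary), `failures`.
#' @export
run_paper_suite <- function(out_dir = NULL, params = model_params(),
                            anchor = c(1.2, 100), grid_n = 256, t_max = 8000,
                            phase = list(), seed = 1) {
  phase <- modifyList(
    list(
      alpha_grid = seq(0, 3, length.out = 10),
      beta_grid = 10^seq(1, 3, length.out = 10),
      grid_n = 96, t_max = 5000,
      scenarios = c(
        "wt", "no-trigger", "triangle-wt",
        "triangle-no-trigger", "weak-anterior"
      )
    ),
    phase
  )
  failures <- character(0)
  p_anchor <- set_dials(params, anchor[1], anchor[2])

  scen_names <- c("wt", "no-trigger", "triangle-no-trigger", "triangle-wt", "lateral")
  sims <- list()
  rows <- list()
  for (nm in scen_names) {
    res <- tryCatch(
      run_to_steady_state(nm, p_anchor, grid_n = grid_n, t_max = t_max),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("scenario ", nm, ": ", conditionMessage(res)))
      next
    }
    sims[[nm]] <- res
    rows[[nm]] <- dplyr::mutate(glance(res), scenario = nm, .before = 1)
  }
  scen_tbl <- dplyr::bind_rows(rows)

  lateral <- if (!is.null(sims[["lateral"]])) {
    lateral_relaxation_check(sims[["lateral"]])
  } else {
    NULL
  }

  diagrams <- list()
  for (nm in phase$scenarios) {
    d <- tryCatch(
      phase_sweep(nm, phase$alpha_grid, phase$beta_grid, params,
        grid_n = phase$grid_n, t_max = phase$t_max
      ),
      error = function(e) e
    )
    if (inherits(d, "error")) {
      failures <- c(failures, paste0("phase ", nm, ": ", conditionMessage(d)))
    } else {
      diagrams[[nm]] <- d
    }
  }

  measurement <- NULL
  if (!is.null(sims[["wt"]])) {
    m <- tryCatch(
      {
        st <- sims[["wt"]]$state
        meas <- domain_extent(st$P * 100, st$x) # arbitrary fluorescence scaling
        runs <- domain_runs(st$P, st$x,
          rel = 0.5,
          floor = 0.35 * p_saturated(p_anchor)
        )
        list(
          n_measured = nrow(meas$boundaries), n_counted = nrow(runs),
          extent_measured = meas$extent,
          extent_counted = sum(runs$width),
          boundary_gap = if (nrow(meas$boundaries) == 1 && nrow(runs) == 1) {
            L <- sims[["wt"]]$circumference
            max(
              circ_dist(meas$boundaries$left, runs$left, L),
              circ_dist(meas$boundaries$right, runs$right, L)
            )
          } else {
            NA_real_
          }
        )
      },
      error = function(e) {
        failures <<- c(failures, paste0("measurement: ", conditionMessage(e)))
        NULL
      }
    )
    measurement <- m
  }

  out <- structure(
    list(
      scenarios = scen_tbl, sims = sims, lateral = lateral,
      diagrams = diagrams, measurement = measurement,
      anchor = anchor, seed = seed, failures = failures
    ),
    class = "paper_suite"
  )
  if (!is.null(out_dir)) write_paper_suite(out, out_dir, params)
  out
}

write_paper_suite <- function(suite, out_dir, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(suite$scenarios, file.path(out_dir, "scenarios.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  for (nm in names(suite$diagrams)) {
    utils::write.table(
      tibble::as_tibble(suite$diagrams[[nm]]),
      file.path(out_dir, paste0("phase_", nm, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  for (nm in names(suite$sims)) {
    sim <- suite$sims[[nm]]
    kymo <- cbind(time = sim$times, sim$kymo)
    utils::write.table(kymo, file.path(out_dir, paste0("kymo_", nm, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE,
      col.names = c("time", sprintf("x%.2f", sim$positions))
    )
  }
  cfg <- as_run_config(list(
    dials = list(
      alpha_over_l = suite$anchor[1],
      beta_scaled = suite$anchor[2]
    ),
    scales = unclass(params$scales)
  ))
  write_run_config(cfg, file.path(out_dir, "config_resolved.yml"))
  invisible(out_dir)
}

#' @export
print.paper_suite <- function(x, ...) {
  cat("<paper_suite>\n")
  print(x$scenarios)
  if (!is.null(x$lateral)) {
    cat(sprintf(
      "lateral relaxation: center %.1f um, %.1f um from pole (%s)\n",
      x$lateral$center, x$lateral$dist,
      if (x$lateral$within_arc) "within polar arc" else "OUTSIDE polar arc"
    ))
  }
  for (nm in names(x$diagrams)) {
    g <- glance(x$diagrams[[nm]])
    cat(
      nm, ": ",
      paste(sprintf("%s=%d", g$label, g$cells), collapse = ", "), "\n"
    )
  }
  if (length(x$failures)) cat("failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}
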