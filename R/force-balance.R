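#' Cortical flow from the active-gel force balance
#'
#' Solves the periodic linear force balance
#' `gamma * v - eta * v'' = d/dx (Pi_active + Pi_passive)` for the cortical
#' flow velocity, with the active stress `Pi_active = pi_active_0 - beta * P`
#' reduced by membrane-bound posterior protein and `Pi_passive` spatially
#' constant. Flows therefore run away from contractility minima (regions
#' rich in the posterior species), the convention that matches the observed
#' flow topology. The solve is spectral (FFT), exact for the
#' constant-coefficient operator on a uniform periodic grid.
#'
#' @param field a data frame with columns `x` (uniform, periodic grid, um)
#'   and `P` (posterior membrane concentration, um^-2). An optional column
#'   `stress` is added to the variable part of the stress (used for trigger
#'   patches).
#' @param params a [model_params()] object (uses `eta`, `gamma`, `beta`).
#' @return The input as a tibble with a `v` column (um/s) appended.
#' @examples
#' p <- set_dials(model_params(), 1.2, 100)
#' g <- tibble::tibble(x = seq(0, 120, length.out = 64), P = 1 + cos(2 * pi * (0:63) / 64))
#' solve_force_balance(g, p)
#' @export
solve_force_balance <- function(field, params) {
  stopifnot(is.data.frame(field), all(c("x", "P") %in% names(field)))
  validate_params(params)
  x <- field$x
  P <- field$P
  n <- length(x)
  if (n < 8) stop("need a periodic grid of at least 8 points", call. = FALSE)
  dx <- diff(x)
  if (any(abs(dx - dx[1]) > 1e-8 * dx[1]) || dx[1] <= 0) {
    stop("grid must be uniform and increasing (periodic arc length)", call. = FALSE)
  }
  if (params$eta <= 0 && params$gamma <= 0) {
    stop("force balance is singular: need eta > 0 or gamma > 0", call. = FALSE)
  }
  L <- n * dx[1]
  Pi_var <- -params$beta * P
  if (!is.null(field[["stress"]])) Pi_var <- Pi_var + field[["stress"]]
  v <- fb_spectral(Pi_var, L, params$eta, params$gamma)
  out <- tibble::as_tibble(field)
  out$v <- v
  out
}

# spectral solve of gamma*v - eta*v'' = dPi/dx on [0, L) periodic
fb_spectral <- function(Pi_var, L, eta, gamma) {
  n <- length(Pi_var)
  k <- 2 * pi / L * c(0:floor(n / 2), -rev(seq_len(ceiling(n / 2) - 1)))
  ik <- 1i * k
  if (n %% 2 == 0) ik[n / 2 + 1] <- 0 # drop odd Nyquist derivative
  Ph <- fft(Pi_var)
  denom <- gamma + eta * k^2
  vh <- ik * Ph / denom
  if (gamma <= 0) vh[1] <- 0 # free mean mode: pin the cortex frame
  Re(fft(vh, inverse = TRUE)) / n
}
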