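# parameters at the phase-diagram anchor point used throughout the suite
anchor_params <- function() {
  set_dials(model_params(), alpha_over_l = 1.2, beta_scaled = 100)
}

# a circle geometry (uniform curvature, no preferred sites)
circle_scenario <- function(trigger = "none", R = 20.31) {
  par_scenario(trigger, list(shape = "ellipse", semi_major = R, semi_minor = R))
}

# brute-force periodic connected-components domain counter: scan linearly,
# then merge the two runs straddling the seam
count_domains_bruteforce <- function(P, rel = 0.5, floor = 0) {
  mx <- max(P)
  if (mx <= floor) {
    return(0L)
  }
  above <- P > max(rel * mx, floor)
  n <- length(above)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (above[i]) {
      if (i > 1 && above[i - 1]) lab[i] <- cur else lab[i] <- cur <- cur + 1L
    }
  }
  k <- length(unique(lab[lab > 0]))
  if (above[1] && above[n] && lab[1] != lab[n]) k <- k - 1L
  k
}

# dense spectral differentiation matrices for the force-balance oracle
spectral_matrices <- function(n, L) {
  k <- 2 * pi / L * c(0:floor(n / 2), -rev(seq_len(ceiling(n / 2) - 1)))
  ik <- 1i * k
  if (n %% 2 == 0) ik[n / 2 + 1] <- 0
  F <- stats::mvfft(diag(n))
  Finv <- Conj(F) / n # inverse DFT (the DFT matrix is symmetric)
  D1 <- Re(Finv %*% diag(ik) %*% F)
  D2 <- Re(Finv %*% diag(-k^2) %*% F)
  list(D1 = D1, D2 = D2)
}
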