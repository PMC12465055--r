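# Shared numerical oracles and small fixtures for the test suite.

# Closed-form survival of the onset age: S(t) = exp(-gamma_o (t^2 - s^2)/2).
onset_survival <- function(t, gamma_o, s) {
  ifelse(t <= s, 1, exp(-gamma_o * (t^2 - s^2) / 2))
}

# Numerical-quadrature survival of the marginal clinical-detection age for a
# single (onset, grade), integrating over the independent metastasis age and
# applying the theta_c hazard switch. Independent of the closed-form
# inversion used by sample_progression (shares only the hazard definitions).
#
# S_c(t) = Integral f_m(s) exp(-Lc(t; s)) ds + S_m(cap) * exp(-Lc(t; no met))
# with Lc(t; s) = C(t0, min(t,s)) + theta_c * C(min(t,s), t) for s < t,
# C(u, v) = gamma_c K (e^{rv} - e^{ru}) / r.
detection_survival_quad <- function(t_grid, onset, grade, nh, psa,
                                    cap = 140, n_s = 4000) {
  ax <- if (grade == "low_risk") psa$a1 else psa$a2
  r <- psa$a0 + ax
  K <- exp(psa$b - ax * onset)
  C <- function(u, v, g) g * K * (exp(r * v) - exp(r * u)) / r
  s_grid <- seq(onset, cap, length.out = n_s)
  ds <- diff(s_grid[1:2])
  # metastasis density on the grid
  Sm <- exp(-C(onset, s_grid, nh$gamma_m))
  fm <- nh$gamma_m * K * exp(r * s_grid) * Sm
  vapply(t_grid, function(t) {
    if (t <= onset) return(1)
    pre <- pmin(s_grid, t)
    Lc <- C(onset, pre, nh$gamma_c) + nh$theta_c * C(pre, pmax(pre, t), nh$gamma_c)
    integral <- sum(fm * exp(-Lc)) * ds
    tail <- Sm[n_s] * exp(-C(onset, t, nh$gamma_c))
    integral + tail
  }, 0)
}

# Empirical survival of a sample at given time points (NA = beyond horizon,
# treated as surviving past every point below the cap).
empirical_survival <- function(x, t_grid, cap = 120) {
  x[is.na(x)] <- cap + 1
  vapply(t_grid, function(t) mean(x > t), 0)
}

# Tiny run configuration for fast engine tests.
small_config <- function(n = 5000, seed = 7L, ...) {
  run_config(n_individuals = n, seed = seed, ...)
}

# Deterministic fake engine for sensitivity-analysis tests: cost and QALY are
# simple functions of two parameters so tornado ordering is known a priori.
fake_engine <- function(config, strategy, latent) {
  base <- is.null(strategy$name) || identical(strategy$name, "none")
  cost <- 100 + 10 * config$costs$psa / 3.78
  qaly <- 1
  if (!base) {
    cost <- cost + 500 * config$nh$gamma_o / 0.00024
    qaly <- qaly + 0.25 * config$utilities$rp / 0.8
  }
  list(econ = list(cost_percap = cost, qaly_percap = qaly))
}
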