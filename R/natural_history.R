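# Natural-history model: tumour onset, grade, latent PSA growth, metastasis and
# clinical (symptomatic) detection, in the FHCRC microsimulation tradition.
#
# The latent log-PSA trajectory is piecewise linear in age,
#   P(t) = b + a0*t + ax*(t - t_onset) for t > t_onset,
# so exp(P) is piecewise exponential and every cumulative hazard below has a
# closed form; event times are drawn by exact inverse-transform sampling.

#' Natural-history hazard parameters
#'
#' Constants governing tumour onset, metastasis and clinical detection.
#' Onset hazard is proportional to age, \eqn{\lambda_o(t) = \gamma_o t};
#' metastasis and clinical-detection hazards are proportional to PSA,
#' \eqn{\lambda_m(t) = e^{P(t)} \gamma_m} and
#' \eqn{\lambda_c(t) = e^{P(t)} \gamma_c}, the latter multiplied by
#' \eqn{\theta_c} once the tumour has metastasised.
#'
#' @param gamma_o onset hazard slope (per year of age, per year).
#' @param gamma_m metastasis hazard coefficient (per year per unit PSA).
#' @param gamma_c clinical-detection hazard coefficient (per year per unit PSA).
#' @param gamma_LR proportion of tumours that are low risk (Gleason grade
#'   group 3 or below), fixed at onset.
#' @param theta_c multiplier applied to the clinical-detection hazard after
#'   metastasis (>= 1).
#' @param onset_accrual_age age (years) at which onset hazard starts to accrue.
#' @return object of class `nh_params`.
#' @export
nh_params <- function(gamma_o = 0.00024, gamma_m = 0.0004, gamma_c = 0.0005,
                      gamma_LR = 0.673, theta_c = 19.1334,
                      onset_accrual_age = 40) {
  if (gamma_o < 0) stop("gamma_o must be non-negative")
  if (gamma_m < 0 || gamma_c < 0) stop("hazard coefficients must be non-negative")
  if (gamma_LR < 0 || gamma_LR > 1) stop("gamma_LR must lie in [0, 1]")
  if (theta_c < 1) stop("theta_c must be >= 1")
  structure(list(gamma_o = gamma_o, gamma_m = gamma_m, gamma_c = gamma_c,
                 gamma_LR = gamma_LR, theta_c = theta_c,
                 onset_accrual_age = onset_accrual_age),
            class = "nh_params")
}

#' PSA growth parameters
#'
#' Log-linear PSA growth with a change-point at tumour onset:
#' \eqn{P(t) = b + a_0 t + a_x (t - t_o) I(t > t_o) + \epsilon},
#' where \eqn{a_x} is `a1` for low-risk and `a2` for high-risk tumours and
#' \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)} is observation noise applied to
#' measured (screening) PSA values only.
#'
#' @param a0 healthy log-PSA slope (log ng/mL per year of age).
#' @param a1 additional slope after onset, low-risk tumours.
#' @param a2 additional slope after onset, high-risk tumours.
#' @param b log-PSA intercept (log ng/mL at age zero).
#' @param sigma_eps standard deviation of the measurement noise (log ng/mL).
#' @return object of class `psa_growth_params`.
#' @export
psa_growth_params <- function(a0 = 0.0215, a1 = 0.0566, a2 = 0.1051,
                              b = -0.1061, sigma_eps = 0.2) {
  if (a1 < 0 || a2 < a1) stop("slopes must satisfy a2 >= a1 >= 0")
  if (sigma_eps < 0) stop("sigma_eps must be non-negative")
  structure(list(a0 = a0, a1 = a1, a2 = a2, b = b, sigma_eps = sigma_eps),
            class = "psa_growth_params")
}

#' Mean (noise-free) log PSA
#'
#' Evaluates the latent log-PSA trajectory at given ages. All arguments are
#' vectorised; `onset_age` may be `NA` (no tumour).
#'
#' @param age age in years.
#' @param onset_age tumour onset age in years, or `NA`.
#' @param grade `"low_risk"`, `"high_risk"`, or `NA` when no tumour.
#' @param params [psa_growth_params()].
#' @return mean log PSA (log ng/mL).
#' @export
mean_log_psa <- function(age, onset_age = NA_real_, grade = NA_character_,
                         params = psa_growth_params()) {
  n <- max(length(age), length(onset_age), length(grade))
  age <- rep_len(age, n)
  onset_age <- rep_len(onset_age, n)
  grade <- rep_len(grade, n)
  if (any(!is.na(onset_age) & is.na(grade)))
    stop("grade must be given when onset_age is present")
  ax <- grade_slope(grade, params)
  post <- !is.na(onset_age) & age > onset_age
  p <- params$b + params$a0 * age
  p[post] <- p[post] + ax[post] * (age[post] - onset_age[post])
  p
}

grade_slope <- function(grade, params) {
  ax <- rep(NA_real_, length(grade))
  ax[grade %in% "low_risk"] <- params$a1
  ax[grade %in% "high_risk"] <- params$a2
  bad <- !is.na(grade) & !grade %in% c("low_risk", "high_risk")
  if (any(bad)) stop("unknown grade: ", paste(unique(grade[bad]), collapse = ", "))
  ax
}

#' Sample an observed PSA value
#'
#' Observed PSA is log-normal around the latent trajectory:
#' `exp(mean_log_psa + eps)` with `eps ~ N(0, sigma_eps^2)`.
#'
#' @inheritParams mean_log_psa
#' @return PSA in ng/mL (strictly positive); vectorised.
#' @export
sample_psa <- function(age, onset_age = NA_real_, grade = NA_character_,
                       params = psa_growth_params()) {
  p <- mean_log_psa(age, onset_age, grade, params)
  exp(p + stats::rnorm(length(p), 0, params$sigma_eps))
}

#' Sample tumour onset ages
#'
#' Inverse-transform sampling from the age-proportional onset hazard
#' \eqn{\lambda_o(t) = \gamma_o t}, accrued from `accrual_start_age`, with
#' cumulative hazard \eqn{\Lambda_o(t) = \gamma_o (t^2 - s^2) / 2}.
#'
#' @param n number of draws.
#' @param params [nh_params()].
#' @param accrual_start_age accrual origin in years (defaults to the value in
#'   `params`).
#' @param max_age ages beyond this are returned as `NA` (onset never realised).
#' @return vector of onset ages in years, `NA` when onset exceeds `max_age`.
#' @export
sample_onset_age <- function(n, params = nh_params(),
                             accrual_start_age = params$onset_accrual_age,
                             max_age = 120) {
  if (params$gamma_o < 0) stop("gamma_o must be non-negative")
  e <- stats::rexp(n)
  if (params$gamma_o == 0) return(rep(NA_real_, n))
  t <- sqrt(accrual_start_age^2 + 2 * e / params$gamma_o)
  t[t > max_age] <- NA_real_
  t
}

#' Assign tumour grade at onset
#'
#' Grade is fixed at onset and never changes: Bernoulli draw with
#' `P(low_risk) = gamma_LR`.
#'
#' @param n number of draws.
#' @param gamma_LR proportion of low-risk tumours.
#' @return character vector, `"low_risk"` or `"high_risk"`.
#' @export
assign_grade <- function(n, gamma_LR = nh_params()$gamma_LR) {
  if (gamma_LR < 0 || gamma_LR > 1) stop("gamma_LR must lie in [0, 1]")
  ifelse(stats::runif(n) < gamma_LR, "low_risk", "high_risk")
}

# Closed-form cumulative hazard of a PSA-proportional event between ages u and v
# (both >= onset), for hazard coef gamma: gamma * K * (exp(r v) - exp(r u)) / r
# with K = exp(b - ax * t_o) and r = a0 + ax.
cumhaz_psa <- function(u, v, gamma, K, r) {
  gamma * K * (exp(r * v) - exp(r * u)) / r
}

# Inverse: age v at which the cumulative hazard from u reaches E.
invert_cumhaz_psa <- function(u, E, gamma, K, r) {
  log(exp(r * u) + r * E / (gamma * K)) / r
}

#' Sample metastasis and clinical-detection ages
#'
#' Given tumour onset, draws the latent metastasis age and the latent
#' clinical-detection age from competing PSA-proportional hazards evaluated on
#' the noise-free mean log-PSA trajectory. The detection hazard switches from
#' \eqn{e^P \gamma_c} to \eqn{e^P \gamma_c \theta_c} at metastasis; a single
#' exponential deviate is inverted through the piecewise cumulative hazard, so
#' the competing-risk structure is exact. Ties are resolved in favour of
#' metastasis.
#'
#' Events are latent: censoring at death or at the simulation horizon is the
#' caller's responsibility. Vectorised over individuals.
#'
#' @param onset_age onset ages (years), no `NA`s.
#' @param grade `"low_risk"` or `"high_risk"` per individual.
#' @param nh [nh_params()].
#' @param psa [psa_growth_params()].
#' @param max_age events beyond this age are returned as `NA`.
#' @return list with numeric vectors `metastasis_age` and
#'   `clinical_detection_age` (`NA` when the event exceeds `max_age`).
#' @export
sample_progression <- function(onset_age, grade, nh = nh_params(),
                               psa = psa_growth_params(), max_age = 120) {
  if (any(is.na(onset_age))) stop("sample_progression requires onset_age")
  n <- length(onset_age)
  grade <- rep_len(grade, n)
  ax <- grade_slope(grade, psa)
  if (any(is.na(ax))) stop("grade must be low_risk or high_risk")
  r <- psa$a0 + ax
  K <- exp(psa$b - ax * onset_age)

  if (nh$gamma_m == 0 && nh$gamma_c == 0)
    return(list(metastasis_age = rep(NA_real_, n),
                clinical_detection_age = rep(NA_real_, n)))

  e_m <- stats::rexp(n)
  e_c <- stats::rexp(n)

  tm <- if (nh$gamma_m > 0) {
    invert_cumhaz_psa(onset_age, e_m, nh$gamma_m, K, r)
  } else rep(Inf, n)

  if (nh$gamma_c > 0) {
    # cumulative detection hazard accrued up to metastasis
    c1 <- cumhaz_psa(onset_age, pmin(tm, max_age), nh$gamma_c, K, r)
    pre <- e_c < c1
    tc <- numeric(n)
    tc[pre] <- invert_cumhaz_psa(onset_age[pre], e_c[pre], nh$gamma_c,
                                 K[pre], r[pre])
    post <- !pre
    tc[post] <- invert_cumhaz_psa(pmin(tm, max_age)[post], (e_c - c1)[post],
                                  nh$gamma_c * nh$theta_c, K[post], r[post])
  } else {
    tc <- rep(Inf, n)
  }

  met <- ifelse(is.finite(tm) & tm <= max_age & tm <= tc, tm, NA_real_)
  det <- ifelse(is.finite(tc) & tc <= max_age, tc, NA_real_)
  list(metastasis_age = met, clinical_detection_age = det)
}
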