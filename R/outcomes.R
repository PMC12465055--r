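# Clinical outcome metrics and harm-benefit trade-off counts.

#' Clinical outcome metrics of a scenario
#'
#' Computes, from a scenario's yearly tallies among men aged 45-84:
#' the average annual incidence per 100,000 person-years, the
#' metastatic-at-initial-detection rate per 100,000, the
#' metastasis-to-incidence (M/I) ratio, and the annual case-fatality rate
#' (prostate-cancer deaths over living diagnosed patients, averaged over the
#' horizon). Incidence and the metastatic rate are pooled over the horizon
#' (total events over total person-years), so the M/I identity
#' `mi_ratio = metastatic / incidence` holds exactly on the tallies.
#'
#' @param sim_output a `scenario_result` from [run_scenario()], or any list
#'   with a compatible `yearly` data.frame.
#' @return object of class `clinical_outcomes`: `avg_incidence_per_100k`,
#'   `metastatic_at_detection_per_100k`, `mi_ratio` (percent, `NA` when
#'   there are no diagnoses), `annual_cfr` (percent), and the `yearly` trace.
#' @export
clinical_metrics <- function(sim_output) {
  y <- sim_output$yearly
  py <- sum(y$py)
  if (py <= 0) stop("no person-years in the 45-84 window")
  dx <- sum(y$diagnoses)
  met <- sum(y$metastatic)
  inc <- dx / py * 1e5
  met_rate <- met / py * 1e5
  mi <- if (dx > 0) met / dx * 100 else NA_real_
  ok <- y$diagnosed_alive > 0
  cfr <- if (any(ok)) mean(y$pca_deaths[ok] / y$diagnosed_alive[ok]) * 100
         else NA_real_
  structure(list(avg_incidence_per_100k = inc,
                 metastatic_at_detection_per_100k = met_rate,
                 mi_ratio = mi, annual_cfr = cfr, yearly = y),
            class = "clinical_outcomes")
}

#' @export
print.clinical_outcomes <- function(x, ...) {
  cat(sprintf("incidence %.2f /100k; metastatic %.2f /100k; M/I %s; CFR %s\n",
              x$avg_incidence_per_100k, x$metastatic_at_detection_per_100k,
              if (is.na(x$mi_ratio)) "undefined" else sprintf("%.2f%%", x$mi_ratio),
              if (is.na(x$annual_cfr)) "undefined" else sprintf("%.2f%%", x$annual_cfr)))
  invisible(x)
}

#' Harm-benefit trade-off vs a baseline
#'
#' Extra PSA tests, biopsies and treatments that would not have happened
#' without screening, per life gained (averted prostate-cancer deaths over
#' the horizon). Ratios are undefined (`NA`) when no lives are gained.
#'
#' `lives_gained` is the difference in prostate-cancer deaths (deaths in the
#' configured Markov attribution states) between baseline and strategy. With
#' the printed transition matrix this is typically negative for intensive
#' screening: screening multiplies the diagnosed pool several-fold and every
#' Markov path carries mortality, so in-model PCa deaths rise even as deaths
#' per diagnosed patient fall. The all-cause difference `deaths_averted`
#' (baseline total deaths within the horizon minus the strategy's) is
#' reported alongside as a diagnostic.
#'
#' @param strategy_output,baseline_output `scenario_result` objects from the
#'   same latent cohort (common random numbers).
#' @return object of class `harm_benefit`.
#' @export
harm_benefit <- function(strategy_output, baseline_output) {
  if (strategy_output$n != baseline_output$n)
    stop("strategy and baseline must share the same population")
  ex_t <- strategy_output$resources$psa_tests - baseline_output$resources$psa_tests
  ex_b <- strategy_output$resources$biopsies - baseline_output$resources$biopsies
  ex_r <- strategy_output$resources$treatments - baseline_output$resources$treatments
  lg <- baseline_output$pca_deaths - strategy_output$pca_deaths
  da <- if (!is.null(baseline_output$total_deaths) &&
            !is.null(strategy_output$total_deaths))
    baseline_output$total_deaths - strategy_output$total_deaths
  else NA_integer_
  ratio <- function(x) if (lg > 0) x / lg else NA_real_
  structure(list(extra_psa_tests = ex_t, extra_biopsies = ex_b,
                 extra_treatments = ex_r, lives_gained = lg,
                 deaths_averted = da,
                 tests_per_life_gained = ratio(ex_t),
                 biopsies_per_life_gained = ratio(ex_b),
                 treatments_per_life_gained = ratio(ex_r)),
            class = "harm_benefit")
}

#' @export
print.harm_benefit <- function(x, ...) {
  cat(sprintf("lives gained: %d\n", x$lives_gained))
  if (x$lives_gained > 0)
    cat(sprintf("per life gained: %.2f tests, %.2f biopsies, %.2f treatments\n",
                x$tests_per_life_gained, x$biopsies_per_life_gained,
                x$treatments_per_life_gained))
  else cat("ratios undefined (no lives gained)\n")
  if (!is.na(x$deaths_averted))
    cat(sprintf("all-cause deaths averted within horizon: %d\n",
                x$deaths_averted))
  invisible(x)
}
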