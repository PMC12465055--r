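# Screening decision tree: PSA test, MRI triage, biopsy, and risk
# stratification by inherited risk (family history / PRS / rare pathogenic
# mutations).

#' Screening strategy definition
#'
#' A population screening protocol: PSA testing between `start_age` and
#' `end_age` every `interval` years, with either a fixed 4.0 ng/mL
#' test-positive threshold or age-specific thresholds
#' (2/3/4/7 ng/mL for ages <50, 50-59, 60-69, >=70). Risk-stratified
#' strategies screen the high-risk arm annually from 45 and the average-risk
#' arm under its own (possibly empty) schedule, after a one-time genetic test
#' (`"prs"` or `"wgs"`) for every man.
#'
#' @param start_age first screening age (years); ignored for `name = "none"`.
#' @param end_age last eligible screening age.
#' @param interval years between screens.
#' @param cutoff_mode `"fixed_4"` or `"age_specific"`.
#' @param risk_stratified logical; stratify the population by inherited risk.
#' @param high_risk_arm list with `start_age` and `interval` for the high-risk
#'   group (defaults: annual from 45).
#' @param average_risk_arm `"none"` for no average-risk screening, otherwise a
#'   list with `start_age` and `interval`.
#' @param genetic_test `"none"`, `"prs"` or `"wgs"`.
#' @param name optional strategy label; `"none"` denotes the no-screening
#'   baseline.
#' @return object of class `screening_strategy`.
#' @export
screening_strategy <- function(start_age = 45, end_age = 74, interval = 1,
                               cutoff_mode = c("fixed_4", "age_specific"),
                               risk_stratified = FALSE,
                               high_risk_arm = list(start_age = 45, interval = 1),
                               average_risk_arm = list(start_age = 50, interval = 1),
                               genetic_test = c("none", "prs", "wgs"),
                               name = NULL) {
  cutoff_mode <- match.arg(cutoff_mode)
  genetic_test <- match.arg(genetic_test)
  if (!identical(name, "none")) {
    if (start_age > end_age) stop("start_age must not exceed end_age")
    if (interval < 1) stop("interval must be >= 1 year")
  }
  if (risk_stratified && genetic_test == "none")
    stop("risk-stratified strategies require a genetic test (prs or wgs)")
  if (is.null(name)) {
    name <- if (risk_stratified) {
      avg <- if (identical(average_risk_arm, "none")) "none" else
        sprintf("%d-%d_q%d", average_risk_arm$start_age, end_age,
                average_risk_arm$interval)
      sprintf("risk_%s_hr%d-%dq%d_avg%s_%s", genetic_test,
              high_risk_arm$start_age, end_age, high_risk_arm$interval,
              avg, cutoff_mode)
    } else {
      sprintf("%d-%d_q%d_%s", start_age, end_age, interval, cutoff_mode)
    }
  }
  structure(list(start_age = start_age, end_age = end_age, interval = interval,
                 cutoff_mode = cutoff_mode, risk_stratified = risk_stratified,
                 high_risk_arm = high_risk_arm,
                 average_risk_arm = average_risk_arm,
                 genetic_test = genetic_test, name = name),
            class = "screening_strategy")
}

#' The no-screening baseline
#' @return a `screening_strategy` with an empty schedule.
#' @export
no_screening <- function() {
  s <- screening_strategy(name = "none")
  s$interval <- Inf
  s
}

is_baseline <- function(strategy) identical(strategy$name, "none")

#' Diagnostic test characteristics
#'
#' @param mri_sens,mri_spec multiparametric MRI sensitivity/specificity for
#'   the PI-RADS >= 4 rule.
#' @param biopsy_sens,biopsy_spec biopsy sensitivity/specificity (specificity
#'   1 means no false-positive diagnoses).
#' @param direct_biopsy_psa PSA (ng/mL) above which men skip MRI and go
#'   directly to systematic biopsy.
#' @return object of class `test_characteristics`.
#' @export
test_characteristics <- function(mri_sens = 0.89, mri_spec = 0.80,
                                 biopsy_sens = 0.64, biopsy_spec = 1.00,
                                 direct_biopsy_psa = 10) {
  p <- c(mri_sens, mri_spec, biopsy_sens, biopsy_spec)
  if (any(p < 0 | p > 1)) stop("test characteristics must lie in [0, 1]")
  structure(list(mri_sens = mri_sens, mri_spec = mri_spec,
                 biopsy_sens = biopsy_sens, biopsy_spec = biopsy_spec,
                 direct_biopsy_psa = direct_biopsy_psa),
            class = "test_characteristics")
}

#' Inherited-risk stratification parameters
#'
#' @param high_risk_fraction share of men classified high risk (family
#'   history, top-25\% PRS, or rare pathogenic mutation carriers).
#' @param prs_cost,wgs_cost one-time test costs (USD).
#' @param onset_rr relative risk applied to the onset hazard of the high-risk
#'   group (1 = no difference in natural history).
#' @return object of class `risk_stratification`.
#' @export
risk_stratification <- function(high_risk_fraction = 0.332, prs_cost = 16.81,
                                wgs_cost = 252.00, onset_rr = 1.0) {
  if (high_risk_fraction < 0 || high_risk_fraction > 1)
    stop("high_risk_fraction must lie in [0, 1]")
  structure(list(high_risk_fraction = high_risk_fraction,
                 prs_cost = prs_cost, wgs_cost = wgs_cost,
                 onset_rr = onset_rr),
            class = "risk_stratification")
}

#' PSA test-positive threshold
#'
#' Age bands for the age-specific mode are left-closed: <50 -> 2.0,
#' 50-59 -> 3.0, 60-69 -> 4.0, >=70 -> 7.0 ng/mL.
#'
#' @param age age in years (vectorised).
#' @param cutoff_mode `"fixed_4"` or `"age_specific"`.
#' @return threshold in ng/mL.
#' @export
psa_threshold <- function(age, cutoff_mode = c("fixed_4", "age_specific")) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (cutoff_mode == "fixed_4") return(rep(4.0, length(age)))
  c(2.0, 3.0, 4.0, 7.0)[findInterval(age, c(-Inf, 50, 60, 70))]
}

#' Screening ages implied by a strategy
#'
#' @param strategy a [screening_strategy()].
#' @param risk_group `"average"` or `"high"`; only relevant for
#'   risk-stratified strategies.
#' @return sorted integer vector of screening ages (empty for the baseline or
#'   a `"none"` arm).
#' @export
build_schedule <- function(strategy, risk_group = "average") {
  if (is_baseline(strategy)) return(integer(0))
  if (strategy$risk_stratified) {
    arm <- if (risk_group == "high") strategy$high_risk_arm
           else strategy$average_risk_arm
    if (identical(arm, "none")) return(integer(0))
    return(seq(arm$start_age, strategy$end_age, by = arm$interval))
  }
  seq(strategy$start_age, strategy$end_age, by = strategy$interval)
}

#' Assign men to inherited-risk groups
#'
#' Bernoulli assignment with probability `high_risk_fraction`; the one-time
#' genetic-test cost is charged per man at his first year in the model (the
#' caller discounts it).
#'
#' @param n number of men.
#' @param risk a [risk_stratification()].
#' @param u optional uniform deviates (for common-random-numbers reuse).
#' @return list with logical vector `high_risk` and scalar `test_cost`
#'   (undiscounted USD per man, excluding the choice of PRS vs WGS which is
#'   the strategy's).
#' @export
stratify_population <- function(n, risk = risk_stratification(), u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  list(high_risk = u < risk$high_risk_fraction)
}

#' Simulate one screening visit
#'
#' A single man's pathway at one visit: observed PSA below threshold is
#' negative; between threshold and the direct-biopsy level, an MRI is done and
#' a PI-RADS >= 4 result (probability `mri_sens` with cancer, `1 - mri_spec`
#' without) triggers a targeted biopsy; PSA above the direct-biopsy level goes
#' straight to systematic biopsy. Biopsy detects cancer with probability
#' `biopsy_sens` and, with specificity 1, never yields a false diagnosis.
#'
#' @param psa observed PSA (ng/mL).
#' @param age age at the visit.
#' @param has_cancer logical: tumour onset has occurred.
#' @param metastatic logical: metastasis has occurred.
#' @param strategy a [screening_strategy()] (supplies the cutoff mode).
#' @param tests a [test_characteristics()].
#' @return list with `outcome` (one of `"negative"`, `"mri_negative"`,
#'   `"biopsy_negative"`, `"screen_detected"`), `stage` (`"localized"`,
#'   `"metastatic"` or `NA`), and integer `resources` (`psa`, `mri`,
#'   `biopsy`).
#' @export
screening_visit <- function(psa, age, has_cancer, metastatic = FALSE,
                            strategy = screening_strategy(),
                            tests = test_characteristics()) {
  thr <- psa_threshold(age, strategy$cutoff_mode)
  res <- c(psa = 1L, mri = 0L, biopsy = 0L)
  if (psa <= thr)
    return(list(outcome = "negative", stage = NA_character_, resources = res))
  if (psa > tests$direct_biopsy_psa) {
    res["biopsy"] <- 1L
    detected <- has_cancer && stats::runif(1) < tests$biopsy_sens
  } else {
    res["mri"] <- 1L
    p_pos <- if (has_cancer) tests$mri_sens else 1 - tests$mri_spec
    if (stats::runif(1) >= p_pos)
      return(list(outcome = "mri_negative", stage = NA_character_,
                  resources = res))
    res["biopsy"] <- 1L
    detected <- has_cancer && stats::runif(1) < tests$biopsy_sens
  }
  if (detected) {
    list(outcome = "screen_detected",
         stage = if (metastatic) "metastatic" else "localized",
         resources = res)
  } else {
    list(outcome = "biopsy_negative", stage = NA_character_, resources = res)
  }
}
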