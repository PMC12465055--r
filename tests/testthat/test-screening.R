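test_that("psa_threshold maps age bands left-closed", {
  expect_equal(psa_threshold(c(48, 55, 65, 72), "age_specific"),
               c(2, 3, 4, 7))
  # band boundaries belong to the older band
  expect_equal(psa_threshold(c(49, 50, 59, 60, 69, 70), "age_specific"),
               c(2, 3, 3, 4, 4, 7))
  expect_equal(psa_threshold(c(45, 80), "fixed_4"), c(4, 4))
})

test_that("strategy construction, naming and validation", {
  s <- screening_strategy(45, 74, 1, "age_specific")
  expect_equal(s$name, "45-74_q1_age_specific")
  expect_error(screening_strategy(80, 74), "start_age")
  expect_error(screening_strategy(interval = 0), "interval")
  expect_error(screening_strategy(risk_stratified = TRUE), "genetic test")
  rs <- screening_strategy(cutoff_mode = "age_specific",
                           risk_stratified = TRUE, genetic_test = "prs",
                           average_risk_arm = list(start_age = 50, interval = 1))
  expect_match(rs$name, "^risk_prs_hr45-74q1_avg50-74_q1_age_specific$")
  expect_equal(no_screening()$name, "none")
})

test_that("build_schedule enumerates screening ages", {
  expect_equal(build_schedule(screening_strategy(60, 70, 5)), c(60, 65, 70))
  expect_equal(build_schedule(screening_strategy(45, 74, 1)), 45:74)
  expect_length(build_schedule(no_screening()), 0)
  rs <- screening_strategy(risk_stratified = TRUE, genetic_test = "wgs",
                           average_risk_arm = "none")
  expect_length(build_schedule(rs, "average"), 0)
  expect_equal(build_schedule(rs, "high"), 45:74)
})

test_that("stratify_population hits the high-risk fraction", {
  n <- 1e5
  set.seed(21)
  g <- stratify_population(n, risk_stratification(high_risk_fraction = 0.332))
  expect_lt(abs(mean(g$high_risk) - 0.332), 3 * sqrt(0.332 * 0.668 / n))
  # deterministic under supplied deviates
  u <- c(0.1, 0.5, 0.331, 0.333)
  expect_equal(stratify_population(4, risk_stratification(), u = u)$high_risk,
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("screening_visit follows the decision tree", {
  s <- screening_strategy(cutoff_mode = "fixed_4")
  tst <- test_characteristics()
  # below threshold: PSA only
  v <- screening_visit(3.0, 55, has_cancer = TRUE, strategy = s, tests = tst)
  expect_equal(v$outcome, "negative")
  expect_equal(v$resources, c(psa = 1L, mri = 0L, biopsy = 0L))
  # above direct-biopsy level: no MRI
  set.seed(1)
  v <- screening_visit(15, 55, has_cancer = TRUE, strategy = s, tests = tst)
  expect_equal(unname(v$resources["mri"]), 0L)
  expect_equal(unname(v$resources["biopsy"]), 1L)
  # perfect tests detect with certainty and stage correctly
  sure <- test_characteristics(mri_sens = 1, biopsy_sens = 1)
  v <- screening_visit(6, 55, TRUE, metastatic = TRUE, s, sure)
  expect_equal(v$outcome, "screen_detected")
  expect_equal(v$stage, "metastatic")
  # specificity 1: a man without cancer can never be falsely diagnosed
  set.seed(2)
  out <- replicate(500, screening_visit(6, 55, FALSE, FALSE, s, tst)$outcome)
  expect_false(any(out == "screen_detected"))
  expect_true(any(out == "biopsy_negative"))  # false-positive MRIs do occur
})

test_that("MRI+biopsy pathway detects cancer at mri_sens * biopsy_sens", {
  s <- screening_strategy(cutoff_mode = "fixed_4")
  tst <- test_characteristics()
  n <- 2e4
  set.seed(22)
  out <- vapply(seq_len(n), function(i)
    screening_visit(6, 55, TRUE, FALSE, s, tst)$outcome, "")
  p <- 0.89 * 0.64
  expect_equal(p, 0.5696)
  expect_lt(abs(mean(out == "screen_detected") - p),
            3 * sqrt(p * (1 - p) / n))
})
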