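test_that("mean_log_psa matches the closed-form trajectory", {
  p <- psa_growth_params()
  # healthy man, age 50: b + a0 * 50
  expect_equal(mean_log_psa(50), -0.1061 + 0.0215 * 50)
  expect_equal(mean_log_psa(50), 0.9689)
  expect_equal(exp(mean_log_psa(50)), 2.635, tolerance = 1e-3)
  # after onset the grade-specific slope adds on top of a0
  expect_equal(mean_log_psa(55, onset_age = 50, grade = "high_risk"),
               -0.1061 + 0.0215 * 55 + 0.1051 * 5)
  expect_equal(mean_log_psa(55, onset_age = 50, grade = "low_risk"),
               -0.1061 + 0.0215 * 55 + 0.0566 * 5)
  # before onset the tumour term is absent
  expect_equal(mean_log_psa(45, onset_age = 50, grade = "high_risk"),
               mean_log_psa(45))
  # vectorised
  expect_equal(mean_log_psa(c(50, 55), c(NA, 50), c(NA, "high_risk")),
               c(mean_log_psa(50),
                 mean_log_psa(55, 50, "high_risk")))
  expect_error(mean_log_psa(60, 50, "medium"), "grade")
})

test_that("sample_psa is exact at sigma = 0 and unbiased on the log scale", {
  p0 <- psa_growth_params(sigma_eps = 0)
  set.seed(1)
  expect_equal(sample_psa(50, params = p0), 2.635, tolerance = 1e-3)
  p <- psa_growth_params()  # sigma_eps = 0.2
  n <- 1e5
  set.seed(42)
  x <- sample_psa(rep(50, n), params = p)
  expect_true(all(x > 0))
  se <- p$sigma_eps / sqrt(n)
  expect_lt(abs(mean(log(x)) - 0.9689), 3 * se)
})

test_that("sample_onset_age follows the linear-hazard closed form", {
  nh <- nh_params()
  n <- 1e5
  set.seed(3)
  t <- sample_onset_age(n, nh, accrual_start_age = 40)
  expect_true(all(is.na(t) | t > 40))
  # P(onset by 70) = 1 - exp(-gamma_o (70^2 - 40^2) / 2) = 0.32699
  p70 <- 1 - onset_survival(70, nh$gamma_o, 40)
  expect_equal(p70, 1 - exp(-0.396))
  phat <- mean(!is.na(t) & t <= 70)
  expect_lt(abs(phat - p70), 3 * sqrt(p70 * (1 - p70) / n))
  # survival curve within DKW band at every point
  grid <- seq(45, 100, by = 5)
  emp <- empirical_survival(t, grid)
  orc <- onset_survival(grid, nh$gamma_o, 40)
  expect_lt(max(abs(emp - orc)), sqrt(log(2 / 1e-6) / (2 * n)) + 1e-3)
  # zero hazard -> no onsets
  expect_true(all(is.na(sample_onset_age(100, nh_params(gamma_o = 0)))))
})

test_that("assign_grade draws the low-risk share", {
  n <- 1e5
  set.seed(4)
  g <- assign_grade(n, 0.673)
  expect_setequal(unique(g), c("low_risk", "high_risk"))
  expect_lt(abs(mean(g == "low_risk") - 0.673),
            3 * sqrt(0.673 * 0.327 / n))
  expect_error(assign_grade(10, 1.5), "gamma_LR")
})

test_that("parameter constructors validate their inputs", {
  expect_error(nh_params(gamma_o = -1), "gamma_o")
  expect_error(nh_params(theta_c = 0.5), "theta_c")
  expect_error(nh_params(gamma_LR = 2), "gamma_LR")
  expect_silent(psa_growth_params())
})

test_that("sample_progression respects ordering and the tie rule", {
  nh <- nh_params()
  set.seed(5)
  onset <- runif(2000, 45, 70)
  grade <- assign_grade(2000)
  pr <- sample_progression(onset, grade, nh)
  m <- pr$metastasis_age; d <- pr$clinical_detection_age
  # events never precede onset
  expect_true(all(is.na(m) | m >= onset))
  expect_true(all(is.na(d) | d >= onset))
  # when both occur, a recorded metastasis precedes (or ties) detection
  both <- !is.na(m) & !is.na(d)
  expect_true(all(m[both] <= d[both]))
  expect_error(sample_progression(NA_real_, "low_risk"), "onset_age")
})

test_that("first latent event is exponential in the PSA cumulative hazard", {
  # the hazard of min(metastasis, detection) is exp(P(t)) (gamma_m + gamma_c)
  # before any switch, so its survival has a closed form
  nh <- nh_params()
  psa <- psa_growth_params()
  onset <- 55; grade <- "high_risk"
  n <- 1e5
  set.seed(6)
  pr <- sample_progression(rep(onset, n), grade, nh, psa, max_age = 1000)
  first <- pmin(pr$metastasis_age, pr$clinical_detection_age, na.rm = TRUE)
  r <- psa$a0 + psa$a2
  K <- exp(psa$b - psa$a2 * onset)
  S <- function(t) exp(-(nh$gamma_m + nh$gamma_c) * K *
                         (exp(r * t) - exp(r * onset)) / r)
  grid <- seq(56, 100, by = 4)
  emp <- empirical_survival(first, grid, cap = 1000)
  expect_lt(max(abs(emp - S(grid))), sqrt(log(2 / 1e-6) / (2 * n)))
  # and conditional on racing, metastasis wins with prob gamma_m/(gamma_m+gamma_c)
  # (the recorded metastasis may still be followed by detection)
  pm <- nh$gamma_m / (nh$gamma_m + nh$gamma_c)
  met_first <- !is.na(pr$metastasis_age)
  expect_lt(abs(mean(met_first) - pm), 3 * sqrt(pm * (1 - pm) / n))
})
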