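test_that("substream seeds stay in the valid set.seed range", {
  sub <- pcascreen:::substream_seed
  seeds <- outer(c(1, 42, 1e6, 2^30, 2147483646), 0:1000, sub)
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_equal(sub(1, 5), sub(1, 5))
  expect_false(sub(1, 5) == sub(1, 6))
})

test_that("simulate_latent is reproducible and excludes prevalent cases", {
  cfg <- small_config(n = 5000)
  lat <- simulate_latent(cfg)
  lat2 <- simulate_latent(cfg)
  expect_identical(lat, lat2)
  expect_true(all(c("a0", "ocd_time", "onset_age", "grade", "met_age",
                    "cdet_age", "high_risk", "u_entry", "u_init") %in%
                    names(lat)))
  # nobody already clinically detected at entry
  expect_true(all(is.na(lat$cdet_age) | lat$cdet_age > lat$a0))
  expect_true(all(lat$ocd_time > 0))
  # by default onset accrues from each man's entry age
  expect_true(all(is.na(lat$onset_age) | lat$onset_age > lat$a0))
})

test_that("prevalent_latent seeds a latent pool before entry", {
  cfg <- small_config(n = 20000, prevalent_latent = TRUE)
  lat <- simulate_latent(cfg)
  # with accrual from the common start age some onsets precede entry
  expect_gt(sum(!is.na(lat$onset_age) & lat$onset_age < lat$a0), 0)
})

test_that("a strategy whose schedule nobody can reach equals the baseline", {
  ages <- 85:100
  pyr <- population_pyramid(ages, rev(seq_along(ages)))
  lt <- life_table(ages, pmin(1, 0.05 * exp(0.1 * (ages - 85))))
  cfg <- run_config(n_individuals = 3000, seed = 11L,
                    pyramid = pyr, life_table = lt)
  lat <- simulate_latent(cfg)
  base <- run_scenario(cfg, no_screening(), lat)
  idle <- run_scenario(cfg, screening_strategy(45, 74, 1), lat)
  expect_identical(idle$yearly, base$yearly)
  expect_identical(idle$econ, base$econ)
  expect_identical(idle$diagnoses, base$diagnoses)
  expect_identical(idle$pca_deaths, base$pca_deaths)
  expect_equal(idle$resources$psa_tests, 0)
})

test_that("scenario invariants hold and screening shifts stage at detection", {
  cfg <- small_config(n = 20000, seed = 3L)
  lat <- simulate_latent(cfg)
  base <- run_scenario(cfg, no_screening(), lat)
  annual <- run_scenario(cfg, screening_strategy(45, 74, 1, "age_specific"), lat)
  q5 <- run_scenario(cfg, screening_strategy(45, 74, 5, "age_specific"), lat)
  # identical runs are bit-identical (common random numbers)
  expect_identical(run_scenario(cfg, no_screening(), lat), base)
  # structural invariants
  for (r in list(base, annual, q5)) {
    expect_lte(r$metastatic_diagnoses, r$diagnoses)
    expect_lte(r$pca_deaths, r$all_markov_deaths)
    expect_equal(sum(r$yearly$diagnoses >= r$yearly$metastatic), 30)
  }
  # screening multiplies diagnoses and resource use
  expect_gt(annual$diagnoses, base$diagnoses)
  expect_gt(annual$resources$psa_tests, q5$resources$psa_tests)
  # and lowers the metastatic share at detection
  expect_lt(annual$metastatic_diagnoses / annual$diagnoses,
            base$metastatic_diagnoses / base$diagnoses)
})

test_that("pca_death_states and lifetime_prognosis flags act as documented", {
  lat_cfg <- small_config(n = 20000, seed = 3L)
  lat <- simulate_latent(lat_cfg)
  all_states <- run_scenario(lat_cfg, screening_strategy(45, 74, 1), lat)
  met_cfg <- small_config(n = 20000, seed = 3L,
                          pca_death_states = c("mHSPC", "nmCRPC", "mCRPC"))
  met_only <- run_scenario(met_cfg, screening_strategy(45, 74, 1), lat)
  expect_lte(met_only$pca_deaths, all_states$pca_deaths)
  expect_equal(met_only$diagnoses, all_states$diagnoses)
  trunc_cfg <- small_config(n = 20000, seed = 3L, lifetime_prognosis = FALSE)
  trunc <- run_scenario(trunc_cfg, screening_strategy(45, 74, 1), lat)
  expect_lte(trunc$econ$cost_percap, all_states$econ$cost_percap)
  expect_lte(trunc$econ$qaly_percap, all_states$econ$qaly_percap)
  expect_error(run_config(pca_death_states = "Death"), "non-Death")
})

test_that("default_strategy_grid enumerates 60 uniquely named strategies", {
  g <- default_strategy_grid()
  expect_length(g, 60)
  expect_false(anyDuplicated(names(g)) > 0)
  expect_length(default_strategy_grid(risk_stratified = FALSE), 32)
})

test_that("run_grid compares strategies against the baseline consistently", {
  cfg <- small_config(
    n = 5000, seed = 2L,
    strategies = list(screening_strategy(60, 74, 5),
                      screening_strategy(45, 74, 1, "age_specific")))
  gr <- run_grid(cfg)
  expect_s3_class(gr, "grid_result")
  expect_equal(nrow(gr$comparison), 2)
  cmp <- gr$comparison
  expect_equal(cmp$dC, cmp$cost - gr$baseline$econ$cost_percap)
  ok <- !is.na(cmp$icer)
  expect_equal(cmp$icer[ok], (cmp$dC / cmp$dQ)[ok])
  # M/I identity within each row
  expect_equal(cmp$mi_ratio, cmp$metastatic / cmp$incidence * 100)
})
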