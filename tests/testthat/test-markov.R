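test_that("transition_matrix is a valid stochastic matrix", {
  tm <- transition_matrix()
  expect_equal(dim(tm), c(8, 8))
  expect_equal(unname(rowSums(tm)), rep(1, 8))
  expect_true(all(tm >= 0))
  # Death absorbing
  expect_equal(unname(tm["Death", ]), c(rep(0, 7), 1))
  # stay probabilities are the row-sum complements
  expect_equal(unname(tm["mHSPC", "mHSPC"]), 1 - 0.000657 - 0.018824)
  expect_equal(unname(tm["mCRPC", "mCRPC"]), 1 - 0.045317)
  # invalid tables rejected
  bad <- data.frame(from = "RP", to = "RT", p = 1.2)
  expect_error(transition_matrix(bad), "\\[0, 1\\]")
  bad2 <- data.frame(from = c("RT", "RT"), to = c("Death", "mHSPC"),
                     p = c(0.9, 0.2))
  expect_error(transition_matrix(bad2), "row sum")
  expect_error(transition_matrix(data.frame(from = "X", to = "RP", p = 0.1)),
               "unknown state")
})

test_that("init_state splits localized RP/RT and sends metastatic to mHSPC", {
  u <- c(0.1, 0.95)
  expect_equal(init_state(c("localized", "localized"), entry_rule(0.9), u),
               c(1L, 2L))
  expect_equal(init_state("metastatic", entry_rule(), u = 0.5), 5L)
  expect_error(init_state("regional"), "unknown stage")
  expect_error(entry_rule(1.2), "localized_rp_share")
})

test_that("markov_step keeps Death absorbing and respects the matrix", {
  tm <- transition_matrix()
  expect_equal(markov_step(rep(8L, 5), tm), rep(8L, 5))
  # u below the first cumulative cell stays (diagonal-first ordering not
  # assumed: check via the deterministic cohort instead)
  set.seed(31)
  s1 <- markov_step(rep(7L, 1e4), tm)
  expect_true(all(s1 %in% c(7L, 8L)))
  p <- 0.045317
  expect_lt(abs(mean(s1 == 8L) - p), 3 * sqrt(p * (1 - p) / 1e4))
})

test_that("mCRPC sojourn matches the geometric closed form", {
  # E[months in mCRPC] = 1 / p_death = 22.07
  p <- 0.045317
  expect_equal(1 / p, 22.0668, tolerance = 1e-4)
  tm <- transition_matrix()
  n <- 1e5
  set.seed(32)
  months <- rgeom(n, p) + 1  # direct geometric reference
  state <- rep(7L, n); sojourn <- numeric(n); active <- seq_len(n)
  m <- 0
  while (length(active) && m < 2000) {
    sojourn[active] <- sojourn[active] + 1
    state[active] <- markov_step(state[active], tm)
    active <- active[state[active] != 8L]
    m <- m + 1
  }
  se <- sqrt(p * (1 - p)) / p^2 / sqrt(n)  # SD of geometric / sqrt(n)
  expect_lt(abs(mean(sojourn) - 1 / p), 3 * se)
  expect_lt(abs(mean(sojourn) - mean(months)), 6 * se)
})

test_that("cohort_solve conserves mass and matches closed forms", {
  tm <- transition_matrix()
  init <- c(1000, 0, 0, 0, 0, 0, 0, 0)
  occ <- cohort_solve(init, tm, 360)
  expect_equal(unname(rowSums(occ)), rep(1000, 361))
  expect_true(all(occ >= -1e-9))
  # Death occupancy non-decreasing
  expect_true(all(diff(occ[, "Death"]) >= -1e-12))
  # pure-mCRPC cohort decays geometrically
  occ2 <- cohort_solve(c(0, 0, 0, 0, 0, 0, 1, 0), tm, 24)
  expect_equal(occ2[, "mCRPC"], (1 - 0.045317)^(0:24))
  expect_error(cohort_solve(c(1, 2), tm, 10))
})

test_that("monthly entry split is uniform", {
  expect_equal(enter_monthly_cohort(120), rep(10, 12))
  expect_error(enter_monthly_cohort(-1), "non-negative")
  set.seed(33)
  m <- sample_entry_month(1e5)
  expect_true(all(m %in% 0:11))
  expect_gt(chisq.test(tabulate(m + 1L, 12))$p.value, 1e-6)
})
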