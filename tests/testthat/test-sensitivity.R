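test_that("param_spec and default specs are well-formed", {
  expect_error(param_spec("x", base = 2, low = 3, high = 4), "low <= base")
  specs <- default_param_specs()
  expect_gt(length(specs), 40)
  expect_false(anyDuplicated(names(specs)) > 0)
  for (sp in specs) {
    expect_true(sp$low <= sp$base && sp$base <= sp$high)
  }
})

test_that("set_config_param reaches nested groups and transitions", {
  cfg <- small_config(n = 100)
  cfg2 <- set_config_param(cfg, "nh.gamma_o", 0.001)
  expect_equal(cfg2$nh$gamma_o, 0.001)
  cfg3 <- set_config_param(cfg, "tp.mCRPC.Death", 0.05)
  i <- with(cfg3$transitions, from == "mCRPC" & to == "Death")
  expect_equal(cfg3$transitions$p[i], 0.05)
  expect_equal(unname(transition_matrix(cfg3$transitions)["mCRPC", "Death"]),
               0.05)
  expect_error(set_config_param(cfg, "tp.RP.RT", 0.1), "unknown transition")
  expect_error(set_config_param(cfg, "magic.x", 1), "unknown parameter group")
  expect_error(set_config_param(cfg, "nh.zeta", 1), "unknown parameter")
})

test_that("one_way orders the tornado by ICER spread", {
  cfg <- small_config(n = 500)
  specs <- list(
    param_spec("nh.gamma_o", 0.00024, 0.00012, 0.00048),
    param_spec("utilities.rp", 0.8, 0.4, 1.0))
  strat <- screening_strategy(45, 74, 1)
  out <- one_way(cfg, specs, strat, engine = fake_engine)
  expect_equal(nrow(out), 4)
  expect_true(all(is.na(out$error)))
  # fake engine: dC = 500 * gamma_o/0.00024, dQ = 0.25 * rp/0.8
  g <- out[out$param == "nh.gamma_o", ]
  expect_equal(sort(g$icer), c(250, 1000) / 0.25)
  u <- out[out$param == "utilities.rp", ]
  expect_equal(sort(u$icer), sort(500 / (0.25 * c(0.4, 1.0) / 0.8)))
  # gamma_o spread (3000) exceeds rp spread (2400): listed first
  expect_equal(out$param[1], "nh.gamma_o")
  expect_true(all(diff(rank(-out$spread, ties.method = "min")) >= 0))
})

test_that("probabilistic analysis respects distributions and CRN", {
  cfg <- small_config(n = 500)
  strats <- list(screening_strategy(45, 74, 1))
  degen <- list(param_spec("nh.gamma_o", 0.00024, 0.0001, 0.001,
                           dist = "degenerate"))
  ps <- probabilistic(cfg, degen, strats, n_iterations = 3,
                      engine = fake_engine)
  expect_s3_class(ps, "psa_result_set")
  expect_equal(nrow(ps$results), 3)
  expect_true(all(ps$draws == 0.00024))
  expect_equal(ps$n_redraws, 0)
  # identical parameters -> identical increments in every iteration
  expect_equal(diff(range(ps$results$dC)), 0)
  expect_equal(diff(range(ps$results$dQ)), 0)
  unif <- list(param_spec("nh.gamma_o", 0.00024, 0.0002, 0.0003))
  ps2 <- probabilistic(cfg, unif, strats, n_iterations = 5, seed = 2L,
                       engine = fake_engine)
  expect_true(all(ps2$draws >= 0.0002 & ps2$draws <= 0.0003))
  expect_gt(stats::var(ps2$results$dC), 0)
  expect_error(probabilistic(cfg, unif, strats, n_iterations = 0), "n_iterations")
})

test_that("ceac computes acceptability from NMB", {
  ps <- structure(list(results = data.frame(
    iteration = rep(1:4, 2),
    strategy = rep(c("A", "B"), each = 4),
    dC = c(rep(1000, 4), c(500, 1500, 2500, 3500)),
    dQ = c(rep(1, 4), rep(1, 4)))), class = "psa_result_set")
  cc <- ceac(ps, wtp_grid = c(0, 999, 1000, 2000, 4000))
  a <- cc[cc$strategy == "A", ]
  expect_equal(a$prob_cost_effective, c(0, 0, 1, 1, 1))
  b <- cc[cc$strategy == "B", ]
  expect_equal(b$prob_cost_effective, c(0, 0.25, 0.25, 0.5, 1))
  # monotone non-decreasing in WTP when all dQ > 0
  expect_true(all(diff(a$prob_cost_effective) >= 0))
  expect_true(all(diff(b$prob_cost_effective) >= 0))
})

test_that("one_way runs end-to-end with the real engine", {
  cfg <- small_config(n = 2000)
  specs <- list(param_spec("costs.psa", 3.78, 2.84, 4.73))
  out <- one_way(cfg, specs, screening_strategy(45, 74, 2), engine = run_scenario)
  expect_equal(nrow(out), 2)
  expect_true(all(is.na(out$error)))
  # higher PSA cost -> higher incremental cost, identical QALYs (CRN)
  expect_gt(out$dC[out$bound == "high"], out$dC[out$bound == "low"])
  expect_equal(out$dQ[out$bound == "high"], out$dQ[out$bound == "low"])
})
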