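# One-way and probabilistic sensitivity analysis, and cost-effectiveness
# acceptability curves.

#' Sensitivity-analysis parameter specification
#'
#' @param name dotted configuration path, e.g. `"nh.gamma_o"`,
#'   `"costs.mcrpc"`, `"tp.mCRPC.Death"` (a transition probability).
#' @param base baseline value.
#' @param low,high range bounds with `low <= base <= high`.
#' @param dist sampling distribution for probabilistic analysis:
#'   `"uniform"` on the range, or `"degenerate"` (always the baseline).
#' @return object of class `param_spec`.
#' @export
param_spec <- function(name, base, low, high, dist = c("uniform", "degenerate")) {
  dist <- match.arg(dist)
  if (!(low <= base && base <= high)) stop("need low <= base <= high: ", name)
  structure(list(name = name, base = base, low = low, high = high,
                 dist = dist), class = "param_spec")
}

#' Default parameter specifications
#'
#' Every varied model parameter with its published plausible range:
#' hazard and PSA-growth parameters, test characteristics, the sixteen
#' transition probabilities, costs and utilities (ranges are 95\% CIs where
#' available, otherwise 0.75-1.33x for exponential-scale parameters and
#' 0.75-1.25x for linear ones).
#'
#' @return named list of [param_spec()] objects.
#' @export
default_param_specs <- function() {
  rows <- list(
    list("nh.gamma_o", 0.00024, 0.00018, 0.00032),
    list("nh.gamma_m", 0.0004, 0.0003, 0.00052),
    list("nh.gamma_c", 0.0005, 0.00038, 0.00067),
    list("nh.gamma_LR", 0.673, 0.505, 0.897),
    list("nh.theta_c", 19.1334, 14.3500, 25.5112),
    list("psa.a0", 0.0215, 0.0210, 0.0220),
    list("psa.a1", 0.0566, 0.0430, 0.0693),
    list("psa.a2", 0.1051, 0.0870, 0.1247),
    list("psa.b", -0.1061, -0.1670, -0.046),
    list("tests.mri_sens", 0.89, 0.83, 0.93),
    list("tests.mri_spec", 0.80, 0.62, 0.90),
    list("tests.biopsy_sens", 0.64, 0.48, 0.80),
    list("tests.biopsy_spec", 1.00, 0.90, 1.00),
    list("tp.RP.BCR_RP", 0.011431, 0.010574, 0.012297),
    list("tp.RP.mHSPC", 0.002305, 0.001927, 0.002685),
    list("tp.RP.Death", 0.000434, 0.000270, 0.000598),
    list("tp.RT.BCR_RT", 0.037776, 0.034893, 0.040758),
    list("tp.RT.mHSPC", 0.008584, 0.007293, 0.009895),
    list("tp.RT.Death", 0.070772, 0.066492, 0.075280),
    list("tp.BCR_RP.nmCRPC", 0.000045, 0.000000, 0.000132),
    list("tp.BCR_RP.mHSPC", 0.001437, 0.000941, 0.001936),
    list("tp.BCR_RP.Death", 0.000761, 0.000400, 0.001123),
    list("tp.BCR_RT.nmCRPC", 0.000904, 0.000315, 0.001496),
    list("tp.BCR_RT.mHSPC", 0.005351, 0.003911, 0.006813),
    list("tp.BCR_RT.Death", 0.053892, 0.048843, 0.059255),
    list("tp.mHSPC.mCRPC", 0.000657, 0.000501, 0.000814),
    list("tp.mHSPC.Death", 0.018824, 0.017956, 0.019700),
    list("tp.nmCRPC.mCRPC", 0.001153, 0.000503, 0.001807),
    list("tp.nmCRPC.Death", 0.040735, 0.036570, 0.045109),
    list("tp.mCRPC.Death", 0.045317, 0.040162, 0.050797),
    list("costs.psa", 3.78, 2.84, 4.73),
    list("costs.mri", 148.05, 111.04, 185.06),
    list("costs.biopsy", 161.70, 121.28, 202.13),
    list("costs.rp", 6594.70, 4946.03, 8243.38),
    list("costs.rt", 4550.00, 3412.50, 5687.50),
    list("costs.post_trt_adt", 312.23, 234.18, 390.29),
    list("costs.monitoring", 3.78, 2.84, 4.73),
    list("costs.bcr_adt", 297.81, 223.36, 372.27),
    list("costs.mhspc", 1060.98, 795.74, 1326.23),
    list("costs.nmcrpc", 1004.09, 753.06, 1255.11),
    list("costs.mcrpc", 2054.00, 1540.50, 2567.50),
    list("utilities.rp", 0.800, 0.600, 1.000),
    list("utilities.rt", 0.800, 0.600, 1.000),
    list("utilities.bcr_rp", 0.790, 0.593, 0.988),
    list("utilities.bcr_rt", 0.790, 0.593, 0.988),
    list("utilities.mhspc", 0.755, 0.566, 0.944),
    list("utilities.nmcrpc", 0.775, 0.581, 0.969),
    list("utilities.mcrpc", 0.726, 0.545, 0.908))
  out <- lapply(rows, function(r) param_spec(r[[1]], r[[2]], r[[3]], r[[4]]))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Set one parameter in a run configuration
#'
#' @param config a [run_config()].
#' @param name dotted path as in [param_spec()].
#' @param value new value.
#' @return the modified configuration.
#' @export
set_config_param <- function(config, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (parts[1] == "tp") {
    i <- which(config$transitions$from == parts[2] &
                 config$transitions$to == parts[3])
    if (length(i) != 1) stop("unknown transition: ", name)
    config$transitions$p[i] <- value
    return(config)
  }
  grp <- parts[1]
  if (!grp %in% c("nh", "psa", "tests", "costs", "utilities", "econ",
                  "entry", "risk"))
    stop("unknown parameter group: ", grp)
  if (!parts[2] %in% names(config[[grp]]))
    stop("unknown parameter: ", name)
  config[[grp]][[parts[2]]] <- value
  config
}

run_icer_at <- function(config, strategy, engine) {
  latent <- simulate_latent(config)
  base <- engine(config, no_screening(), latent)
  res <- engine(config, strategy, latent)
  icer(res$econ$cost_percap, res$econ$qaly_percap,
       base$econ$cost_percap, base$econ$qaly_percap, name = strategy$name)
}

#' One-way sensitivity analysis
#'
#' Re-evaluates the incremental cost-effectiveness of one strategy vs the
#' no-screening baseline with each parameter in turn set to its low and high
#' bound (all others at baseline). Both the baseline and the strategy are
#' re-simulated at every setting, with common random numbers. Rows are
#' returned in tornado order (largest ICER spread first).
#'
#' @param config a [run_config()].
#' @param specs list of [param_spec()] (default [default_param_specs()]).
#' @param strategy a [screening_strategy()].
#' @param engine scenario engine `(config, strategy, latent) -> result`;
#'   defaults to [run_scenario()].
#' @return data.frame with columns `param`, `bound`, `value`, `dC`, `dQ`,
#'   `icer` (and an error message column for failed rows).
#' @export
one_way <- function(config, specs = default_param_specs(), strategy,
                    engine = run_scenario) {
  rows <- list()
  for (sp in specs) {
    for (bound in c("low", "high")) {
      v <- sp[[bound]]
      row <- data.frame(param = sp$name, bound = bound, value = v,
                        dC = NA_real_, dQ = NA_real_, icer = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      ce <- tryCatch(run_icer_at(set_config_param(config, sp$name, v),
                                 strategy, engine),
                     error = function(e) conditionMessage(e))
      if (is.character(ce)) row$error <- ce
      else { row$dC <- ce$dC; row$dQ <- ce$dQ; row$icer <- ce$icer }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  spread <- tapply(out$icer, out$param,
                   function(x) diff(range(x, na.rm = TRUE)))
  out$spread <- spread[out$param]
  out[order(-out$spread, out$param, out$bound), ]
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters simultaneously from their distributions for
#' `n_iterations` iterations; within an iteration every strategy (and the
#' baseline) sees the same parameter draw and the same population random
#' numbers. Draws that push any Markov row sum above 1 are redrawn (counted
#' and reported).
#'
#' @param config a [run_config()].
#' @param specs list of [param_spec()].
#' @param strategies list of [screening_strategy()].
#' @param n_iterations number of parameter draws.
#' @param seed seed for the parameter-draw stream (population seeds stay at
#'   `config$seed`).
#' @param engine scenario engine, defaults to [run_scenario()].
#' @return object of class `psa_result_set`: `results` (data.frame
#'   `iteration, strategy, dC, dQ`), `draws` (matrix), `n_redraws`.
#' @export
probabilistic <- function(config, specs = default_param_specs(), strategies,
                          n_iterations = 1000, seed = 1L,
                          engine = run_scenario) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  set.seed(seed)
  pnames <- vapply(specs, `[[`, "", "name")
  draws <- matrix(NA_real_, n_iterations, length(specs),
                  dimnames = list(NULL, pnames))
  n_redraws <- 0L
  results <- list()
  for (it in seq_len(n_iterations)) {
    repeat {
      v <- vapply(specs, function(sp)
        if (sp$dist == "degenerate") sp$base
        else stats::runif(1, sp$low, sp$high), 0)
      cfg <- config
      for (j in seq_along(specs))
        cfg <- set_config_param(cfg, specs[[j]]$name, v[j])
      ok <- tryCatch({ transition_matrix(cfg$transitions); TRUE },
                     error = function(e) FALSE)
      if (ok) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 100 * n_iterations) stop("too many invalid draws")
    }
    draws[it, ] <- v
    latent <- simulate_latent(cfg)
    base <- engine(cfg, no_screening(), latent)
    for (s in strategies) {
      res <- engine(cfg, s, latent)
      results[[length(results) + 1L]] <- data.frame(
        iteration = it, strategy = s$name,
        dC = res$econ$cost_percap - base$econ$cost_percap,
        dQ = res$econ$qaly_percap - base$econ$qaly_percap,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(results = do.call(rbind, results), draws = draws,
                 n_iterations = n_iterations, n_redraws = n_redraws,
                 seed = seed),
            class = "psa_result_set")
}

#' Cost-effectiveness acceptability curves
#'
#' For each strategy, the fraction of probabilistic iterations with
#' non-negative net monetary benefit at each willingness-to-pay value.
#'
#' @param psa a `psa_result_set` from [probabilistic()].
#' @param wtp_grid willingness-to-pay values (USD/QALY).
#' @return data.frame with columns `strategy`, `wtp`,
#'   `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 20000, by = 500)) {
  if (!nrow(psa$results)) stop("empty PSA result set")
  out <- list()
  for (s in unique(psa$results$strategy)) {
    r <- psa$results[psa$results$strategy == s, ]
    p <- vapply(wtp_grid, function(w) mean(nmb(r$dC, r$dQ, w) >= 0), 0)
    out[[s]] <- data.frame(strategy = s, wtp = wtp_grid,
                           prob_cost_effective = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
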