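# Costs, utilities, discounting, and incremental cost-effectiveness measures.

#' Cost table (USD)
#'
#' One-time event costs and monthly state costs. Monthly disease-state costs
#' are mapped from the table rows as: RP/RT states incur monitoring plus
#' post-treatment ADT; BCR states incur monitoring plus BCR ADT; mHSPC,
#' nmCRPC and mCRPC incur their named monthly treatment costs.
#'
#' @param psa,mri,biopsy,rp,rt,wgs,prs one-time costs.
#' @param post_trt_adt,monitoring,bcr_adt,mhspc,nmcrpc,mcrpc monthly costs.
#' @return object of class `cost_table`.
#' @export
cost_table <- function(psa = 3.78, mri = 148.05, biopsy = 161.70,
                       rp = 6594.70, rt = 4550.00, wgs = 252.00, prs = 16.81,
                       post_trt_adt = 312.23, monitoring = 3.78,
                       bcr_adt = 297.81, mhspc = 1060.98, nmcrpc = 1004.09,
                       mcrpc = 2054.00) {
  x <- list(psa = psa, mri = mri, biopsy = biopsy, rp = rp, rt = rt,
            wgs = wgs, prs = prs, post_trt_adt = post_trt_adt,
            monitoring = monitoring, bcr_adt = bcr_adt, mhspc = mhspc,
            nmcrpc = nmcrpc, mcrpc = mcrpc)
  if (any(unlist(x) < 0)) stop("costs must be non-negative")
  structure(x, class = "cost_table")
}

#' Monthly cost per Markov state
#' @param costs a [cost_table()].
#' @return numeric vector over [markov_states()].
#' @export
state_monthly_cost <- function(costs = cost_table()) {
  c(RP = costs$monitoring + costs$post_trt_adt,
    RT = costs$monitoring + costs$post_trt_adt,
    BCR_RP = costs$monitoring + costs$bcr_adt,
    BCR_RT = costs$monitoring + costs$bcr_adt,
    mHSPC = costs$mhspc, nmCRPC = costs$nmcrpc, mCRPC = costs$mcrpc,
    Death = 0)
}

#' Health-state utilities
#'
#' EQ-5D utilities per state-month (applied as `utility / 12` per monthly
#' cycle). `undiagnosed` is the utility weight attached to pre-diagnosis
#' person-time; the headline cost-effectiveness comparison accrues QALYs
#' along the disease course only (see the package vignette), so the engine
#' default sets it to zero, while trajectory-level accounting with
#' `undiagnosed = 1` gives whole-life QALYs.
#'
#' @param rp,rt,bcr_rp,bcr_rt,mhspc,nmcrpc,mcrpc state utilities in `[0,1]`.
#' @param death utility of the Death state (0).
#' @param undiagnosed utility weight for pre-diagnosis person-time.
#' @return object of class `utility_table`.
#' @export
utility_table <- function(rp = 0.800, rt = 0.800, bcr_rp = 0.790,
                          bcr_rt = 0.790, mhspc = 0.755, nmcrpc = 0.775,
                          mcrpc = 0.726, death = 0, undiagnosed = 1.0) {
  x <- list(rp = rp, rt = rt, bcr_rp = bcr_rp, bcr_rt = bcr_rt,
            mhspc = mhspc, nmcrpc = nmcrpc, mcrpc = mcrpc, death = death,
            undiagnosed = undiagnosed)
  if (any(unlist(x) < 0 | unlist(x) > 1)) stop("utilities must lie in [0, 1]")
  structure(x, class = "utility_table")
}

#' Utility per Markov state
#' @param utilities a [utility_table()].
#' @return numeric vector over [markov_states()].
#' @export
state_utility <- function(utilities = utility_table()) {
  c(RP = utilities$rp, RT = utilities$rt, BCR_RP = utilities$bcr_rp,
    BCR_RT = utilities$bcr_rt, mHSPC = utilities$mhspc,
    nmCRPC = utilities$nmcrpc, mCRPC = utilities$mcrpc,
    Death = utilities$death)
}

#' Economic evaluation parameters
#'
#' @param annual_discount annual discount rate for both costs and QALYs.
#' @param horizon_years simulation horizon.
#' @param wtp_national national willingness-to-pay threshold (USD/QALY).
#' @param wtp_regional named vector of regional thresholds.
#' @return object of class `econ_params`.
#' @export
econ_params <- function(annual_discount = 0.03, horizon_years = 30,
                        wtp_national = 12510.12,
                        wtp_regional = c(Gansu = 6738.06, Hunan = 10602.35,
                                         Guangdong = 15007.15,
                                         Zhejiang = 17493.90,
                                         Jiangsu = 21081.75,
                                         Shanghai = 26699.95)) {
  if (annual_discount < 0) stop("discount rate must be non-negative")
  structure(list(annual_discount = annual_discount,
                 horizon_years = horizon_years,
                 wtp_national = wtp_national, wtp_regional = wtp_regional),
            class = "econ_params")
}

#' Monthly discount factor
#'
#' `(1 + rate)^(-month / 12)`: month 0 is undiscounted.
#'
#' @param month_index month index (>= 0), vectorised.
#' @param annual_rate annual discount rate.
#' @return dimensionless factor.
#' @export
discount_factor <- function(month_index, annual_rate = 0.03) {
  if (annual_rate < 0) stop("rate must be non-negative")
  (1 + annual_rate)^(-month_index / 12)
}

# Sum of discount factors over months m1..(m2-1); closed-form geometric sum.
discount_month_sum <- function(m1, m2, annual_rate) {
  if (annual_rate == 0) return(pmax(m2 - m1, 0))
  v <- (1 + annual_rate)^(-1 / 12)
  out <- (v^m1 - v^m2) / (1 - v)
  pmax(out, 0)
}

#' Accumulate discounted costs and QALYs along one trajectory
#'
#' `trajectory` is a data.frame with columns `month` and `state`, one row per
#' lived month; states are [markov_states()] entries or `"undiagnosed"`.
#' `events` is an optional data.frame with columns `month` and `cost` of
#' one-time costs. Each state-month contributes its monthly cost and
#' `utility / 12` QALYs, both discounted to month 0; Death contributes
#' nothing.
#'
#' @param trajectory per-month states.
#' @param events one-time costs.
#' @param costs a [cost_table()].
#' @param utilities a [utility_table()].
#' @param econ an [econ_params()].
#' @return named vector `c(cost = , qaly = )`, discounted USD and QALYs.
#' @export
accumulate <- function(trajectory, events = NULL, costs = cost_table(),
                       utilities = utility_table(), econ = econ_params()) {
  known <- c(markov_states(), "undiagnosed")
  if (any(!trajectory$state %in% known))
    stop("unknown state: ",
         paste(setdiff(trajectory$state, known), collapse = ", "))
  sc <- c(state_monthly_cost(costs), undiagnosed = 0)
  su <- c(state_utility(utilities), undiagnosed = utilities$undiagnosed)
  v <- discount_factor(trajectory$month, econ$annual_discount)
  cost <- sum(sc[trajectory$state] * v)
  qaly <- sum(su[trajectory$state] / 12 * v)
  if (!is.null(events) && nrow(events))
    cost <- cost + sum(events$cost *
                         discount_factor(events$month, econ$annual_discount))
  c(cost = cost, qaly = qaly)
}

#' Incremental cost-effectiveness ratio
#'
#' @param cost,qaly discounted per-capita totals of the strategy.
#' @param baseline_cost,baseline_qaly the comparator's totals.
#' @param name optional strategy label.
#' @return object of class `cea_result` with `dC`, `dQ`, `icer` (`NA` when
#'   `dQ == 0`) and a `dominant` flag (`dC < 0` and `dQ > 0`).
#' @export
icer <- function(cost, qaly, baseline_cost, baseline_qaly, name = NULL) {
  dC <- cost - baseline_cost
  dQ <- qaly - baseline_qaly
  structure(list(strategy = name, cost = cost, qaly = qaly,
                 dC = dC, dQ = dQ,
                 icer = if (dQ != 0) dC / dQ else NA_real_,
                 dominant = dC < 0 && dQ > 0),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("cea_result%s: dC = %.2f USD, dQ = %.4f QALY, ICER = %s\n",
              if (is.null(x$strategy)) "" else paste0(" [", x$strategy, "]"),
              x$dC, x$dQ,
              if (is.na(x$icer)) "undefined" else sprintf("%.2f USD/QALY", x$icer)))
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * dQ - dC`; non-negative NMB is equivalent to ICER <= wtp when
#' `dQ > 0`.
#'
#' @param dC incremental cost (USD).
#' @param dQ incremental QALYs.
#' @param wtp willingness-to-pay threshold (USD/QALY, >= 0).
#' @return USD.
#' @export
nmb <- function(dC, dQ, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative")
  wtp * dQ - dC
}
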