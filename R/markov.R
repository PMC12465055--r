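# Eight-state monthly Markov model of post-diagnosis prognosis:
# RP, RT, BCR_RP, BCR_RT, mHSPC, nmCRPC, mCRPC, Death.
# Only the transitions observed in the source cohort are non-zero; the stay
# probability is the complement of each row sum and Death is absorbing.

#' Markov state names
#' @return character vector of the eight states, in canonical order.
#' @export
markov_states <- function() {
  c("RP", "RT", "BCR_RP", "BCR_RT", "mHSPC", "nmCRPC", "mCRPC", "Death")
}

#' Default monthly transition probabilities
#'
#' The sixteen observed source-to-target monthly probabilities.
#'
#' @return data.frame with columns `from`, `to`, `p`.
#' @export
default_transitions <- function() {
  data.frame(
    from = c("RP", "RP", "RP",
             "RT", "RT", "RT",
             "BCR_RP", "BCR_RP", "BCR_RP",
             "BCR_RT", "BCR_RT", "BCR_RT",
             "mHSPC", "mHSPC",
             "nmCRPC", "nmCRPC",
             "mCRPC"),
    to = c("BCR_RP", "mHSPC", "Death",
           "BCR_RT", "mHSPC", "Death",
           "nmCRPC", "mHSPC", "Death",
           "nmCRPC", "mHSPC", "Death",
           "mCRPC", "Death",
           "mCRPC", "Death",
           "Death"),
    p = c(0.011431, 0.002305, 0.000434,
          0.037776, 0.008584, 0.070772,
          0.000045, 0.001437, 0.000761,
          0.000904, 0.005351, 0.053892,
          0.000657, 0.018824,
          0.001153, 0.040735,
          0.045317))
}

#' Build and validate a monthly transition matrix
#'
#' Constructs the full 8x8 monthly matrix from a `from,to,p` table, filling
#' each diagonal with the complement of the row sum and making Death
#' absorbing. Rows whose off-diagonal probabilities exceed 1 are rejected.
#'
#' @param transitions data.frame with columns `from`, `to`, `p` (defaults to
#'   [default_transitions()]).
#' @return 8x8 matrix of class `transition_matrix` with dimnames
#'   [markov_states()].
#' @export
transition_matrix <- function(transitions = default_transitions()) {
  st <- markov_states()
  if (any(!transitions$from %in% st) || any(!transitions$to %in% st))
    stop("unknown state in transition table")
  if (any(transitions$p < 0 | transitions$p > 1))
    stop("transition probabilities must lie in [0, 1]")
  m <- matrix(0, 8, 8, dimnames = list(st, st))
  for (i in seq_len(nrow(transitions)))
    m[transitions$from[i], transitions$to[i]] <-
      m[transitions$from[i], transitions$to[i]] + transitions$p[i]
  rs <- rowSums(m)
  if (any(rs > 1 + 1e-12))
    stop("row sum exceeds 1 for state(s): ",
         paste(st[rs > 1 + 1e-12], collapse = ", "))
  diag(m) <- diag(m) + 1 - rs
  m["Death", ] <- 0; m["Death", "Death"] <- 1
  structure(m, class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("monthly transition matrix (8 states, Death absorbing)\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Markov entry rule
#'
#' Newly diagnosed localized disease enters radical prostatectomy (RP) with
#' probability `localized_rp_share` and radiotherapy (RT) otherwise;
#' metastatic disease enters mHSPC.
#'
#' @param localized_rp_share probability that a localized case is treated
#'   with RP (around 90\% of localized patients receive surgery rather than
#'   radiotherapy in the modelled setting).
#' @return object of class `entry_rule`.
#' @export
entry_rule <- function(localized_rp_share = 0.90) {
  if (localized_rp_share < 0 || localized_rp_share > 1)
    stop("localized_rp_share must lie in [0, 1]")
  structure(list(localized_rp_share = localized_rp_share),
            class = "entry_rule")
}

#' Initial Markov state at diagnosis
#'
#' @param stage `"localized"` or `"metastatic"` per individual (vectorised).
#' @param entry an [entry_rule()].
#' @param u optional uniform deviates for the RP/RT split (common random
#'   numbers).
#' @return integer state indices into [markov_states()].
#' @export
init_state <- function(stage, entry = entry_rule(), u = NULL) {
  n <- length(stage)
  if (is.null(u)) u <- stats::runif(n)
  out <- integer(n)
  loc <- stage == "localized"
  out[loc] <- ifelse(u[loc] < entry$localized_rp_share, 1L, 2L)
  out[!loc] <- 5L   # mHSPC
  if (any(!stage %in% c("localized", "metastatic"))) stop("unknown stage")
  out
}

#' One Markov step
#'
#' Vectorised categorical draw of next states; Death is absorbing.
#'
#' @param state integer state indices (1..8).
#' @param tm a [transition_matrix()].
#' @param u optional uniform deviates.
#' @return integer vector of next states.
#' @export
markov_step <- function(state, tm, u = NULL) {
  if (is.null(u)) u <- stats::runif(length(state))
  cum <- t(apply(unclass(tm), 1, cumsum))
  nxt <- integer(length(state))
  for (s in unique(state)) {
    i <- which(state == s)
    nxt[i] <- findInterval(u[i], cum[s, ], left.open = FALSE) + 1L
  }
  pmin(nxt, 8L)
}

#' Split a yearly diagnosed cohort over monthly entry cycles
#'
#' Deterministic (cohort) version: each of the 12 months receives
#' `count / 12`. For microsimulation, [sample_entry_month()] assigns each man
#' a uniform entry month.
#'
#' @param yearly_diagnosed non-negative count.
#' @return numeric vector of 12 monthly entries.
#' @export
enter_monthly_cohort <- function(yearly_diagnosed) {
  if (yearly_diagnosed < 0) stop("count must be non-negative")
  rep(yearly_diagnosed / 12, 12)
}

#' @rdname enter_monthly_cohort
#' @param n number of men.
#' @param u optional uniform deviates.
#' @return integer entry months in `0:11`.
#' @export
sample_entry_month <- function(n, u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  as.integer(floor(u * 12))
}

#' Deterministic cohort occupancy
#'
#' Expected state occupancy over time by repeated application of the
#' transition matrix; the deterministic oracle for the stochastic walker.
#'
#' @param init occupancy vector over the 8 states at month 0 (any
#'   non-negative mass).
#' @param tm a [transition_matrix()].
#' @param n_months number of monthly cycles.
#' @return `(n_months + 1) x 8` matrix of occupancies; each row sums to the
#'   entering mass.
#' @export
cohort_solve <- function(init, tm, n_months) {
  stopifnot(length(init) == 8, all(init >= 0))
  out <- matrix(0, n_months + 1, 8, dimnames = list(NULL, markov_states()))
  occ <- as.numeric(init)
  out[1, ] <- occ
  m <- unclass(tm)
  for (k in seq_len(n_months)) {
    occ <- as.numeric(occ %*% m)
    out[k + 1, ] <- occ
  }
  out
}

# Engine-internal vectorised Markov walker with fused economics.
#
# state0: integer initial states; m0: integer entry months (0-based, global
# clock); horizon_months: simulate months 0..horizon_months-1; cum: 8x8
# row-cumulative matrix; state_cost: monthly cost per state; state_util:
# monthly utility per state; vmonth: discount factor per month (length
# horizon_months). Death during cycle m is recorded with death month m (the
# man occupies his state for cycle m, transitions at its end).
run_markov_cohort <- function(state0, m0, tm, horizon_months,
                              state_cost, state_util, vmonth) {
  n <- length(state0)
  state <- as.integer(state0)
  death_month <- rep(NA_integer_, n)
  death_state <- rep(NA_integer_, n)
  cost <- numeric(n)
  qaly <- numeric(n)
  cum <- t(apply(unclass(tm), 1, cumsum))
  if (n == 0)
    return(list(death_month = death_month, death_state = death_state,
                cost = cost, qaly = qaly))
  for (m in seq_len(horizon_months) - 1L) {
    idx <- which(m0 <= m & state != 8L)
    if (!length(idx)) next
    s <- state[idx]
    v <- vmonth[m + 1L]
    cost[idx] <- cost[idx] + state_cost[s] * v
    qaly[idx] <- qaly[idx] + state_util[s] / 12 * v
    u <- stats::runif(length(idx))
    nxt <- integer(length(idx))
    for (k in unique(s)) {
      j <- which(s == k)
      nxt[j] <- findInterval(u[j], cum[k, ]) + 1L
    }
    nxt <- pmin(nxt, 8L)
    died <- nxt == 8L
    if (any(died)) {
      death_month[idx[died]] <- m
      death_state[idx[died]] <- s[died]
    }
    state[idx] <- nxt
  }
  list(death_month = death_month, death_state = death_state,
       cost = cost, qaly = qaly, final_state = state)
}
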