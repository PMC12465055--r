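# Male population pyramid, life table, deterministic projection, and
# stochastic sampling of individual other-cause death ages.

#' Population pyramid
#'
#' Counts of men by single year of age. Ages must be contiguous from the
#' youngest modelled age up to an open-ended top bin (the top age is treated
#' as absorbing in projections).
#'
#' @param age integer ages (years).
#' @param count number of men at each age (non-negative).
#' @param reference_year calendar year the counts refer to.
#' @return object of class `population_pyramid`.
#' @export
population_pyramid <- function(age, count, reference_year = NA_integer_) {
  age <- as.integer(age)
  if (anyNA(age) || anyNA(count)) stop("age and count must not contain NA")
  o <- order(age)
  age <- age[o]; count <- as.numeric(count)[o]
  if (any(diff(age) != 1L)) stop("ages must be contiguous single years")
  if (any(count < 0)) stop("counts must be non-negative")
  structure(list(age = age, count = count, reference_year = reference_year),
            class = "population_pyramid")
}

#' @export
print.population_pyramid <- function(x, ...) {
  cat(sprintf("population_pyramid: ages %d-%d, %s men%s\n",
              min(x$age), max(x$age), format(round(sum(x$count))),
              if (is.na(x$reference_year)) "" else
                sprintf(" (reference year %d)", x$reference_year)))
  invisible(x)
}

#' Life table
#'
#' Annual probabilities of all-cause death `qx` by single year of age.
#'
#' @param age integer ages.
#' @param qx annual death probability at each age, in `[0, 1]`.
#' @return object of class `life_table`.
#' @export
life_table <- function(age, qx) {
  age <- as.integer(age)
  o <- order(age)
  age <- age[o]; qx <- as.numeric(qx)[o]
  if (anyNA(qx) || any(qx < 0) || any(qx > 1)) stop("qx must lie in [0, 1]")
  if (any(diff(age) != 1L)) stop("ages must be contiguous single years")
  structure(list(age = age, qx = qx), class = "life_table")
}

lt_qx <- function(lt, age) {
  i <- pmin(pmax(age, min(lt$age)), max(lt$age)) - min(lt$age) + 1L
  lt$qx[i]
}

#' Read a pyramid or life table from CSV
#'
#' `read_pyramid()` expects columns `age,count`; `read_life_table()` expects
#' `age,qx`.
#'
#' @param path path to a CSV file.
#' @param reference_year optional calendar year attached to the pyramid.
#' @return a [population_pyramid()] or [life_table()].
#' @export
read_pyramid <- function(path, reference_year = NA_integer_) {
  d <- utils::read.csv(path)
  if (!all(c("age", "count") %in% names(d)))
    stop("pyramid file must have columns age,count")
  population_pyramid(d$age, d$count, reference_year)
}

#' @rdname read_pyramid
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(d)))
    stop("life table file must have columns age,qx")
  life_table(d$age, d$qx)
}

#' Write a pyramid or life table to CSV
#' @param x object to write.
#' @param path output path.
#' @export
write_pyramid <- function(x, path) {
  utils::write.csv(data.frame(age = x$age, count = x$count), path,
                   row.names = FALSE)
}

#' @rdname write_pyramid
#' @export
write_life_table <- function(x, path) {
  utils::write.csv(data.frame(age = x$age, qx = x$qx), path, row.names = FALSE)
}

#' Deterministic population projection
#'
#' Projects the pyramid forward by expected-value survival: each year every
#' age-`a` count is multiplied by `1 - qx(a)` and shifted to age `a + 1`.
#' There is no inflow at the youngest age (closed cohort of men already in the
#' model) and the top age bin is absorbing, with its `qx` applied annually.
#'
#' @param pyramid a [population_pyramid()].
#' @param lt a [life_table()] covering all pyramid ages.
#' @param n_years number of years to project.
#' @return list of `n_years + 1` pyramids (the first is the input).
#' @export
project_population <- function(pyramid, lt, n_years) {
  if (n_years < 0) stop("n_years must be non-negative")
  if (min(pyramid$age) < min(lt$age) || max(pyramid$age) > max(lt$age))
    stop("life table must cover all pyramid ages")
  out <- vector("list", n_years + 1)
  out[[1]] <- pyramid
  cnt <- pyramid$count
  qx <- lt_qx(lt, pyramid$age)
  k <- length(cnt)
  yr <- pyramid$reference_year
  for (y in seq_len(n_years)) {
    surv <- cnt * (1 - qx)
    nxt <- numeric(k)
    if (k > 1) nxt[2:k] <- surv[1:(k - 1)]
    nxt[k] <- nxt[k] + surv[k]      # absorbing top bin
    cnt <- nxt
    out[[y + 1]] <- population_pyramid(pyramid$age, cnt,
                                       if (is.na(yr)) NA_integer_ else yr + y)
  }
  out
}

#' Sample individual death ages from a life table
#'
#' Draws, for each man, the exact (continuous) age at other-cause death,
#' consistent in expectation with [project_population()]: death occurs during
#' year `[a, a+1)` with probability `qx(a)` given survival to `a`, uniformly
#' within the year. Beyond the life-table top age the last `qx` keeps applying,
#' and death is forced by `max_age`.
#'
#' @param entry_age integer current ages (vectorised).
#' @param lt a [life_table()].
#' @param max_age hard upper bound on age at death.
#' @return numeric vector of death ages (> `entry_age`).
#' @export
sample_death_age <- function(entry_age, lt, max_age = 110) {
  ages <- seq(min(lt$age), max_age - 1L)
  qx <- lt_qx(lt, ages)
  # cumulative survival from the table's first age
  lsurv <- c(0, cumsum(log1p(-pmin(qx, 1 - 1e-12))))
  n <- length(entry_age)
  u <- stats::runif(n)
  out <- numeric(n)
  for (a in unique(entry_age)) {
    sel <- entry_age == a
    i0 <- a - ages[1] + 1L
    s <- exp(lsurv[i0:length(lsurv)] - lsurv[i0])  # survival from age a, decreasing
    # die during year j (0-based): S(j) >= u > S(j+1), with S(j) = s[j+1]
    j <- length(s) - findInterval(u[sel], rev(s)) - 1L
    j <- pmax(pmin(j, length(s) - 1L), 0L)
    out[sel] <- a + j
  }
  out + stats::runif(n)
}
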