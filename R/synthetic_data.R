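# Synthetic-data generators: census-like male population pyramid, Gompertz
# life table, longitudinal PSA screening-trial tables with known ground
# truth, and reference age-specific incidence curves for calibration.

#' Synthetic-data configuration
#'
#' @param n_individuals number of men to simulate / total pyramid mass.
#' @param pyramid_knot_age,pyramid_knot_weight piecewise-linear density knots
#'   of the age distribution over 40-100. The default approximates the shape
#'   of the 2020 Chinese male census population aged 40+: a broad bulge
#'   through the late 40s and 50s, a trough around 60, then steep decline --
#'   an ageing population whose mass shifts above 60 over the projection.
#' @param gompertz_a,gompertz_b Gompertz mortality parameters:
#'   `qx = min(1, a * exp(b * (age - 40)))`.
#' @param nh a [nh_params()].
#' @param psa a [psa_growth_params()].
#' @param seed integer seed; the same seed reproduces outputs exactly.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 1e5,
                             pyramid_knot_age = c(40, 50, 55, 60, 65, 70, 75,
                                                  80, 85, 90, 95, 100),
                             pyramid_knot_weight = c(1.00, 1.15, 1.05, 0.75,
                                                     0.72, 0.55, 0.32, 0.18,
                                                     0.08, 0.03, 0.008, 0.001),
                             gompertz_a = 0.002, gompertz_b = 0.085,
                             nh = nh_params(), psa = psa_growth_params(),
                             seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  structure(list(n_individuals = n_individuals,
                 pyramid_knot_age = pyramid_knot_age,
                 pyramid_knot_weight = pyramid_knot_weight,
                 gompertz_a = gompertz_a, gompertz_b = gompertz_b,
                 nh = nh, psa = psa, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Synthetic population pyramid and life table
#'
#' @param config a [synthetic_config()].
#' @return list with a [population_pyramid()] (total mass
#'   `n_individuals`) and a [life_table()] with `qx` non-decreasing in age.
#' @export
make_population <- function(config = synthetic_config()) {
  ages <- 40:100
  w <- stats::approx(config$pyramid_knot_age, config$pyramid_knot_weight,
                     xout = ages, rule = 2)$y
  cnt <- w / sum(w) * config$n_individuals
  qx <- pmin(1, config$gompertz_a * exp(config$gompertz_b * (ages - 40)))
  list(pyramid = population_pyramid(ages, cnt, reference_year = 2020L),
       life_table = life_table(ages, qx))
}

#' Sample individual entry ages from a pyramid
#'
#' @param n number of men.
#' @param pyramid a [population_pyramid()].
#' @return integer ages.
#' @export
sample_entry_ages <- function(n, pyramid) {
  sample(pyramid$age, n, replace = TRUE, prob = pyramid$count)
}

#' Synthetic longitudinal PSA screening-trial table
#'
#' Generates subjects with latent natural histories from the exact
#' onset/grade/PSA model and observes noisy PSA at yearly visits, emulating
#' the structure of a multi-year prospective screening trial. Ground-truth
#' onset ages and grades are returned alongside for recovery tests.
#'
#' @param config a [synthetic_config()] (supplies parameters and seed).
#' @param n_subjects number of subjects.
#' @param visits_per_subject yearly visits per subject.
#' @param entry_age_range ages at trial entry are drawn uniformly in this
#'   range.
#' @return list with `observations` (data.frame `id, age, psa`) and `truth`
#'   (data.frame `id, entry_age, onset_age, grade`).
#' @export
make_screening_trial <- function(config = synthetic_config(),
                                 n_subjects = 1000, visits_per_subject = 5,
                                 entry_age_range = c(45, 70)) {
  set.seed(config$seed)
  entry <- floor(stats::runif(n_subjects, entry_age_range[1],
                              entry_age_range[2] + 1))
  onset <- sample_onset_age(n_subjects, config$nh)
  grade <- rep(NA_character_, n_subjects)
  has <- !is.na(onset)
  grade[has] <- assign_grade(sum(has), config$nh$gamma_LR)
  id <- rep(seq_len(n_subjects), each = visits_per_subject)
  age <- entry[id] + rep(seq_len(visits_per_subject) - 1, n_subjects)
  psa <- sample_psa(age, onset[id], grade[id], config$psa)
  list(observations = data.frame(id = id, age = age, psa = psa),
       truth = data.frame(id = seq_len(n_subjects), entry_age = entry,
                          onset_age = onset, grade = grade,
                          stringsAsFactors = FALSE))
}

#' Synthetic reference incidence curve
#'
#' Runs the latent incidence simulator at planted hazard multipliers and
#' returns the resulting age-specific clinical-incidence curve; stands in for
#' an external age-specific incidence reference when exercising the
#' multiplier grid search.
#'
#' @param config a [synthetic_config()].
#' @param planted_multipliers length-2 positive vector: multipliers for
#'   (`gamma_o`, `gamma_c`).
#' @param n_years simulated follow-up years.
#' @return an [incidence_curve()] on 5-year bands over 45-84.
#' @export
make_reference_incidence <- function(config = synthetic_config(),
                                     planted_multipliers = c(1, 1),
                                     n_years = 30) {
  if (any(planted_multipliers <= 0)) stop("multipliers must be positive")
  simulate_incidence_curve(config, planted_multipliers, n_years)
}

#' Write a complete synthetic fixture set
#'
#' PSA values in the trial table are rounded to three decimals (well below
#' assay precision) to keep each fixture file small.
#'
#' @param dir output directory (created if needed).
#' @param config a [synthetic_config()].
#' @param n_subjects trial subjects written to the fixture.
#' @return invisibly, the paths written.
#' @export
write_fixtures <- function(dir, config = synthetic_config(),
                           n_subjects = 600) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pop <- make_population(config)
  write_pyramid(pop$pyramid, file.path(dir, "pyramid.csv"))
  write_life_table(pop$life_table, file.path(dir, "life_table.csv"))
  trial <- make_screening_trial(config, n_subjects = n_subjects)
  obs <- trial$observations
  obs$psa <- round(obs$psa, 3)
  utils::write.csv(obs, file.path(dir, "psa_trial.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$truth, file.path(dir, "psa_trial_truth.csv"),
                   row.names = FALSE)
  ref <- make_reference_incidence(config)
  utils::write.csv(as.data.frame(ref), file.path(dir, "reference_incidence.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, c("pyramid.csv", "life_table.csv", "psa_trial.csv",
                             "psa_trial_truth.csv", "reference_incidence.csv")))
}
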