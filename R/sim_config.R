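#' Cause-of-death groups used throughout the package
#'
#' Six named cause groups plus an ill-defined category that is later
#' redistributed proportionally within period x age x sex strata.
#'
#' @return Character vector of the six named cause groups.
#' @export
cause_groups <- function() {
  c("neoplasms", "dementia_alzheimers", "circulatory",
    "respiratory", "alcohol_related", "external")
}

#' Default annual out-migration hazard
#'
#' Piecewise-constant in age: children move with their families at a low rate,
#' migration peaks at young-adult (study/work) ages, and declines through
#' working ages into retirement.
#'
#' @param age Integer vector of attained ages.
#' @param sex Character vector ("male"/"female"), same length; unused by the
#'   default but part of the hazard signature.
#' @return Annual probabilities of leaving the current region.
#' @export
default_out_migration_hazard <- function(age, sex) {
  ifelse(age < 17, 0.010,
    ifelse(age < 30, 0.030,
      ifelse(age < 60, 0.008, 0.004)))
}

#' Gompertz baseline log-mortality
#'
#' Returns a function age -> log rate with log(rate) = log(a) + b * age.
#' Defaults give roughly 1.3e-4 at age 20 and 0.1 at age 90, a plausible
#' high-income adult schedule.
#'
#' @param a Level parameter (rate at age 0).
#' @param b Log-linear slope per year of age.
#' @return Function of age returning the log mortality rate.
#' @export
gompertz_baseline <- function(a = 2e-5, b = 0.095) {
  force(a); force(b)
  function(age) log(a) + b * age
}

#' Default cause-of-death mix
#'
#' Smooth age profile over the six cause groups: external and alcohol-related
#' causes dominate young-adult deaths, circulatory disease and neoplasms rise
#' through midlife, respiratory disease and dementia concentrate at the oldest
#' ages. Ignores status (the generator's ill-defined relabelling is applied
#' separately).
#'
#' @param age Numeric vector of ages at death.
#' @param status Latent status at death (unused by the default mix).
#' @return Matrix `length(age)` x 6 of probabilities, rows summing to 1,
#'   columns named as [cause_groups()].
#' @export
default_cause_mix <- function(age, status = NULL) {
  w <- cbind(
    neoplasms           = 0.05 + 0.55 * stats::plogis((age - 55) / 12),
    dementia_alzheimers = 0.45 * stats::plogis((age - 82) / 5),
    circulatory         = 0.10 + 0.90 * stats::plogis((age - 60) / 10),
    respiratory         = 0.02 + 0.20 * stats::plogis((age - 70) / 8),
    alcohol_related     = 0.02 + 0.30 * exp(-((age - 50) / 15)^2),
    external            = 0.05 + 0.55 * exp(-((age - 25) / 15)^2)
  )
  w / rowSums(w)
}

#' Default observation scheme
#'
#' Census years 1970, 1975, 1980 and 1985 followed by annual register
#' observation 1987-2018 (1986 is unobserved). Residence is recorded on
#' December 31 of each observed year.
#'
#' @return Sorted integer vector of observed calendar years.
#' @export
default_observed_years <- function() {
  sort(c(1970L, 1975L, 1980L, 1985L, 1987:2018))
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic register
#' generator. Defaults encode the study conditions the package emulates:
#' 21 birth regions, follow-up 1970-2018, a Gompertz mortality baseline with
#' sum-to-zero region and calendar-year log-rate offsets, migration hazards
#' piecewise-constant in age, constant status log-rate effects, a six-group
#' cause mix and a 2% ill-defined fraction.
#'
#' @param n_individuals Number of individuals to simulate.
#' @param n_regions Number of birth regions (default 21).
#' @param years Length-2 integer vector, closed follow-up interval
#'   (default `c(1970, 2018)`).
#' @param cohort_range Length-2 integer vector of birth years
#'   (default `c(1905, 1998)`; everyone is treated as alive at the horizon
#'   start, mirroring a sample conditioned on survival to 1970).
#' @param sex_ratio Proportion male.
#' @param out_migration_hazard Function `(age, sex) -> annual probability` of
#'   leaving the current (birth) region.
#' @param return_hazard Annual probability that a person outside their birth
#'   region returns to it.
#' @param onward_hazard Annual probability of an onward move between two
#'   non-birth regions (does not change status category).
#' @param destination_rule Either `"uniform"` (default: uniform over eligible
#'   regions) or a function `(n, exclude1, exclude2) -> region indices`.
#' @param baseline_log_mortality Function of age returning the baseline log
#'   mortality rate; `-Inf` is allowed (zero mortality).
#' @param region_effects Numeric vector of log-rate offsets, length
#'   `n_regions`, centred to sum to zero (default: linear gradient +-0.15).
#' @param year_effects Numeric vector of log-rate offsets, one per calendar
#'   year of the horizon, centred to sum to zero (default: linear decline
#'   +0.25 to -0.25, i.e. secular mortality improvement).
#' @param status_effects Named list with elements `stayer`, `leaver`,
#'   `returnee`; each a numeric log-rate offset or a function of age. The
#'   `leaver` effect applies while outside the birth region, the `returnee`
#'   effect after a return.
#' @param cause_mix Function `(age, status) -> matrix` of probabilities over
#'   [cause_groups()].
#' @param illdefined_fraction Probability that a death's cause is relabelled
#'   ill-defined (default 0.02).
#' @param death_year_exposure Person-years credited in the year of death
#'   (default 0.5).
#' @param death_year_residence `"death_year_snapshot"` (default: the region
#'   lived in during the death year is observed through the death record) or
#'   `"last_observed_year"`.
#' @param seed Integer random seed (mandatory).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_individuals,
                       n_regions = 21L,
                       years = c(1970L, 2018L),
                       cohort_range = c(1905L, 1998L),
                       sex_ratio = 0.5,
                       out_migration_hazard = default_out_migration_hazard,
                       return_hazard = 0.01,
                       onward_hazard = 0.005,
                       destination_rule = "uniform",
                       baseline_log_mortality = gompertz_baseline(),
                       region_effects = NULL,
                       year_effects = NULL,
                       status_effects = list(stayer = 0, leaver = -0.15,
                                             returnee = -0.25),
                       cause_mix = default_cause_mix,
                       illdefined_fraction = 0.02,
                       death_year_exposure = 0.5,
                       death_year_residence = c("death_year_snapshot",
                                                "last_observed_year"),
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory in sim_config()")
  stopifnot(n_individuals >= 1, n_regions >= 2,
            length(years) == 2, years[1] <= years[2],
            length(cohort_range) == 2, cohort_range[1] <= cohort_range[2],
            cohort_range[2] <= years[2],
            sex_ratio >= 0, sex_ratio <= 1,
            is.function(out_migration_hazard),
            return_hazard >= 0, return_hazard <= 1,
            onward_hazard >= 0, onward_hazard <= 1,
            is.function(baseline_log_mortality),
            illdefined_fraction >= 0, illdefined_fraction <= 1,
            death_year_exposure >= 0, death_year_exposure <= 1)
  death_year_residence <- match.arg(death_year_residence)
  nyr <- years[2] - years[1] + 1L
  if (is.null(region_effects)) {
    region_effects <- seq(-0.15, 0.15, length.out = n_regions)
  }
  if (is.null(year_effects)) {
    year_effects <- seq(0.25, -0.25, length.out = nyr)
  }
  stopifnot(length(region_effects) == n_regions, length(year_effects) == nyr)
  # identifiability of the generator mirrors the model's reference coding
  region_effects <- region_effects - mean(region_effects)
  year_effects <- year_effects - mean(year_effects)
  stopifnot(all(c("stayer", "leaver", "returnee") %in% names(status_effects)))
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_regions = as.integer(n_regions),
    years = as.integer(years), cohort_range = as.integer(cohort_range),
    sex_ratio = sex_ratio, out_migration_hazard = out_migration_hazard,
    return_hazard = return_hazard, onward_hazard = onward_hazard,
    destination_rule = destination_rule,
    baseline_log_mortality = baseline_log_mortality,
    region_effects = region_effects, year_effects = year_effects,
    status_effects = status_effects, cause_mix = cause_mix,
    illdefined_fraction = illdefined_fraction,
    death_year_exposure = death_year_exposure,
    death_year_residence = death_year_residence,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# evaluate a status effect entry (scalar or function of age) for a vector
status_effect_at <- function(effect, age) {
  if (is.function(effect)) effect(age) else rep(effect, length(age))
}
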