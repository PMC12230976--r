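# Censoring-record extraction and event-age imputation.

res1 <- function(v, years) {
  m <- matrix(as.integer(v), nrow = 1)
  colnames(m) <- years
  m
}

test_that("a move between censuses yields the implied age interval", {
  years <- c(1970, 1975, 1980, 1985)
  h <- make_histories(data.frame(person_id = 1L, birth_year = 1950L,
                                 birth_region = 1L),
                      res1(c(1, 1, 2, 2), years), years)
  cl <- classify_histories(h)
  r <- extract_censoring_records(h, cl)
  # in birth region Dec 31 1975 (age 25), outside Dec 31 1980 (age 30):
  # the move year lies in (1975, 1980], so ages 26..30 are possible
  expect_equal(r$low, 26)
  expect_equal(r$high, 31)
  expect_false(r$exact)
})

test_that("annual observation of a move gives an exact width-1 interval", {
  years <- 2000:2003
  h <- make_histories(data.frame(person_id = 1L, birth_year = 1980L,
                                 birth_region = 1L),
                      res1(c(1, 1, 2, 2), years), years)
  r <- extract_censoring_records(h, classify_histories(h))
  expect_equal(r$low, 22)
  expect_equal(r$high, 23)
  expect_true(r$exact)
})

test_that("a first observation already outside the birth region is left-censored", {
  years <- c(1970, 1975)
  h <- make_histories(data.frame(person_id = 1L, birth_year = 1940L,
                                 birth_region = 1L),
                      res1(c(2, 2), years), years)
  r <- extract_censoring_records(h, classify_histories(h))
  expect_equal(r$low, 1)
  expect_equal(r$high, 31)   # moved at latest in 1970, age 30
})

test_that("returnee records carry bounds for the final return", {
  years <- c(1970, 1975, 1980, 1985)
  h <- make_histories(data.frame(person_id = 1L, birth_year = 1950L,
                                 birth_region = 1L),
                      res1(c(1, 2, 2, 1), years), years)
  r <- extract_censoring_records(h, classify_histories(h))
  ret <- r[r$event == "return", ]
  # last observed outside Dec 31 1980 (age 30), back by Dec 31 1985 (age 35)
  expect_equal(ret$low, 31)
  expect_equal(ret$high, 36)
  # a return observed through the death record, between observation years
  h2 <- make_histories(data.frame(person_id = 1L, birth_year = 1950L,
                                  birth_region = 1L, death_year = 1983L,
                                  death_age = 33L, death_region = 1L),
                       res1(c(1, 2, 2, NA), years), years)
  r2 <- extract_censoring_records(h2, classify_histories(h2))
  ret2 <- r2[r2$event == "return", ]
  expect_equal(ret2$low, 31)
  expect_equal(ret2$high, 34)   # returned by the death year 1983
})

test_that("an inconsistent mover classification is rejected", {
  years <- c(1970, 1975)
  h <- make_histories(data.frame(person_id = 1L, birth_year = 1950L,
                                 birth_region = 1L),
                      res1(c(1, 1), years), years)
  cl <- data.frame(person_id = 1L, status = "leaver")
  expect_error(extract_censoring_records(h, cl), "never observed outside")
})

test_that("degenerate intervals are imputed deterministically to their bound", {
  rec <- data.frame(person_id = 1L, event = "first_migration", low = 22,
                    high = 23, exact = TRUE, sex = "male",
                    birth_year = 1980L, cohort_band = "1970plus",
                    birth_region = 1L)
  m <- structure(list(event = "first_migration", bands = c(0, 17, 30, 60),
                      strata = list(), pooled = list(log_haz = rep(log(0.05), 4))),
                 class = "event_age_model")
  for (s in 1:3) {
    imp <- impute_event_ages(rec, m, seed = s)
    expect_equal(imp$age, 22)
  }
})

test_that("truncated draws match the quadrature mean under a constant hazard", {
  lambda <- 0.05
  m <- structure(list(event = "first_migration", bands = c(0, 17, 30, 60),
                      strata = list(),
                      pooled = list(log_haz = rep(log(lambda), 4))),
                 class = "event_age_model")
  rec <- data.frame(person_id = 1:10000, event = "first_migration",
                    low = 20, high = 30, exact = FALSE, sex = "male",
                    birth_year = 1980L, cohort_band = "1970plus",
                    birth_region = 1L)
  imp <- impute_event_ages(rec, m, seed = 4)
  expect_true(all(imp$age >= 20 & imp$age < 30))
  # independent oracle: mean of floor(T) for T truncated-exponential on
  # [20, 30), by numerical integration of the continuous density
  dens <- function(t) lambda * exp(-lambda * t)
  num <- stats::integrate(function(t) floor(t) * dens(t), 20, 30)$value
  den <- stats::integrate(dens, 20, 30)$value
  expect_lt(abs(mean(imp$age) - num / den), 0.2)
})

test_that("imputed ages always lie inside their bounds (simulated histories)", {
  cfg <- sim_config(n_individuals = 3000, n_regions = 5,
                    years = c(1970, 2018), cohort_range = c(1920, 1995),
                    seed = 13)
  h <- apply_observation_scheme(simulate_population(cfg))
  cl <- classify_histories(h)
  recs <- extract_censoring_records(h, cl)
  mods <- suppressWarnings(lapply(split(recs, recs$event),
                                  fit_event_age_model))
  imp <- impute_event_ages(recs, mods, seed = 2)
  expect_true(all(imp$age >= recs$low & imp$age < recs$high))
  # determinism under the seed
  imp2 <- impute_event_ages(recs, mods, seed = 2)
  expect_identical(imp, imp2)
})

test_that("band assignment error shrinks as the observation scheme densifies", {
  # cohorts born from 1970 on, so every move falls inside the observation
  # window and annual observation pins each event age exactly
  cfg <- sim_config(n_individuals = 4000, n_regions = 5,
                    years = c(1970, 2018), cohort_range = c(1970, 1995),
                    out_migration_hazard = function(age, sex)
                      rep(0.04, length(age)),
                    return_hazard = 0.04, seed = 29)
  h <- simulate_population(cfg)
  truth_band <- function(h, cl) {
    ev <- rbind(
      data.frame(person_id = h$persons$person_id, event = "first_migration",
                 age = h$persons$true_age_first_migration),
      data.frame(person_id = h$persons$person_id, event = "return",
                 age = h$persons$true_age_return))
    ev <- ev[!is.na(ev$age), ]
    assign_status_bands(cl, ev)$status_band
  }
  mismatch <- function(observed_years) {
    ho <- apply_observation_scheme(h, observed_years)
    cl <- classify_histories(ho)
    recs <- extract_censoring_records(ho, cl)
    mods <- suppressWarnings(lapply(split(recs, recs$event),
                                    fit_event_age_model))
    imp <- impute_event_ages(recs, mods, seed = 6)
    got <- assign_status_bands(cl, imp)$status_band
    mean(got != truth_band(h, cl))
  }
  m_annual <- mismatch(1970:2018)
  m_census <- mismatch(default_observed_years())
  m_sparse <- mismatch(c(seq(1970, 2015, by = 15), 2018))
  expect_equal(m_annual, 0)
  expect_lte(m_census, m_sparse)
})

test_that("a pooled fallback kicks in for thin strata", {
  rec <- data.frame(person_id = 1:20, event = "first_migration",
                    low = rep(c(20, 25), 10), high = rep(c(21, 26), 10),
                    exact = TRUE,
                    sex = rep(c("male", "female"), each = 10),
                    birth_year = 1980L, cohort_band = "1970plus",
                    birth_region = 1L)
  expect_warning(fit_event_age_model(rec, min_exact = 15),
                 "fell back to the pooled fit")
})
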