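# Negative-binomial GAM fitting, age-range restriction, and prediction.

# build a synthetic exposure table directly on a balanced grid
synth_table <- function(ages = seq(20, 92, 3), years = 2000:2004,
                        regions = 1:3, statuses = c("stayer", "leaver"),
                        rate_fun = function(x, st)
                          exp(-9 + 0.08 * x + ifelse(st == "leaver", -0.3, 0)),
                        E = 500, seed = 1, theta = Inf) {
  set.seed(seed)
  g <- expand.grid(age_lower = ages, year = years, birth_region = regions,
                   status = statuses, stringsAsFactors = FALSE)
  g$age_mid <- g$age_lower + 1.5
  g$sex <- "male"
  g$status_coarse <- g$status
  g$E <- E
  mu <- rate_fun(g$age_mid, g$status) * g$E
  g$D_total <- if (is.infinite(theta)) rpois(nrow(g), mu) else
    rnbinom(nrow(g), size = theta, mu = mu)
  for (cc in paste0("D_", cause_groups())) g[[cc]] <- 0
  g$D_circulatory <- g$D_total
  tab <- data.table::as.data.table(g)
  data.table::setattr(tab, "exposure_meta",
                      list(age_range = c(20, 95), group_width = 3))
  data.table::setattr(tab, "class",
                      c("exposure_table", class(data.table::data.table())))
  tab
}

test_that("cause age-range restriction implements the share/count rule", {
  tab <- synth_table()
  tab[, D_respiratory := 0]
  tab[age_lower >= 50, D_respiratory := 40]       # deaths only from age 50
  expect_equal(restrict_cause_ages(tab, "respiratory")[1], 50)
  expect_equal(restrict_cause_ages(tab, "respiratory")[2], 95)
  # flat mortality: every group passes the share rule and the full domain
  # is retained
  tab_flat <- synth_table(rate_fun = function(x, st) rep(0.01, length(x)),
                          E = 1000, seed = 11)
  expect_equal(restrict_cause_ages(tab_flat, "total"), c(20, 95))
  # the absolute count rule keeps a group below the share threshold
  tab2 <- synth_table()
  tab2[, D_external := 0]
  tab2[age_lower >= 80, D_external := 5000]
  tab2[age_lower == 20 & year == 2000 & birth_region == 1 &
         status == "stayer", D_external := 1000]
  lim <- restrict_cause_ages(tab2, "external")
  expect_equal(lim[1], 20)
  expect_error(restrict_cause_ages(synth_table()[, D_dementia_alzheimers := 0],
                                   "dementia_alzheimers"),
               "no age group passes")
})

test_that("the Poisson single-stratum limit recovers the closed-form MLE", {
  tab <- synth_table(ages = 50, years = 2000, regions = 1,
                     statuses = "stayer", E = 1000, seed = 2)
  tab <- data.table::rbindlist(lapply(1:6, function(i) {
    t <- data.table::copy(tab)
    set.seed(100 + i)
    t[, D_total := rpois(1, 0.02 * E)]
    t
  }))
  data.table::setattr(tab, "exposure_meta",
                      list(age_range = c(20, 95), group_width = 3))
  data.table::setattr(tab, "class",
                      c("exposure_table", class(data.table::data.table())))
  m <- fit_mortality_gam(tab, sex = "male", family = "poisson",
                         engine = "gam")
  expect_equal(unname(coef(m$fit)[1]),
               log(sum(tab$D_total) / sum(tab$E)), tolerance = 1e-10)
})

test_that("an unpenalized fit matches an independent Newton NB fit", {
  # parametric-only design (two distinct ages: smooth is dropped)
  tab <- synth_table(ages = c(50, 53), years = 2000:2001, regions = 1:2,
                     statuses = c("stayer", "leaver"), E = 800, seed = 3,
                     theta = 2)
  m <- fit_mortality_gam(tab, sex = "male", family = "negbin", theta = 2,
                         engine = "gam")
  dat <- m$fit$model
  X <- model.matrix(~ region_f + year_f + status_f, data = dat)
  beta_oracle <- nb_newton_fit(X, dat$D, log(tab$E), theta = 2)
  got <- coef(m$fit)[colnames(X)]
  expect_lt(max(abs(unname(got) - unname(beta_oracle))), 1e-6)
})

test_that("status smooths are centred over the observed age midpoints", {
  tab <- synth_table(seed = 4)
  m <- fit_mortality_gam(tab, sex = "male", engine = "gam")
  trm <- predict(m$fit, type = "terms")
  for (st in m$status_levels) {
    col <- sprintf("s(age_mid):status_f%s", st)
    rows <- m$fit$model$status_f == st
    expect_lt(abs(mean(trm[rows, col])), 1e-8)
  }
})

test_that("the NB fit approaches the Poisson fit as theta grows", {
  tab <- synth_table(seed = 5)
  sp_fix <- c(1, 1)
  m_pois <- fit_mortality_gam(tab, sex = "male", family = "poisson",
                              engine = "gam", sp = sp_fix)
  m_nb <- fit_mortality_gam(tab, sex = "male", family = "negbin",
                            theta = 1e6, engine = "gam", sp = sp_fix)
  expect_lt(max(abs(coef(m_pois$fit) - coef(m_nb$fit))), 1e-4)
})

test_that("effective degrees of freedom fall as the smoothing parameter rises", {
  tab <- synth_table(seed = 6)
  edf_at <- function(spv) {
    m <- fit_mortality_gam(tab, sex = "male", family = "poisson",
                           engine = "gam", sp = rep(spv, 2))
    sum(m$fit$edf[grep("s\\(age_mid\\)", names(coef(m$fit)))])
  }
  e <- vapply(c(1e-4, 1, 1e4), edf_at, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("prediction reproduces saturated observations and flags structural zeros", {
  # per-status saturation: replicate cells within two statuses; fitted rates
  # must equal each status's pooled D/E exactly
  one <- synth_table(ages = 50, years = 2000, regions = 1,
                     statuses = c("stayer", "leaver"), E = 1000, seed = 7)
  tab <- data.table::rbindlist(lapply(1:4, function(i) {
    t <- data.table::copy(one)
    set.seed(200 + i)
    t[, D_total := rpois(.N, 0.02 * E)]
    t
  }))
  data.table::setattr(tab, "exposure_meta",
                      list(age_range = c(20, 95), group_width = 3))
  data.table::setattr(tab, "class",
                      c("exposure_table", class(data.table::data.table())))
  m <- fit_mortality_gam(tab, sex = "male", family = "poisson",
                         engine = "gam")
  for (st in c("stayer", "leaver")) {
    pr <- predict_log_rate(m, data.frame(age_mid = 51.5, year = 2000,
                                         birth_region = 1, status = st))
    sub <- tab[tab$status == st, ]
    expect_equal(pr$log_rate, log(sum(sub$D_total) / sum(sub$E)),
                 tolerance = 1e-10)
  }
  expect_error(predict_log_rate(m, data.frame(age_mid = 51.5, year = 1999,
                                              birth_region = 1,
                                              status = "stayer")),
               "unseen calendar-year")
  # banded fit: a request below the band's lower bound is structurally zero
  tab2 <- synth_table(ages = seq(59, 92, 3), statuses = "returnee_60p")
  tab2[, status_coarse := "returnee"]
  m2 <- fit_mortality_gam(tab2, sex = "male", family = "poisson",
                          status_var = "status", engine = "gam")
  pr2 <- predict_log_rate(m2, data.frame(age_mid = c(45.5, 72.5), year = 2000,
                                         birth_region = 1,
                                         status = "returnee_60p"))
  expect_true(pr2$structural[1])
  expect_identical(pr2$log_rate[1], -Inf)
  expect_false(pr2$structural[2])
  expect_error(predict_log_rate(m2, data.frame(age_mid = 96.5, year = 2000,
                                               birth_region = 1,
                                               status = "returnee_60p")),
               "outside the fitted age domain")
})

test_that("two statuses with identical rate structure predict alike", {
  tab <- synth_table(statuses = c("stayer", "leaver"),
                     rate_fun = function(x, st) exp(-9 + 0.08 * x),
                     E = 5000, seed = 8)
  m <- fit_mortality_gam(tab, sex = "male", family = "poisson",
                         engine = "gam")
  nd <- data.frame(age_mid = c(33.5, 63.5), year = 2000, birth_region = 1)
  p_st <- predict_log_rate(m, transform(nd, status = "stayer"))
  p_lv <- predict_log_rate(m, transform(nd, status = "leaver"))
  expect_equal(p_st$log_rate, p_lv$log_rate, tolerance = 0.05)
})

test_that("delta-method standard errors agree with coefficient-draw simulation", {
  tab <- synth_table(seed = 9)
  m <- fit_mortality_gam(tab, sex = "male", engine = "gam")
  nd <- data.frame(age_mid = 51.5, year = 2001, birth_region = 2,
                   status = "leaver")
  pr <- predict_log_rate(m, nd)
  Xp <- predict(m$fit,
                newdata = data.frame(age_mid = 51.5,
                                     year_f = factor(2001, levels = m$years),
                                     region_f = factor(2, levels = m$regions),
                                     status_f = factor("leaver",
                                                       levels = m$status_levels),
                                     E = 1),
                type = "lpmatrix", newdata.guaranteed = TRUE)
  set.seed(42)
  draws <- MASS::mvrnorm(2000, coef(m$fit), vcov(m$fit))
  sim_sd <- sd(draws %*% t(Xp))
  expect_lt(abs(sim_sd - pr$se) / pr$se, 0.05)
})
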