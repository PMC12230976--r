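#' Restrict the age range for a cause-specific model
#'
#' Returns the contiguous hull of 3-year age groups in which, aggregated over
#' all years, at least 0.5% of all deaths from the cause occurred or at least
#' 1000 deaths from the cause occurred, intersected with the table's age
#' range. Used to avoid fitting cause-specific models at ages with
#' essentially no mortality from that cause.
#'
#' @param table An `exposure_table`.
#' @param cause One of [cause_groups()] (or `"total"` for all-cause).
#' @param share_threshold Minimum share of the cause's deaths (default 0.005).
#' @param count_threshold Absolute death count that also qualifies an age
#'   group (default 1000).
#' @return Numeric length-2 vector: the closed interval of qualifying age
#'   group lower bounds `c(first_lower, last_lower + width - 1)`.
#' @export
restrict_cause_ages <- function(table, cause, share_threshold = 0.005,
                                count_threshold = 1000) {
  col <- if (cause == "total") "D_total" else paste0("D_", cause)
  if (!col %in% names(table)) stop(sprintf("no column %s in table", col))
  meta <- attr(table, "exposure_meta")
  gw <- if (!is.null(meta)) meta$group_width else 3
  tab <- as.data.table(table)
  byage <- tab[, .(D = sum(get(col))), by = age_lower][order(age_lower)]
  tot <- sum(byage$D)
  pass <- (byage$D / max(tot, 1e-300)) >= share_threshold |
    byage$D >= count_threshold
  if (!any(pass)) {
    stop(sprintf("no age group passes the death-count rule for cause '%s'",
                 cause))
  }
  lo <- byage$age_lower[min(which(pass))]
  hi <- byage$age_lower[max(which(pass))] + gw
  c(lo, hi)
}

#' Fit a negative-binomial GAM of mortality by migration status
#'
#' Fits `D ~ region + year + status + s(age, by = status) + offset(log E)`
#' with a negative-binomial response: death counts in cells of age group x
#' calendar year x birth region x migration status, with person-years as
#' offset. Age enters through one penalized cubic-regression-spline smooth
#' per status (default basis size 10), expressed as a deviation from the
#' status intercept and centred (sum-to-zero) for identifiability. Calendar
#' year is categorical by default. Smoothing parameters are selected by REML
#' and the overdispersion parameter theta is estimated alongside (mgcv's
#' `nb()` family); a Poisson response or a fixed theta are available for
#' nested comparisons.
#'
#' @param table An `exposure_table` (after redistribution for cause-specific
#'   fits).
#' @param sex Which sex to fit (`"male"`/`"female"`; fits are always
#'   sex-specific).
#' @param cause `"total"` (default) or one of [cause_groups()].
#' @param status_var `"status"` (banded, default) or `"status_coarse"`
#'   (stayer/leaver/returnee).
#' @param k Spline basis dimension per status smooth (default 10; reduced
#'   automatically when a status has fewer distinct age midpoints).
#' @param year_term `"factor"` (default, one coefficient per year) or
#'   `"smooth"`.
#' @param family `"nb"` (theta estimated, default), `"poisson"`, or
#'   `"negbin"` with `theta` fixed.
#' @param theta Fixed overdispersion parameter for `family = "negbin"`.
#' @param method Smoothing-selection criterion (default `"REML"`;
#'   `"GCV.Cp"` available).
#' @param age_limits Optional closed age interval restricting the fit (e.g.
#'   from [restrict_cause_ages()]); applied automatically for cause-specific
#'   fits when `NULL`.
#' @param engine `"auto"` (default: `bam` beyond 20,000 rows), `"gam"`, or
#'   `"bam"`.
#' @param sp Optional vector of fixed smoothing parameters (passed to mgcv).
#' @return Object of class `mortality_gam` wrapping the mgcv fit with the
#'   status levels, per-status age domains, theta, and convergence flag.
#' @export
fit_mortality_gam <- function(table, sex, cause = "total",
                              status_var = c("status", "status_coarse"),
                              k = 10, year_term = c("factor", "smooth"),
                              family = c("nb", "poisson", "negbin"),
                              theta = NULL, method = "REML",
                              age_limits = NULL,
                              engine = c("auto", "gam", "bam"), sp = NULL) {
  status_var <- match.arg(status_var)
  year_term <- match.arg(year_term)
  family <- match.arg(family)
  engine <- match.arg(engine)
  sx <- sex
  tab <- as.data.table(table)[sex == sx]
  if (nrow(tab) == 0) stop(sprintf("no rows for sex '%s'", sx))
  col <- if (cause == "total") "D_total" else paste0("D_", cause)
  if (!col %in% names(tab)) stop(sprintf("no column %s in table", col))
  if (is.null(age_limits) && cause != "total") {
    age_limits <- restrict_cause_ages(table[table$sex == sx, ], cause)
  }
  if (!is.null(age_limits)) {
    tab <- tab[age_lower >= age_limits[1] & age_lower < age_limits[2]]
  }
  n_zero <- sum(tab$E <= 0)
  if (n_zero > 0) {
    message(sprintf("fit_mortality_gam: dropping %d rows with zero exposure",
                    n_zero))
    tab <- tab[E > 0]
  }
  dat <- data.frame(
    D = tab[[col]],
    E = tab$E,
    age_mid = tab$age_mid,
    year_f = factor(tab$year),
    region_f = factor(tab$birth_region),
    status_f = tab[[status_var]]
  )
  lev <- unique(dat$status_f)
  lev <- c(intersect("stayer", lev), sort(setdiff(lev, "stayer")))
  dat$status_f <- factor(dat$status_f, levels = lev)

  min_unique <- min(tapply(dat$age_mid, dat$status_f,
                           function(a) length(unique(a))))
  k_use <- max(3, min(k, min_unique))
  if (k_use < k && min_unique >= 3) {
    message(sprintf("fit_mortality_gam: basis size reduced to %d (few distinct age midpoints)",
                    k_use))
  }
  smooth_term <- if (min_unique >= 3) {
    sprintf("s(age_mid, by = status_f, bs = 'cr', k = %d)", k_use)
  }  # too few distinct ages: age handled by the factor structure alone
  terms <- c("region_f",
             if (year_term == "factor") "year_f" else "s(year_n, bs = 'cr', k = 10)",
             "status_f",
             smooth_term,
             "offset(log(E))")
  if (nlevels(dat$region_f) < 2) terms <- setdiff(terms, "region_f")
  if (year_term == "factor" && nlevels(dat$year_f) < 2) {
    terms <- setdiff(terms, "year_f")
  }
  if (nlevels(dat$status_f) < 2) terms <- setdiff(terms, "status_f")
  if (year_term == "smooth") dat$year_n <- as.numeric(as.character(dat$year_f))
  rhs_terms <- setdiff(terms, "offset(log(E))")
  rhs <- paste(c(if (length(rhs_terms) == 0) "1", rhs_terms, "offset(log(E))"),
               collapse = " + ")
  fml <- stats::as.formula(paste("D ~", rhs))

  fam <- switch(family,
                nb = mgcv::nb(),
                poisson = stats::poisson(),
                negbin = {
                  if (is.null(theta)) stop("family='negbin' needs `theta`")
                  mgcv::negbin(theta)
                })
  use_bam <- engine == "bam" || (engine == "auto" && nrow(dat) > 20000)
  fit <- if (use_bam) {
    mgcv::bam(fml, data = dat, family = fam, method = "fREML",
              discrete = TRUE, sp = sp)
  } else {
    mgcv::gam(fml, data = dat, family = fam, method = method, sp = sp)
  }
  converged <- isTRUE(fit$converged)
  if (!converged) {
    warning("fit_mortality_gam: fit did not converge; model is flagged")
  }
  th <- if (family == "poisson") Inf else {
    if (family == "negbin") theta else fit$family$getTheta(TRUE)
  }
  domains <- lapply(split(dat$age_mid, dat$status_f), range)
  band_lo <- band_lower_from_label(levels(dat$status_f))
  names(band_lo) <- levels(dat$status_f)

  structure(list(fit = fit, sex = sx, cause = cause, status_var = status_var,
                 status_levels = levels(dat$status_f), domains = domains,
                 band_lower = band_lo, theta = th, converged = converged,
                 year_term = year_term, k = k_use,
                 regions = levels(dat$region_f), years = levels(dat$year_f),
                 age_limits = age_limits, n_dropped_zero_exposure = n_zero),
            class = "mortality_gam")
}

#' @export
print.mortality_gam <- function(x, ...) {
  cat(sprintf("mortality_gam: sex=%s cause=%s, %d statuses, theta=%.3g%s\n",
              x$sex, x$cause, length(x$status_levels), x$theta,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Predict log mortality rates from a fitted model
#'
#' Evaluates the linear predictor (region + year + status + status-specific
#' age smooth) with its delta-method standard error. Requests at ages below a
#' status band's lower bound return an explicit structural-zero result
#' (`log_rate = -Inf`, `structural = TRUE`) rather than an extrapolation;
#' requests above a status's fitted age domain, or at unseen region/year
#' levels, are errors.
#'
#' @param model A converged `mortality_gam`.
#' @param newdata Data frame with columns `age_mid`, `year`, `birth_region`,
#'   `status`.
#' @param force Evaluate even if the model is flagged non-converged.
#' @return `newdata` with columns `log_rate`, `se`, `structural`.
#' @export
predict_log_rate <- function(model, newdata, force = FALSE) {
  stopifnot(inherits(model, "mortality_gam"))
  if (!model$converged && !force) {
    stop("model is flagged non-converged; pass force = TRUE to override")
  }
  nd <- as.data.frame(newdata)
  req <- c("age_mid", "year", "birth_region", "status")
  if (!all(req %in% names(nd))) {
    stop("newdata needs columns age_mid, year, birth_region, status")
  }
  if (!all(as.character(nd$year) %in% model$years)) {
    stop("unseen calendar-year level in newdata")
  }
  if (!all(as.character(nd$birth_region) %in% model$regions)) {
    stop("unseen birth-region level in newdata")
  }
  if (!all(nd$status %in% model$status_levels)) {
    stop("unseen status level in newdata")
  }
  structural <- nd$age_mid < model$band_lower[nd$status]
  dom_hi <- vapply(model$domains, `[`, numeric(1), 2)[nd$status]
  dom_lo <- vapply(model$domains, `[`, numeric(1), 1)[nd$status]
  beyond <- !structural & (nd$age_mid > dom_hi | nd$age_mid < dom_lo)
  if (any(beyond)) {
    stop(sprintf("%d requests outside the fitted age domain (first: status %s at age %.1f)",
                 sum(beyond), nd$status[which(beyond)[1]],
                 nd$age_mid[which(beyond)[1]]))
  }
  df <- data.frame(age_mid = nd$age_mid,
                   year_f = factor(as.character(nd$year),
                                   levels = model$years),
                   region_f = factor(as.character(nd$birth_region),
                                     levels = model$regions),
                   status_f = factor(nd$status,
                                     levels = model$status_levels),
                   E = 1)
  if (model$year_term == "smooth") {
    df$year_n <- as.numeric(as.character(df$year_f))
  }
  # keep structural rows out of the mgcv prediction (their smooth is not
  # defined there); fill with a midpoint of the valid domain, then overwrite
  df$age_mid[structural] <- dom_lo[structural]
  pr <- predict(model$fit, newdata = df, type = "link", se.fit = TRUE,
                newdata.guaranteed = TRUE, discrete = FALSE)
  nd$log_rate <- as.numeric(pr$fit)
  nd$se <- as.numeric(pr$se.fit)
  nd$log_rate[structural] <- -Inf
  nd$se[structural] <- NA_real_
  nd$structural <- structural
  nd
}
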