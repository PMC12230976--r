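#' Extract censoring records for migration-event ages
#'
#' For every mover, derives the age interval implied by the observation
#' scheme for the event that defines their band: age at first out-migration
#' (all movers) and age at final return (returnees). A move observed between
#' Dec-31 snapshots in years `y_prev` (origin state) and `y_out` (destination
#' state) occurred in a calendar year in `(y_prev, y_out]`, so the age bounds
#' are `[y_prev - b + 1, y_out - b + 1)` at annual granularity (`b` = birth
#' year). When the first observation is already in the destination state the
#' event age is left-censored with lower bound 1. Width-1 intervals are exact.
#'
#' @param histories An `individual_histories` object after
#'   [apply_observation_scheme()].
#' @param classification Output of [classify_histories()].
#' @param cohort_breaks Birth-year breaks defining cohort bands used as
#'   imputation strata (default `c(1940, 1970)`).
#' @return Data frame of class `censoring_records`: `person_id`, `event`,
#'   `low`, `high` (age interval `[low, high)`), `exact` (width 1), `sex`,
#'   `birth_year`, `cohort_band`, `birth_region`.
#' @export
extract_censoring_records <- function(histories, classification,
                                      cohort_breaks = c(1940, 1970)) {
  stopifnot(inherits(histories, "individual_histories"))
  p <- histories$persons
  res <- histories$residence
  oy <- histories$observed_years
  movers <- classification[classification$status != "stayer", ]
  if (nrow(movers) == 0) {
    out <- data.frame(person_id = integer(), event = character(),
                      low = numeric(), high = numeric(), exact = logical(),
                      sex = character(), birth_year = integer(),
                      cohort_band = character(), birth_region = integer())
    class(out) <- c("censoring_records", class(out))
    return(out)
  }
  idx <- match(movers$person_id, p$person_id)
  b <- p$birth_year[idx]; br <- p$birth_region[idx]
  dy <- p$death_year[idx]; dr <- p$death_region[idx]
  dead <- !is.na(dy)
  M <- res[idx, , drop = FALSE]
  # mask observations after death
  ycols <- matrix(oy, nrow = nrow(M), ncol = length(oy), byrow = TRUE)
  M[dead & !is.na(dy) & ycols > ifelse(is.na(dy), Inf, dy)] <- NA_integer_
  out_mat <- !is.na(M) & M != br     # observed outside birth region
  in_mat  <- !is.na(M) & M == br     # observed in birth region
  colidx <- matrix(seq_along(oy), nrow = nrow(M), ncol = length(oy), byrow = TRUE)

  any_out_scheme <- rowSums(out_mat) > 0
  death_out <- dead & !is.na(dr) & dr != br
  if (any(!any_out_scheme & !death_out)) {
    bad <- movers$person_id[which(!any_out_scheme & !death_out)[1]]
    stop(sprintf("inconsistent residence sequence for person %s: mover never observed outside birth region",
                 bad))
  }

  # ---- first out-migration: first observation in the outside state ----
  j1 <- ifelse(any_out_scheme,
               max.col(out_mat, ties.method = "first"), NA_integer_)
  y_out <- ifelse(any_out_scheme, oy[ifelse(is.na(j1), 1L, j1)], dy)
  # last in-birth observation strictly before the first outside observation
  before_mask <- in_mat & (colidx < ifelse(is.na(j1), Inf, j1)) &
    (ycols < y_out)
  has_prev <- rowSums(before_mask) > 0
  jprev <- max.col(before_mask, ties.method = "last")
  y_prev <- ifelse(has_prev, oy[jprev], NA_integer_)
  low <- ifelse(has_prev, y_prev - b + 1L, 1L)
  low <- pmax(low, 1L)
  high <- y_out - b + 1L
  rec1 <- data.frame(person_id = movers$person_id, event = "first_migration",
                     low = as.numeric(low), high = as.numeric(high),
                     stringsAsFactors = FALSE)

  # ---- final return (returnees): last outside observation, then first
  # in-birth observation after it (the death record counts) ----
  is_ret <- movers$status == "returnee"
  rec2 <- NULL
  if (any(is_ret)) {
    om <- out_mat[is_ret, , drop = FALSE]
    im <- in_mat[is_ret, , drop = FALSE]
    ci <- colidx[is_ret, , drop = FALSE]
    if (any(rowSums(om) == 0)) {
      bad <- movers$person_id[is_ret][which(rowSums(om) == 0)[1]]
      stop(sprintf("inconsistent residence sequence for person %s: returnee never observed outside birth region",
                   bad))
    }
    jL <- max.col(om, ties.method = "last")
    y_last_out <- oy[jL]
    after_mask <- im & (ci > jL)
    has_back <- rowSums(after_mask) > 0
    jback <- max.col(after_mask, ties.method = "first")
    y_back_scheme <- ifelse(has_back, oy[jback], NA_integer_)
    y_back <- pmin(y_back_scheme, ifelse(dead[is_ret], dy[is_ret], NA_integer_),
                   na.rm = TRUE)
    if (any(!is.finite(y_back))) {
      bad <- movers$person_id[is_ret][which(!is.finite(y_back))[1]]
      stop(sprintf("inconsistent residence sequence for person %s: returnee with no observed return",
                   bad))
    }
    rec2 <- data.frame(person_id = movers$person_id[is_ret], event = "return",
                       low = as.numeric(y_last_out - b[is_ret] + 1L),
                       high = as.numeric(y_back - b[is_ret] + 1L),
                       stringsAsFactors = FALSE)
  }
  recs <- rbind(rec1, rec2)
  m <- match(recs$person_id, p$person_id)
  # right-truncation age: the event had to occur by the person's last
  # observation for them to enter the mover sample at all
  last_obs_year <- rep(NA_integer_, nrow(p))
  has_any <- rowSums(!is.na(res)) > 0
  if (any(has_any)) {
    j <- max.col(!is.na(res[has_any, , drop = FALSE]), ties.method = "last")
    last_obs_year[has_any] <- oy[j]
  }
  last_obs_year <- ifelse(!is.na(p$death_year),
                          pmax(p$death_year, last_obs_year, na.rm = TRUE),
                          last_obs_year)
  recs$trunc <- last_obs_year[m] - p$birth_year[m] + 1L
  recs$exact <- (recs$high - recs$low) == 1
  recs$sex <- p$sex[m]
  recs$birth_year <- p$birth_year[m]
  cb <- sort(cohort_breaks)
  lab <- c(sprintf("pre%d", cb[1]),
           if (length(cb) > 1) sprintf("%d_%d", cb[-length(cb)], cb[-1] - 1),
           sprintf("%dplus", cb[length(cb)]))
  recs$cohort_band <- lab[findInterval(recs$birth_year, cb) + 1L]
  recs$birth_region <- p$birth_region[m]
  stopifnot(all(recs$low < recs$high))
  class(recs) <- c("censoring_records", class(recs))
  recs
}

# cumulative hazard of a piecewise-constant hazard at numeric ages
pch_cumhaz <- function(t, breaks, log_haz) {
  # breaks: lower bounds of hazard bands, breaks[1] == 0
  haz <- exp(log_haz)
  upper <- c(breaks[-1], Inf)
  cumH_at_break <- c(0, cumsum(haz[-length(haz)] *
                               (upper[-length(upper)] - breaks[-length(breaks)])))
  i <- findInterval(t, breaks)
  i[i < 1] <- 1
  H <- cumH_at_break[i] + haz[i] * (t - breaks[i])
  H[t <= 0] <- 0
  H[is.infinite(t)] <- Inf
  H
}

pch_surv <- function(t, breaks, log_haz) {
  exp(-pch_cumhaz(t, breaks, log_haz))
}

# log(exp(a_log) - exp(b_log)) for a_log >= b_log, stably
log_diff_exp <- function(a_log, b_log) {
  d <- b_log - a_log
  a_log + log1p(-pmin(exp(d), 1 - 1e-16))
}

#' Fit a piecewise-constant-hazard model for an event age
#'
#' Maximum-likelihood fit of a piecewise-constant hazard on age bands (default
#' 0-16, 17-29, 30-59, 60+) from exact and interval-censored records, the
#' missing-data treatment of censored migration ages. An exact age `a`
#' contributes `S(a) - S(a+1)`; an interval `[L, H)` contributes
#' `S(L) - S(H)`. Models are stratified by sex x cohort band; strata with too
#' few exactly-observed events fall back to the pooled model with a warning.
#'
#' @param records A `censoring_records` data frame (one event type).
#' @param event Which event to model (default the single event present).
#' @param bands Lower bounds of the hazard age bands (default
#'   `c(0, 17, 30, 60)`).
#' @param min_exact Minimum exactly-observed events for a stratum-specific fit
#'   (default 30).
#' @return Object of class `event_age_model`: per-stratum log hazards, the
#'   pooled fit, the bands, and fit diagnostics.
#' @export
fit_event_age_model <- function(records, event = NULL,
                                bands = c(0, 17, 30, 60),
                                min_exact = 30) {
  if (is.null(event)) {
    ev <- unique(records$event)
    if (length(ev) != 1) stop("records contain several events; pass `event`")
    event <- ev
  }
  r <- records[records$event == event, ]
  if (nrow(r) == 0) stop(sprintf("no records for event '%s'", event))

  # right-truncated interval-censored likelihood: the record enters the
  # sample only because the event occurred before the person's last
  # observation, so each contribution is P(L <= T < H) / P(1 <= T < C)
  if (is.null(r$trunc)) r$trunc <- Inf
  negll <- function(log_haz, low, high, trunc) {
    lnum <- log_diff_exp(-pch_cumhaz(low, bands, log_haz),
                         -pch_cumhaz(high, bands, log_haz))
    lden <- log_diff_exp(-pch_cumhaz(rep(1, length(low)), bands, log_haz),
                         -pch_cumhaz(trunc, bands, log_haz))
    -sum(lnum - lden)
  }
  fit_one <- function(low, high, trunc) {
    start <- rep(log(0.02), length(bands))
    opt <- optim(start, negll, low = low, high = high, trunc = trunc,
                 method = "L-BFGS-B", lower = log(1e-5), upper = log(0.95),
                 control = list(maxit = 500))
    list(log_haz = opt$par, value = opt$value,
         converged = opt$convergence == 0, n = length(low))
  }

  pooled <- fit_one(r$low, r$high, r$trunc)
  strata <- split(seq_len(nrow(r)), paste(r$sex, r$cohort_band, sep = "."))
  fits <- list(); fallback <- character()
  for (s in names(strata)) {
    i <- strata[[s]]
    if (sum(r$exact[i]) >= min_exact) {
      fits[[s]] <- fit_one(r$low[i], r$high[i], r$trunc[i])
    } else {
      fits[[s]] <- pooled
      fallback <- c(fallback, s)
    }
  }
  if (length(fallback)) {
    warning(sprintf("event_age_model: %d strata fell back to the pooled fit (%s)",
                    length(fallback), paste(fallback, collapse = ", ")))
  }
  structure(list(event = event, bands = bands, strata = fits,
                 pooled = pooled, fallback = fallback),
            class = "event_age_model")
}

#' Impute censored event ages
#'
#' Draws each censored age from the fitted distribution truncated to its
#' bounds; exact (width-1) records are forced to their lower bound. Intervals
#' with zero model mass fall back to their midpoint, with a count kept in the
#' `n_fallback` attribute.
#'
#' @param records A `censoring_records` data frame.
#' @param model An `event_age_model` (or named list of models keyed by event).
#' @param seed Integer seed; imputation is deterministic given the seed.
#' @param audit If `TRUE`, attach the per-record source ("exact", "draw",
#'   "midpoint") as a column.
#' @return Data frame `person_id`, `event`, `age`, with attribute
#'   `n_fallback`.
#' @export
impute_event_ages <- function(records, model, seed, audit = FALSE) {
  set.seed(as.integer(seed))
  models <- if (inherits(model, "event_age_model")) {
    setNames(list(model), model$event)
  } else model
  out <- records[, c("person_id", "event")]
  out$age <- NA_real_
  src <- rep(NA_character_, nrow(records))
  n_fallback <- 0L
  exact <- records$exact
  out$age[exact] <- records$low[exact]
  src[exact] <- "exact"
  for (k in which(!exact)) {
    ev <- records$event[k]
    m <- models[[ev]]
    if (is.null(m)) stop(sprintf("no model supplied for event '%s'", ev))
    key <- paste(records$sex[k], records$cohort_band[k], sep = ".")
    fit <- if (!is.null(m$strata[[key]])) m$strata[[key]] else m$pooled
    ages <- seq.int(records$low[k], records$high[k] - 1L)
    pr <- pch_surv(ages, m$bands, fit$log_haz) -
          pch_surv(ages + 1, m$bands, fit$log_haz)
    if (!any(pr > 0) || !all(is.finite(pr))) {
      out$age[k] <- floor((records$low[k] + records$high[k] - 1) / 2)
      src[k] <- "midpoint"
      n_fallback <- n_fallback + 1L
    } else {
      out$age[k] <- if (length(ages) == 1) ages else
        sample(ages, 1L, prob = pr)
      src[k] <- "draw"
    }
  }
  if (n_fallback > 0) {
    warning(sprintf("impute_event_ages: %d zero-mass intervals imputed at their midpoint",
                    n_fallback))
  }
  if (audit) out$source <- src
  attr(out, "n_fallback") <- n_fallback
  rownames(out) <- NULL
  out
}
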