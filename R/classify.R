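#' Classify migration status from observed residences
#'
#' A person is a *stayer* if every observed residence equals the birth region;
#' a *leaver* if at least one observation is outside the birth region and the
#' last relevant observation (December 31 of the final follow-up year, or the
#' year of death) is outside it; and a *returnee* if at least one observation
#' is outside the birth region but the last relevant observation equals it.
#' The death record's region counts as an observation in the year of death.
#'
#' @param histories An `individual_histories` object (usually after
#'   [apply_observation_scheme()]).
#' @return Data frame with `person_id` and `status`
#'   (`stayer`/`leaver`/`returnee`), one row per classifiable person.
#'   Attribute `n_unclassifiable` counts persons with no observation and no
#'   death record (excluded).
#' @export
classify_histories <- function(histories) {
  stopifnot(inherits(histories, "individual_histories"))
  p <- histories$persons
  res <- histories$residence
  oy <- histories$observed_years
  n <- nrow(p)

  # mask observations after death (snapshot in the death year itself is kept)
  dead <- !is.na(p$death_year)
  if (any(dead)) {
    after <- outer(p$death_year, oy, FUN = function(d, y) !is.na(d) & y > d)
    res[after] <- NA_integer_
  }

  out_mat <- res != p$birth_region         # NA where unobserved
  ever_out <- rowSums(out_mat, na.rm = TRUE) > 0
  has_obs <- rowSums(!is.na(res)) > 0

  # last relevant observation: death-year region for the dead, else the last
  # observed residence
  last_obs <- rep(NA_integer_, n)
  any_obs <- which(has_obs)
  if (length(any_obs)) {
    idx <- max.col(!is.na(res[any_obs, , drop = FALSE]), ties.method = "last")
    last_obs[any_obs] <- res[cbind(any_obs, idx)]
  }
  last_rel <- ifelse(dead, p$death_region, last_obs)
  ever_out <- ever_out | (!is.na(last_rel) & last_rel != p$birth_region)

  classifiable <- has_obs | dead
  status <- ifelse(!ever_out, "stayer",
                   ifelse(last_rel == p$birth_region, "returnee", "leaver"))
  out <- data.frame(person_id = p$person_id, status = status,
                    stringsAsFactors = FALSE)[classifiable, ]
  n_uncl <- sum(!classifiable)
  if (n_uncl > 0) {
    message(sprintf("classify_histories: %d unclassifiable individuals excluded",
                    n_uncl))
  }
  attr(out, "n_unclassifiable") <- n_uncl
  rownames(out) <- NULL
  out
}

#' Assign age-at-migration bands to classified individuals
#'
#' Leavers are banded by age at first out-migration (`<17`, `17-29`, `30-59`,
#' `>=60` by default) and returnees by age at return (`<30`, `30-59`, `>=60`).
#' Event ages come from observation (exact) or imputation. Stayers form a
#' single band.
#'
#' @param classification Output of [classify_histories()].
#' @param event_ages Data frame `person_id`, `event`
#'   (`first_migration`/`return`), `age` — as returned by
#'   [impute_event_ages()].
#' @param leaver_breaks Lower bounds of the leaver bands after the first
#'   (default `c(17, 30, 60)`).
#' @param returnee_breaks Lower bounds of the returnee bands after the first
#'   (default `c(30, 60)`; pass `c(17, 30, 60)` for the four descriptive
#'   bands used in sample summaries).
#' @return The classification with columns `age_first_migration`,
#'   `age_return` (per-person event ages where known), `event_age` (the
#'   band-defining one), `status_band` (e.g. `"leaver_17_29"`), and
#'   `band_lower` (the band's lower age bound; 0 for stayers and first
#'   bands).
#' @export
assign_status_bands <- function(classification, event_ages,
                                leaver_breaks = c(17, 30, 60),
                                returnee_breaks = c(30, 60)) {
  cl <- classification
  ea <- event_ages
  key_ea <- paste(ea$person_id, ea$event)
  cl$age_first_migration <-
    ea$age[match(paste(cl$person_id, "first_migration"), key_ea)]
  cl$age_return <- ea$age[match(paste(cl$person_id, "return"), key_ea)]
  cl$event_age <- ifelse(cl$status == "leaver", cl$age_first_migration,
                         ifelse(cl$status == "returnee", cl$age_return,
                                NA_real_))
  missing_ev <- cl$status != "stayer" & is.na(cl$event_age)
  if (any(missing_ev)) {
    stop(sprintf("missing event age for %d movers (first person_id %s)",
                 sum(missing_ev), cl$person_id[which(missing_ev)[1]]))
  }
  band_of <- function(age, breaks) {
    # returns band index and label parts
    findInterval(age, breaks) + 1L
  }
  lab <- function(breaks) {
    lo <- c(0, breaks); hi <- c(breaks, Inf)
    ifelse(lo == 0, sprintf("lt%g", hi),
           ifelse(is.infinite(hi), sprintf("%gp", lo),
                  sprintf("%g_%g", lo, hi - 1)))
  }
  cl$status_band <- "stayer"
  cl$band_lower <- 0
  lv <- cl$status == "leaver"
  if (any(lv)) {
    i <- band_of(cl$event_age[lv], leaver_breaks)
    cl$status_band[lv] <- paste0("leaver_", lab(leaver_breaks)[i])
    cl$band_lower[lv] <- c(0, leaver_breaks)[i]
  }
  rt <- cl$status == "returnee"
  if (any(rt)) {
    i <- band_of(cl$event_age[rt], returnee_breaks)
    cl$status_band[rt] <- paste0("returnee_", lab(returnee_breaks)[i])
    cl$band_lower[rt] <- c(0, returnee_breaks)[i]
  }
  cl
}
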