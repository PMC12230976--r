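#' Build the aggregated exposure table
#'
#' Expands individual histories into person-years and aggregates deaths `D`
#' and exposure `E` by 3-year age group, calendar year, sex, birth region and
#' migration state. Each full alive calendar year contributes 1 person-year
#' (the death year contributes the configured fraction, default 0.5); ages
#' outside `[20, 95)` are excluded.
#'
#' Person-years are attributed to the migration state occupied that year:
#' years before the (observed or imputed) first out-migration — and all years
#' of never-movers — count as stayer exposure; years outside the birth region
#' count as leaver exposure, banded by age at first out-migration; years back
#' in the birth region after a return count as returnee exposure, banded by
#' the age at the return that opened the spell (for a classified returnee's
#' final spell, the imputed age at final return). Deaths attributed this way
#' coincide exactly with the retrospective stayer/leaver/returnee
#' classification: a death outside the birth region is a leaver death, a
#' death in the birth region after a return is a returnee death. This
#' attribution keeps death counts and person-years referring to the same risk
#' sets (see the methods vignette). Between observation years, residence is
#' carried backward from the next observation (the death-year region counts
#' as an observation); the imputed event ages override the backfill for the
#' defining transitions. Exposure of returnees in the youngest band is capped
#' at the last full age group below the configured upper limit.
#'
#' @param histories An `individual_histories` object.
#' @param status_bands Output of [assign_status_bands()] (columns
#'   `person_id`, `status`, `status_band`, `age_first_migration`,
#'   `age_return`).
#' @param age_range Half-open age interval (default `c(20, 95)`).
#' @param group_width Age-group width in years (default 3).
#' @param death_year_exposure Person-years credited in the death year
#'   (default from the simulation config, else 0.5).
#' @param returnee_young_cap Upper modeling age for the youngest returnee
#'   band (default 77); exposure is kept for whole age groups ending below
#'   this limit.
#' @param leaver_breaks,returnee_breaks Band lower bounds after the first
#'   band (defaults `c(17, 30, 60)` and `c(30, 60)`), used to band
#'   state-years.
#' @return `data.table` of class `exposure_table`: `age_lower`, `age_mid`,
#'   `year`, `sex`, `birth_region`, `status_coarse`, `status` (band label),
#'   `E`, `D_total` and one `D_<cause>` column per cause (including
#'   `D_ill_defined`). Attribute `accounting` reconciles total person-years.
#' @export
build_exposure_table <- function(histories, status_bands,
                                 age_range = c(20, 95), group_width = 3,
                                 death_year_exposure = NULL,
                                 returnee_young_cap = 77,
                                 leaver_breaks = c(17, 30, 60),
                                 returnee_breaks = c(30, 60)) {
  stopifnot(inherits(histories, "individual_histories"))
  p <- as.data.table(histories$persons)
  y0 <- histories$years[1]; y1 <- histories$years[length(histories$years)]
  if (is.null(death_year_exposure)) {
    death_year_exposure <- histories$config$death_year_exposure
    if (is.null(death_year_exposure)) death_year_exposure <- 0.5
  }
  sb <- as.data.table(status_bands)[, .(person_id, status, status_band,
                                        age_first_migration, age_return)]
  dt <- merge(p, sb, by = "person_id")
  if (nrow(dt) == 0) stop("no classified individuals")

  dt[, entry_year := pmax(birth_year, y0)]
  dt[, exit_year := fifelse(is.na(death_year), y1, as.integer(death_year))]
  dt <- dt[exit_year >= entry_year]
  dt[, nyears := exit_year - entry_year + 1L]

  # person-year expansion
  offsets <- sequence(dt$nyears) - 1L
  long <- dt[rep(seq_len(.N), nyears)]
  long[, year := entry_year + offsets]
  long[, age := year - birth_year]
  if (any(is.na(long$age))) {
    bad <- long$person_id[which(is.na(long$age))[1]]
    stop(sprintf("person-year with undefined age for person %s", bad))
  }
  long <- long[age >= age_range[1] & age < age_range[2]]
  long[, E := fifelse(!is.na(death_year) & year == death_year,
                      death_year_exposure, 1)]
  raw_in_range <- sum(long$E)

  # ---- current-state attribution -------------------------------------
  # backfilled residence (next observation at or after the year, with the
  # death-year region appended as an observation)
  obs_years <- histories$observed_years
  res <- histories$residence
  obs_long <- data.table(
    person_id = rep(histories$persons$person_id, length(obs_years)),
    year = rep(as.integer(obs_years), each = nrow(res)),
    region = as.integer(res))
  obs_long <- obs_long[!is.na(region)]
  pd <- p[!is.na(death_year),
          .(person_id, year = as.integer(death_year), region = death_region)]
  obs_long <- unique(rbind(obs_long, pd), by = c("person_id", "year"))
  setkeyv(obs_long, c("person_id", "year"))
  long[, bf_region := obs_long[long[, .(person_id, year)],
                               on = c("person_id", "year"),
                               roll = -Inf, region]]

  # a classified stayer (never observed outside) is stayer throughout, even
  # if an event-age table carries ages for them
  mover <- long$status != "stayer" & !is.na(long$age_first_migration) &
    long$age >= long$age_first_migration
  post_final_return <- mover & long$status == "returnee" &
    !is.na(long$age_return) & long$age >= long$age_return
  away <- mover & !post_final_return & !is.na(long$bf_region) &
    long$bf_region != long$birth_region
  interim_home <- mover & !post_final_return & !away
  unresolved <- mover & !post_final_return & is.na(long$bf_region)
  n_unresolved <- sum(long$E[unresolved])

  band_label <- function(age, breaks) {
    lo <- c(0, breaks); hi <- c(breaks, Inf)
    lab <- ifelse(lo == 0, sprintf("lt%g", hi),
                  ifelse(is.infinite(hi), sprintf("%gp", lo),
                         sprintf("%g_%g", lo, hi - 1)))
    lab[findInterval(age, breaks) + 1L]
  }

  long[, state_coarse := "stayer"]
  long[, state := "stayer"]
  if (any(away)) {
    long$state_coarse[away] <- "leaver"
    long$state[away] <- paste0("leaver_",
      band_label(long$age_first_migration[away], leaver_breaks))
  }
  if (any(post_final_return)) {
    long$state_coarse[post_final_return] <- "returnee"
    long$state[post_final_return] <- paste0("returnee_",
      band_label(long$age_return[post_final_return], returnee_breaks))
  }
  if (any(interim_home)) {
    # interim in-birth-region spells: band by the age at the start of the
    # consecutive in-birth run (the return that opened the spell)
    long[, .tmp_interim := interim_home]
    long[, .tmp_run := data.table::rleid(.tmp_interim), by = person_id]
    long[.tmp_interim == TRUE,
         .tmp_spell_age := min(age), by = .(person_id, .tmp_run)]
    ih <- which(long$.tmp_interim)
    long$state_coarse[ih] <- "returnee"
    long$state[ih] <- paste0("returnee_",
      band_label(long$.tmp_spell_age[ih], returnee_breaks))
    long[, c(".tmp_interim", ".tmp_run", ".tmp_spell_age") := NULL]
  }

  # cap the youngest returnee band at whole age groups below the upper limit
  grp_starts <- seq(age_range[1], age_range[2] - 1, by = group_width)
  cap_lower <- max(grp_starts[grp_starts + group_width <= returnee_young_cap])
  cap_age <- cap_lower + group_width  # first excluded age
  young_ret <- startsWith(long$state, "returnee_lt")
  capped <- young_ret & long$age >= cap_age
  dropped_cap <- sum(long$E[capped])
  if (any(capped)) long <- long[!capped]

  long[, age_lower := age_range[1] +
         group_width * ((age - age_range[1]) %/% group_width)]
  etab <- long[, .(E = sum(E)),
               by = .(age_lower, year, sex, birth_region,
                      status_coarse = state_coarse, status = state)]

  # deaths: state at death equals the retrospective classification
  d <- dt[!is.na(death_year) & death_age >= age_range[1] &
            death_age < age_range[2]]
  d <- d[status == "stayer" |
           (status == "leaver" & death_age >= age_first_migration) |
           (status == "returnee" & death_age >= age_return)]
  d <- d[!(startsWith(status_band, "returnee_lt") & death_age >= cap_age)]
  if (nrow(d)) {
    d[, age_lower := age_range[1] +
        group_width * ((death_age - age_range[1]) %/% group_width)]
    dtab <- dcast(d, age_lower + death_year + sex + birth_region + status +
                    status_band ~ cause, fun.aggregate = length,
                  value.var = "person_id")
    setnames(dtab, c("death_year", "status", "status_band"),
             c("year", "status_coarse", "status"))
    cause_cols <- setdiff(names(dtab),
                          c("age_lower", "year", "sex", "birth_region",
                            "status_coarse", "status"))
    setnames(dtab, cause_cols, paste0("D_", cause_cols))
  } else {
    dtab <- NULL
  }

  all_causes <- c(cause_groups(), "ill_defined")
  tab <- if (is.null(dtab)) etab else {
    merge(etab, dtab,
          by = c("age_lower", "year", "sex", "birth_region",
                 "status_coarse", "status"),
          all = TRUE)
  }
  for (cc in paste0("D_", all_causes)) {
    if (!cc %in% names(tab)) tab[, (cc) := 0]
    tab[is.na(get(cc)), (cc) := 0]
  }
  tab[is.na(E), E := 0]
  tab[, D_total := rowSums(.SD), .SDcols = paste0("D_", all_causes)]
  tab[, age_mid := age_lower + (group_width - 1) / 2 + 0.5]
  setkeyv(tab, c("sex", "status", "age_lower", "year", "birth_region"))

  structure_attr <- list(
    age_range = age_range, group_width = group_width,
    death_year_exposure = death_year_exposure,
    returnee_young_cap = cap_age,
    accounting = c(in_range_person_years = raw_in_range,
                   dropped_returnee_cap = dropped_cap,
                   unresolved_residence = n_unresolved,
                   tabulated = sum(tab$E)))
  setattr(tab, "exposure_meta", structure_attr)
  setattr(tab, "class", c("exposure_table", class(data.table())))
  tab[]
}

#' Verify structural-zero cells of an exposure table
#'
#' For every banded status, cells whose age group ends before the band's
#' lower age bound must contain zero deaths and zero exposure: membership in
#' e.g. the returnee->=60 band requires surviving to a return at 60 or later.
#'
#' @param table An `exposure_table`.
#' @return `TRUE` invisibly; stops with a message if a violation is found.
#' @export
check_structural_zeros <- function(table) {
  meta <- attr(table, "exposure_meta")
  gw <- meta$group_width
  bl <- band_lower_from_label(table$status)
  age_upper <- table$age_lower + gw - 1
  bad <- age_upper < bl & (table$E > 0 | table$D_total > 0)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("structural-zero violation: status %s has E=%.3g, D=%g in age group %d-%d",
                 table$status[i], table$E[i], table$D_total[i],
                 table$age_lower[i], age_upper[i]))
  }
  invisible(TRUE)
}

# parse the lower age bound out of band labels like "leaver_17_29",
# "returnee_60p", "leaver_lt17", "stayer"
band_lower_from_label <- function(label) {
  out <- rep(0, length(label))
  part <- sub("^[a-z]+_", "", label)
  p60 <- grepl("^[0-9]+p$", part)
  out[p60] <- as.numeric(sub("p$", "", part[p60]))
  rng <- grepl("^[0-9]+_[0-9]+$", part)
  out[rng] <- as.numeric(sub("_[0-9]+$", "", part[rng]))
  out
}
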