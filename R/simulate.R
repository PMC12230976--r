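#' Simulate individual residential and mortality histories
#'
#' Each person starts in their birth region and evolves in discrete annual
#' steps: first a possible move (out-migration while in the birth region;
#' return or onward move while outside), then a death draw with annual
#' probability `1 - exp(-rate)` where
#' `log(rate) = baseline(age) + region_effect[birth_region] + year_effect +
#' status_effect(current latent status, age)`. The year-end region determines
#' that year's residence snapshot. Years before the horizon start simulate
#' residential mobility only (the sample is conditioned on being alive at the
#' horizon start), which is what generates left censoring of migration ages.
#'
#' @param config A [sim_config()] object.
#' @return Object of class `individual_histories`: a list with `persons`
#'   (one row per person: ids, sex, birth year/region, death year/age/region,
#'   cause, ground-truth migration ages), `residence` (integer matrix person x
#'   horizon year, `NA` before birth or after death), `years` (horizon
#'   years), `observed_years` (initially all horizon years) and `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n  <- config$n_individuals
  y0 <- config$years[1]; y1 <- config$years[2]
  yrs <- y0:y1

  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
  birth_year <- sample(seq.int(config$cohort_range[1], config$cohort_range[2]),
                       n, replace = TRUE)
  birth_region <- sample.int(config$n_regions, n, replace = TRUE)

  cur <- birth_region
  ever_left <- logical(n)
  first_mig_age <- rep(NA_integer_, n)
  last_ret_age  <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  death_year <- rep(NA_integer_, n); death_age <- rep(NA_integer_, n)
  death_region <- rep(NA_integer_, n); cause <- rep(NA_character_, n)

  res <- matrix(NA_integer_, nrow = n, ncol = length(yrs),
                dimnames = list(NULL, yrs))
  causes <- cause_groups()
  dest_uniform <- function(k, exclude1, exclude2 = NULL) {
    # uniform draw over regions excluding one or two indices, vectorised
    R <- config$n_regions
    if (is.null(exclude2)) {
      d <- sample.int(R - 1L, k, replace = TRUE)
      d + (d >= exclude1)
    } else {
      ex_lo <- pmin(exclude1, exclude2); ex_hi <- pmax(exclude1, exclude2)
      same <- ex_lo == ex_hi
      d <- sample.int(R - 2L, k, replace = TRUE)
      d <- d + (d >= ex_lo)
      d <- d + (d >= ex_hi & !same)
      # when the two exclusions coincide (mover whose current region is the
      # only exclusion) fall back to single-exclusion logic
      if (any(same)) {
        d2 <- sample.int(R - 1L, sum(same), replace = TRUE)
        d[same] <- d2 + (d2 >= ex_lo[same])
      }
      d
    }
  }
  draw_dest <- if (is.function(config$destination_rule)) {
    config$destination_rule
  } else dest_uniform

  for (y in seq.int(min(min(birth_year) + 1L, y0), y1)) {
    age <- y - birth_year
    born <- birth_year <= y

    # --- moves (move first, then death; year-end region is observed) ---
    can_move <- alive & born & age >= 1L
    # at most one move per year: branch on the start-of-year state
    in_birth <- can_move & cur == birth_region
    away <- can_move & cur != birth_region
    if (any(in_birth)) {
      h <- config$out_migration_hazard(age, sex)
      bad <- in_birth & (!is.finite(h) | h < 0 | h > 1)
      if (any(bad)) {
        i <- which(bad)[1]
        stop(sprintf("out-migration hazard invalid (%.3g) at age %d, year %d",
                     h[i], age[i], y))
      }
      mv_out <- in_birth & runif(n) < h
      if (any(mv_out)) {
        k <- which(mv_out)
        cur[k] <- draw_dest(length(k), birth_region[k])
        newly <- k[!ever_left[k]]
        first_mig_age[newly] <- age[newly]
        ever_left[k] <- TRUE
      }
    }
    if (any(away)) {
      u <- runif(n)
      mv_ret <- away & u < config$return_hazard
      mv_onw <- away & !mv_ret & runif(n) < config$onward_hazard
      if (any(mv_ret)) {
        k <- which(mv_ret)
        cur[k] <- birth_region[k]
        last_ret_age[k] <- age[k]
      }
      if (any(mv_onw)) {
        k <- which(mv_onw)
        cur[k] <- draw_dest(length(k), birth_region[k], cur[k])
      }
    }

    # --- mortality (horizon years only) ---
    if (y >= y0) {
      at_risk <- alive & born
      if (any(at_risk)) {
        latent <- ifelse(!ever_left, "stayer",
                         ifelse(cur == birth_region, "returnee", "leaver"))
        lrate <- config$baseline_log_mortality(age) +
          config$region_effects[birth_region] +
          config$year_effects[y - y0 + 1L]
        for (st in c("stayer", "leaver", "returnee")) {
          k <- latent == st
          if (any(k & at_risk)) {
            lrate[k] <- lrate[k] +
              status_effect_at(config$status_effects[[st]], age[k])
          }
        }
        rate <- exp(lrate)
        bad <- at_risk & (is.nan(rate) | (is.infinite(rate) & rate > 0))
        if (any(bad)) {
          i <- which(bad)[1]
          stop(sprintf("non-finite mortality rate at age %d, year %d",
                       age[i], y))
        }
        p <- 1 - exp(-rate)
        die <- at_risk & runif(n) < p
        # residence snapshot for everyone at risk this year (death-year
        # snapshot convention: the dying keep their within-year region)
        res[at_risk, y - y0 + 1L] <- cur[at_risk]
        if (any(die)) {
          k <- which(die)
          death_year[k] <- y
          death_age[k] <- age[k]
          death_region[k] <- cur[k]
          latent_k <- latent[k]
          pm <- config$cause_mix(age[k], latent_k)
          if (is.null(dim(pm))) pm <- matrix(pm, nrow = length(k), byrow = FALSE)
          cs <- pm %*% upper.tri(diag(ncol(pm)), diag = TRUE)
          u <- runif(length(k))
          ci <- rowSums(u > cs) + 1L
          cause[k] <- causes[pmin(ci, length(causes))]
          ill <- runif(length(k)) < config$illdefined_fraction
          cause[k][ill] <- "ill_defined"
          alive[k] <- FALSE
        }
      }
    }
  }

  persons <- data.frame(
    person_id = seq_len(n), sex = sex, birth_year = birth_year,
    birth_region = birth_region, death_year = death_year,
    death_age = death_age, death_region = death_region, cause = cause,
    true_age_first_migration = first_mig_age,
    true_age_return = last_ret_age,
    stringsAsFactors = FALSE)

  structure(list(persons = persons, residence = res, years = yrs,
                 observed_years = yrs, config = config),
            class = "individual_histories")
}

#' Restrict histories to an observation scheme
#'
#' Keeps residence snapshots only at the observed calendar years, emulating
#' register data in which residence is recorded at censuses and then annually.
#' Birth region and vital events remain fully known; ground-truth migration
#' ages are retained but flagged hidden (for test harnesses only).
#'
#' @param histories An `individual_histories` object.
#' @param observed_years Integer vector of observed calendar years, a subset
#'   of the horizon (default [default_observed_years()] intersected with the
#'   horizon).
#' @return The histories with `residence` restricted to observed years and
#'   `observed_years` updated; attribute `ground_truth_hidden` set.
#' @export
apply_observation_scheme <- function(histories,
                                     observed_years = default_observed_years()) {
  stopifnot(inherits(histories, "individual_histories"))
  observed_years <- sort(unique(as.integer(observed_years)))
  observed_years <- observed_years[observed_years %in% histories$years]
  if (length(observed_years) == 0) {
    stop("observed_years is empty (or disjoint from the simulation horizon)")
  }
  keep <- match(observed_years, histories$years)
  histories$residence <- histories$residence[, keep, drop = FALSE]
  histories$observed_years <- observed_years
  attr(histories, "ground_truth_hidden") <- TRUE
  histories
}

#' @export
print.individual_histories <- function(x, ...) {
  p <- x$persons
  cat(sprintf("individual_histories: %d persons, horizon %d-%d, %d observed years\n",
              nrow(p), min(x$years), max(x$years), length(x$observed_years)))
  cat(sprintf("  deaths: %d (%.1f%%); ever-migrated (truth): %d\n",
              sum(!is.na(p$death_year)),
              100 * mean(!is.na(p$death_year)),
              sum(!is.na(p$true_age_first_migration))))
  invisible(x)
}

#' Total alive person-years of a history set at annual granularity
#'
#' Sum over individuals of `min(death_year, horizon end) - entry year + f`,
#' where the death year contributes the configured fraction and entry is the
#' later of birth year and horizon start. Used by conservation checks.
#'
#' @param histories An `individual_histories` object.
#' @return Total person-years (scalar).
#' @export
person_years <- function(histories) {
  p <- histories$persons
  y0 <- histories$years[1]; y1 <- histories$years[length(histories$years)]
  entry <- pmax(p$birth_year, y0)
  f <- histories$config$death_year_exposure
  exit_full <- ifelse(is.na(p$death_year), y1, p$death_year - 1L)
  full_years <- pmax(exit_full - entry + 1L, 0)
  frac <- ifelse(is.na(p$death_year), 0, f)
  sum(full_years + frac)
}
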