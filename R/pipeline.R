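#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list and validates it against the
#' pipeline schema (unknown keys are rejected). Scalar simulation parameters
#' are passed through to [sim_config()]; the Gompertz baseline is specified
#' by its `a`/`b` parameters and status effects by constant log offsets.
#'
#' @param x Path to a YAML file, or a list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  known <- c("seed", "simulation", "observation", "bands", "imputation",
             "model", "marginal", "lifetable", "decomposition")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop(sprintf("unknown pipeline config keys: %s",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$seed)) stop("pipeline config requires a global `seed`")
  sim_known <- c("n_individuals", "n_regions", "years", "cohort_range",
                 "sex_ratio", "return_hazard", "onward_hazard",
                 "gompertz_a", "gompertz_b", "status_effect_leaver",
                 "status_effect_returnee", "illdefined_fraction",
                 "death_year_exposure", "out_migration_hazard_bands")
  unknown <- setdiff(names(cfg$simulation), sim_known)
  if (length(unknown)) {
    stop(sprintf("unknown simulation config keys: %s",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$simulation$n_individuals)) {
    stop("simulation$n_individuals is required")
  }
  defaults <- list(
    observation = list(scheme = "census_then_annual"),
    bands = list(leaver_breaks = c(17, 30, 60), returnee_breaks = c(30, 60)),
    imputation = list(bands = c(0, 17, 30, 60), min_exact = 30),
    model = list(k = 10, status_var = "status_coarse", family = "nb",
                 sexes = c("male", "female"), causes = character()),
    marginal = list(n_draws = 1000),
    lifetable = list(from_ages = c(20, 50, 80)),
    decomposition = list(n_steps = 1000))
  for (sec in names(defaults)) {
    user <- cfg[[sec]]
    unknown <- setdiff(names(user), names(defaults[[sec]]))
    if (length(unknown)) {
      stop(sprintf("unknown %s config keys: %s", sec,
                   paste(unknown, collapse = ", ")))
    }
    cfg[[sec]] <- utils::modifyList(defaults[[sec]], user %||% list())
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# build the sim_config from a pipeline_config
build_sim_config <- function(cfg) {
  s <- cfg$simulation
  args <- list(n_individuals = s$n_individuals, seed = cfg$seed)
  if (!is.null(s$n_regions)) args$n_regions <- s$n_regions
  if (!is.null(s$years)) args$years <- s$years
  if (!is.null(s$cohort_range)) args$cohort_range <- s$cohort_range
  if (!is.null(s$sex_ratio)) args$sex_ratio <- s$sex_ratio
  if (!is.null(s$return_hazard)) args$return_hazard <- s$return_hazard
  if (!is.null(s$onward_hazard)) args$onward_hazard <- s$onward_hazard
  if (!is.null(s$illdefined_fraction)) {
    args$illdefined_fraction <- s$illdefined_fraction
  }
  if (!is.null(s$death_year_exposure)) {
    args$death_year_exposure <- s$death_year_exposure
  }
  if (!is.null(s$gompertz_a) || !is.null(s$gompertz_b)) {
    args$baseline_log_mortality <- gompertz_baseline(
      a = s$gompertz_a %||% 2e-5, b = s$gompertz_b %||% 0.095)
  }
  se <- list(stayer = 0,
             leaver = s$status_effect_leaver %||% -0.15,
             returnee = s$status_effect_returnee %||% -0.25)
  args$status_effects <- se
  if (!is.null(s$out_migration_hazard_bands)) {
    hb <- s$out_migration_hazard_bands   # named: rates for <17, 17-29, 30-59, 60+
    stopifnot(length(hb) == 4)
    args$out_migration_hazard <- local({
      hb <- as.numeric(hb)
      function(age, sex) {
        ifelse(age < 17, hb[1], ifelse(age < 30, hb[2],
          ifelse(age < 60, hb[3], hb[4])))
      }
    })
  }
  do.call(sim_config, args)
}

#' Run the full analysis pipeline
#'
#' Simulate -> observe -> classify -> impute censored migration ages ->
#' aggregate exposure -> redistribute ill-defined causes -> fit NB GAMs ->
#' marginal rates and rate ratios -> partial life tables and
#' temporary-expectancy gaps -> (optionally) cause decomposition. Artifacts
#' are written as CSV to `out_dir` together with a JSON manifest carrying the
#' seed and the MD5 hash of the configuration; a run with the same
#' configuration and seed reproduces the numeric artifacts byte for byte.
#'
#' @param config A `pipeline_config` (or something [pipeline_config()]
#'   accepts).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the principal in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_log <- character()
  t_start <- Sys.time()
  log_stage <- function(name) {
    message(sprintf("[%s] %s (%.1fs elapsed)", format(Sys.time(), "%H:%M:%S"),
                    name, as.numeric(Sys.time() - t_start, units = "secs")))
    stage_log <<- c(stage_log, name)
  }
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  cfg_path <- file.path(out_dir, "config.yaml")
  writeLines(cfg_yaml, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  log_stage("simulate")
  sim_cfg <- build_sim_config(cfg)
  hist_full <- simulate_population(sim_cfg)

  log_stage("observe")
  scheme <- switch(cfg$observation$scheme,
                   census_then_annual = default_observed_years(),
                   annual = sim_cfg$years[1]:sim_cfg$years[2],
                   as.integer(cfg$observation$scheme))
  hist_obs <- apply_observation_scheme(hist_full, scheme)

  log_stage("classify")
  cl <- classify_histories(hist_obs)
  n_movers <- sum(cl$status != "stayer")

  imputed <- NULL
  if (n_movers > 0) {
    log_stage("impute")
    recs <- extract_censoring_records(hist_obs, cl)
    models <- list()
    for (ev in unique(recs$event)) {
      models[[ev]] <- fit_event_age_model(
        recs[recs$event == ev, ], event = ev,
        bands = cfg$imputation$bands, min_exact = cfg$imputation$min_exact)
    }
    imputed <- impute_event_ages(recs, models, seed = cfg$seed + 1L)
    data.table::fwrite(imputed, file.path(out_dir, "imputed_ages.csv"))
  } else {
    message("run_pipeline: no movers in the population; mover analyses are empty")
  }
  bands <- assign_status_bands(cl, imputed %||%
                                 data.frame(person_id = integer(),
                                            event = character(),
                                            age = numeric()),
                               leaver_breaks = cfg$bands$leaver_breaks,
                               returnee_breaks = cfg$bands$returnee_breaks)

  log_stage("build-table")
  tab <- build_exposure_table(hist_obs, bands)
  tab <- redistribute_illdefined(tab)
  data.table::fwrite(tab, file.path(out_dir, "exposure_table.csv"))

  results <- list(config_hash = cfg_hash, classification = bands,
                  exposure_table = tab)
  schedules <- list(); ratios <- list(); gaps <- list(); decomp <- list()
  for (sx in cfg$model$sexes) {
    log_stage(paste0("fit-", sx))
    m <- fit_mortality_gam(tab, sex = sx, cause = "total",
                           status_var = cfg$model$status_var,
                           k = cfg$model$k, family = cfg$model$family)
    log_stage(paste0("marginalize-", sx))
    sch <- average_marginal_rates(m, n_draws = cfg$marginal$n_draws,
                                  seed = cfg$seed + 2L)
    sch$sex <- sx
    schedules[[sx]] <- sch
    if (n_movers > 0 && length(unique(sch$status)) > 1) {
      rr <- rate_ratios(sch)
      rr$sex <- sx
      ratios[[sx]] <- rr
      gaps[[sx]] <- expectancy_gaps(sch, from_ages = cfg$lifetable$from_ages)
      gaps[[sx]]$sex <- sx
    }
    # cause-specific fits and decomposition
    if (length(cfg$model$causes) > 0 && n_movers > 0) {
      log_stage(paste0("decompose-", sx))
      decomp[[sx]] <- decompose_by_cause(
        tab, sx, causes = cfg$model$causes,
        status_var = cfg$model$status_var, k = cfg$model$k,
        family = cfg$model$family, n_steps = cfg$decomposition$n_steps,
        seed = cfg$seed + 3L)
    }
  }
  write_stacked <- function(lst, file) {
    if (length(lst)) {
      data.table::fwrite(rbindlist(lapply(lst, as.data.frame)),
                         file.path(out_dir, file))
    }
  }
  write_stacked(schedules, "marginal_rates.csv")
  write_stacked(ratios, "rate_ratios.csv")
  write_stacked(gaps, "expectancy_gaps.csv")
  if (length(decomp)) {
    dd <- rbindlist(lapply(names(decomp), function(sx) {
      rbindlist(lapply(names(decomp[[sx]]$decompositions), function(st) {
        d <- decomp[[sx]]$decompositions[[st]]
        dt <- as.data.table(as.table(d$contributions))
        setnames(dt, c("age_group", "cause", "years"))
        dt[, `:=`(sex = sx, status = st)]
        dt
      }))
    }))
    data.table::fwrite(dd, file.path(out_dir, "decomposition.csv"))
  }

  results$schedules <- schedules
  results$ratios <- ratios
  results$gaps <- gaps
  results$decomposition <- decomp
  log_stage("report")
  manifest <- list(seed = cfg$seed, config_hash = cfg_hash,
                   stages = stage_log,
                   n_individuals = sim_cfg$n_individuals,
                   n_movers = n_movers,
                   notes = if (n_movers == 0)
                     "no movers generated: mover schedules, ratios, gaps and decompositions are empty" else
                     "complete")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Temporary-expectancy gaps between movers and stayers
#'
#' Builds a partial life table per status from a marginal rate schedule and
#' reports, for each requested starting age, the mover-minus-stayer gap in
#' temporary life expectancy to the end of the common span, in years, months,
#' and percent of the stayer's expectancy. Comparisons are computed on the
#' ages both schedules cover (for banded statuses: from the band entry age
#' upward).
#'
#' @param schedules A `marginal_schedules` object.
#' @param from_ages Starting ages (default `c(20, 50, 80)`); ages outside a
#'   status's domain are skipped for that status.
#' @param reference Reference status (default `"stayer"`).
#' @return Data frame `status`, `from_age`, `to_age`, `gap_years`,
#'   `gap_months`, `gap_pct`, `e_ref`, `e_cmp`.
#' @export
expectancy_gaps <- function(schedules, from_ages = c(20, 50, 80),
                            reference = "stayer") {
  stopifnot(inherits(schedules, "marginal_schedules"))
  ref <- schedules[schedules$status == reference, ]
  if (nrow(ref) == 0) stop("reference status absent from schedules")
  out <- list()
  for (st in setdiff(unique(schedules$status), reference)) {
    cmp <- schedules[schedules$status == st, ]
    common <- sort(intersect(ref$age_mid, cmp$age_mid))
    if (length(common) < 2) next
    width <- diff(common)[1]
    age_lo <- common - width / 2
    lt_ref <- build_partial_life_table(age_lo,
                                       ref$rate[match(common, ref$age_mid)],
                                       width = width)
    lt_cmp <- build_partial_life_table(age_lo,
                                       cmp$rate[match(common, cmp$age_mid)],
                                       width = width)
    to_age <- max(age_lo) + width
    for (fa in from_ages) {
      if (!(fa %in% age_lo)) next
      e_ref <- temporary_expectancy(lt_ref, fa, to_age)
      e_cmp <- temporary_expectancy(lt_cmp, fa, to_age)
      out[[length(out) + 1L]] <- data.frame(
        status = st, from_age = fa, to_age = to_age,
        gap_years = e_cmp - e_ref, gap_months = 12 * (e_cmp - e_ref),
        gap_pct = 100 * (e_cmp - e_ref) / e_ref,
        e_ref = e_ref, e_cmp = e_cmp, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cause-specific fits and age-by-cause decomposition for one sex
#'
#' Fits one NB GAM per cause, assembles cause-specific marginal rate
#' matrices per status (ages outside a cause's fitted range contribute a zero
#' rate), and decomposes each mover-vs-stayer temporary-expectancy gap with
#' [decompose_gap()].
#'
#' @param table An `exposure_table` after [redistribute_illdefined()].
#' @param sex Sex to analyse.
#' @param causes Character vector of causes (default all six groups).
#' @param status_var,k,family Passed to [fit_mortality_gam()].
#' @param n_steps Decomposition steps.
#' @param seed Seed for the (point-estimate) marginalization.
#' @param reference Reference status.
#' @return List with `rates` (list status -> age x cause matrix),
#'   `age_lower`, `decompositions` (list status -> `decomposition`), and
#'   `shares` (list status -> [summarize_contributions()] output).
#' @export
decompose_by_cause <- function(table, sex, causes = cause_groups(),
                               status_var = "status_coarse", k = 10,
                               family = "nb", n_steps = 1000, seed = 1,
                               reference = "stayer") {
  meta <- attr(table, "exposure_meta")
  gw <- meta$group_width
  sch <- list()
  for (cc in causes) {
    m <- fit_mortality_gam(table, sex = sex, cause = cc,
                           status_var = status_var, k = k, family = family)
    sch[[cc]] <- average_marginal_rates(m, n_draws = 100, seed = seed)
  }
  statuses <- sort(unique(unlist(lapply(sch, function(s) unique(s$status)))))
  ages <- sort(unique(unlist(lapply(sch, function(s) unique(s$age_mid)))))
  rates <- list()
  for (st in statuses) {
    M <- matrix(0, length(ages), length(causes),
                dimnames = list(ages, causes))
    for (cc in causes) {
      s <- sch[[cc]][sch[[cc]]$status == st, ]
      M[match(s$age_mid, ages), cc] <- s$rate
    }
    rates[[st]] <- M
  }
  age_lower <- ages - gw / 2
  dec <- list(); shares <- list()
  for (st in setdiff(statuses, reference)) {
    # restrict to the ages both groups cover (banded statuses enter later)
    ok <- rowSums(rates[[st]]) > 0 & rowSums(rates[[reference]]) > 0
    if (sum(ok) < 2) next
    d <- decompose_gap(rates[[reference]][ok, , drop = FALSE],
                       rates[[st]][ok, , drop = FALSE],
                       age_lower = age_lower[ok], width = gw,
                       n_steps = n_steps)
    dec[[st]] <- d
    shares[[st]] <- summarize_contributions(d)
  }
  list(rates = rates, age_lower = age_lower, decompositions = dec,
       shares = shares)
}
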