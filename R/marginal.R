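#' Average marginal age-specific rates per migration status
#'
#' For each status and age midpoint, predicts the mortality rate at every
#' (birth region, calendar year) combination in the reference table and
#' averages on the rate scale — the usual average-marginal-effects
#' construction. Uncertainty comes from posterior simulation: coefficient
#' vectors are drawn from a multivariate normal with the model's coefficient
#' covariance, the averaged rate is recomputed per draw, and the 5th/95th
#' percentiles form a 90% band.
#'
#' @param model A converged `mortality_gam`.
#' @param reference_table Data frame with columns `birth_region` and `year`
#'   defining the combinations averaged over (default: all combinations seen
#'   in the fit, equally weighted).
#' @param ages Named list (per status) or vector of age midpoints (default:
#'   each status's fitted midpoints).
#' @param n_draws Number of coefficient draws (default 1000; fewer than 100
#'   warns).
#' @param seed Integer seed for the draws.
#' @param force Evaluate a flagged (non-converged) model.
#' @return Object of class `marginal_schedules`: data frame `status`,
#'   `age_mid`, `rate`, `lower90`, `upper90` with per-draw averaged rates in
#'   attribute `draws` (list of age x draw matrices, one per status).
#' @export
average_marginal_rates <- function(model, reference_table = NULL,
                                   ages = NULL, n_draws = 1000, seed = 1,
                                   force = FALSE) {
  stopifnot(inherits(model, "mortality_gam"))
  if (!model$converged && !force) {
    stop("model is flagged non-converged; pass force = TRUE to override")
  }
  if (n_draws < 100) warning("n_draws < 100: percentile bands will be noisy")
  fit <- model$fit
  if (is.null(reference_table)) {
    md <- fit$model
    # single-level terms are dropped from the formula (and the model frame);
    # their one level still defines the conditioning grid
    rg <- if (!is.null(md$region_f)) as.character(md$region_f) else
      rep(model$regions, nrow(md))
    yr <- if (!is.null(md$year_f)) as.character(md$year_f) else
      rep(model$years, nrow(md))
    reference_table <- unique(data.frame(
      birth_region = rg, year = yr, stringsAsFactors = FALSE))
  }
  K <- nrow(reference_table)
  beta <- coef(fit)
  V <- vcov(fit)
  set.seed(as.integer(seed))
  draws <- MASS::mvrnorm(n_draws, beta, V)

  res <- list(); dr <- list()
  for (st in model$status_levels) {
    age_st <- if (is.null(ages)) {
      md <- fit$model
      sort(unique(md$age_mid[md$status_f == st]))
    } else if (is.list(ages)) ages[[st]] else {
      a <- sort(unique(ages))
      a[a >= model$domains[[st]][1] & a <= model$domains[[st]][2]]
    }
    if (length(age_st) == 0) next
    nd <- data.frame(
      age_mid = rep(age_st, each = K),
      year_f = factor(rep(reference_table$year, length(age_st)),
                      levels = model$years),
      region_f = factor(rep(reference_table$birth_region, length(age_st)),
                        levels = model$regions),
      status_f = factor(st, levels = model$status_levels),
      E = 1)
    if (model$year_term == "smooth") {
      nd$year_n <- as.numeric(as.character(nd$year_f))
    }
    Xp <- predict(fit, newdata = nd, type = "lpmatrix",
                  newdata.guaranteed = TRUE, discrete = FALSE)
    grp <- rep(seq_along(age_st), each = K)
    point <- rowsum(exp(as.numeric(Xp %*% beta)), grp) / K
    # draw-wise averaged rates, chunked to bound memory
    dm <- matrix(NA_real_, length(age_st), n_draws)
    chunk <- 200L
    for (s0 in seq(1, n_draws, by = chunk)) {
      s1 <- min(s0 + chunk - 1L, n_draws)
      eta <- Xp %*% t(draws[s0:s1, , drop = FALSE])
      dm[, s0:s1] <- rowsum(exp(eta), grp) / K
    }
    qs <- t(apply(dm, 1, quantile, probs = c(0.05, 0.95)))
    res[[st]] <- data.frame(status = st, age_mid = age_st,
                            rate = as.numeric(point),
                            lower90 = qs[, 1], upper90 = qs[, 2],
                            stringsAsFactors = FALSE)
    dr[[st]] <- dm
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "draws") <- dr
  attr(out, "model_info") <- list(sex = model$sex, cause = model$cause,
                                  n_draws = n_draws, n_combos = K)
  class(out) <- c("marginal_schedules", class(out))
  out
}

#' Rate ratios relative to a reference status
#'
#' Computes `ratio(x) = rate_reference(x) / rate_m(x)` at the ages common to
#' both schedules (the reference — stayers — in the numerator, so ratios
#' above 1 mean lower mortality for the comparison group). Percentile bounds
#' are computed draw-wise: the ratio is formed for every coefficient draw and
#' the 5th/95th percentiles are reported.
#'
#' @param schedules A `marginal_schedules` object.
#' @param reference Reference status (default `"stayer"`).
#' @return Data frame `status`, `age_mid`, `ratio`, `lower90`, `upper90`,
#'   with draw-wise ratio matrices in attribute `draws`. Ages present in only
#'   one schedule are excluded.
#' @export
rate_ratios <- function(schedules, reference = "stayer") {
  stopifnot(inherits(schedules, "marginal_schedules"))
  dr <- attr(schedules, "draws")
  if (!reference %in% schedules$status) {
    stop(sprintf("reference status '%s' not in schedules", reference))
  }
  ref <- schedules[schedules$status == reference, ]
  res <- list(); rd <- list()
  for (st in setdiff(unique(schedules$status), reference)) {
    cmp <- schedules[schedules$status == st, ]
    common <- intersect(ref$age_mid, cmp$age_mid)
    dropped <- length(setdiff(union(ref$age_mid, cmp$age_mid), common))
    if (dropped > 0) {
      message(sprintf("rate_ratios: %d ages outside the common domain of %s vs %s excluded",
                      dropped, reference, st))
    }
    if (length(common) == 0) next
    i_ref <- match(common, ref$age_mid)
    i_cmp <- match(common, cmp$age_mid)
    ratio <- ref$rate[i_ref] / cmp$rate[i_cmp]
    rmat <- dr[[reference]][i_ref, , drop = FALSE] /
      dr[[st]][i_cmp, , drop = FALSE]
    qs <- t(apply(rmat, 1, quantile, probs = c(0.05, 0.95)))
    res[[st]] <- data.frame(status = st, age_mid = common, ratio = ratio,
                            lower90 = qs[, 1], upper90 = qs[, 2],
                            stringsAsFactors = FALSE)
    rd[[st]] <- rmat
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "draws") <- rd
  attr(out, "reference") <- reference
  class(out) <- c("rate_ratio_schedules", class(out))
  out
}
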