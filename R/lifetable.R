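#' Build a partial (temporary) life table
#'
#' Standard grouped-age life-table columns on a closed age span (default
#' 20-95): `nqx = n * nmx / (1 + (n - nax) * nmx)`, survivorship `lx` from a
#' radix of 100,000, decedents `ndx`, person-years `nLx = n * lx - (n - nax)
#' * ndx`, cumulative `Tx` and the partial expectancy `ex` within the span.
#' The table is closed by truncation at the upper bound (no open-ended
#' group), so `ex` at the first age is the temporary life expectancy over the
#' span. Decedents are assumed to live `nax = n/2` years in their interval of
#' death (adult ages only, so no infant correction is needed).
#'
#' @param age_lower Lower bounds of the age groups (must tile the span).
#' @param nmx Mortality rates (deaths per person-year) per group.
#' @param width Group width(s) in years; scalar or vector (default 3).
#' @param nax Average years lived in the interval by decedents (default
#'   `width / 2`).
#' @param radix Initial survivors (default 100,000).
#' @return Data frame of class `life_table` with columns `age`, `n`, `nmx`,
#'   `nqx`, `nax`, `lx`, `ndx`, `nLx`, `Tx`, `ex`.
#' @export
build_partial_life_table <- function(age_lower, nmx, width = 3, nax = NULL,
                                     radix = 1e5) {
  stopifnot(length(age_lower) == length(nmx), all(nmx >= 0), all(is.finite(nmx)))
  n <- if (length(width) == 1) rep(width, length(nmx)) else width
  stopifnot(length(n) == length(nmx))
  if (length(age_lower) > 1 &&
      any(abs(diff(age_lower) - n[-length(n)]) > 1e-9)) {
    stop("age groups must tile the span: age_lower[i+1] == age_lower[i] + width[i]")
  }
  if (is.null(nax)) nax <- n / 2
  if (length(nax) == 1) nax <- rep(nax, length(nmx))
  qx <- n * nmx / (1 + (n - nax) * nmx)
  if (any(qx > 1)) {
    warning(sprintf("build_partial_life_table: %d death probabilities capped at 1",
                    sum(qx > 1)))
    qx <- pmin(qx, 1)
  }
  lx <- radix * c(1, cumprod(1 - qx))[seq_along(qx)]
  dx <- lx * qx
  Lx <- n * lx - (n - nax) * dx
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  out <- data.frame(age = age_lower, n = n, nmx = nmx, nqx = qx, nax = nax,
                    lx = lx, ndx = dx, nLx = Lx, Tx = Tx, ex = ex)
  class(out) <- c("life_table", class(out))
  out
}

#' Temporary life expectancy between two ages
#'
#' Expected years lived between `from_age` and `to_age` by a survivor to
#' `from_age`: the sum of `nLx` over `[from_age, to_age)` divided by
#' `l(from_age)`.
#'
#' @param lt A `life_table`.
#' @param from_age Lower age (must be a group boundary).
#' @param to_age Upper age (default: end of the table).
#' @return Years (scalar).
#' @export
temporary_expectancy <- function(lt, from_age,
                                 to_age = max(lt$age + lt$n)) {
  if (from_age >= to_age) stop("from_age must be below to_age")
  bounds <- c(lt$age, max(lt$age + lt$n))
  if (!(from_age %in% bounds) || !(to_age %in% bounds)) {
    stop("from_age and to_age must lie on age-group boundaries")
  }
  i <- lt$age >= from_age & lt$age < to_age
  l0 <- lt$lx[match(from_age, lt$age)]
  if (l0 <= 0) return(0)
  sum(lt$nLx[i]) / l0
}

# lean internal evaluator used by the decomposition: temporary expectancy
# from the first group, for an all-cause rate vector on a fixed grid
lt_temp_expectancy <- function(nmx, n, nax) {
  qx <- n * nmx / (1 + (n - nax) * nmx)
  qx[qx > 1] <- 1
  lx <- c(1, cumprod(1 - qx))
  dx <- lx[-length(lx)] * qx
  Lx <- n * lx[-length(lx)] - (n - nax) * dx
  sum(Lx)
}
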