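#' Redistribute ill-defined causes of death
#'
#' Deaths with ill-defined cause are assigned proportionally to the six named
#' cause groups within strata of 5-year calendar period, 5-year age group and
#' sex (each exposure-table row is assigned to the stratum containing its age
#' midpoint). Strata whose named-cause total is zero fall back to the pooled
#' cause distribution of the adjacent age strata (same period and sex), then
#' to the sex-by-period margin, then to the global margin, with a warning.
#' Per-stratum total deaths are conserved; the `D_ill_defined` column is
#' removed.
#'
#' @param table An `exposure_table` with a `D_ill_defined` column.
#' @param period_width Calendar-period stratum width in years (default 5).
#' @param age_width Age stratum width in years (default 5).
#' @return The table with ill-defined deaths reallocated (cause columns may
#'   be non-integer) and `D_ill_defined` dropped.
#' @export
redistribute_illdefined <- function(table, period_width = 5, age_width = 5) {
  if (!"D_ill_defined" %in% names(table)) {
    stop("table has no D_ill_defined column")
  }
  tab <- copy(as.data.table(table))
  meta <- attr(table, "exposure_meta")
  causes <- paste0("D_", cause_groups())
  y_min <- min(tab$year)
  tab[, period5 := y_min + period_width * ((year - y_min) %/% period_width)]
  tab[, age5 := age_width * (floor(age_mid) %/% age_width)]
  tab[, stratum := paste(period5, age5, sex, sep = ".")]

  named <- tab[, lapply(.SD, sum), by = stratum, .SDcols = causes]
  named[, total_named := rowSums(.SD), .SDcols = causes]
  ill <- tab[, .(ill = sum(D_ill_defined)), by = stratum]
  st <- merge(named, ill, by = "stratum")

  # stratum-level target distribution over named causes
  dist <- as.matrix(st[, causes, with = FALSE])
  tn <- st$total_named
  need_fallback <- st$ill > 0 & tn == 0
  if (any(need_fallback)) {
    parts <- do.call(rbind, strsplit(st$stratum, ".", fixed = TRUE))
    per <- parts[, 1]; ag <- as.numeric(parts[, 2]); sx <- parts[, 3]
    for (i in which(need_fallback)) {
      adj <- which(per == per[i] & sx == sx[i] &
                     abs(ag - ag[i]) <= age_width & tn > 0)
      if (length(adj)) {
        dist[i, ] <- colSums(dist[adj, , drop = FALSE])
      } else {
        marg <- which(per == per[i] & sx == sx[i] & tn > 0)
        if (length(marg)) {
          dist[i, ] <- colSums(dist[marg, , drop = FALSE])
        } else {
          dist[i, ] <- colSums(dist[tn > 0, , drop = FALSE])
        }
      }
    }
    warning(sprintf("redistribute_illdefined: %d strata with ill-defined but no named-cause deaths; used adjacent/marginal distributions",
                    sum(need_fallback)))
  }
  # scale factor per stratum and cause: reallocated = D_c * (1 + ill/total)
  # expressed through the (possibly fallback) distribution
  prop <- dist / pmax(rowSums(dist), 1e-300)
  add <- prop * st$ill                       # extra deaths per stratum x cause
  # spread the stratum-level extra over the stratum's rows proportionally to
  # each row's share of the stratum's named-cause deaths; rows in fallback
  # strata (no named deaths anywhere) get the extra spread by row ill share
  for (ci in seq_along(causes)) {
    cc <- causes[ci]
    row_named <- tab[[cc]]
    st_named_row <- st[[cc]][match(tab$stratum, st$stratum)]
    share <- ifelse(st_named_row > 0, row_named / st_named_row, NA_real_)
    # fallback strata: spread by the row's share of stratum ill-defined deaths
    st_ill_row <- st$ill[match(tab$stratum, st$stratum)]
    share_fb <- ifelse(st_ill_row > 0, tab$D_ill_defined / st_ill_row, 0)
    share[is.na(share)] <- share_fb[is.na(share)]
    tab[, (cc) := row_named + add[match(tab$stratum, st$stratum), ci] * share]
  }
  tab[, D_ill_defined := NULL]
  tab[, c("period5", "age5", "stratum") := NULL]
  # per row, D_total is again the sum over (now non-integer) cause columns;
  # per stratum the grand total of deaths is conserved
  tab[, D_total := rowSums(.SD), .SDcols = causes]
  setattr(tab, "exposure_meta", meta)
  setattr(tab, "class", c("exposure_table", class(data.table())))
  tab[]
}
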