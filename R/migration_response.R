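## Daily binary group-migration response built from per-animal migration
## intervals, and herd-year / cross-herd summary statistics.

#' Per-day counts of animals simultaneously in migration
#'
#' An animal counts as migrating on day `i` when
#' `start_day <= i <= end_day` (both ends inclusive).
#'
#' @param records [migration_records()] for a single herd-year.
#' @return integer vector of counts over days 1..366.
#' @export
simultaneous_counts <- function(records) {
  if (!nrow(records)) gw_domain_error("no migration records supplied")
  if (length(unique(records$herd)) != 1 || length(unique(records$year)) != 1) {
    gw_domain_error("records must share one herd and one year")
  }
  counts <- integer(366)
  for (i in seq_len(nrow(records))) {
    span <- records$start_day[i]:records$end_day[i]
    counts[span] <- counts[span] + 1L
  }
  counts
}

#' Group (herd) migration initiation day
#'
#' The first day the maximum observed number of collared animals are
#' simultaneously in migration: with `m = max(counts)`, the first day with
#' `counts >= m`.
#'
#' @param counts per-day counts from [simultaneous_counts()].
#' @return Julian day (integer).
#' @export
group_initiation_day <- function(counts) {
  if (!length(counts) || all(counts == 0)) gw_domain_error("no nonzero counts")
  m <- max(counts)
  as.integer(which(counts >= m)[1])
}

#' Daily binary migration response
#'
#' Days before initiation are 0; days from initiation through the horizon are
#' 1. The default horizon is Julian day 150 (end of May in common years),
#' chosen to cover the latest observed phenology and migration days.
#' Initiation beyond the horizon yields an all-zero response with a warning.
#'
#' @param initiation_day group initiation day, `>= 1`.
#' @param horizon last modeled day (inclusive); default 150.
#' @return integer 0/1 vector over days `1..horizon`.
#' @export
binary_response <- function(initiation_day, horizon = 150) {
  if (is.na(initiation_day) || initiation_day < 1) {
    gw_domain_error("initiation_day must be >= 1")
  }
  if (initiation_day > horizon) {
    warning(sprintf("initiation day %d beyond horizon %d: all-zero response",
                    initiation_day, horizon))
    return(integer(horizon))
  }
  as.integer(seq_len(horizon) >= initiation_day)
}

#' Long-format daily responses for every herd-year
#'
#' @param records [migration_records()] spanning any herds/years.
#' @param horizon passed to [binary_response()].
#' @return data frame: `herd`, `year`, `day`, `response`.
#' @export
build_responses <- function(records, horizon = 150) {
  groups <- split(records, list(records$herd, records$year), drop = TRUE)
  rows <- lapply(groups, function(g) {
    init <- group_initiation_day(simultaneous_counts(g))
    data.frame(herd = g$herd[1], year = g$year[1], day = seq_len(horizon),
               response = binary_response(init, horizon))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$herd, out$year, out$day), ]
}

#' Herd-year summary statistics
#'
#' Per herd-year: number of animals, earliest individual start day, group
#' initiation day, maximum simultaneous count, and median displacement.
#'
#' @inheritParams build_responses
#' @return data frame, one row per herd-year.
#' @export
herd_year_stats <- function(records) {
  groups <- split(records, list(records$herd, records$year), drop = TRUE)
  rows <- lapply(groups, function(g) {
    counts <- simultaneous_counts(g)
    data.frame(herd = g$herd[1], year = g$year[1], n = nrow(g),
               indiv_start_day = min(g$start_day),
               herd_start_day = group_initiation_day(counts),
               max_simultaneous = max(counts),
               median_displacement_km = stats::median(g$displacement_km))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$herd, out$year), ]
}

#' Cross-herd migration summaries
#'
#' Works on any herd-year table carrying `herd`, `year`, `herd_start_day`,
#' `indiv_start_day`, `median_displacement_km` -- either [herd_year_stats()]
#' output or the packaged summary table [atlantic_rim_herd_years()]. Computes:
#' the median over years of the per-year NAR minus SAR difference in group
#' initiation day; the difference of across-year median displacements
#' (SAR minus NAR); the latest group initiation day; and the earliest
#' individual start day per herd. Cross-herd fields are `NA` when only one
#' herd is present.
#'
#' @param herd_years herd-year summary data frame.
#' @return list: `initiation_diff_median_days`, `displacement_diff_km`,
#'   `latest_group_initiation_day`, `earliest_individual_day` (named by herd).
#' @export
cross_herd_stats <- function(herd_years) {
  stopifnot(nrow(herd_years) >= 1)
  earliest <- tapply(herd_years$indiv_start_day, herd_years$herd, min)
  out <- list(
    initiation_diff_median_days = NA_real_,
    displacement_diff_km = NA_real_,
    latest_group_initiation_day = max(herd_years$herd_start_day),
    earliest_individual_day = earliest
  )
  nar <- herd_years[herd_years$herd == "NAR", ]
  sar <- herd_years[herd_years$herd == "SAR", ]
  if (nrow(nar) && nrow(sar)) {
    paired <- merge(nar[, c("year", "herd_start_day")],
                    sar[, c("year", "herd_start_day")],
                    by = "year", suffixes = c("_nar", "_sar"))
    if (nrow(paired)) {
      out$initiation_diff_median_days <-
        stats::median(paired$herd_start_day_nar - paired$herd_start_day_sar)
    }
    out$displacement_diff_km <-
      stats::median(sar$median_displacement_km) -
      stats::median(nar$median_displacement_km)
  }
  out
}

#' Herd summaries from raw records
#'
#' Convenience wrapper: [herd_year_stats()] plus [cross_herd_stats()].
#'
#' @inheritParams build_responses
#' @return list with `per_herd_year` (data frame) and `cross_herd` (list).
#' @export
herd_summaries <- function(records) {
  per <- herd_year_stats(records)
  list(per_herd_year = per, cross_herd = cross_herd_stats(per))
}
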