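#' Read a daily-values file
#'
#' Reads either a plain two-column CSV (`date,value`) or a USGS NWIS
#' daily-values RDB export (tab-delimited, `#` comment block, a column-name
#' row, then a column-format row such as `5s 15s 20d 14n 10s`). For the RDB
#' dialect the value column is the first numeric (`n`-format) column that is
#' not a qualifier (`*_cd`) column; qualifier codes appended to a value cell
#' are stripped by splitting on whitespace. Non-numeric value codes (e.g.
#' `Ice`, `Eqp`, empty cells) become explicit gaps. Provisional-flagged values
#' are treated as valid.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"usgs_rdb"`.
#' @param id station id; defaults to the RDB `site_no` when present.
#' @inheritParams daily_series
#' @return a [daily_series()].
#' @export
read_daily_values <- function(path, dialect = c("csv", "usgs_rdb"),
                              id = NULL,
                              variable = c("discharge", "temperature"),
                              units = NULL) {
  dialect <- match.arg(dialect)
  variable <- match.arg(variable)
  if (!file.exists(path)) gw_format_error(sprintf("file not found: %s", path))
  if (dialect == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) gw_format_error("CSV needs columns 'date' and 'value'")
    if (all(c("date", "value") %in% names(tab))) {
      raw_dates <- tab$date
      vals <- tab$value
    } else {
      raw_dates <- tab[[1]]
      vals <- tab[[2]]
    }
    dates <- parse_dates_or_die(raw_dates, path, offset = 1L)
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
    return(daily_series(dates, suppressWarnings(as.numeric(vals)),
                        id = id, variable = variable, units = units))
  }
  read_usgs_rdb(path, id = id, variable = variable, units = units)
}

parse_dates_or_die <- function(raw, path, offset = 0L) {
  raw <- as.character(raw)
  dates <- as.Date(raw, format = "%Y-%m-%d")
  ## reject impossible calendar dates that as.Date would not roll over but
  ## strptime variants might silently accept
  bad <- is.na(dates) | format(dates, "%Y-%m-%d") != sprintf("%04d-%02d-%02d",
    as.integer(substr(raw, 1, 4)), suppressWarnings(as.integer(substr(raw, 6, 7))),
    suppressWarnings(as.integer(substr(raw, 9, 10))))
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    gw_format_error(sprintf("%s: unparseable date '%s' at data line %d",
                            path, raw[which(bad)[1]], which(bad)[1] + offset))
  }
  dates
}

read_usgs_rdb <- function(path, id = NULL, variable = "discharge", units = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) gw_format_error(sprintf("%s: no RDB header rows", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  formats <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  date_col <- match("datetime", header)
  if (is.na(date_col)) gw_format_error(sprintf("%s: no 'datetime' column", path))
  numeric_cols <- grepl("n$", formats) & !grepl("_cd$", header)
  value_col <- which(numeric_cols)[1]
  if (is.na(value_col)) gw_format_error(sprintf("%s: no numeric value column", path))
  cells <- strsplit(body, "\t", fixed = TRUE)
  get <- function(row, j) if (length(row) >= j) row[[j]] else ""
  raw_dates <- vapply(cells, get, "", date_col)
  dates <- parse_dates_or_die(raw_dates, path, offset = 2L)
  raw_vals <- vapply(cells, get, "", value_col)
  ## qualifier codes may be appended to the value ("12.3 A"); keep first token
  first_tok <- vapply(strsplit(trimws(raw_vals), "\\s+"), function(t)
    if (length(t)) t[[1]] else "", "")
  vals <- suppressWarnings(as.numeric(first_tok))
  if (is.null(id)) {
    site_col <- match("site_no", header)
    id <- if (!is.na(site_col) && length(cells)) get(cells[[1]], site_col) else basename(path)
  }
  if (is.null(units) && variable == "discharge") units <- "ft3/s"
  daily_series(dates, vals, id = id, variable = variable, units = units)
}

#' Write a daily series as CSV
#'
#' Writes `date,value` rows; gaps become empty cells. A write/read round trip
#' through [read_daily_values()] reproduces dates and values exactly.
#'
#' @param x a [daily_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_daily_values <- function(x, path) {
  utils::write.csv(
    data.frame(date = format(x$date, "%Y-%m-%d"), value = x$value),
    path, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' Read a per-animal migration table
#'
#' Expects CSV columns `herd` (NAR/SAR), `year`, `animal_id`, `start_date`,
#' `end_date` (ISO dates), `displacement_km`. Dates are converted to
#' leap-year-aware Julian days.
#'
#' @param path file path.
#' @return a `migration_records` data frame with columns `animal_id`, `herd`,
#'   `year`, `start_day`, `end_day`, `displacement_km`.
#' @export
read_migration_table <- function(path) {
  if (!file.exists(path)) gw_format_error(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("herd", "year", "animal_id", "start_date", "end_date", "displacement_km")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    gw_format_error(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  migration_records(
    animal_id = as.character(tab$animal_id),
    herd = tab$herd,
    year = as.integer(tab$year),
    start_day = julian_day(parse_dates_or_die(tab$start_date, path, offset = 1L)),
    end_day = julian_day(parse_dates_or_die(tab$end_date, path, offset = 1L)),
    displacement_km = as.numeric(tab$displacement_km)
  )
}

#' Construct migration records
#'
#' @param animal_id character ids.
#' @param herd `"NAR"` or `"SAR"` per record.
#' @param year integer calendar year.
#' @param start_day,end_day Julian days, `1 <= start_day <= end_day <= 366`.
#' @param displacement_km nonnegative straight-line displacement.
#' @return a `migration_records` data frame.
#' @export
migration_records <- function(animal_id, herd, year, start_day, end_day,
                              displacement_km) {
  herd <- as.character(herd)
  if (!all(herd %in% c("NAR", "SAR"))) {
    gw_integrity_error("herd must be 'NAR' or 'SAR'")
  }
  start_day <- as.integer(start_day)
  end_day <- as.integer(end_day)
  if (any(start_day < 1L | end_day > 366L)) {
    gw_integrity_error("migration days must lie in 1..366")
  }
  if (any(end_day < start_day)) {
    i <- which(end_day < start_day)[1]
    gw_integrity_error(sprintf("record %s: end day %d before start day %d",
                               animal_id[i], end_day[i], start_day[i]))
  }
  if (any(displacement_km < 0)) gw_integrity_error("displacement_km must be >= 0")
  structure(
    data.frame(animal_id = as.character(animal_id), herd = herd,
               year = as.integer(year), start_day = start_day,
               end_day = end_day, displacement_km = as.numeric(displacement_km)),
    class = c("migration_records", "data.frame")
  )
}

#' Packaged Atlantic Rim herd-year migration summaries
#'
#' Herd-year summaries for the northern (NAR) and southern (SAR) Atlantic Rim
#' mule deer herds over the nine tracked years (2005-2006, 2008-2010,
#' 2015-2018): number of collared females, earliest individual migration start
#' date, group (herd) migration start date, maximum number migrating
#' simultaneously, and median displacement distance.
#'
#' @return data frame with columns `herd`, `year`, `n`, `indiv_start_date`,
#'   `herd_start_date`, `max_simultaneous`, `median_displacement_km`, plus
#'   derived Julian-day columns `indiv_start_day` and `herd_start_day`.
#' @export
atlantic_rim_herd_years <- function() {
  path <- system.file("extdata", "atlantic_rim_herd_years.csv",
                      package = "greenwave", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$indiv_start_date <- as.Date(tab$indiv_start_date)
  tab$herd_start_date <- as.Date(tab$herd_start_date)
  tab$indiv_start_day <- julian_day(tab$indiv_start_date)
  tab$herd_start_day <- julian_day(tab$herd_start_date)
  tab
}
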