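survey_columns <- c("site", "patch", "length_mm", "mass_g", "band_age_years")

#' Read a coral survey CSV
#'
#' Reads individual-polyp survey records (one row per collected polyp) with
#' the schema `site, patch, length_mm, mass_g, band_age_years`.  A blank
#' `band_age_years` means the skeleton was not band-dated.  Malformed rows
#' (non-numeric or non-positive length, negative mass, band age below 1 —
#' a banded skeleton is at least one year old) are collected into a reject
#' report with their line numbers, never silently dropped.
#'
#' @param path path to the CSV file.
#' @return Data frame of valid records with a `"rejects"` attribute: a data
#'   frame with columns `line` (1-based file line, header = line 1) and
#'   `reason`.
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, na.strings = c("", "NA"))
  missing <- setdiff(survey_columns, names(raw))
  if (length(missing) > 0L)
    stop_schema(paste("missing mandatory column(s):",
                      paste(missing, collapse = ", ")))
  raw <- raw[, survey_columns, drop = FALSE]
  len <- suppressWarnings(as.numeric(raw$length_mm))
  mass <- suppressWarnings(as.numeric(raw$mass_g))
  band <- suppressWarnings(as.numeric(raw$band_age_years))

  reason <- rep(NA_character_, nrow(raw))
  bad_len <- is.na(len) | len <= 0
  reason[bad_len] <- "length_mm missing, non-numeric or <= 0"
  bad_mass <- !is.na(raw$mass_g) & (is.na(mass) | mass < 0)
  reason[is.na(reason) & bad_mass] <- "mass_g non-numeric or negative"
  bad_band <- !is.na(raw$band_age_years) &
    (is.na(band) | band < 1 | band != round(band))
  reason[is.na(reason) & bad_band] <-
    "band_age_years must be a positive integer (>= 1)"
  bad_site <- is.na(raw$site)
  reason[is.na(reason) & bad_site] <- "site missing"

  keep <- is.na(reason)
  records <- data.frame(
    site = raw$site[keep],
    patch = raw$patch[keep],
    length_mm = len[keep],
    mass_g = mass[keep],
    band_age_years = as.integer(band[keep])
  )
  rejects <- data.frame(line = which(!keep) + 1L, reason = reason[!keep])
  attr(records, "rejects") <- rejects
  records
}

#' Write a coral survey CSV
#'
#' Writes records in the schema read back by [read_survey_csv()].  Hidden
#' simulator columns (such as `true_age`) are not written.
#'
#' @param records survey data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(records, path) {
  out <- records[, survey_columns, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a temperature-series CSV
#'
#' Schema: `timestamp` (ISO-8601 date or datetime), `temp_c`, `series`
#' (`surface` or `depth`).  Timestamps must parse and be strictly
#' increasing within each series; temperatures must be plausible seawater
#' values (-5 to 45 degrees C).
#'
#' @param path path to the CSV file.
#' @return Data frame with columns `timestamp` (Date), `temp_c`, `series`.
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, strip.white = TRUE)
  need <- c("timestamp", "temp_c", "series")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L)
    stop_schema(paste("missing mandatory column(s):",
                      paste(missing, collapse = ", ")))
  ts <- as.Date(as.character(raw$timestamp))
  if (any(is.na(ts))) stop_schema("unparseable (non ISO-8601) timestamps")
  temp <- as.numeric(raw$temp_c)
  if (any(!is.finite(temp)) || any(temp <= -5) || any(temp >= 45))
    stop_schema("temperatures must be finite and within (-5, 45) C")
  out <- data.frame(timestamp = ts, temp_c = temp,
                    series = as.character(raw$series))
  for (s in split(out, out$series))
    if (is.unsorted(s$timestamp, strictly = TRUE))
      stop_schema("timestamps must be strictly increasing within a series")
  out
}

#' Write a temperature-series CSV
#'
#' @param series a single temperature data frame or a list of them (e.g.
#'   the `surface`/`depth` pair from [simulate_temperature_series()]); all
#'   are stacked into one file readable by [read_temperature_csv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_temperature_csv <- function(series, path) {
  if (is.data.frame(series)) series <- list(series)
  out <- do.call(rbind, lapply(series, function(s)
    data.frame(timestamp = format(as.Date(s$timestamp)),
               temp_c = s$temp_c, series = s$series)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Mean annual SST of a temperature series
#'
#' Hourly (or denser) measurements are first averaged to daily means to
#' temper serial correlation; the annual mean is the grand mean of the
#' daily means and its SE is computed over days.  Requires at least 300
#' days of coverage in the selected range so the seasonal cycle cannot
#' bias the mean.
#'
#' @param series temperature data frame (`timestamp`, `temp_c`).
#' @param years optional integer vector restricting to calendar years.
#' @return List with `mean_c`, `se_c` and `n_days`.
#' @export
annual_sst_mean <- function(series, years = NULL) {
  daily <- daily_means(series)
  if (!is.null(years))
    daily <- daily[as.integer(format(daily$date, "%Y")) %in% years, , drop = FALSE]
  if (nrow(daily) < 300L)
    stop_coverage(sprintf("only %d days of coverage; need >= 300", nrow(daily)))
  list(mean_c = mean(daily$temp_c),
       se_c = stats::sd(daily$temp_c) / sqrt(nrow(daily)),
       n_days = nrow(daily))
}
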