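#' Construct a daily temperature series
#'
#' A daily series is a tibble with one row per calendar day and columns
#' `date` (class `Date`), `value` (temperature, degrees Celsius, `NA` when
#' missing), `provenance` (character: a source label, `"interpolated"`,
#' `"predicted"`, or `"missing"`), and `variable` (`"air"` or `"water"`).
#' All package functions that consume temperature records take this shape.
#'
#' @param date Vector coercible to `Date`.
#' @param value Numeric temperatures in degrees Celsius; `NA` where missing.
#' @param provenance Character source tag per day. Defaults to `source_name`
#'   where `value` is present and `"missing"` elsewhere.
#' @param variable `"air"` or `"water"` (recycled).
#' @param source_name Label used for observed days when `provenance` is not
#'   supplied.
#'
#' @return A tibble of class `daily_series`, sorted by date.
#' @examples
#' d <- daily_series(as.Date("2000-01-01") + 0:5, c(4, NA, 5, 5.5, NA, 6),
#'                   variable = "water", source_name = "pier")
#' interpolate_gaps(d)
#' @export
daily_series <- function(date, value, provenance = NULL, variable, source_name = "observed") {
  date <- as.Date(date)
  value <- as.numeric(value)
  if (is.null(provenance)) {
    provenance <- ifelse(is.na(value), "missing", source_name)
  }
  out <- tibble::tibble(
    date = date,
    value = value,
    provenance = as.character(provenance),
    variable = rep_len(as.character(variable), length(date))
  )
  out <- dplyr::arrange(out, .data$date)
  validate_daily_series(out)
}

#' Validate the daily-series contract
#'
#' Checks column presence and types, a single `variable` value, no duplicate
#' dates, and that missing values carry the `"missing"` provenance tag.
#'
#' @param data A data frame to check.
#' @return `data` as a `daily_series` tibble, invisibly usable in pipes.
#' @export
validate_daily_series <- function(data) {
  req <- c("date", "value", "provenance", "variable")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("daily series lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!inherits(data$date, "Date")) abort("`date` must be a Date vector")
  if (anyDuplicated(data$date) > 0) abort("duplicate dates in daily series")
  v <- unique(data$variable)
  if (length(v) != 1 || !v %in% c("air", "water")) {
    abort("`variable` must be a single value, \"air\" or \"water\"")
  }
  if (any(is.na(data$value) & data$provenance != "missing")) {
    abort("missing values must carry provenance \"missing\"")
  }
  out <- tibble::as_tibble(data)
  class(out) <- unique(c("daily_series", class(out)))
  out
}

#' Complete the calendar of a daily series
#'
#' Expands the record to every calendar day between its first and last date;
#' inserted days get `NA` value and `"missing"` provenance. After completion
#' dates are strictly increasing with a one-day step.
#'
#' @param data A `daily_series`.
#' @return A `daily_series` covering a contiguous daily calendar.
#' @export
complete_calendar <- function(data) {
  data <- validate_daily_series(data)
  if (nrow(data) == 0) return(data)
  grid <- tibble::tibble(date = seq(min(data$date), max(data$date), by = "day"))
  out <- dplyr::left_join(grid, data, by = "date")
  out$provenance[is.na(out$value) & is.na(out$provenance)] <- "missing"
  out$provenance[is.na(out$provenance)] <- "missing"
  out$variable <- data$variable[[1]]
  validate_daily_series(out)
}

#' Merge temperature sources in priority order
#'
#' Combines a primary record with ordered fallback records: each day takes
#' the primary value when present, otherwise the first fallback that has a
#' value. The winning series' own provenance tag is recorded; days with no
#' value anywhere stay `"missing"`. This reproduces the construction of a
#' "combined" column from co-located stations (pier record first, then
#' nearby buoy and monitoring-program stations).
#'
#' @param primary A `daily_series`.
#' @param fallbacks A list of `daily_series`, highest priority first.
#' @return A merged `daily_series` on the union of all calendars, completed.
#' @examples
#' a <- daily_series(as.Date("2000-01-01") + 0:2, c(5, NA, 6), variable = "air",
#'                   source_name = "pier")
#' b <- daily_series(as.Date("2000-01-01") + 0:2, c(4, 4.5, NA), variable = "air",
#'                   source_name = "buoy")
#' merge_sources(a, list(b))
#' @export
merge_sources <- function(primary, fallbacks = list()) {
  primary <- validate_daily_series(primary)
  if (inherits(fallbacks, "data.frame")) fallbacks <- list(fallbacks)
  fallbacks <- lapply(fallbacks, validate_daily_series)
  all_series <- c(list(primary), fallbacks)
  vars <- unique(vapply(all_series, function(s) s$variable[[1]], character(1)))
  if (length(vars) != 1) abort("cannot merge sources with mixed variable types")

  dates <- sort(unique(as.Date(unlist(lapply(all_series, function(s) s$date)),
                               origin = "1970-01-01")))
  value <- rep(NA_real_, length(dates))
  provenance <- rep("missing", length(dates))
  # fill lowest priority first so higher priority overwrites
  for (s in rev(all_series)) {
    obs <- s[!is.na(s$value), ]
    idx <- match(obs$date, dates)
    value[idx] <- obs$value
    provenance[idx] <- obs$provenance
  }
  out <- tibble::tibble(date = dates, value = value, provenance = provenance,
                        variable = vars)
  complete_calendar(validate_daily_series(out))
}

# maximal runs of interior missing days; returns tibble(start_idx, length)
missing_runs <- function(is_missing) {
  r <- rle(is_missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = starts[keep], length = r$lengths[keep])
}

#' Fill interior gaps by linear interpolation
#'
#' Each interior run of missing days is replaced by the straight line
#' between its flanking observed values, evaluated at integer day offsets;
#' filled days are tagged `"interpolated"`. Leading and trailing missing
#' runs are trimmed, never extrapolated. Water temperature changes slowly
#' day to day (high specific heat), which is what justifies linear filling
#' of short gaps in these records.
#'
#' @param data A `daily_series`.
#' @param max_gap Longest run (days) that will be filled; longer runs are
#'   left missing and reported in a message. Default `Inf` fills everything.
#' @return A gap-filled `daily_series` with a contiguous calendar.
#' @export
interpolate_gaps <- function(data, max_gap = Inf) {
  data <- complete_calendar(data)
  obs <- which(!is.na(data$value))
  if (length(obs) < 2) abort("need at least two observed values to interpolate")
  data <- data[seq(min(obs), max(obs)), ] # trim leading/trailing missing
  miss <- is.na(data$value)
  if (!any(miss)) return(validate_daily_series(data))

  t <- as.numeric(data$date)
  filled <- approx(t[!miss], data$value[!miss], xout = t, method = "linear")$y
  runs <- missing_runs(miss)
  too_long <- runs[runs$length > max_gap, ]
  fill_idx <- which(miss)
  if (nrow(too_long) > 0) {
    skip <- unlist(purrr::map2(too_long$start, too_long$length, ~ .x + seq_len(.y) - 1))
    fill_idx <- setdiff(fill_idx, skip)
    inform(paste0(nrow(too_long), " gap(s) longer than max_gap = ", max_gap,
                  " left unfilled"))
  }
  data$value[fill_idx] <- filled[fill_idx]
  data$provenance[fill_idx] <- "interpolated"
  validate_daily_series(data)
}

#' Summarise gaps in a raw daily series
#'
#' Describes the maximal runs of consecutive interior missing days of an
#' uninterpolated record: their count, mean and maximum length, and the
#' fraction of the series they cover. Run on the raw record, before
#' [interpolate_gaps()].
#'
#' @param data A `daily_series`.
#' @return A one-row tibble: `n_gaps`, `mean_gap_length`, `max_gap_length`,
#'   `filled_fraction` (missing interior days / total series days).
#' @export
gap_statistics <- function(data) {
  data <- complete_calendar(data)
  obs <- which(!is.na(data$value))
  if (length(obs) > 0) data <- data[seq(min(obs), max(obs)), ]
  runs <- missing_runs(is.na(data$value))
  tibble::tibble(
    n_gaps = nrow(runs),
    mean_gap_length = if (nrow(runs) > 0) mean(runs$length) else 0,
    max_gap_length = if (nrow(runs) > 0) max(runs$length) else 0,
    filled_fraction = if (nrow(data) > 0) sum(runs$length) / nrow(data) else 0
  )
}

#' Temporal decorrelation scale of a daily series
#'
#' The smallest positive lag at which the sample autocorrelation of the
#' daily series first drops below 1/e. On a record dominated by the annual
#' cycle this measures the persistence of the seasonal signal; with
#' `detrend = TRUE` the fitted trend-plus-harmonic model is removed first
#' and the scale describes the residual (weather-band) persistence.
#'
#' @param data A complete (gap-filled) `daily_series` spanning at least two
#'   years.
#' @param detrend Remove the fitted harmonic model (see [fit_harmonic()])
#'   before computing the autocorrelation? Default `FALSE`.
#' @param M Harmonic count used when `detrend = TRUE`.
#' @param threshold Autocorrelation level defining decorrelation; default
#'   `exp(-1)` (the e-folding criterion).
#' @return The decorrelation scale in days (integer lag).
#' @export
decorrelation_scale <- function(data, detrend = FALSE, M = 1, threshold = exp(-1)) {
  data <- validate_daily_series(data)
  if (any(is.na(data$value))) abort("series must be gap-filled (no missing values)")
  if (nrow(data) < 731) abort("series must span at least two years of daily data")
  if (any(diff(as.numeric(data$date)) != 1)) abort("series calendar must be contiguous")
  x <- data$value
  if (detrend) {
    fit <- fit_harmonic(data, M = M, time_origin = min(data$date))
    x <- x - predict_harmonic(fit, data$date)
  }
  lag_max <- min(nrow(data) - 1, 2000L)
  rho <- acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1]
  below <- which(rho < threshold)
  if (length(below) == 0) {
    abort("autocorrelation never falls below the threshold within the usable lag range")
  }
  as.integer(below[[1]])
}

#' Read a multi-source temperature table
#'
#' Reads a delimited file (or data frame) laid out as one row per day with a
#' date column and one temperature column per source, and returns one
#' `daily_series` per source, ready for [merge_sources()].
#'
#' @param x Path to a CSV file, or a data frame.
#' @param source_cols Named character vector mapping source labels to column
#'   names, in merge priority order (first = primary).
#' @param variable `"air"` or `"water"`.
#' @param date_col Name of the date column (ISO 8601). Default `"date"`.
#' @return A named list of `daily_series`, in `source_cols` order.
#' @export
read_temperature_table <- function(x, source_cols, variable, date_col = "date") {
  df <- if (is.character(x)) readr::read_csv(x, show_col_types = FALSE) else tibble::as_tibble(x)
  if (!date_col %in% names(df)) abort(paste0("no date column `", date_col, "`"))
  missing_src <- setdiff(unname(source_cols), names(df))
  if (length(missing_src) > 0) {
    abort(paste0("source column(s) not found: ", paste(missing_src, collapse = ", ")))
  }
  labels <- names(source_cols) %||% unname(source_cols)
  if (is.null(names(source_cols))) names(source_cols) <- labels
  purrr::imap(as.list(source_cols), function(col, label) {
    daily_series(df[[date_col]], df[[col]], variable = variable, source_name = label)
  })
}

#' Write a completed daily series to CSV
#'
#' @param data A `daily_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(data, path) {
  readr::write_csv(validate_daily_series(data), path)
  invisible(path)
}
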