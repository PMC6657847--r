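#' Winter-year label for a date
#'
#' A winter spans two calendar years, so winters are labelled by the year
#' in which they begin: dates from July 1 of year `y` through June 30 of
#' year `y + 1` map to winter year `y` (the winter of 1990-1991 is winter
#' 1990). Anchoring the window at July 1 keeps each winter contiguous.
#'
#' @param date A `Date` vector.
#' @return Integer winter-year labels.
#' @examples
#' assign_winter_year(as.Date(c("1990-12-31", "1991-01-01", "1991-06-30")))
#' @export
assign_winter_year <- function(date) {
  date <- as.Date(date)
  y <- lubridate::year(date)
  as.integer(ifelse(lubridate::month(date) >= 7, y, y - 1))
}

winter_window_days <- function(winter_year) {
  # Jul 1 (y) .. Jun 30 (y+1); contains Feb 29 when y+1 is a leap year
  365L + lubridate::leap_year(winter_year + 1L)
}

#' Per-winter overwintering duration and severity
#'
#' Converts a complete daily water-temperature series into one record per
#' winter year: the number of days with temperature strictly below the
#' critical threshold (the overwintering period length for blue crab, 9
#' degrees Celsius by default) and the winter severity, defined as the mean
#' temperature over those below-threshold days. Only winters whose full
#' July-June window is covered by the series are emitted; partially covered
#' winters at the series edges are dropped with a message. A winter
#' containing February 29 has one more day available to fall below the
#' threshold, so cold leap-year winters can be a day longer than identical
#' non-leap patterns.
#'
#' @param data A complete (gap-free) water `daily_series`.
#' @param threshold Critical temperature, degrees Celsius; default 9.
#' @param exclusions Integer winter years to flag as excluded (e.g. winters
#'   with unusable observational coverage); they are still computed.
#' @param severity `"below"` (default) averages only the below-threshold
#'   days; `"window"` averages the whole July-June window.
#' @return A tibble of class `winter_records` with columns `winter_year`,
#'   `length_days`, `severity` (`NA` when no day is below threshold),
#'   `excluded`; the threshold is kept as an attribute.
#' @export
winter_metrics <- function(data, threshold = 9, exclusions = integer(),
                           severity = c("below", "window")) {
  data <- validate_daily_series(data)
  severity <- match.arg(severity)
  if (any(is.na(data$value))) abort("winter metrics need a complete (gap-filled) series")
  data <- dplyr::mutate(data, winter_year = assign_winter_year(.data$date))
  per <- data |>
    dplyr::group_by(.data$winter_year) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      length_days = sum(.data$value < threshold),
      severity_below = ifelse(.data$length_days > 0,
                              mean(.data$value[.data$value < threshold]), NA_real_),
      severity_window = mean(.data$value),
      .groups = "drop"
    )
  full <- per$n_days == winter_window_days(per$winter_year)
  if (any(!full)) {
    inform(paste0("omitting ", sum(!full),
                  " partially covered winter(s) at the series edges"))
  }
  per <- per[full, ]
  out <- tibble::tibble(
    winter_year = per$winter_year,
    length_days = as.integer(per$length_days),
    severity = if (severity == "below") per$severity_below else per$severity_window,
    excluded = per$winter_year %in% exclusions
  )
  attr(out, "threshold") <- threshold
  class(out) <- unique(c("winter_records", class(out)))
  out
}

#' Overwinter survival model parameters
#'
#' Bundles the coefficients of the Weibull accelerated-failure-time
#' overwinter survival model: linear predictor
#' \eqn{lp = \beta_0 + \beta_T Temp + \beta_S Sal + \beta_Z Size}, survival
#' \eqn{S(t) = \exp(-(t/\eta)^\lambda)} with time scale
#' \eqn{\eta = \exp(lp)}. The default slope coefficients (3.59, 0.10 per
#' degree Celsius, 0.02 per salinity unit, 0.03 per mm carapace width) come
#' from a field-calibrated juvenile blue crab model; the shape `lambda` and
#' the ambient salinity have no in-package default and must be supplied.
#'
#' @param lambda Weibull shape (> 0), dimensionless.
#' @param sal Ambient salinity, practical salinity units.
#' @param size Carapace width, mm; default 40 (juvenile stage).
#' @param temp Optional default overwintering temperature, degrees Celsius.
#' @param beta0,beta_temp,beta_sal,beta_size Linear-predictor coefficients.
#' @return An object of class `survival_params`.
#' @export
survival_params <- function(lambda, sal, size = 40, temp = NULL,
                            beta0 = 3.59, beta_temp = 0.10,
                            beta_sal = 0.02, beta_size = 0.03) {
  if (missing(lambda) || !is.numeric(lambda) || lambda <= 0) {
    abort("`lambda` (Weibull shape) must be supplied and > 0")
  }
  if (missing(sal) || !is.numeric(sal)) abort("`sal` (salinity) must be supplied")
  if (size <= 0) abort("`size` must be positive")
  structure(
    list(lambda = lambda, sal = sal, size = size, temp = temp,
         beta0 = beta0, beta_temp = beta_temp, beta_sal = beta_sal,
         beta_size = beta_size),
    class = "survival_params"
  )
}

#' @export
print.survival_params <- function(x, ...) {
  cat("<survival_params> lambda = ", x$lambda, ", Sal = ", x$sal,
      ", Size = ", x$size, " mm\n", sep = "")
  cat("  lp = ", x$beta0, " + ", x$beta_temp, "*Temp + ", x$beta_sal,
      "*Sal + ", x$beta_size, "*Size\n", sep = "")
  invisible(x)
}

#' Probability of surviving an overwintering period
#'
#' Weibull accelerated-failure-time survival
#' \deqn{S(t) = \exp(-t^\lambda e^{-\lambda \, lp}), \quad
#'       lp = \beta_0 + \beta_T Temp + \beta_S Sal + \beta_Z Size}
#' where `t` is the overwinter duration in days and `Temp` the mean
#' temperature over the overwintering period. S(0) = 1 exactly; S is
#' strictly decreasing in `t` and increasing in each covariate (warmer,
#' saltier winters and larger crabs survive better). With `lambda = 1` the
#' model reduces to exponential survival \eqn{\exp(-t e^{-lp})}.
#'
#' @param t Overwinter duration, days (>= 0); vectorised.
#' @param params A [survival_params()] object.
#' @param temp Overwintering-period mean temperature, degrees Celsius;
#'   defaults to `params$temp`.
#' @return Survival probabilities in (0, 1].
#' @examples
#' p <- survival_params(lambda = 1, sal = 12, size = 40)
#' survival_probability(100, p, temp = 5)
#' @export
survival_probability <- function(t, params, temp = params$temp) {
  stopifnot(inherits(params, "survival_params"))
  if (any(t < 0)) abort("overwinter duration t must be non-negative")
  if (is.null(temp)) abort("overwintering temperature `temp` must be supplied")
  lp <- params$beta0 + params$beta_temp * temp + params$beta_sal * params$sal +
    params$beta_size * params$size
  exp(-t^params$lambda * exp(-params$lambda * lp))
}

#' Per-winter overwinter survival probabilities
#'
#' Evaluates the survival model on each winter record, using the winter's
#' own length as duration and its severity as the temperature covariate.
#' Winters with no below-threshold days impose no overwinter exposure and
#' get survival 1.
#'
#' @param winters A `winter_records` tibble from [winter_metrics()].
#' @param params A [survival_params()] object (severity overrides any
#'   `temp` stored in it).
#' @return `winters` with a `survival` column appended.
#' @export
winter_survival_series <- function(winters, params) {
  stopifnot(inherits(params, "survival_params"))
  out <- dplyr::mutate(
    winters,
    survival = ifelse(
      .data$length_days == 0, 1,
      survival_probability(.data$length_days, params, temp = .data$severity)
    )
  )
  attr(out, "threshold") <- attr(winters, "threshold")
  class(out) <- unique(c("winter_records", class(out)))
  out
}
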