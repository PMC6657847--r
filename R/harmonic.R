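#' Fit a trend-plus-harmonic model to a daily temperature series
#'
#' Ordinary least squares fit of
#' \deqn{T(t_i) = B_0 + B_1 t_i + \sum_{m=1}^{M} [C_m \cos(m w t_i) + S_m \sin(m w t_i)]}
#' where \eqn{w = 2\pi/365.25} is the exact annual angular frequency and
#' \eqn{t_i} is time in days since `time_origin`. The continuous time
#' coordinate lets \eqn{B_1} carry a multi-decadal warming trend while the
#' harmonic terms keep correct seasonal phase. `mode = "day_of_year"` is a
#' degraded climatology-only mode in which \eqn{t_i} is the day of year
#' (1-366) and \eqn{B_1} has no long-term meaning.
#'
#' @param data A `daily_series`; missing days are dropped from the fit.
#' @param M Number of harmonics (annual cycle only when `M = 1`).
#' @param time_origin Date of \eqn{t = 0}.
#' @param mode `"continuous"` (default) or `"day_of_year"`.
#' @param stage Fit stage label: `"calibration"`, `"validation"` or `"final"`.
#' @return An object of class `harmonic_fit`: coefficient estimates and
#'   standard errors, `rmse` over the fitted data, and fit metadata. Use
#'   [generics::tidy()] / [generics::glance()] to extract tibbles and
#'   [predict_harmonic()] to evaluate it.
#' @examples
#' sim <- generate_pair(climate_sim_config(end = "1942-12-31",
#'   noise = list(ar1 = 0, sd = 0, cor = 0), gaps = list(weekend = FALSE)))
#' fit <- fit_harmonic(sim$air, M = 1, time_origin = as.Date("1938-01-01"))
#' tidy(fit)
#' @export
fit_harmonic <- function(data, M = 1, time_origin = as.Date("1938-01-01"),
                         mode = c("continuous", "day_of_year"),
                         stage = c("final", "calibration", "validation")) {
  data <- validate_daily_series(data)
  mode <- match.arg(mode)
  stage <- match.arg(stage)
  if (M < 1) abort("M must be at least 1")
  data <- data[!is.na(data$value), ]
  span <- as.numeric(max(data$date) - min(data$date))
  if (span < 2 * 365.25 - 1) {
    abort("series must span at least two full annual cycles (trend/harmonic confounding)")
  }
  time_origin <- as.Date(time_origin)
  t <- harmonic_time(data$date, time_origin, mode)
  X <- harmonic_design(t, M)
  fit <- lm(data$value ~ ., data = as.data.frame(X))
  est <- coef(fit)
  se <- sqrt(diag(vcov_safe(fit)))
  terms <- c("B0", "B1", paste0(rep(c("C", "S"), M), rep(seq_len(M), each = 2)))
  coefs <- tibble::tibble(term = terms, estimate = unname(est), std.error = unname(se))
  structure(
    list(
      coefficients = coefs,
      B0 = est[[1]], B1 = est[[2]],
      C = est[2 + 2 * seq_len(M) - 1], S = est[2 + 2 * seq_len(M)],
      M = as.integer(M), w = ANNUAL_W,
      time_origin = time_origin, mode = mode, stage = stage,
      rmse = sqrt(mean(fit$residuals^2)),
      n = nrow(data),
      variable = data$variable[[1]],
      first_date = min(data$date), last_date = max(data$date)
    ),
    class = "harmonic_fit"
  )
}

# noiseless series are legitimate inputs (synthetic oracles), so the
# "essentially perfect fit" warning from summary.lm is muffled
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

vcov_safe <- function(fit) {
  v <- try(quiet_perfect_fit(stats::vcov(fit)), silent = TRUE)
  if (inherits(v, "try-error")) matrix(NA_real_, length(coef(fit)), length(coef(fit))) else v
}

harmonic_time <- function(dates, time_origin, mode) {
  if (mode == "day_of_year") as.numeric(lubridate::yday(dates))
  else as.numeric(as.Date(dates) - time_origin)
}

harmonic_design <- function(t, M) {
  cols <- list(t = t)
  for (m in seq_len(M)) {
    cols[[paste0("cos", m)]] <- cos(m * ANNUAL_W * t)
    cols[[paste0("sin", m)]] <- sin(m * ANNUAL_W * t)
  }
  do.call(cbind, cols)
}

# evaluate B0 + B1 t + sum_m C_m cos(m w t) + S_m sin(m w t)
eval_harmonic <- function(B0, B1, C, S, t, w = ANNUAL_W) {
  out <- B0 + B1 * t
  for (m in seq_along(C)) {
    out <- out + C[[m]] * cos(m * w * t) + S[[m]] * sin(m * w * t)
  }
  out
}

#' Evaluate a fitted harmonic model on dates
#'
#' @param fit A `harmonic_fit`.
#' @param dates Dates to evaluate at.
#' @return Numeric vector of fitted temperatures.
#' @export
predict_harmonic <- function(fit, dates) {
  t <- harmonic_time(as.Date(dates), fit$time_origin, fit$mode)
  eval_harmonic(fit$B0, fit$B1, fit$C, fit$S, t, fit$w)
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("<harmonic_fit> ", x$variable, " temperature, M = ", x$M,
      ", stage = ", x$stage, "\n", sep = "")
  cat("  span: ", format(x$first_date), " to ", format(x$last_date),
      " (n = ", x$n, ")\n", sep = "")
  cat("  B0 = ", signif(x$B0, 5), " degC, B1 = ", signif(x$B1, 4),
      " degC/day, RMSE = ", signif(x$rmse, 4), " degC\n", sep = "")
  invisible(x)
}

#' Random calibration/validation split of a daily series
#'
#' Samples a fraction of the observed days uniformly without replacement as
#' the calibration set; the remainder is the validation set. The two outputs
#' partition the input and the split is reproducible under a fixed seed.
#'
#' @param data A `daily_series`.
#' @param fraction Calibration fraction in (0, 1); default 0.3.
#' @param seed Integer seed controlling the draw.
#' @return A list with elements `calibration` and `validation`.
#' @export
calibration_split <- function(data, fraction = 0.3, seed) {
  data <- validate_daily_series(data)
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  n <- nrow(data)
  n_cal <- round(fraction * n)
  idx <- withr::with_seed(seed, sample.int(n, n_cal))
  out <- list(
    calibration = validate_daily_series(data[sort(idx), ]),
    validation = validate_daily_series(data[sort(setdiff(seq_len(n), idx)), ])
  )
  spans <- vapply(out, function(s) as.numeric(max(s$date) - min(s$date)), numeric(1))
  if (any(spans < 2 * 365.25 - 1)) {
    abort("split leaves fewer than two annual cycles of span in one part")
  }
  out
}

#' Build the air-to-water transfer function from paired fits
#'
#' Forms the per-harmonic coefficient ratios
#' \eqn{cr_m = CW_m / CA_m} and \eqn{sr_m = SW_m / SA_m} between a water-
#' and an air-temperature harmonic fit estimated on the same days, plus the
#' trend ratio \eqn{B_{1,water} / B_{1,air}}. The ratios, applied to the
#' harmonic structure of any air series, predict the corresponding water
#' seasonal cycle (see [predict_water()]).
#'
#' @param air_fit,water_fit `harmonic_fit` objects with equal `M` and equal
#'   stage, fitted on the same calendar.
#' @param tol Air coefficients with absolute value below `tol` (degrees
#'   Celsius) make the ratio undefined and are rejected.
#' @return An object of class `transfer_function` carrying the ratio
#'   vectors, the water fit (`water_base`, supplying intercept and trend)
#'   and the air fit (`air_shape`, supplying harmonic structure).
#' @export
build_transfer <- function(air_fit, water_fit, tol = 1e-6) {
  stopifnot(inherits(air_fit, "harmonic_fit"), inherits(water_fit, "harmonic_fit"))
  if (air_fit$M != water_fit$M) abort("fits must share the harmonic count M")
  if (air_fit$stage != water_fit$stage) abort("fits must come from the same stage")
  if (any(abs(c(air_fit$C, air_fit$S)) < tol) || abs(air_fit$B1) < tol) {
    abort("air coefficient within tolerance of zero; ratio undefined")
  }
  structure(
    list(
      water_base = water_fit,
      air_shape = air_fit,
      cr = unname(water_fit$C / air_fit$C),
      sr = unname(water_fit$S / air_fit$S),
      trend_ratio = water_fit$B1 / air_fit$B1,
      M = air_fit$M, w = air_fit$w,
      time_origin = air_fit$time_origin,
      stage = air_fit$stage
    ),
    class = "transfer_function"
  )
}

#' @export
print.transfer_function <- function(x, ...) {
  cat("<transfer_function> M = ", x$M, ", stage = ", x$stage, "\n", sep = "")
  cat("  cr:", paste(signif(x$cr, 4), collapse = ", "),
      " sr:", paste(signif(x$sr, 4), collapse = ", "), "\n")
  cat("  trend ratio:", signif(x$trend_ratio, 4), "\n")
  invisible(x)
}

#' Predict daily water temperature from air-temperature structure
#'
#' Evaluates
#' \deqn{WT(t_i) = B_0 + B_1 t_i + \sum_m [cr_m CA_m \cos(m w t_i) + sr_m SA_m \sin(m w t_i)]}
#' where \eqn{CA_m, SA_m} are the harmonic coefficients of `air_fit` and the
#' ratios come from the transfer function. Two intercept/trend conventions
#' are provided:
#'
#' * `"water"` (the literal transfer equation): \eqn{B_0, B_1} are taken
#'   from the water-side fit. Appropriate when the driving air fit is the
#'   one the transfer was built from (historical window, extended-trend
#'   projection).
#' * `"continuity"`: for an independently fitted air series (e.g. a climate
#'   model member), the predicted trend is `trend_ratio` times the air
#'   fit's trend — so the prediction inherits the driving scenario's
#'   warming — and the intercept is offset so the trend line is continuous
#'   with the observed water record at its last day.
#'
#' @param tf A `transfer_function`.
#' @param dates Dates to predict (must not predate the fit's time origin).
#' @param air_fit A `harmonic_fit` for air with the same `M`; defaults to
#'   the transfer function's own air fit.
#' @param intercept `"water"` or `"continuity"` (see Details).
#' @return A `daily_series` (variable `"water"`, provenance `"predicted"`).
#' @export
predict_water <- function(tf, dates, air_fit = NULL,
                          intercept = c("water", "continuity")) {
  stopifnot(inherits(tf, "transfer_function"))
  intercept <- match.arg(intercept)
  air_fit <- air_fit %||% tf$air_shape
  if (air_fit$M != tf$M) abort("air_fit must share the transfer function's M")
  dates <- as.Date(dates)
  if (any(dates < tf$time_origin)) {
    abort("prediction dates predate the transfer function's time origin")
  }
  t <- as.numeric(dates - tf$time_origin)
  wb <- tf$water_base
  if (intercept == "water") {
    B0 <- wb$B0
    B1 <- wb$B1
  } else {
    B1 <- tf$trend_ratio * air_fit$B1
    t_ref <- as.numeric(wb$last_date - tf$time_origin)
    B0 <- wb$B0 + (wb$B1 - B1) * t_ref # trend lines meet at the last observed day
  }
  vals <- eval_harmonic(B0, B1, tf$cr * air_fit$C, tf$sr * air_fit$S, t, tf$w)
  daily_series(dates, vals, provenance = "predicted", variable = "water")
}

#' Root-mean-squared error on a holdout series
#'
#' Evaluates a harmonic fit or transfer function on the days of a holdout
#' series and returns the RMSE of the residuals. The holdout must be
#' disjoint from the days used to estimate the coefficients (the caller's
#' responsibility; overlap with a `harmonic_fit`'s fitted span cannot be
#' detected day-by-day and is not checked).
#'
#' @param object A `harmonic_fit` or `transfer_function`.
#' @param holdout A `daily_series` with observed values.
#' @param ... Passed to [predict_water()] for transfer functions.
#' @return RMSE in degrees Celsius.
#' @export
validate_fit <- function(object, holdout, ...) {
  holdout <- validate_daily_series(holdout)
  holdout <- holdout[!is.na(holdout$value), ]
  if (nrow(holdout) == 0) abort("holdout series has no observed values")
  pred <- if (inherits(object, "transfer_function")) {
    predict_water(object, holdout$date, ...)$value
  } else if (inherits(object, "harmonic_fit")) {
    predict_harmonic(object, holdout$date)
  } else {
    abort("object must be a harmonic_fit or transfer_function")
  }
  sqrt(mean((holdout$value - pred)^2))
}

#' Run the full calibration/validation/final transfer protocol
#'
#' Convenience wrapper: splits the paired air/water record, fits
#' calibration-stage models on the sampled fraction, reports validation
#' RMSE on the remainder, then refits both models on all days and rebuilds
#' the transfer function (the "final" model used for projection).
#'
#' @param air,water Complete `daily_series` on a shared calendar.
#' @param M Harmonic count.
#' @param fraction Calibration fraction; default 0.3.
#' @param seed Integer seed for the split.
#' @param time_origin Date of \eqn{t = 0}.
#' @return A list: `transfer` (final-stage `transfer_function`),
#'   `calibration_transfer`, `rmse_validation` (calibration-stage transfer
#'   on the holdout) and `rmse_final` (final transfer on the same holdout).
#' @export
fit_transfer_protocol <- function(air, water, M = 1, fraction = 0.3, seed = 1,
                                  time_origin = as.Date("1938-01-01")) {
  air <- validate_daily_series(air)
  water <- validate_daily_series(water)
  split <- calibration_split(water, fraction = fraction, seed = seed)
  cal_dates <- split$calibration$date
  air_cal <- validate_daily_series(air[air$date %in% cal_dates, ])
  tf_cal <- build_transfer(
    fit_harmonic(air_cal, M, time_origin, stage = "calibration"),
    fit_harmonic(split$calibration, M, time_origin, stage = "calibration")
  )
  tf_final <- build_transfer(
    fit_harmonic(air, M, time_origin, stage = "final"),
    fit_harmonic(water, M, time_origin, stage = "final")
  )
  list(
    transfer = tf_final,
    calibration_transfer = tf_cal,
    rmse_validation = validate_fit(tf_cal, split$validation),
    rmse_final = validate_fit(tf_final, split$validation)
  )
}
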