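new_projection_ensemble <- function(members, scenario) {
  stopifnot(length(members) >= 1)
  dates <- members[[1]]$date
  for (m in members) {
    if (!identical(m$date, dates)) abort("ensemble members must share one date range")
  }
  vals <- vapply(members, function(m) m$value, numeric(length(dates)))
  vals <- matrix(vals, nrow = length(dates))
  summary <- tibble::tibble(
    date = dates,
    mean = rowMeans(vals),
    sd = if (ncol(vals) > 1) apply(vals, 1, sd) else rep(0, length(dates))
  )
  if (is.null(names(members))) {
    names(members) <- sprintf("m%02d", seq_along(members))
  }
  long <- dplyr::bind_rows(
    purrr::imap(members, ~ tibble::tibble(member = .y, date = .x$date, value = .x$value))
  )
  structure(
    list(summary = summary, members = long, scenario = scenario,
         n_members = length(members)),
    class = "projection_ensemble"
  )
}

#' @export
print.projection_ensemble <- function(x, ...) {
  cat("<projection_ensemble> scenario = ", x$scenario,
      ", members = ", x$n_members, "\n", sep = "")
  cat("  ", format(min(x$summary$date)), " to ", format(max(x$summary$date)),
      " (", nrow(x$summary), " days)\n", sep = "")
  invisible(x)
}

#' Extend the observed temperature trend to a future date
#'
#' Evaluates the final-model water prediction (the transfer equation with
#' its least-squares point estimates) on every day from the end of the
#' observational record through `end_date`. This is the conservative
#' projection scenario: the future simply continues the trend and seasonal
#' cycle estimated from the observations.
#'
#' @param tf A `transfer_function` fitted on the full observational record.
#' @param end_date Last projected day.
#' @return A `daily_series` of projected water temperature.
#' @export
extend_trend <- function(tf, end_date) {
  stopifnot(inherits(tf, "transfer_function"))
  end_date <- as.Date(end_date)
  obs_end <- tf$water_base$last_date
  if (end_date <= obs_end) abort("end_date must follow the end of observations")
  dates <- seq(obs_end + 1, end_date, by = "day")
  predict_water(tf, dates, intercept = "water")
}

# draw a copy of a harmonic fit with every coefficient resampled from
# Normal(estimate, std.error)
perturb_fit <- function(fit) {
  se <- fit$coefficients$std.error
  if (any(is.na(se))) abort("fit lacks coefficient standard errors")
  draw <- rnorm(length(se), mean = fit$coefficients$estimate, sd = se)
  fit$coefficients$estimate <- draw
  fit$B0 <- draw[[1]]
  fit$B1 <- draw[[2]]
  fit$C <- draw[2 + 2 * seq_len(fit$M) - 1]
  fit$S <- draw[2 + 2 * seq_len(fit$M)]
  fit
}

#' Parameter-resampling uncertainty for the extended-trend projection
#'
#' Draws each regression coefficient of the transfer function's air and
#' water fits independently from a normal distribution centred on its
#' point estimate with the estimate's standard error as spread, rebuilds
#' the transfer function, and evaluates the projection; repeated `n` times.
#' The per-day mean and standard deviation across the resampled projections
#' quantify parameter uncertainty in the extended-trend scenario. The draws
#' ignore coefficient covariance (only mean and SD are propagated), which
#' understates joint uncertainty.
#'
#' @param tf A `transfer_function` whose fits carry standard errors.
#' @param n Number of resampled projections (>= 2); 50 in typical use.
#' @param seed Integer seed; the ensemble is reproducible under it.
#' @param end_date Last projected day.
#' @return A `projection_ensemble` (scenario `"extended_trend"`).
#' @export
resample_projections <- function(tf, n, seed, end_date) {
  stopifnot(inherits(tf, "transfer_function"))
  if (n < 2) abort("n must be at least 2")
  members <- withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      tf_i <- tf
      tf_i$air_shape <- perturb_fit(tf$air_shape)
      tf_i$water_base <- perturb_fit(tf$water_base)
      tf_i$cr <- unname(tf_i$water_base$C / tf_i$air_shape$C)
      tf_i$sr <- unname(tf_i$water_base$S / tf_i$air_shape$S)
      tf_i$trend_ratio <- tf_i$water_base$B1 / tf_i$air_shape$B1
      extend_trend(tf_i, end_date)
    })
  })
  new_projection_ensemble(members, scenario = "extended_trend")
}

parse_member_cols <- function(nms, sep) {
  parts <- strsplit(nms, sep, fixed = TRUE)
  ok <- lengths(parts) == 3 & vapply(parts, function(p) p[[3]] %in% c("min", "max"),
                                     logical(1))
  tibble::tibble(
    col = nms[ok],
    member = vapply(parts[ok], `[[`, character(1), 1),
    cell = vapply(parts[ok], `[[`, character(1), 2),
    which = vapply(parts[ok], `[[`, character(1), 3)
  )
}

#' Read a daily min/max temperature ensemble
#'
#' Turns per-member, per-grid-cell daily minimum and maximum air
#' temperatures (the layout of downscaled climate-model output) into one
#' air `daily_series` per member: each day's value is the mean over grid
#' cells of the (min + max)/2 midpoint. Days where min exceeds max are
#' dropped with a warning; members missing more than `max_missing` of the
#' ensemble's days are rejected with a warning.
#'
#' @param x Either a long data frame with columns `member`, `date`, `cell`,
#'   `tmin`, `tmax`, or a path to a wide CSV with a `date` column and
#'   columns named `<member><sep><cell><sep>min` / `...max`.
#' @param sep Separator in wide-format column names; default `"."`.
#' @param max_missing Maximum tolerated fraction of missing days per
#'   member; default 0.05.
#' @return A named list of air `daily_series`, one per retained member.
#' @export
read_member_ensemble <- function(x, sep = ".", max_missing = 0.05) {
  if (is.character(x)) {
    wide <- readr::read_csv(x, show_col_types = FALSE)
    map <- parse_member_cols(setdiff(names(wide), "date"), sep)
    if (nrow(map) == 0) abort("no member columns matched <member><sep><cell><sep>min/max")
    long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(map$col),
                                names_to = "col", values_to = "temp")
    long <- dplyr::left_join(long, map, by = "col")
    x <- tidyr::pivot_wider(
      dplyr::select(long, "date", "member", "cell", "which", "temp"),
      names_from = "which", values_from = "temp", names_prefix = "t"
    )
  }
  x <- tibble::as_tibble(x)
  req <- c("member", "date", "cell", "tmin", "tmax")
  if (!all(req %in% names(x))) {
    abort(paste0("ensemble table needs columns: ", paste(req, collapse = ", ")))
  }
  x$date <- as.Date(x$date)
  bad <- !is.na(x$tmin) & !is.na(x$tmax) & x$tmin > x$tmax
  if (any(bad)) {
    warn(paste0(sum(bad), " day-cell record(s) with min > max dropped"))
    x <- x[!bad, ]
  }
  daily <- x |>
    dplyr::group_by(.data$member, .data$date) |>
    dplyr::summarise(value = mean((.data$tmin + .data$tmax) / 2), .groups = "drop")
  all_dates <- seq(min(daily$date), max(daily$date), by = "day")
  members <- split(daily, daily$member)
  out <- purrr::imap(members, function(d, name) {
    miss_frac <- 1 - sum(!is.na(d$value)) / length(all_dates)
    if (miss_frac > max_missing) {
      warn(paste0("member ", name, " rejected: ",
                  signif(100 * miss_frac, 3), "% of days missing"))
      return(NULL)
    }
    daily_series(d$date, d$value, variable = "air", source_name = name)
  })
  purrr::compact(out)
}

#' Project water temperature under an air-temperature ensemble
#'
#' For each ensemble member, fits the air harmonic model to the member's
#' series and applies the transfer-function ratios to predict daily water
#' temperature (with the `"continuity"` intercept/trend rule, so each
#' member's water projection inherits that member's warming rate); then
#' summarises mean and SD across members per day. Only days after the end
#' of the observational record are reported — member days overlapping the
#' observations inform the fit but not the projection.
#'
#' @param tf A `transfer_function` from the observational record.
#' @param air_members A (named) list of air `daily_series`, e.g. from
#'   [read_member_ensemble()].
#' @param refit_window `"full"` fits each member over its whole span
#'   (default); `"sliding"` refits on a trailing window of
#'   `window_years` before each projected year, tracking curvature in the
#'   member's warming at the cost of noisier coefficients.
#' @param window_years Trailing window length for `"sliding"`.
#' @return A `projection_ensemble` (scenario `"downscaled_gcm"`).
#' @export
project_ensemble <- function(tf, air_members, refit_window = c("full", "sliding"),
                             window_years = 30) {
  stopifnot(inherits(tf, "transfer_function"))
  refit_window <- match.arg(refit_window)
  obs_end <- tf$water_base$last_date
  members <- purrr::map(air_members, function(m) {
    m <- validate_daily_series(m)
    dates <- m$date[m$date > obs_end]
    if (length(dates) == 0) abort("member has no days after the observational record")
    if (refit_window == "full") {
      fit <- fit_harmonic(m, M = tf$M, time_origin = tf$time_origin)
      predict_water(tf, dates, air_fit = fit, intercept = "continuity")
    } else {
      yrs <- sort(unique(lubridate::year(dates)))
      preds <- purrr::map(yrs, function(y) {
        win_start <- as.Date(sprintf("%d-01-01", y - window_years))
        win <- m[m$date >= win_start & m$date < as.Date(sprintf("%d-01-01", y)), ]
        fit <- fit_harmonic(win, M = tf$M, time_origin = tf$time_origin)
        predict_water(tf, dates[lubridate::year(dates) == y],
                      air_fit = fit, intercept = "continuity")
      })
      validate_daily_series(dplyr::bind_rows(preds))
    }
  })
  new_projection_ensemble(members, scenario = "downscaled_gcm")
}
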