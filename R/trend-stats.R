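#' Linear trend of an annual quantity
#'
#' Ordinary least-squares regression of a per-winter (or per-year) quantity
#' on year, with a two-sided test of zero slope. Used for the long-term
#' decline in overwintering-period length and the rise in overwinter
#' survival.
#'
#' @param data A data frame (e.g. `winter_records`).
#' @param year,value Column names (tidy-eval) of the year label and the
#'   response. Defaults suit `winter_records`.
#' @param exclusions Integer years dropped before fitting (rows flagged
#'   `excluded`, if the column exists, are dropped too).
#' @return A one-row tibble: `slope` (per year), `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linear_trend <- function(data, year = winter_year, value = length_days,
                         exclusions = integer()) {
  df <- tibble::tibble(
    x = as.numeric(dplyr::pull(data, {{ year }})),
    y = as.numeric(dplyr::pull(data, {{ value }}))
  )
  if ("excluded" %in% names(data)) df <- df[!data$excluded, ]
  df <- df[!df$x %in% exclusions & complete.cases(df), ]
  if (nrow(df) < 3) abort("need at least three years after exclusions")
  if (length(unique(df$x)) < 2) abort("year values are constant")
  fit <- lm(y ~ x, data = df)
  s <- quiet_perfect_fit(summary(fit))
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = s$coefficients[2, 4],
    n = nrow(df)
  )
}

#' Compare two scenarios' per-winter values over time intervals
#'
#' For each interval of winter years, a two-sample t-test (Welch by
#' default) between the values of the two scenarios — e.g. extended-trend
#' versus downscaled-GCM overwintering lengths in 2017-2030, 2031-2050,
#' 2051-2070 and 2071-2100. Intervals with fewer than two winters on
#' either side are reported as not computable rather than dropped.
#'
#' @param a,b Data frames with columns `winter_year` and the value column.
#' @param intervals A list of `c(start, end)` year pairs (inclusive).
#' @param value Column name (tidy-eval) of the compared quantity.
#' @param var_equal Use the pooled-variance Student test instead of Welch?
#' @param adjust Multiple-testing adjustment across intervals passed to
#'   [stats::p.adjust()]; default `"none"` (raw p-values).
#' @return A tibble, one row per interval: `start`, `end`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `t`, `df`, `p_value`, `note`.
#' @export
scenario_contrast <- function(a, b, intervals, value = length_days,
                              var_equal = FALSE, adjust = "none") {
  rows <- purrr::map(intervals, function(iv) {
    start <- iv[[1]]; end <- iv[[2]]
    xa <- dplyr::pull(dplyr::filter(a, dplyr::between(.data$winter_year, start, end)),
                      {{ value }})
    xb <- dplyr::pull(dplyr::filter(b, dplyr::between(.data$winter_year, start, end)),
                      {{ value }})
    base <- tibble::tibble(start = start, end = end,
                           n_a = length(xa), n_b = length(xb))
    if (length(xa) < 2 || length(xb) < 2) {
      return(dplyr::mutate(base, mean_a = NA_real_, mean_b = NA_real_,
                           t = NA_real_, df = NA_real_, p_value = NA_real_,
                           note = "not computable: fewer than 2 winters in an arm"))
    }
    tt <- if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb)) {
      # identical degenerate inputs: no variance, no difference
      list(statistic = 0, parameter = length(xa) + length(xb) - 2, p.value = 1)
    } else {
      t.test(xa, xb, var.equal = var_equal)
    }
    dplyr::mutate(base, mean_a = mean(xa), mean_b = mean(xb),
                  t = unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value, note = "")
  })
  out <- dplyr::bind_rows(rows)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out
}

#' Latitude with an equivalent number of sub-threshold days
#'
#' Regresses observed days-below-threshold on latitude across anchor sites
#' along a coastline, then inverts the fit to find the latitude whose
#' current climate matches a projected number of overwintering days —
#' i.e. where on the coast the projected future winter already exists
#' today. Refuses to extrapolate beyond the anchor latitude range plus a
#' 10% margin, and warns when the slope is not significantly positive
#' (the inversion is then unreliable).
#'
#' @param anchors A data frame with columns `latitude` (degrees North) and
#'   `days` (observed days below threshold); at least 3 sites.
#' @param projected_days Projected days below threshold (vectorised).
#' @param margin Allowed extrapolation fraction of the anchor latitude
#'   range; default 0.1.
#' @return Equivalent latitudes, degrees North.
#' @export
latitude_equivalent <- function(anchors, projected_days, margin = 0.1) {
  anchors <- tibble::as_tibble(anchors)
  if (!all(c("latitude", "days") %in% names(anchors))) {
    abort("anchors must have columns `latitude` and `days`")
  }
  if (nrow(anchors) < 3) abort("need at least three anchor sites")
  fit <- lm(days ~ latitude, data = anchors)
  slope <- unname(coef(fit)[2])
  s <- quiet_perfect_fit(summary(fit))
  p_pos <- pt(s$coefficients[2, 3], df = fit$df.residual, lower.tail = FALSE)
  if (!is.finite(p_pos) || p_pos >= 0.05 || slope <= 0) {
    warn("days-latitude slope not significantly positive; inversion unreliable")
  }
  lat <- (projected_days - unname(coef(fit)[1])) / slope
  rng <- range(anchors$latitude)
  lim <- rng + c(-1, 1) * margin * diff(rng)
  if (any(lat < lim[1] | lat > lim[2])) {
    abort("equivalent latitude falls outside the anchor range (+/- margin); refusing to extrapolate")
  }
  lat
}
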