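#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a harmonic fit
#'
#' @param x A `harmonic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.harmonic_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a harmonic fit
#'
#' @param x A `harmonic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `variable`, `stage`, `M`, `rmse`, `n`,
#'   `first_date`, `last_date`.
#' @export
glance.harmonic_fit <- function(x, ...) {
  tibble::tibble(
    variable = x$variable, stage = x$stage, M = x$M,
    rmse = x$rmse, n = x$n,
    first_date = x$first_date, last_date = x$last_date
  )
}

#' Tidy a transfer function
#'
#' @param x A `transfer_function`.
#' @param ... Unused.
#' @return A tibble with one row per harmonic: `harmonic`, `cr`, `sr`.
#' @export
tidy.transfer_function <- function(x, ...) {
  tibble::tibble(harmonic = seq_len(x$M), cr = x$cr, sr = x$sr)
}

#' One-row summary of a transfer function
#'
#' @param x A `transfer_function`.
#' @param ... Unused.
#' @return A one-row tibble: `M`, `stage`, `trend_ratio`, the water-side
#'   intercept/trend, and the water fit's RMSE.
#' @export
glance.transfer_function <- function(x, ...) {
  tibble::tibble(
    M = x$M, stage = x$stage, trend_ratio = x$trend_ratio,
    water_b0 = x$water_base$B0, water_b1 = x$water_base$B1,
    water_rmse = x$water_base$rmse
  )
}

#' Tidy a projection ensemble
#'
#' @param x A `projection_ensemble`.
#' @param ... Unused.
#' @return The per-day summary tibble: `date`, `mean`, `sd`.
#' @export
tidy.projection_ensemble <- function(x, ...) {
  x$summary
}

#' One-row summary of a projection ensemble
#'
#' @param x A `projection_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: `scenario`, `n_members`, date range, and the
#'   mean projected temperature over the final 30 years.
#' @export
glance.projection_ensemble <- function(x, ...) {
  last30 <- x$summary[x$summary$date > max(x$summary$date) - round(30 * 365.25), ]
  tibble::tibble(
    scenario = x$scenario, n_members = x$n_members,
    first_date = min(x$summary$date), last_date = max(x$summary$date),
    mean_last30yr = mean(last30$mean)
  )
}
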