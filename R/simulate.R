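#' Configuration for the synthetic daily climate generator
#'
#' Parameters of a synthetic paired air/water daily temperature record:
#' linear warming trend plus annual harmonic cycle plus AR(1) daily noise,
#' a known air-to-water coefficient-ratio relationship, and observational
#' gaps (weekends plus scattered days plus occasional long runs). The
#' defaults emulate a long mid-latitude estuarine pier record (1938-2016):
#' water mean near 15.2 degrees Celsius over 1961-1990, seasonal amplitude
#' near 12.2 degrees, warming about 2.2 degrees per century, producing
#' winters of roughly 75-145 days below 9 degrees.
#'
#' @param start,end First and last calendar day.
#' @param air List: `b0` intercept (degC at `start`), `b1` trend (degC per
#'   day), `cos`, `sin` per-harmonic coefficient vectors (degC).
#' @param water List: `cr`, `sr` per-harmonic ratios, `trend_ratio`,
#'   `offset` (water minus air intercept, degC).
#' @param noise List: `ar1` autoregressive coefficient (|ar1| < 1), `sd`
#'   innovation standard deviation (degC), `cor` air-water innovation
#'   correlation.
#' @param gaps List: `weekend` (drop all Saturdays/Sundays?),
#'   `holiday_frac` (fraction of remaining days dropped at random),
#'   `long_gap_rate` (expected long gaps per year, Poisson),
#'   `long_gap_mean` (mean long-gap length, days, geometric).
#' @param seed Integer seed; identical seeds give identical records.
#' @return A list of class `climate_sim_config`.
#' @export
climate_sim_config <- function(start = "1938-01-01", end = "2016-12-31",
                               air = list(), water = list(), noise = list(),
                               gaps = list(), seed = 1L) {
  air <- utils::modifyList(
    list(b0 = 13.5, b1 = 6.0e-5, cos = -12.3, sin = -3.7), air)
  water <- utils::modifyList(
    list(cr = 0.95, sr = 0.95, trend_ratio = 1.0, offset = 0.88), water)
  noise <- utils::modifyList(
    list(ar1 = 0.8, sd = 1.2, cor = 0.7), noise)
  gaps <- utils::modifyList(
    list(weekend = TRUE, holiday_frac = 0.02, long_gap_rate = 0.5,
         long_gap_mean = 10), gaps)
  if (length(air$cos) != length(air$sin)) abort("air cos/sin lengths differ")
  if (length(water$cr) != length(air$cos) || length(water$sr) != length(air$sin)) {
    abort("water ratio lengths must match the air harmonic count")
  }
  if (abs(noise$ar1) >= 1) abort("|ar1| must be below 1")
  if (noise$sd < 0) abort("noise sd must be non-negative")
  if (noise$cor < -1 || noise$cor > 1) abort("noise cor must be in [-1, 1]")
  if (gaps$holiday_frac < 0 || gaps$holiday_frac > 1) {
    abort("holiday_frac must be in [0, 1]")
  }
  structure(
    list(start = as.Date(start), end = as.Date(end), air = air, water = water,
         noise = noise, gaps = gaps, seed = as.integer(seed)),
    class = "climate_sim_config"
  )
}

ar1_series <- function(innov, phi) {
  if (phi == 0) return(innov)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

inject_gaps <- function(values, dates, gaps) {
  n <- length(values)
  miss <- rep(FALSE, n)
  if (isTRUE(gaps$weekend)) {
    miss <- miss | lubridate::wday(dates) %in% c(1, 7)
  }
  if (gaps$holiday_frac > 0) {
    miss <- miss | (runif(n) < gaps$holiday_frac)
  }
  if (gaps$long_gap_rate > 0) {
    n_years <- n / 365.25
    k <- rpois(1, gaps$long_gap_rate * n_years)
    if (k > 0) {
      starts <- sample.int(n, k)
      lens <- rgeom(k, 1 / gaps$long_gap_mean) + 1
      for (i in seq_len(k)) {
        miss[seq(starts[i], min(n, starts[i] + lens[i] - 1))] <- TRUE
      }
    }
  }
  # gaps are interior by construction of downstream trimming; keep endpoints
  miss[c(1, n)] <- FALSE
  replace(values, miss, NA_real_)
}

#' Generate a paired air/water daily temperature record
#'
#' Simulates air temperature as trend + harmonics + AR(1) noise, and water
#' temperature as the ratio-transformed deterministic curve plus AR(1)
#' noise whose innovations are correlated with the air innovations; then
#' injects observational gaps into the returned "raw" records while keeping
#' the complete noisy series and every generating parameter in the truth
#' record. Identical seeds give identical output.
#'
#' @param config A [climate_sim_config()].
#' @return A list: `air`, `water` (gapped `daily_series`), and `truth`
#'   (list: `config`, complete `air_full`/`water_full` series, noise-free
#'   `air_det`/`water_det` curves, and the water-side true coefficients).
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "climate_sim_config"))
  dates <- seq(config$start, config$end, by = "day")
  t <- as.numeric(dates - config$start)
  a <- config$air; wtr <- config$water; nz <- config$noise
  air_det <- eval_harmonic(a$b0, a$b1, a$cos, a$sin, t)
  water_det <- eval_harmonic(a$b0 + wtr$offset, wtr$trend_ratio * a$b1,
                             wtr$cr * a$cos, wtr$sr * a$sin, t)
  withr::with_seed(config$seed, {
    e_air <- rnorm(length(t), sd = nz$sd)
    e_ind <- rnorm(length(t), sd = nz$sd)
    e_water <- nz$cor * e_air + sqrt(1 - nz$cor^2) * e_ind
    air_full <- air_det + ar1_series(e_air, nz$ar1)
    water_full <- water_det + ar1_series(e_water, nz$ar1)
    air_raw <- inject_gaps(air_full, dates, config$gaps)
    water_raw <- inject_gaps(water_full, dates, config$gaps)
    list(
      air = daily_series(dates, air_raw, variable = "air", source_name = "sim"),
      water = daily_series(dates, water_raw, variable = "water", source_name = "sim"),
      truth = list(
        config = config,
        air_det = air_det, water_det = water_det,
        air_full = daily_series(dates, air_full, variable = "air",
                                source_name = "sim"),
        water_full = daily_series(dates, water_full, variable = "water",
                                  source_name = "sim"),
        water_b0 = a$b0 + wtr$offset,
        water_b1 = wtr$trend_ratio * a$b1,
        water_cos = wtr$cr * a$cos,
        water_sin = wtr$sr * a$sin
      )
    )
  })
}

#' Generate a synthetic air-temperature projection ensemble
#'
#' Builds `n_members` GCM-like daily air-temperature members sharing the
#' config's seasonal structure but differing in warming rate — drawn from a
#' normal distribution centred on the config's air trend with the given
#' spread — and in noise realisation. Each member is emitted as daily
#' minimum and maximum temperature over `n_cells` grid cells (midpoint =
#' member value + cell offset; offsets sum to zero so the cell-mean
#' midpoint recovers the member series exactly), the layout that
#' [read_member_ensemble()] consumes.
#'
#' @param config A [climate_sim_config()]; its `start`/`end` default is
#'   usually overridden to the projection span (e.g. 1950-2099).
#' @param n_members Number of members (>= 2).
#' @param trend_spread Member-to-member warming-rate SD, degrees Celsius
#'   per century.
#' @param seed Integer seed.
#' @param n_cells Grid cells per member; default 3.
#' @param diurnal_range Daily max minus min, degrees Celsius; default 8.
#' @return A list: `table` (long tibble `member, date, cell, tmin, tmax`)
#'   and `truth` (tibble of each member's true trend, degC/day).
#' @export
generate_member_ensemble <- function(config, n_members = 41, trend_spread = 1.0,
                                     seed = 1L, n_cells = 3, diurnal_range = 8) {
  stopifnot(inherits(config, "climate_sim_config"))
  if (n_members < 2) abort("n_members must be at least 2")
  dates <- seq(config$start, config$end, by = "day")
  t <- as.numeric(dates - config$start)
  a <- config$air; nz <- config$noise
  cell_offsets <- seq(-0.2, 0.2, length.out = n_cells)
  cell_offsets <- cell_offsets - mean(cell_offsets)
  withr::with_seed(seed, {
    b1_m <- rnorm(n_members, mean = a$b1, sd = trend_spread / 36525)
    tabs <- purrr::map(seq_len(n_members), function(i) {
      det <- eval_harmonic(a$b0, b1_m[i], a$cos, a$sin, t)
      noise <- ar1_series(rnorm(length(t), sd = nz$sd), nz$ar1)
      value <- det + noise
      purrr::map(seq_len(n_cells), function(j) {
        tibble::tibble(
          member = sprintf("m%02d", i),
          date = dates,
          cell = sprintf("c%d", j),
          tmin = value + cell_offsets[j] - diurnal_range / 2,
          tmax = value + cell_offsets[j] + diurnal_range / 2
        )
      }) |> dplyr::bind_rows()
    })
  })
  list(
    table = dplyr::bind_rows(tabs),
    truth = tibble::tibble(member = sprintf("m%02d", seq_len(n_members)),
                           b1 = b1_m)
  )
}

#' Write a member ensemble to a wide CSV
#'
#' One row per day, columns `<member>.<cell>.min` and `<member>.<cell>.max`
#' — the wide layout [read_member_ensemble()] reads back.
#'
#' @param table Long tibble from [generate_member_ensemble()].
#' @param path Output file path.
#' @param sep Separator for column names; default `"."`.
#' @return `path`, invisibly.
#' @export
write_member_ensemble <- function(table, path, sep = ".") {
  wide <- table |>
    tidyr::pivot_longer(c("tmin", "tmax"), names_to = "which", values_to = "temp") |>
    dplyr::mutate(col = paste(.data$member, .data$cell,
                              sub("^t", "", .data$which), sep = sep)) |>
    dplyr::select("date", "col", "temp") |>
    tidyr::pivot_wider(names_from = "col", values_from = "temp")
  readr::write_csv(wide, path)
  invisible(path)
}
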