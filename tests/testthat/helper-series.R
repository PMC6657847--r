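# quick constructors and independent brute-force oracles used across tests

ds <- function(values, start = "2000-01-01", variable = "water",
               source_name = "obs") {
  daily_series(as.Date(start) + seq_along(values) - 1, values,
               variable = variable, source_name = source_name)
}

# day-by-day first-non-missing scan across sources (merge oracle)
scan_merge_oracle <- function(series_list) {
  dates <- sort(unique(as.Date(unlist(lapply(series_list, function(s) s$date)),
                               origin = "1970-01-01")))
  vapply(dates, function(d) {
    for (s in series_list) {
      v <- s$value[s$date == d]
      if (length(v) == 1 && !is.na(v)) return(v)
    }
    NA_real_
  }, numeric(1))
}

# closed-form two-point line evaluation at integer day offsets (fill oracle)
line_fill_oracle <- function(values) {
  obs <- which(!is.na(values))
  out <- values
  for (k in seq_len(length(obs) - 1)) {
    i <- obs[k]; j <- obs[k + 1]
    if (j > i + 1) {
      mid <- (i + 1):(j - 1)
      out[mid] <- values[i] + (values[j] - values[i]) * (mid - i) / (j - i)
    }
  }
  out
}

# run-length-encoding gap oracle on a logical missing mask
rle_gap_oracle <- function(miss) {
  r <- rle(miss)
  lens <- r$lengths[r$values]
  list(
    n_gaps = length(lens),
    mean_gap_length = if (length(lens)) mean(lens) else 0,
    max_gap_length = if (length(lens)) max(lens) else 0,
    filled_fraction = sum(lens) / length(miss)
  )
}

# brute-force per-day winter counting oracle, independent month arithmetic
winter_count_oracle <- function(dates, values, threshold = 9) {
  m <- as.integer(format(dates, "%m"))
  y <- as.integer(format(dates, "%Y"))
  wy <- ifelse(m >= 7, y, y - 1L)
  out <- list()
  for (w in unique(wy)) {
    sel <- wy == w
    below <- values[sel] < threshold
    out[[as.character(w)]] <- list(
      winter_year = w,
      n_days = sum(sel),
      length_days = sum(below),
      severity = if (any(below)) mean(values[sel][below]) else NA_real_
    )
  }
  out
}

# two-harmonic curve evaluator, independent of the package's internals
eval2 <- function(b0, b1, C, S, t) {
  w <- 2 * pi / 365.25
  y <- b0 + b1 * t
  for (m in seq_along(C)) y <- y + C[m] * cos(m * w * t) + S[m] * sin(m * w * t)
  y
}

noiseless_config <- function(start = "2000-01-01", end = "2007-12-31", ...) {
  climate_sim_config(start = start, end = end,
                     noise = list(ar1 = 0, sd = 0, cor = 0),
                     gaps = list(weekend = FALSE, holiday_frac = 0,
                                 long_gap_rate = 0), ...)
}
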