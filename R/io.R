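#' Serialize a transfer function to JSON
#'
#' Writes every coefficient and standard error of the air and water fits,
#' the ratios, and the fit metadata, so a fitted transfer function can be
#' handed between pipeline stages or sessions as plain text.
#'
#' @param tf A `transfer_function`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transfer_json <- function(tf, path) {
  stopifnot(inherits(tf, "transfer_function"))
  ser_fit <- function(f) {
    list(
      coefficients = f$coefficients,
      M = f$M, w = f$w, time_origin = format(f$time_origin),
      mode = f$mode, stage = f$stage, rmse = f$rmse, n = f$n,
      variable = f$variable,
      first_date = format(f$first_date), last_date = format(f$last_date)
    )
  }
  obj <- list(
    cr = tf$cr, sr = tf$sr, trend_ratio = tf$trend_ratio,
    M = tf$M, w = tf$w, time_origin = format(tf$time_origin), stage = tf$stage,
    water_base = ser_fit(tf$water_base), air_shape = ser_fit(tf$air_shape)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transfer function from JSON
#'
#' @param path Path written by [write_transfer_json()].
#' @return A `transfer_function`.
#' @export
read_transfer_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_fit <- function(f) {
    coefs <- tibble::as_tibble(f$coefficients)
    M <- as.integer(f$M)
    structure(
      list(
        coefficients = coefs,
        B0 = coefs$estimate[[1]], B1 = coefs$estimate[[2]],
        C = coefs$estimate[2 + 2 * seq_len(M) - 1],
        S = coefs$estimate[2 + 2 * seq_len(M)],
        M = M, w = f$w, time_origin = as.Date(f$time_origin),
        mode = f$mode, stage = f$stage, rmse = f$rmse, n = f$n,
        variable = f$variable,
        first_date = as.Date(f$first_date), last_date = as.Date(f$last_date)
      ),
      class = "harmonic_fit"
    )
  }
  structure(
    list(
      water_base = de_fit(obj$water_base), air_shape = de_fit(obj$air_shape),
      cr = obj$cr, sr = obj$sr, trend_ratio = obj$trend_ratio,
      M = as.integer(obj$M), w = obj$w,
      time_origin = as.Date(obj$time_origin), stage = obj$stage
    ),
    class = "transfer_function"
  )
}
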