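origin <- as.Date("2000-01-01")
w <- 2 * pi / 365.25

test_that("fit_harmonic recovers known coefficients", {
  dates <- origin + 0:(4 * 366)
  t <- as.numeric(dates - origin)

  # constant series: intercept only
  fit0 <- fit_harmonic(daily_series(dates, rep(10, length(t)), variable = "air"),
                       time_origin = origin)
  expect_equal(fit0$B0, 10, tolerance = 1e-9)
  expect_lt(max(abs(c(fit0$B1, fit0$C, fit0$S))), 1e-9)

  # noiseless generated series: exact recovery
  y <- 15 + 1e-4 * t + 10 * cos(w * t) + 2 * sin(w * t)
  fit <- fit_harmonic(daily_series(dates, y, variable = "air"), time_origin = origin)
  expect_equal(fit$B0, 15, tolerance = 1e-6)
  expect_equal(fit$B1, 1e-4, tolerance = 1e-6)
  expect_equal(unname(fit$C), 10, tolerance = 1e-6)
  expect_equal(unname(fit$S), 2, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)

  # AR(1) noise (sd 1.5, coefficient 0.8): estimates within 4 standard
  # errors after inflating the OLS errors by the analytic AR(1) factor
  # sqrt((1+phi)/(1-phi)), since OLS assumes independent errors
  set.seed(11)
  n <- 10000
  dates_l <- origin + 0:(n - 1)
  tl <- as.numeric(dates_l - origin)
  noise <- as.numeric(stats::filter(rnorm(n, sd = 1.5), 0.8, method = "recursive"))
  yl <- 15 + 1e-4 * tl + 10 * cos(w * tl) + 2 * sin(w * tl) + noise
  fitl <- fit_harmonic(daily_series(dates_l, yl, variable = "air"),
                       time_origin = origin)
  infl <- sqrt(1.8 / 0.2)
  truth <- c(15, 1e-4, 10, 2)
  err <- abs(fitl$coefficients$estimate - truth)
  expect_true(all(err < 4 * infl * fitl$coefficients$std.error))

  # shorter than two annual cycles is rejected
  expect_error(
    fit_harmonic(daily_series(origin + 0:500, rnorm(501), variable = "air"),
                 time_origin = origin),
    "two full annual cycles"
  )
})

test_that("calibration_split partitions reproducibly at the requested fraction", {
  s <- ds(rnorm(1000), start = "2000-01-01")
  sp <- calibration_split(s, fraction = 0.3, seed = 9)
  expect_equal(nrow(sp$calibration), 300)
  expect_equal(nrow(sp$validation), 700)
  expect_length(intersect(sp$calibration$date, sp$validation$date), 0)
  expect_setequal(c(sp$calibration$date, sp$validation$date), s$date)

  sp2 <- calibration_split(s, fraction = 0.3, seed = 9)
  expect_identical(sp$calibration$date, sp2$calibration$date)

  # empirical inclusion frequency of one fixed day over many seeded splits
  day <- s$date[[417]]
  hits <- vapply(1:400, function(seed) {
    day %in% calibration_split(s, 0.3, seed = seed)$calibration$date
  }, logical(1))
  expect_equal(mean(hits), 0.3, tolerance = 4 * sqrt(0.3 * 0.7 / 400))

  expect_error(calibration_split(s, fraction = 1.2, seed = 1), "in \\(0, 1\\)")
})

test_that("build_transfer forms element-wise coefficient ratios", {
  dates <- origin + 0:1500
  t <- as.numeric(dates - origin)
  air <- daily_series(dates, 14 + 5e-5 * t + 10 * cos(w * t) + 2 * sin(w * t),
                      variable = "air")
  afit <- fit_harmonic(air, time_origin = origin)

  # identical fits: all ratios one
  wfit <- afit; wfit$variable <- "water"
  tf <- build_transfer(afit, wfit)
  expect_equal(tf$cr, 1, tolerance = 1e-9)
  expect_equal(tf$sr, 1, tolerance = 1e-9)
  expect_equal(tf$trend_ratio, 1, tolerance = 1e-9)

  # forced division
  water <- daily_series(dates, 14 + 5e-5 * t + 9 * cos(w * t) + 1.8 * sin(w * t),
                        variable = "water")
  tf2 <- build_transfer(afit, fit_harmonic(water, time_origin = origin))
  expect_equal(tf2$cr, 0.9, tolerance = 1e-6)
  expect_equal(tf2$sr, 0.9, tolerance = 1e-6)

  # random coefficient sets match the element-wise division oracle
  set.seed(21)
  for (rep in 1:5) {
    ca <- runif(2, 2, 12); sa <- runif(2, 2, 12)
    cw <- runif(2, 2, 12); sw <- runif(2, 2, 12)
    a2 <- daily_series(dates, eval2(14, 5e-5, ca, sa, t), variable = "air")
    w2 <- daily_series(dates, eval2(14, 5e-5, cw, sw, t), variable = "water")
    tfr <- build_transfer(fit_harmonic(a2, M = 2, time_origin = origin),
                          fit_harmonic(w2, M = 2, time_origin = origin))
    expect_equal(tfr$cr, cw / ca, tolerance = 1e-6)
    expect_equal(tfr$sr, sw / sa, tolerance = 1e-6)
  }

  # near-zero air coefficient makes a ratio undefined
  flat <- daily_series(dates, 14 + 5e-5 * t + 0 * cos(w * t) + 2 * sin(w * t),
                       variable = "air")
  expect_error(build_transfer(fit_harmonic(flat, time_origin = origin), wfit),
               "ratio undefined")
})

test_that("predict_water applies the transfer equation", {
  dates <- origin + 0:2000
  t <- as.numeric(dates - origin)
  air <- daily_series(dates, 14 + 5e-5 * t + 10 * cos(w * t) + 2 * sin(w * t),
                      variable = "air")
  water <- daily_series(dates, 14.9 + 5e-5 * t + 9 * cos(w * t) + 1.8 * sin(w * t),
                        variable = "water")
  afit <- fit_harmonic(air, time_origin = origin)
  wfit <- fit_harmonic(water, time_origin = origin)
  tf <- build_transfer(afit, wfit)

  # identity: driving with the fit the ratios came from returns the water fit
  pred <- predict_water(tf, dates)
  expect_equal(pred$value, predict_harmonic(wfit, dates), tolerance = 1e-9)
  expect_equal(pred$variable[[1]], "water")
  expect_equal(unique(pred$provenance), "predicted")

  # known-ratio synthetic pair reproduced without noise
  expect_equal(pred$value, water$value, tolerance = 1e-6)

  # periodic up to trend: 4 years is an exact multiple of the 365.25-day period
  d1 <- origin + 3000 + 0:50
  d2 <- d1 + 1461
  p1 <- predict_water(tf, d1)$value
  p2 <- predict_water(tf, d2)$value
  expect_equal(p2 - p1, rep(wfit$B1 * 1461, 51), tolerance = 1e-8)

  expect_error(predict_water(tf, origin - 5), "predate")
})

test_that("validate_fit computes holdout RMSE", {
  dates <- origin + 0:1000
  t <- as.numeric(dates - origin)
  curve <- 14 + 1e-4 * t + 8 * cos(w * t)
  fit <- fit_harmonic(daily_series(dates, curve, variable = "water"),
                      time_origin = origin)

  hold <- daily_series(dates[1:100], curve[1:100], variable = "water")
  expect_equal(validate_fit(fit, hold), 0, tolerance = 1e-9)

  # residuals +1 and -1 on two days
  h2 <- daily_series(dates[1:2], curve[1:2] + c(1, -1), variable = "water")
  expect_equal(validate_fit(fit, h2), 1, tolerance = 1e-9)

  # gaussian residuals sd 2: RMSE concentrates at 2 (chi distribution)
  set.seed(31)
  h3 <- daily_series(origin + 0:4999,
                     predict_harmonic(fit, origin + 0:4999) + rnorm(5000, sd = 2),
                     variable = "water")
  expect_equal(validate_fit(fit, h3), 2, tolerance = 0.05)

  expect_error(validate_fit(fit, daily_series(dates[1], NA_real_,
                                              variable = "water")),
               "no observed values")
})

test_that("the calibration/validation/final protocol behaves on noiseless data", {
  sim <- generate_pair(noiseless_config())
  proto <- fit_transfer_protocol(sim$air, sim$water, seed = 3,
                                 time_origin = as.Date("2000-01-01"))
  # exactly specified model: both stages fit perfectly, and the final
  # model cannot be worse than the calibration-stage model
  expect_lt(proto$rmse_validation, 1e-6)
  expect_lte(proto$rmse_final, proto$rmse_validation + 1e-12)
  expect_equal(proto$transfer$cr, 0.95, tolerance = 1e-6)
  expect_equal(proto$transfer$sr, 0.95, tolerance = 1e-6)
  expect_equal(proto$transfer$stage, "final")
  expect_equal(proto$calibration_transfer$stage, "calibration")
})

test_that("transfer functions round-trip through JSON", {
  sim <- generate_pair(noiseless_config())
  proto <- fit_transfer_protocol(sim$air, sim$water, seed = 3,
                                 time_origin = as.Date("2000-01-01"))
  path <- withr::local_tempfile(fileext = ".json")
  write_transfer_json(proto$transfer, path)
  back <- read_transfer_json(path)
  expect_equal(back$cr, proto$transfer$cr)
  expect_equal(back$water_base$coefficients, proto$transfer$water_base$coefficients)
  d <- as.Date("2006-06-01") + 0:30
  expect_equal(predict_water(back, d)$value, predict_water(proto$transfer, d)$value)
})
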