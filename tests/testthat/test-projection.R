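origin <- as.Date("2000-01-01")
w <- 2 * pi / 365.25

make_tf <- function(b1 = 5e-5, end = "2007-12-31", tol = 1e-6) {
  sim <- generate_pair(noiseless_config(end = end, air = list(b1 = b1)))
  afit <- fit_harmonic(sim$air, time_origin = origin)
  wfit <- fit_harmonic(sim$water, time_origin = origin)
  build_transfer(afit, wfit, tol = tol)
}

test_that("extend_trend continues the fitted curve with its trend", {
  # no trend: projected windows repeat the historical climatology exactly
  # when the windows are a whole number of 365.25-day periods apart
  tf0 <- make_tf(b1 = 0, tol = 0)
  proj <- extend_trend(tf0, as.Date("2035-12-31"))
  ref <- predict_water(tf0, seq(as.Date("2001-01-01"), by = "day",
                                length.out = 1461))
  fut <- proj[proj$date %in% (ref$date + 1461 * 7), ]
  expect_equal(mean(fut$value), mean(ref$value), tolerance = 1e-9)

  # known trend: window means shift by B1 times the separation
  b1 <- 0.02 / 365.25 # +0.02 degC per year
  tf <- make_tf(b1 = b1)
  proj2 <- extend_trend(tf, as.Date("2060-12-31"))
  ref2 <- predict_water(tf, seq(as.Date("2001-01-01"), by = "day",
                                length.out = 1461))
  gap_days <- 1461 * 13
  fut2 <- proj2[proj2$date %in% (ref2$date + gap_days), ]
  expect_equal(mean(fut2$value) - mean(ref2$value), tf$water_base$B1 * gap_days,
               tolerance = 1e-6)

  expect_error(extend_trend(tf, as.Date("2001-01-01")), "must follow")
})

zero_se <- function(fit) {
  fit$coefficients$std.error <- rep(0, nrow(fit$coefficients))
  fit
}

test_that("resample_projections propagates coefficient uncertainty", {
  tf <- make_tf()
  end <- as.Date("2011-12-31")

  # all SDs zero: every member collapses onto the point projection
  tf0 <- tf
  tf0$air_shape <- zero_se(tf$air_shape)
  tf0$water_base <- zero_se(tf$water_base)
  ens0 <- resample_projections(tf0, n = 5, seed = 1, end_date = end)
  point <- extend_trend(tf, end)
  expect_equal(max(abs(ens0$summary$sd)), 0)
  expect_equal(ens0$summary$mean, point$value, tolerance = 1e-12)

  # only the water intercept uncertain: daily SD equals that SD everywhere
  tfb <- tf0
  tfb$water_base$coefficients$std.error[1] <- 0.5
  ensb <- resample_projections(tfb, n = 1000, seed = 2, end_date = end)
  expect_equal(mean(ensb$summary$sd), 0.5, tolerance = 0.05)
  expect_lt(diff(range(ensb$summary$sd)), 1e-9) # a pure level shift per member

  # ensemble mean converges on the point projection (3 x standard error)
  se_mean <- 0.5 / sqrt(1000)
  expect_lt(max(abs(ensb$summary$mean - point$value)), 3 * se_mean + 1e-9)

  # determinism under a fixed seed
  e1 <- resample_projections(tf, n = 10, seed = 7, end_date = end)
  e2 <- resample_projections(tf, n = 10, seed = 7, end_date = end)
  expect_identical(e1$members, e2$members)

  # missing standard errors are rejected
  tfn <- tf
  tfn$water_base$coefficients$std.error[2] <- NA
  expect_error(resample_projections(tfn, n = 5, seed = 1, end_date = end),
               "standard errors")
})

test_that("read_member_ensemble averages cell midpoints and screens members", {
  d <- as.Date("2050-01-01") + 0:9

  # single cell: midpoint of min and max
  one <- tibble::tibble(member = "m01", date = d[1], cell = "c1",
                        tmin = 10, tmax = 20)
  expect_equal(read_member_ensemble(one)$m01$value, 15)

  # three cells: mean of midpoints
  three <- tibble::tibble(member = "m01", date = d[1], cell = c("c1", "c2", "c3"),
                          tmin = c(9, 10, 11), tmax = c(19, 20, 21))
  expect_equal(read_member_ensemble(three)$m01$value, 15)

  # randomized grids equal the nested-loop oracle
  set.seed(41)
  tab <- tidyr::expand_grid(member = c("a", "b"), date = d, cell = c("c1", "c2"))
  tab$tmin <- runif(nrow(tab), 0, 10)
  tab$tmax <- tab$tmin + runif(nrow(tab), 0, 10)
  got <- read_member_ensemble(tab)
  for (m in c("a", "b")) {
    for (i in seq_along(d)) {
      rows <- tab[tab$member == m & tab$date == d[i], ]
      expect_equal(got[[m]]$value[got[[m]]$date == d[i]],
                   mean((rows$tmin + rows$tmax) / 2))
    }
  }

  # min > max drops the day with a warning
  bad <- tibble::tibble(member = "m01", date = d[1:2], cell = "c1",
                        tmin = c(10, 25), tmax = c(20, 20))
  expect_warning(gotb <- read_member_ensemble(bad), "min > max")
  expect_equal(nrow(gotb$m01), 1)

  # a member with too many missing days is rejected
  sparse <- tibble::tibble(member = rep(c("full", "holey"), each = 10),
                           date = rep(d, 2), cell = "c1",
                           tmin = 10, tmax = 20)
  sparse <- sparse[!(sparse$member == "holey" & sparse$date > d[5]), ]
  expect_warning(gots <- read_member_ensemble(sparse), "rejected")
  expect_named(gots, "full")
})

test_that("project_ensemble recovers member-specific warming", {
  tf <- make_tf()
  cfg <- noiseless_config(start = "2000-01-01", end = "2049-12-31")
  a <- cfg$air

  # members with known warming rates 2, 3, 4 degC/century
  rates <- c(2, 3, 4) / 36525
  dates <- seq(cfg$start, cfg$end, by = "day")
  t <- as.numeric(dates - origin)
  members <- lapply(rates, function(b1) {
    daily_series(dates, eval2(a$b0, b1, a$cos, a$sin, t), variable = "air")
  })
  names(members) <- paste0("r", 1:3)
  ens <- project_ensemble(tf, members)
  expect_equal(ens$n_members, 3)

  # closed-form target: continuity at the end of observations, then each
  # member's own water trend; compare member means over the last 4 years
  t_ref <- as.numeric(tf$water_base$last_date - origin)
  last4 <- ens$members[ens$members$date > cfg$end - 1461, ]
  for (i in 1:3) {
    got <- mean(last4$value[last4$member == names(members)[i]])
    b1w <- tf$trend_ratio * rates[i]
    days <- as.numeric(unique(last4$date) - origin)
    want <- tf$water_base$B0 + (tf$water_base$B1 - b1w) * t_ref +
      b1w * mean(days) + mean(eval2(0, 0, tf$cr * a$cos, tf$sr * a$sin, days))
    expect_equal(got, want, tolerance = 0.02)
  }

  # identical members: zero spread, mean equals the single-member projection
  same <- list(members[[1]], members[[1]], members[[1]])
  ens_same <- project_ensemble(tf, same)
  expect_equal(max(ens_same$summary$sd), 0)
  one <- project_ensemble(tf, members[1])
  expect_equal(ens_same$summary$mean, one$summary$mean)

  # permutation invariance of the summary
  ens_perm <- project_ensemble(tf, members[c(3, 1, 2)])
  expect_equal(ens_perm$summary$mean, ens$summary$mean, tolerance = 1e-12)
  expect_equal(ens_perm$summary$sd, ens$summary$sd, tolerance = 1e-12)

  # every projected series is gap-free over its declared range
  expect_false(any(is.na(ens$members$value)))
  expect_equal(unique(diff(as.numeric(ens$summary$date))), 1)
})
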