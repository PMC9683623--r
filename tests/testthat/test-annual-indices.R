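test_that("daily summaries compute per-day mean, max, and completeness", {
  stamps <- as.POSIXct("2005-06-01 00:00:00", tz = "UTC") + 0:23 * 3600
  d <- data.frame(location_id = "a", timestamp = stamps,
                  t_air_c = ((0:23) - 32) * 5 / 9,  # deg F values 0..23
                  hi_f = 80, wbgt_f = 70)
  s <- daily_summaries(d)
  tmp <- s[s$index_type == "temperature", ]
  expect_equal(tmp$daily_mean, 11.5)
  expect_equal(tmp$daily_max, 23)
  expect_equal(tmp$n_hours, 24)
  expect_true(tmp$complete)
  hi <- s[s$index_type == "heat_index", ]
  expect_equal(hi$daily_mean, 80)
  expect_equal(hi$daily_max, 80)

  # 20 of 24 hours at threshold 0.9 (>= 22 needed): flagged incomplete
  s20 <- daily_summaries(d[1:20, ])
  expect_false(any(s20$complete))
  s20b <- daily_summaries(d[1:20, ], completeness = 0.8)
  expect_true(all(s20b$complete))

  expect_error(daily_summaries(rbind(d, d[1, ])), "duplicate")
})

test_that("climatology keys by calendar day with sample SD", {
  # two baseline years, constant-by-day values 60 and 80
  der <- rbind(
    make_derived("a", 2001, function(doy, hour) rep(60, length(doy))),
    make_derived("a", 2002, function(doy, hour) rep(80, length(doy))))
  daily <- daily_summaries(der)
  clim <- build_climatology(daily, baseline_years = c(2001, 2002))
  tmp <- clim[clim$index_type == "temperature", ]
  expect_equal(nrow(tmp), 365)
  expect_equal(unique(tmp$clim_mean), 70)
  expect_equal(unique(tmp$clim_sd), sd(c(60, 80)))
  expect_equal(unique(tmp$n_years), 2)

  # a single baseline year leaves the SD undefined
  expect_error(build_climatology(daily, baseline_years = c(2001, 2001)),
               "fewer than 2")
})

test_that("Feb 29 forms its own climatology key from leap years only", {
  der <- rbind(
    make_derived("a", 2004, function(doy, hour) rep(50, length(doy))),
    make_derived("a", 2008, function(doy, hour) rep(54, length(doy))),
    make_derived("a", 2005, function(doy, hour) rep(70, length(doy))))
  daily <- daily_summaries(der)
  clim <- build_climatology(daily, baseline_years = c(2004, 2008))
  feb29 <- clim[clim$month == 2 & clim$day == 29 &
                  clim$index_type == "temperature", ]
  expect_equal(nrow(feb29), 1)
  expect_equal(feb29$n_years, 2)   # only the two leap years contribute
  expect_equal(feb29$clim_mean, 52)
})

test_that("annual statistics follow their strict-threshold semantics", {
  # hourly exceedance counts use strict > on hourly values
  stamps <- as.POSIXct("2005-07-01 00:00:00", tz = "UTC") + 0:2 * 3600
  hourly <- data.frame(location_id = "a", timestamp = stamps,
                       t_air_c = (c(89, 91, 92) - 32) * 5 / 9,
                       hi_f = 0, wbgt_f = 0)
  daily <- daily_summaries(hourly)
  spec <- data.frame(index_type = "temperature", statistic = "hours_above",
                     threshold_f = 90, window = "full_year")
  v <- compute_annual_index(daily, hourly, NULL, spec, 2005)
  expect_equal(v$value, 2)

  # constant 80 over the heat season
  der <- make_derived("a", 2005, function(doy, hour) rep(80, length(doy)))
  daily <- daily_summaries(der)
  spec <- data.frame(index_type = "temperature",
                     statistic = "mean_of_daily_mean", threshold_f = NA,
                     window = "heat_season")
  expect_equal(compute_annual_index(daily, der, NULL, spec, 2005)$value, 80)
})

test_that("days_above_1sd counts strictly above mean + 1 SD", {
  # one July day at 76 (counts) and one at 75 (tie at 70 + 5, does not)
  der <- make_derived("a", 2005, function(doy, hour) {
    ifelse(doy == 182, 76, ifelse(doy == 183, 75, 60))
  })
  daily <- daily_summaries(der)
  clim <- expand.grid(month = 1:12, day = 1:31)
  clim <- clim[clim$day <= c(31, 29, 31, 30, 31, 30, 31, 31, 30, 31, 30,
                             31)[clim$month], ]
  clim <- data.frame(location_id = "a", index_type = "temperature",
                     month = clim$month, day = clim$day, clim_mean = 70,
                     clim_sd = 5, n_years = 10)
  spec <- data.frame(index_type = "temperature",
                     statistic = "days_above_1sd", threshold_f = NA,
                     window = "full_year")
  expect_equal(compute_annual_index(daily, der, clim, spec, 2005)$value, 1)
  # zero-SD baseline: strictly above the mean counts
  clim0 <- clim; clim0$clim_sd <- 0
  expect_equal(compute_annual_index(daily, der, clim0, spec, 2005)$value, 2)
  # missing climatology for a needed day errors
  expect_error(compute_annual_index(daily, der, clim[-1, ], spec, 2005),
               "missing climatology")
})

test_that("a series equal to its own climatology has zero anomalies", {
  f <- function(doy, hour) 60 + 20 * cos(2 * pi * (doy - 196) / 365.25)
  der <- rbind(make_derived("a", 2001, f), make_derived("a", 2002, f))
  daily <- daily_summaries(der)
  clim <- build_climatology(daily, baseline_years = c(2001, 2002))
  spec <- data.frame(index_type = "temperature", statistic = "mean_anomaly",
                     threshold_f = NA, window = "full_year")
  for (y in 2001:2002) {
    expect_equal(compute_annual_index(daily, der, clim, spec, y)$value, 0,
                 tolerance = 1e-10)
  }
})

test_that("baseline-period anomalies average to zero by construction", {
  set.seed(5)
  offsets <- rnorm(3, sd = 3)
  # non-leap years only, so every calendar day has a full baseline
  der <- do.call(rbind, lapply(1:3, function(i) {
    make_derived("a", 2000 + i, function(doy, hour) {
      55 + 18 * cos(2 * pi * (doy - 196) / 365.25) + offsets[i]
    })
  }))
  daily <- daily_summaries(der)
  clim <- build_climatology(daily, baseline_years = c(2001, 2003))
  spec <- data.frame(index_type = "temperature", statistic = "mean_anomaly",
                     threshold_f = NA, window = "full_year")
  vals <- vapply(2001:2003, function(y) {
    compute_annual_index(daily, der, clim, spec, y)$value
  }, numeric(1))
  expect_equal(mean(vals), 0, tolerance = 1e-9)
})

test_that("the catalogue enumerates exactly the thirty indices", {
  cat_ <- annual_index_catalogue()
  expect_equal(nrow(cat_), 30)
  expect_equal(sum(cat_$statistic == "hours_above"), 6)
  expect_true(all(is.na(cat_$threshold_f) == (cat_$statistic != "hours_above")))
  # thresholds per index type
  thr <- function(it) sort(cat_$threshold_f[cat_$index_type == it &
                                              cat_$statistic == "hours_above"])
  expect_equal(thr("temperature"), c(90, 100))
  expect_equal(thr("heat_index"), c(90, 105))
  expect_equal(thr("wbgt"), c(85, 90))
  # hour counts are full-year only; every other statistic has both windows
  expect_true(all(cat_$window[cat_$statistic == "hours_above"] == "full_year"))
  expect_equal(sum(cat_$window == "heat_season"), 12)
})

test_that("compute_all_indices yields 30 rows per location-year", {
  f <- function(doy, hour) {
    60 + 25 * cos(2 * pi * (doy - 196) / 365.25) + 8 * cos(2 * pi * (hour - 15) / 24)
  }
  der <- do.call(rbind, lapply(c("a", "b"), function(l) {
    rbind(make_derived(l, 2001, f), make_derived(l, 2002, f))
  }))
  daily <- daily_summaries(der)
  clim <- build_climatology(daily, baseline_years = c(2001, 2002))
  ann <- compute_all_indices(der, clim, 2001:2002)
  expect_equal(nrow(ann), 120)
  expect_equal(nrow(ann[ann$location_id == "a" & ann$year == 2001, ]), 30)
  # empty input gives an empty result
  expect_equal(nrow(compute_all_indices(der[0, ], clim, 2001:2002)), 0)

  # invariants on the computed values
  wide <- ann[ann$statistic %in% c("mean_of_daily_mean", "mean_of_daily_max"), ]
  for (k in split(wide, paste(wide$location_id, wide$year, wide$index_type,
                              wide$window))) {
    expect_gte(k$value[k$statistic == "mean_of_daily_max"],
               k$value[k$statistic == "mean_of_daily_mean"])
  }
  hrs <- ann[ann$statistic == "hours_above", ]
  for (k in split(hrs, paste(hrs$location_id, hrs$year, hrs$index_type))) {
    k <- k[order(k$threshold_f), ]
    expect_true(all(diff(k$value) <= 0))
  }
})

test_that("window restriction commutes with aggregation", {
  f <- function(doy, hour) {
    58 + 22 * cos(2 * pi * (doy - 196) / 365.25) + 6 * cos(2 * pi * (hour - 15) / 24)
  }
  der <- rbind(make_derived("a", 2001, f), make_derived("a", 2002, f))
  daily <- daily_summaries(der)
  spec <- data.frame(index_type = "temperature",
                     statistic = "mean_of_daily_mean", threshold_f = NA,
                     window = "heat_season")
  full <- compute_annual_index(daily, der, NULL, spec, 2002)$value
  # restrict the input to May-September first, then aggregate
  m <- as.integer(format(as.Date(format(der$timestamp, "%Y-%m-%d")), "%m"))
  der_hs <- der[m >= 5 & m <= 9, ]
  restricted <- compute_annual_index(daily_summaries(der_hs), der_hs, NULL,
                                     spec, 2002)$value
  expect_equal(full, restricted)
})
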