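test_that("grid extent sums areas of cells strictly above 30% concentration", {
  expect_equal(grid_to_extent(c(0.20, 0.40, 0.31, 0.30), 25), 50)
  expect_equal(grid_to_extent(rep(0, 6), 25), 0)
  expect_equal(grid_to_extent(rep(1, 4), 12.5), 50)
  expect_error(grid_to_extent(numeric(0), 25), "empty")
  expect_error(grid_to_extent(c(0.5, 1.2), 25), "fraction")
})

test_that("transition threshold is the midpoint of the window climatologies", {
  yrs <- 1990:1999
  s <- segment_ice_series(yrs, list(c(1, 120, 150), c(121, 240, 90),
                                    c(241, 280, 50), c(281, 366, 150)))
  thr <- transition_threshold(s, reference_years = yrs)
  expect_equal(thr$value_km2, 100)          # (150 + 50) / 2
  expect_equal(thr$september_km2, 50)
  expect_equal(thr$march_km2, 150)

  flat <- segment_ice_series(yrs, list(c(1, 366, 70)))
  expect_equal(transition_threshold(flat, reference_years = yrs)$value_km2, 70)

  # linearly varying September {40,60} and March {140,160} means -> 100
  two <- rbind(
    as.data.frame(segment_ice_series(1990, list(c(1, 235, 140), c(236, 366, 40)))),
    as.data.frame(segment_ice_series(1991, list(c(1, 235, 160), c(236, 366, 60)))))
  two <- daily_ice_series(two$date, two$extent_km2)
  expect_equal(transition_threshold(two, reference_years = 1990:1991)$value_km2,
               100)

  expect_error(transition_threshold(s, reference_years = 1980:1989), "cover")
})

test_that("break-up is the 5th day of the first sustained sub-threshold run", {
  yr <- 2005
  s <- segment_ice_series(yr, list(c(1, 59, 120), c(60, 179, 120),
                                   c(180, 366, 80)))
  expect_equal(detect_breakup(s, 100, yr), 184)

  # a 4-day dip does not trigger; sustained drop from day 200 does
  dip <- segment_ice_series(yr, list(c(1, 149, 120), c(150, 153, 80),
                                     c(154, 199, 120), c(200, 366, 80)))
  expect_equal(detect_breakup(dip, 100, yr), 204)

  high <- segment_ice_series(yr, list(c(1, 366, 120)))
  expect_true(is.na(detect_breakup(high, 100, yr)))

  # first-day convention for sensitivity checks
  expect_equal(detect_breakup(s, 100, yr, convention = "first"), 180)

  # ties at the threshold never count towards a run
  tie <- segment_ice_series(yr, list(c(1, 179, 120), c(180, 366, 100)))
  expect_true(is.na(detect_breakup(tie, 100, yr)))
})

test_that("freeze-up scans past break-up and spills into the next year", {
  yr <- 2005
  s <- segment_ice_series(yr, list(c(1, 179, 120), c(180, 299, 80),
                                   c(300, 366, 120)))
  b <- detect_breakup(s, 100, yr)
  expect_equal(detect_freezeup(s, 100, yr, b), 304)

  # refreeze on 10 January of the next year: 375 after a non-leap year,
  # 376 after a leap break-up year
  for (case in list(c(2005, 375), c(2004, 376))) {
    y0 <- case[1]
    low <- rbind(
      as.data.frame(segment_ice_series(y0, list(c(1, 179, 120), c(180, 366, 80)))),
      as.data.frame(segment_ice_series(y0 + 1, list(c(1, 9, 80), c(10, 366, 120)))))
    low <- daily_ice_series(low$date, low$extent_km2)
    b0 <- detect_breakup(low, 100, y0)
    expect_equal(detect_freezeup(low, 100, y0, b0), case[2] + 4)
  }

  never <- segment_ice_series(yr:(yr + 1), list(c(1, 179, 120), c(180, 366, 80)))
  # year yr+1 also mostly below after day 180; never 5 days above after breakup?
  never2 <- segment_ice_series(yr:(yr + 1), list(c(1, 366, 80)))
  expect_true(is.na(detect_freezeup(never2, 100, yr, 184)))
  expect_true(is.na(detect_freezeup(s, 100, yr, NA)))
})

test_that("run detection matches an exhaustive window scan on random series", {
  set.seed(402)
  yr <- 2010
  dates <- seq(as.Date("2010-03-01"), by = "day", length.out = 306)
  for (rep in 1:50) {
    below <- runif(306) < runif(1, 0.2, 0.8)
    ext <- ifelse(below, 50, 150)
    s <- daily_ice_series(dates, ext)
    got <- detect_breakup(s, 100, yr)
    want <- brute_force_run(below, 5L)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want + 59L)  # series starts 1 March = doy 60
    }
  }
})

test_that("raising the threshold weakly advances break-up and delays freeze-up", {
  set.seed(403)
  dates <- seq(as.Date("2012-01-01"), as.Date("2013-12-31"), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  ext <- 100 + 60 * cospi(2 * (doy - 75) / 365) + rnorm(length(dates), 0, 6)
  s <- daily_ice_series(dates, pmax(ext, 0))
  thrs <- c(80, 100, 120)
  b <- vapply(thrs, function(t) detect_breakup(s, t, 2012), 1L)
  f <- vapply(thrs, function(t) detect_freezeup(s, t, 2012, b[2]), 1L)
  expect_true(all(diff(b) <= 0))
  expect_true(all(diff(f) >= 0))
})

test_that("short gaps are bridged, long gaps void candidate runs", {
  yr <- 2010
  base <- as.data.frame(segment_ice_series(yr, list(c(1, 179, 120), c(180, 366, 80))))
  # remove 2 days inside the first qualifying run: linear interpolation keeps
  # the run alive (interpolated values stay below threshold)
  drop2 <- base[!(as.POSIXlt(base$date)$yday + 1) %in% c(181, 182), ]
  s2 <- daily_ice_series(drop2$date, drop2$extent_km2)
  expect_equal(detect_breakup(s2, 100, yr), 184)
  # remove 4 days: the gap voids the run, detection shifts past the gap
  drop4 <- base[!(as.POSIXlt(base$date)$yday + 1) %in% 181:184, ]
  s4 <- daily_ice_series(drop4$date, drop4$extent_km2)
  expect_equal(detect_breakup(s4, 100, yr), 189)
})

test_that("ice-free days subtracts the transition dates and rejects inversions", {
  expect_equal(ice_free_days(184, 304), 120)
  expect_equal(ice_free_days(184, 375), 191)
  expect_true(is.na(ice_free_days(NA, 304)))
  expect_error(ice_free_days(184, 184), "strictly after")
})

test_that("annual covariate lagging shifts by whole years", {
  tab <- data.frame(year = 2000:2002, v = c(0.3, -0.2, 0.5))
  out <- lag_covariate(tab, "v", 1)
  expect_equal(out$v_lag1, c(NA, 0.3, -0.2))
  out0 <- lag_covariate(tab, "v", 0)
  expect_equal(out0$v_lag0, tab$v)
  expect_error(lag_covariate(rbind(tab, tab[1, ]), "v"), "duplicate")
})

test_that("AO covariates average the winter and spring windows", {
  monthly <- expand.grid(month = 1:12, year = 1999:2001)
  monthly$ao <- ifelse(monthly$year == 2000 & monthly$month %in% 10:12, 1,
                ifelse(monthly$year == 2001 & monthly$month == 1, 2,
                ifelse(monthly$year == 2001 & monthly$month %in% 4:6, 3,
                ifelse(monthly$year == 2000 & monthly$month %in% 4:6, -1, 0))))
  out <- ao_covariates(monthly, 2001)
  expect_equal(out$winter_ao, (1 + 1 + 1 + 2) / 4)  # Oct-Dec 2000 + Jan 2001
  expect_equal(out$spring_ao, 3)                    # Apr-Jun 2001
  expect_equal(out$spring_ao_lag1, -1)              # Apr-Jun 2000
  expect_error(ao_covariates(monthly, 1999), "missing months")
})
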