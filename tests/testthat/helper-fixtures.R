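# Shared fixtures: all data is generated in code at test time.

# Reduced-size simulated dataset, prepared for fitting.
small_sim_data <- function(seed = 11, n_bears = 60, sex = "F", ...) {
  cfg <- sim_config(seed = seed, sex = sex, n_bears = n_bears, ...)
  sim <- suppressWarnings(simulate_captures(cfg))
  list(config = cfg, sim = sim, data = suppressWarnings(prepare_sim_data(sim)))
}

# Fast fitting settings for tests: coarse smoother grids, small spatial
# basis, moderate draw cache.
quick_settings <- function(seed = 1, n_draws = 400, ...) {
  fit_settings(seed = seed, n_draws = n_draws, n_starts = 1, maxit = 300,
               n_basis = c(5, 5), n_bins = 8, max_integer_knots = 0, ...)
}

# Daily ice series with, for each year, constant extents per day-of-year
# segments. `segments` is a list of c(from_doy, to_doy, extent).
segment_ice_series <- function(years, segments) {
  rows <- lapply(years, function(y) {
    dates <- seq(as.Date(sprintf("%d-01-01", y)),
                 as.Date(sprintf("%d-12-31", y)), by = "day")
    doy <- as.POSIXlt(dates)$yday + 1L
    ext <- rep(NA_real_, length(dates))
    for (s in segments) ext[doy >= s[1] & doy <= s[2]] <- s[3]
    data.frame(date = dates, extent_km2 = ext)
  })
  d <- do.call(rbind, rows)
  d <- d[!is.na(d$extent_km2), ]
  daily_ice_series(d$date, d$extent_km2)
}

# Brute-force run detector: day-of-run index of the `run`th day of the
# first window of `run` consecutive TRUEs, scanning all windows.
brute_force_run <- function(cond, run = 5L) {
  cond[is.na(cond)] <- FALSE
  n <- length(cond)
  if (n < run) return(NA_integer_)
  for (i in seq_len(n - run + 1L)) {
    if (all(cond[i:(i + run - 1L)])) return(i + run - 1L)
  }
  NA_integer_
}
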