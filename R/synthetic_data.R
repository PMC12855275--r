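#' Configuration for the synthetic capture-study generator
#'
#' Bundles every parameter of the simulated study: the capture process
#' (bears, years, recapture probability), the generating truth (smooth year,
#' age and day effects; reproductive-class offsets; individual and residual
#' variances; spatial field), the climate/ice drivers (AO series, daily ice
#' extent with an earlier-break-up / later-freeze-up trend), and the
#' morphometric back-solve used to turn a target condition index into girth
#' and length measurements. The defaults describe the emulated study
#' conditions: captures 1995--2019 in spring (day 22--69, i.e. 22 March to
#' 8 May), adults aged 5--28, 1--8 captures per bear, longitudes 0--35 E and
#' latitudes 74--81 N, a U-shaped year effect dipping near 2000, an age
#' effect plateauing near age 12 (males) or 10 (females), a day effect
#' declining to mid-April, reproductive offsets Fy-Fc = 1.38 and
#' F-Fc = 1.58 with intercept -1.23 (females), and a spatial surface that is
#' low in the northwest and high in the southeast.
#'
#' @param seed integer seed; every simulation function derives its RNG
#'   stream from it.
#' @param sex `"M"` or `"F"` (one sex-specific dataset per call, mirroring
#'   the sex-separated analyses).
#' @param n_bears number of distinct bears captured at least once.
#' @param years capture years.
#' @param capture_prob per-available-year capture probability (each bear is
#'   guaranteed one capture; captures are capped at `max_captures`).
#' @param max_captures cap on captures per bear.
#' @param intercept baseline condition (for females, the Fc class).
#' @param repro_offsets named offsets for `Fc`, `Fy`, `F` (females).
#' @param f_year_amp,f_age_amp,f_day_amp amplitudes of the smooth effects
#'   (condition-index units).
#' @param sigma_bear,sigma individual random-intercept and residual
#'   standard deviations.
#' @param sp_sd,sp_range,sp_gradient marginal sd (index units), Matern
#'   range (km) and northwest-to-southeast gradient amplitude of the
#'   spatial surface.
#' @param day_range capture-day window (1 = 1 March).
#' @param ice_years years covered by the daily ice series (must include the
#'   1990--1999 reference decade and the year before the first capture).
#' @param ice_high,ice_low winter maximum and summer minimum extent, km^2.
#' @param breakup0,freezeup0 break-up / freeze-up day-of-year at the start
#'   of the study (freeze-up beyond 365 spills into the next calendar year).
#' @param breakup_advance,freezeup_delay total shift (days) of the two
#'   transition dates across the study period; their sum is the growth in
#'   ice-free days (default about 100 days).
#' @param ice_ramp_days length of the melt/freeze ramps.
#' @param breakup_jitter_sd,freezeup_jitter_sd interannual standard
#'   deviations (days) of the transition dates around their trends; real
#'   break-up and freeze-up dates vary by a few weeks between years, which
#'   also keeps the ice covariates from being deterministic functions of
#'   year.
#' @param ice_noise_sd,ice_ar AR(1) innovation sd (km^2) and coefficient of
#'   the daily extent noise.
#' @param ao_phi,ao_sd,ao_seasonal_amp monthly AO process: lag-1
#'   autocorrelation, marginal sd, and amplitude of the seasonal cycle.
#' @param length_inf,length_5,length_k,length_sd logistic-type growth curve
#'   for body length (asymptote, length at age 5, rate, residual sd in cm).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, sex = c("F", "M"), n_bears = 300L,
                       years = 1995:2019, capture_prob = 0.16,
                       max_captures = 8L,
                       intercept = NULL,
                       repro_offsets = c(Fc = 0, Fy = 1.38, F = 1.58),
                       f_year_amp = 0.5, f_age_amp = NULL, f_day_amp = 0.3,
                       sigma_bear = 0.6, sigma = 0.8,
                       sp_sd = 0.4, sp_range = 150, sp_gradient = 0.3,
                       day_range = c(22L, 69L),
                       ice_years = 1989:2020,
                       ice_high = 150e3, ice_low = 20e3,
                       breakup0 = 180L, freezeup0 = 310L,
                       breakup_advance = 35L, freezeup_delay = 65L,
                       ice_ramp_days = 20L,
                       breakup_jitter_sd = 18, freezeup_jitter_sd = 35,
                       ice_noise_sd = 2e3, ice_ar = 0.8,
                       ao_phi = 0.6, ao_sd = 1, ao_seasonal_amp = 0.2,
                       length_inf = NULL, length_5 = NULL,
                       length_k = 0.25, length_sd = 5) {
  sex <- match.arg(sex)
  if (is.null(intercept)) intercept <- if (sex == "F") -1.23 else 0
  if (is.null(f_age_amp)) f_age_amp <- if (sex == "M") 0.8 else 0.4
  if (is.null(length_inf)) length_inf <- if (sex == "M") 235 else 200
  if (is.null(length_5)) length_5 <- if (sex == "M") 210 else 185
  stopifnot(sigma > 0, sigma_bear >= 0, sp_sd >= 0,
            capture_prob > 0, capture_prob <= 1,
            length(seed) == 1L, is.finite(seed))
  structure(as.list(environment()), class = "sim_config")
}

#' Presets emulating the deposited study's sample structure
#'
#' The male dataset of the emulated study holds 524 captures of 330 bears,
#' the female one 664 captures of 440 bears; these presets set `n_bears`
#' and `capture_prob` accordingly (about 1.6 and 1.5 captures per bear).
#'
#' @param sex `"M"` or `"F"`.
#' @param seed integer seed.
#' @param ... further overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
study_config <- function(sex = c("M", "F"), seed = 1L, ...) {
  sex <- match.arg(sex)
  if (sex == "M") {
    sim_config(seed = seed, sex = "M", n_bears = 330L, capture_prob = 0.115, ...)
  } else {
    sim_config(seed = seed, sex = "F", n_bears = 440L, capture_prob = 0.105, ...)
  }
}

# --- generating truth: smooth functions -----------------------------------

# U-shaped year effect: sharp decline 1995 -> 2000, recovery over the next
# decade, mild variation after; centred to zero mean over the capture years.
true_year_effect <- function(year, config) {
  ctrl_x <- c(1994, 1995, 2000, 2005, 2010, 2019, 2020)
  ctrl_y <- c(0.62, 0.6, -0.6, -0.1, 0.45, 0.55, 0.55) / 0.6
  f <- stats::splinefun(ctrl_x, ctrl_y, method = "natural")
  v <- config$f_year_amp * f(year)
  v - mean(config$f_year_amp * f(config$years))
}

# Rise to a plateau (age ~12 males, ~10 females), slight old-age decline in
# males; centred over ages 5..28.
true_age_effect <- function(age, config) {
  plateau <- if (config$sex == "M") 12 else 10
  shape <- function(a) {
    v <- 1 - exp(-(a - 5) / ((plateau - 5) / 2))
    if (config$sex == "M") v <- v - 0.2 * pmax(a - 20, 0) / 8
    v
  }
  v <- config$f_age_amp * shape(age)
  v - mean(config$f_age_amp * shape(5:28))
}

# Decline from late March to a mid-April minimum (day 46), then a weaker
# rise; centred over the capture-day window.
true_day_effect <- function(day, config) {
  shape <- function(d) ((d - 46) / 24)^2 * ifelse(d > 46, 0.45, 1)
  grid <- seq(config$day_range[1], config$day_range[2])
  v <- config$f_day_amp * shape(day)
  v - mean(config$f_day_amp * shape(grid))
}

# --- climate and ice drivers ----------------------------------------------

#' Simulate a monthly Arctic Oscillation series
#'
#' Stationary AR(1) with marginal sd `ao_sd` and lag-1 autocorrelation
#' `ao_phi`, plus a fixed seasonal cycle of amplitude `ao_seasonal_amp`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to the config seed).
#' @param years years to simulate (defaults to `config$ice_years`).
#' @return data frame `year`, `month`, `ao`.
#' @export
simulate_ao_monthly <- function(config, seed = config$seed,
                                years = config$ice_years) {
  n <- 12L * length(years)
  with_seed(seed + 11L, function() {
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, config$ao_sd)
    innov_sd <- config$ao_sd * sqrt(1 - config$ao_phi^2)
    for (t in 2:n) {
      x[t] <- config$ao_phi * x[t - 1] + stats::rnorm(1, 0, innov_sd)
    }
    month <- rep(1:12, length(years))
    data.frame(year = rep(years, each = 12L), month = month,
               ao = x + config$ao_seasonal_amp * cospi(2 * (month - 1) / 12))
  })
}

# Transition-date truth per melt cycle: linear trends plus interannual
# jitter, clamped so that the March and September climatology windows of
# every cycle stay fully ice-covered / ice-free (which pins the derived
# transition threshold at the trapezoid midpoint). Integers, day-of-year of
# the cycle year; freeze-up may exceed 365.
ice_cycle_table <- function(config, seed = config$seed) {
  cyears <- (min(config$ice_years) - 1L):max(config$ice_years)
  span <- diff(range(config$years))
  frac <- pmin(pmax((cyears - config$years[1]) / span, 0), 1)
  jit <- with_seed(seed + 31L, function() {
    cbind(stats::rnorm(length(cyears), 0, config$breakup_jitter_sd),
          stats::rnorm(length(cyears), 0, config$freezeup_jitter_sd))
  })
  b <- round(config$breakup0 - config$breakup_advance * frac + jit[, 1])
  f <- round(config$freezeup0 + config$freezeup_delay * frac + jit[, 2])
  b <- pmin(pmax(b, 100L), 230L)
  f <- pmin(pmax(f, 290L), 410L)
  data.frame(year = cyears, breakup = b, freezeup = f)
}

# Noise-free extent for dates, built from per-cycle trapezoids whose ramps
# cross the (ice_high + ice_low)/2 midpoint exactly at the cycle dates.
ice_clean_extent <- function(dates, config, cycles) {
  lt <- as.POSIXlt(dates)
  year <- lt$year + 1900L
  doy <- lt$yday + 1L
  cycle <- ifelse(doy >= 60L, year, year - 1L)
  tau <- as.integer(dates - as.Date(sprintf("%d-01-01", cycle))) + 1L
  half <- config$ice_ramp_days / 2
  ext <- numeric(length(dates))
  for (cy in unique(cycle)) {
    cd <- as.list(cycles[match(cy, cycles$year), c("breakup", "freezeup")])
    sel <- cycle == cy
    t <- tau[sel]
    cover <- rep(1, length(t))
    cover[t > cd$breakup - half & t <= cd$breakup + half] <-
      1 - (t[t > cd$breakup - half & t <= cd$breakup + half] -
             (cd$breakup - half)) / config$ice_ramp_days
    cover[t > cd$breakup + half] <- 0
    rise <- t > cd$freezeup - half & t <= cd$freezeup + half
    cover[rise] <- (t[rise] - (cd$freezeup - half)) / config$ice_ramp_days
    cover[t > cd$freezeup + half] <- 1
    ext[sel] <- config$ice_low + (config$ice_high - config$ice_low) * cover
  }
  ext
}

#' Simulate a daily sea-ice extent series
#'
#' Per-year trapezoidal melt cycles whose midpoint crossings advance
#' (break-up) and recede (freeze-up) linearly over the study period,
#' emulating the observed lengthening of the ice-free season by about 100
#' days, plus AR(1) noise. The constructed crossing dates and the dates the
#' 5-consecutive-day detector recovers on the noise-free series are
#' recorded as truth.
#'
#' @inheritParams simulate_ao_monthly
#' @param noise add the AR(1) noise (disable for a noise-free series).
#' @return a [daily_ice_series()] with attribute `truth`: data frame of
#'   per-cycle crossing dates and their 5th-day detection equivalents.
#' @export
simulate_daily_ice <- function(config, seed = config$seed, noise = TRUE) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(config$ice_years))),
               as.Date(sprintf("%d-12-31", max(config$ice_years))), by = "day")
  cycles <- ice_cycle_table(config, seed)
  ext <- ice_clean_extent(dates, config, cycles)
  if (noise) {
    ext <- ext + with_seed(seed + 13L, function() {
      as.numeric(stats::arima.sim(list(ar = config$ice_ar), length(dates),
                                  sd = config$ice_noise_sd *
                                    sqrt(1 - config$ice_ar^2)))
    })
  }
  ext <- pmax(ext, 0)
  truth <- data.frame(year = cycles$year,
                      breakup_cross = cycles$breakup,
                      freezeup_cross = cycles$freezeup,
                      breakup_doy = cycles$breakup + 5L,
                      freezeup_doy = cycles$freezeup + 5L,
                      ice_free_days = cycles$freezeup - cycles$breakup)
  truth <- truth[truth$year %in% config$ice_years, ]
  rownames(truth) <- NULL
  out <- daily_ice_series(dates, ext)
  attr(out, "truth") <- truth
  out
}

#' Simulate the full covariate stack for a capture study
#'
#' Generates the monthly AO series and the daily ice series, then derives
#' the annual covariates exactly as the analysis pipeline would: the
#' transition threshold from the 1990--1999 reference decade of the
#' generated series, per-year break-up/freeze-up/ice-free-days from the
#' 5-consecutive-day detector, AO window means, and the one-year lags.
#' Ice-free days attached to a capture year refer to the preceding season.
#'
#' @inheritParams simulate_ao_monthly
#' @return list with `monthly_ao`, `daily_ice`, `threshold`, `phenology`,
#'   `annual` (capture-year covariate table keyed by `year`), and
#'   `truth_ice`.
#' @export
simulate_covariate_series <- function(config, seed = config$seed) {
  monthly <- simulate_ao_monthly(config, seed)
  ice <- simulate_daily_ice(config, seed)
  ref_years <- intersect(1990:1999, config$ice_years)
  thr <- transition_threshold(ice, reference_years = ref_years)
  phen_years <- (min(config$years) - 1L):max(config$years)
  phen <- ice_phenology(ice, thr, phen_years)
  ao <- ao_covariates(monthly, config$years)

  annual <- merge(ao, phen[c("year", "breakup_doy", "breakup_lag1")],
                  by = "year")
  names(annual)[names(annual) == "breakup_doy"] <- "breakup"
  # ice-free season preceding capture: previous year's record
  ifd <- lag_covariate(phen, "ice_free_days", k = 1,
                       new_name = "ice_free_days_prev")
  annual$ice_free_days <- ifd$ice_free_days_prev[match(annual$year, ifd$year)]
  list(monthly_ao = monthly, daily_ice = ice, threshold = thr,
       phenology = phen, annual = annual,
       truth_ice = attr(ice, "truth"))
}

# --- capture process ------------------------------------------------------

# Three-state reproductive cycle Fc -> Fy -> F -> Fc with litter loss and
# skipped breeding; rows are from-states, columns to-states.
repro_transition <- matrix(c(0.20, 0.50, 0.30,
                             0.30, 0.10, 0.60,
                             0.50, 0.05, 0.45),
                           3, 3, byrow = TRUE,
                           dimnames = list(c("Fc", "Fy", "F"),
                                           c("Fc", "Fy", "F")))

#' Simulate a capture dataset with known generating truth
#'
#' Draws a population of bears with persistent identities, random
#' intercepts and reproductive histories; samples their capture years, days
#' and locations; assembles the latent condition surface from the
#' configured truth (year/age/day effects, reproductive offsets, spatial
#' field, individual effects); draws the observed condition index; and
#' back-solves body length (from an age-sex growth curve), mass (from the
#' condition-index equation) and girth (from the mass regression) so that
#' recomputing the index from the morphometrics reproduces the generated
#' response exactly.
#'
#' @inheritParams simulate_ao_monthly
#' @return object of class `simulated_dataset`: list with `captures` (one
#'   row per capture, passing all capture-table validators with zero
#'   drops), `annual` (covariate table), `monthly_ao`, `daily_ice`, and
#'   `truth` (generating functions on their grids, offsets, variances,
#'   per-capture field values, per-bear effects, ice truth).
#' @export
simulate_captures <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  covs <- simulate_covariate_series(config, seed)

  caps <- with_seed(seed, function() {
    years <- config$years
    rows <- list()
    for (i in seq_len(config$n_bears)) {
      id <- sprintf("B%04d", i)
      y0 <- sample(years, 1)
      a0 <- sample(5:20, 1)
      avail <- seq(y0, min(max(years), y0 + 28L - a0))
      captured <- avail[stats::runif(length(avail)) < config$capture_prob]
      if (length(captured) == 0L) captured <- y0
      if (length(captured) > config$max_captures) {
        captured <- captured[seq_len(config$max_captures)]
      }
      state <- sample(c("Fc", "Fy", "F"), 1, prob = c(0.35, 0.25, 0.40))
      repro_by_year <- character(length(avail))
      for (k in seq_along(avail)) {
        repro_by_year[k] <- state
        state <- sample(colnames(repro_transition), 1,
                        prob = repro_transition[state, ])
      }
      span <- diff(range(years))
      for (y in captured) {
        frac <- (y - years[1]) / span
        day <- sample(seq(config$day_range[1], config$day_range[2]), 1)
        lon <- min(max(stats::rnorm(1, 26 - 10 * frac, 3.5), 0.5), 34.5)
        lat <- min(max(stats::rnorm(1, 76.3 + 1.6 * frac, 1.1), 74.2), 80.8)
        rows[[length(rows) + 1L]] <- data.frame(
          bear_id = id, year = y, day = day,
          date = as.Date(sprintf("%d-03-01", y)) + (day - 1L),
          sex = config$sex, age = a0 + (y - y0),
          repro = if (config$sex == "F") repro_by_year[match(y, avail)]
                  else NA_character_,
          lon = lon, lat = lat)
      }
    }
    out <- do.call(rbind, rows)
    out[order(out$year, out$bear_id), ]
  })
  rownames(caps) <- NULL

  bear_ids <- unique(caps$bear_id)
  bear_eff <- with_seed(seed + 21L, function() {
    stats::setNames(stats::rnorm(length(bear_ids), 0, config$sigma_bear),
                    bear_ids)
  })

  proj <- project_locations(caps$lon, caps$lat)
  sp_field <- with_seed(seed + 22L, function() {
    xy <- cbind(proj$x_km, proj$y_km)
    grad <- config$sp_gradient *
      (scale(xy[, 1])[, 1] - scale(xy[, 2])[, 1]) / sqrt(2)
    wiggle <- 0
    if (config$sp_sd > 0) {
      C <- config$sp_sd^2 * matern1_cov(as.matrix(stats::dist(xy)),
                                        config$sp_range)
      wiggle <- as.numeric(t(chol(C + diag(1e-8, nrow(C)))) %*%
                             stats::rnorm(nrow(C)))
    }
    grad + wiggle
  })

  off <- if (config$sex == "F") config$repro_offsets[caps$repro] else 0
  mu <- config$intercept +
    true_year_effect(caps$year, config) +
    true_age_effect(caps$age, config) +
    true_day_effect(caps$day, config) +
    as.numeric(off) + sp_field + bear_eff[caps$bear_id]
  bci <- with_seed(seed + 23L, function() {
    mu + stats::rnorm(length(mu), 0, config$sigma)
  })

  morph <- with_seed(seed + 24L, function() {
    n <- nrow(caps)
    bl <- numeric(n); g <- numeric(n)
    mean_bl <- config$length_inf -
      (config$length_inf - config$length_5) *
      exp(-config$length_k * (caps$age - 5))
    for (i in seq_len(n)) {
      for (try in 1:20) {
        bl_i <- min(max(stats::rnorm(1, mean_bl[i], config$length_sd), 120), 275)
        w_i <- weight_for_bci(bci[i], bl_i)
        g_i <- girth_for_weight(w_i, bl_i)
        if (g_i >= 50 && g_i <= 220) break
      }
      if (g_i < 50 || g_i > 220) {
        warning(sprintf("capture %d: back-solved girth %.1f cm outside plausible range",
                        i, g_i), call. = FALSE)
      }
      bl[i] <- bl_i; g[i] <- g_i
    }
    list(length_cm = bl, girth_cm = g)
  })
  caps$girth_cm <- morph$girth_cm
  caps$length_cm <- morph$length_cm
  if (config$sex == "F") caps$repro <- encode_reproductive_state(caps$repro)

  truth <- list(
    config = config,
    intercept = config$intercept,
    repro_offsets = config$repro_offsets,
    f_year = data.frame(year = config$years,
                        effect = true_year_effect(config$years, config)),
    f_age = data.frame(age = 5:28, effect = true_age_effect(5:28, config)),
    f_day = data.frame(
      day = seq(config$day_range[1], config$day_range[2]),
      effect = true_day_effect(seq(config$day_range[1], config$day_range[2]),
                               config)),
    sigma = config$sigma, sigma_bear = config$sigma_bear,
    bear_effects = bear_eff, spatial_field = sp_field, mu = mu,
    ice = covs$truth_ice)

  structure(list(captures = caps, annual = covs$annual,
                 monthly_ao = covs$monthly_ao, daily_ice = covs$daily_ice,
                 threshold = covs$threshold, phenology = covs$phenology,
                 truth = truth, seed = seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated capture dataset (%s): %d captures of %d bears, %d-%d\n",
    x$truth$config$sex, nrow(x$captures),
    length(unique(x$captures$bear_id)),
    min(x$captures$year), max(x$captures$year)))
  invisible(x)
}

#' Prepare a simulated dataset for model fitting
#'
#' Runs the standard preparation chain on a [simulate_captures()] result:
#' condition scores from the morphometrics, exclusion filters (a no-op on
#' generated data), annual covariate attachment, and location projection.
#'
#' @param sim a `simulated_dataset`.
#' @return data frame ready for [fit_model()] / [fit_all()].
#' @export
prepare_sim_data <- function(sim) {
  stopifnot(inherits(sim, "simulated_dataset"))
  d <- add_condition_scores(sim$captures)
  flt <- apply_exclusions(d)
  d <- attach_annual_covariates(flt$records, sim$annual)
  proj <- project_locations(d$lon, d$lat)
  d$x_km <- proj$x_km
  d$y_km <- proj$y_km
  d
}
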