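test_that("simulation is deterministic in the seed and structure-stable across seeds", {
  cfg <- sim_config(seed = 101, n_bears = 40)
  s1 <- suppressWarnings(simulate_captures(cfg))
  s2 <- suppressWarnings(simulate_captures(cfg))
  expect_identical(s1$captures, s2$captures)
  expect_identical(s1$annual, s2$annual)
  expect_identical(s1$truth$bear_effects, s2$truth$bear_effects)

  s3 <- suppressWarnings(simulate_captures(sim_config(seed = 102, n_bears = 40)))
  expect_false(identical(s1$captures$girth_cm, s3$captures$girth_cm))
  expect_identical(names(s1$truth), names(s3$truth))
  expect_identical(s1$truth$f_age$age, s3$truth$f_age$age)
})

test_that("morphometric back-solve closes the condition-index loop", {
  fx <- small_sim_data(seed = 103, n_bears = 50)
  recomputed <- body_condition_index(
    estimate_weight(fx$sim$captures$girth_cm, fx$sim$captures$length_cm),
    fx$sim$captures$length_cm)
  resid <- recomputed - fx$sim$truth$mu
  # generated response = truth mean + residual noise with the configured sd
  expect_lt(abs(sd(resid) - fx$config$sigma) / fx$config$sigma, 0.25)
  expect_equal(fx$data$bci, recomputed[order(fx$sim$captures$year,
                                             fx$sim$captures$bear_id)],
               tolerance = 1e-8)
})

test_that("generated captures satisfy the study-design constraints", {
  fx <- small_sim_data(seed = 104, n_bears = 120)
  caps <- fx$sim$captures
  expect_true(all(table(caps$bear_id) <= 8))
  expect_true(all(caps$age >= 5 & caps$age <= 28))
  expect_true(all(caps$year >= 1995 & caps$year <= 2019))
  expect_true(all(caps$day >= 22 & caps$day <= 69))
  expect_true(all(caps$lon >= 0 & caps$lon <= 35))
  expect_false(any(duplicated(caps[c("bear_id", "year")])))

  flt <- apply_exclusions(add_condition_scores(caps))
  expect_equal(sum(unlist(flt$report$n_dropped_by_rule)), 0)
})

test_that("bear-level random effects have the configured spread", {
  cfg <- sim_config(seed = 105, n_bears = 500)
  sim <- suppressWarnings(simulate_captures(cfg))
  expect_lt(abs(sd(sim$truth$bear_effects) - cfg$sigma_bear) / cfg$sigma_bear,
            0.15)
})

test_that("AO series has the configured lag-1 autocorrelation", {
  cfg <- sim_config(seed = 106, ao_seasonal_amp = 0,
                    ice_years = 1700:1999)   # 300 years of monthly values
  ao <- simulate_ao_monthly(cfg)
  expect_equal(nrow(ao), 300 * 12)
  rho <- cor(ao$ao[-1], ao$ao[-nrow(ao)])
  expect_lt(abs(rho - cfg$ao_phi), 0.1)
})

test_that("ice truth is internally consistent and recovered from clean series", {
  cfg <- sim_config(seed = 107)
  ice <- simulate_daily_ice(cfg, noise = FALSE)
  tr <- attr(ice, "truth")
  expect_equal(tr$ice_free_days, tr$freezeup_cross - tr$breakup_cross)
  expect_equal(tr$breakup_doy, tr$breakup_cross + 5L)

  thr <- transition_threshold(ice)
  ph <- ice_phenology(ice, thr, 1995:2019)
  m <- merge(ph, tr, by = "year")
  expect_equal(m$breakup_doy.x, m$breakup_doy.y)
  expect_equal(m$freezeup_doy.x, m$freezeup_doy.y)
  expect_equal(m$ice_free_days.x, m$ice_free_days.y)

  # the configured trend lengthens the late-study ice-free season by ~100 days
  expect_equal(mean(tr$ice_free_days[tr$year >= 2015]) -
                 mean(tr$ice_free_days[tr$year %in% 1990:1999]),
               cfg$breakup_advance + cfg$freezeup_delay, tolerance = 0.35)
})

test_that("annual covariates are derived from the ice series, not drawn independently", {
  cfg <- sim_config(seed = 108)
  covs <- simulate_covariate_series(cfg)
  expect_equal(covs$phenology$ice_free_days,
               covs$phenology$freezeup_doy - covs$phenology$breakup_doy)
  # capture-year ice-free days equal the previous season's record
  prev <- covs$phenology$ice_free_days[match(covs$annual$year - 1,
                                             covs$phenology$year)]
  expect_equal(covs$annual$ice_free_days, prev)
  # break-up lag is the previous capture year's break-up
  expect_equal(covs$annual$breakup_lag1[-1],
               covs$annual$breakup[-nrow(covs$annual)])
})
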