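# polarcond

Body-condition modelling for Svalbard polar bears: condition indices from
capture morphometrics, sea-ice phenology covariates from daily extent
series, and Bayesian Gaussian additive mixed models compared across a-priori
candidate structures.

## Who this is for

Quantitative ecologists analysing repeated capture data of a long-lived
mammal who need to (a) turn field morphometrics into a condition index,
(b) derive habitat phenology covariates from satellite-style daily series,
and (c) ask which combination of intrinsic (age, reproductive state, date)
and extrinsic (climate indices, ice phenology, location, year) drivers best
explains condition — with individual heterogeneity and spatial dependence
handled properly.

## The model

Condition of bear *i* at capture *j* is modelled as

    BCI_ij ~ N(mu_ij, sigma^2)
    mu_ij  = intercept + fixed effects + sum_k f_k(x_k,ij) + b_i + u(s_ij)

where the `f_k` are second-order random-walk (RW2) smoothers on discretized
covariate grids under penalized-complexity priors, `b_i ~ N(0, sigma_Bear^2)`
is a per-bear random intercept, and `u(s)` is a low-rank Matérn spatial
random field at the projected capture location. The condition index itself is

    W   = 0.00003377 * G^1.7515 * BL^1.3678          (girth G, length BL in cm)
    BCI = (ln W - 3.07 ln BL + 10.76) / (0.17 + 0.009 ln BL)

Because the likelihood is Gaussian, the latent field integrates out exactly;
`fit_model()` maximizes the hyperparameter posterior (empirical Bayes,
multi-start Nelder–Mead on log scales) and takes the exact Gaussian latent
conditional at the optimum. A seeded draws cache feeds DIC, WAIC and scaled
quantile residuals. `enumerate_candidates()` builds the 19 candidate model
structures per sex (all with the bear intercept; 4, 8a–c, 9a–c and 10 with
the spatial field; female models with reproductive state Fc/Fy/F), and
`fit_all()` ranks them by WAIC with DIC reported alongside.

Sea-ice covariates come from `transition_threshold()` (midpoint of the
September-minimum and March-maximum climatologies over a reference decade),
`detect_breakup()` / `detect_freezeup()` (five consecutive days strictly
below / above the threshold; freeze-up may run into the next calendar year)
and `ice_free_days()`. Arctic Oscillation covariates are window means
(winter: Oct–Jan; spring: Apr–Jun, plus a one-year lag).

A seeded synthetic-data generator (`simulate_captures()`) emulates the whole
study — capture process, reproductive-state dynamics, smooth effects,
spatial surface, AO and daily-ice drivers — and back-solves girth and length
from the generated index so every stage of the chain is testable end to end
with known truth.

## Worked example

```r
library(polarcond)

cfg  <- sim_config(seed = 1)          # default validation scenario, females
sim  <- simulate_captures(cfg)
data <- prepare_sim_data(sim)         # scores, filters, covariates, projection

fit <- fit_model(
  model_spec("F10", fixed = "repro", smoothers = c("year", "age", "day"),
             random_intercept = TRUE, spatial = TRUE),
  data,
  fit_settings(seed = 1, n_basis = c(6, 6)))
fit
#> F10: bci ~ 1 + repro + s(year) + s(age) + s(day) + (1 | bear) + SRF(x, y)
#>   n = 604, latent dim = 431, log posterior = -920.59
#>   hyperparameters: sigma = 0.8582, sigma_bear = 0.4953, sigma_year = 0.05757,
#>   sigma_age = 0.03429, sigma_day = 0.0009571, sigma_field = 0.5237, range = 460.8

predict_partial_effect(fit, "repro")
#>         value     mean         sd  lower95  upper95
#>            Fc 0.000000 0.00000000 0.000000 0.000000
#> reproFy    Fy 1.275460 0.10521858 1.069232 1.481689
#> reproF      F 1.486606 0.08833813 1.313464 1.659749
```

The generating truth here is `Fy − Fc = 1.38` and `F − Fc = 1.58`: both
recovered within two posterior standard deviations, and the estimated
residual and bear standard deviations (0.86, 0.50) sit close to the
generating values (0.8, 0.6). `compute_waic(fit)` gives `WAIC = 1658.6`
(`p_waic = 112.9`) for this fit; `quantile_residuals(fit, data, ...)`
summarizes model adequacy. `run_pipeline(pipeline_config(seed = 1), "out/")`
runs the full two-sex, 19-model comparison and writes tables plus a manifest
of seeds and file hashes.

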