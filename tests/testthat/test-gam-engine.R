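test_that("RW2 structure matrix has second-difference form and null space", {
  Q3 <- rw2_precision(3)
  expect_equal(unname(Q3), matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3))
  expect_equal(qr(Q3)$rank, 1)

  Q <- rw2_precision(12)
  expect_equal(qr(Q)$rank, 10)
  expect_equal(as.numeric(Q %*% rep(1, 12)), rep(0, 12), tolerance = 1e-12)
  expect_equal(as.numeric(Q %*% seq_len(12)), rep(0, 12), tolerance = 1e-10)
  expect_error(rw2_precision(2), "at least 3")
})

test_that("PC prior satisfies its tail calibration and matches its closed form", {
  pr <- pc_prior(u = 2, alpha = 0.05)
  # defining property P(scale > u) = alpha, by numeric integration
  surv <- integrate(function(s) exp(pc_prior_logdensity(s, pr)), 2, Inf)$value
  expect_equal(surv, 0.05, tolerance = 1e-6)
  expect_equal(pc_prior_logdensity(1.3, pr), dexp(1.3, pr$rate, log = TRUE))
  # alpha -> 1 flattens the prior (rate -> 0)
  expect_lt(pc_prior(2, 0.999)$rate, 0.001)
  # closed-form mean 1/rate against a large sampling oracle
  set.seed(501)
  expect_equal(mean(rexp(1e5, pr$rate)), 1 / pr$rate, tolerance = 0.02)
  expect_error(pc_prior(-1, 0.5), "positive")
  expect_error(pc_prior(1, 1.5), "alpha")
})

test_that("latent system dimensions follow the spec terms", {
  d <- data.frame(bci = rnorm(30), bear_id = rep(letters[1:10], 3),
                  age = rep(5:14, 3))
  s0 <- build_latent_system(model_spec("m", random_intercept = FALSE), d)
  expect_equal(sum(sapply(s0$blocks, `[[`, "size")), 1)  # intercept only

  st <- fit_settings(n_bins = 7, max_integer_knots = 0)
  s1 <- build_latent_system(model_spec("m", smoothers = "age",
                                       random_intercept = FALSE), d, st)
  sm <- Filter(function(b) b$type == "smoother", s1$blocks)[[1]]
  expect_equal(sm$size, 6)  # k knots -> k-1 sum-to-zero dimensions

  expect_error(model_spec("m", fixed = "age", smoothers = "age"), "aliased")
  d$dup <- d$age
  expect_error(build_latent_system(
    model_spec("m", fixed = c("age", "dup"), random_intercept = FALSE), d),
    "rank-deficient")
})

test_that("integrated likelihood matches quadrature on toy systems", {
  set.seed(600)
  vague_sd <- 2    # flat-ish intercept prior, chosen quadrature-friendly
  for (rep in 1:4) {
    # dim 1: intercept only
    y <- rnorm(5, rnorm(1, 0, 1), 0.9)
    d <- data.frame(bci = y, bear_id = "a")
    sys <- build_latent_system(model_spec("t", random_intercept = FALSE), d,
                               fit_settings(sigma_fixed = 0.9,
                                            vague_prec = 1 / vague_sd^2))
    expect_equal(log_marginal_posterior(list(sigma = 0.9), sys,
                                        include_priors = FALSE),
                 quadrature_marginal_loglik(y, matrix(1, 5, 1), vague_sd, 0.9),
                 tolerance = 1e-6)
    # dim 3: intercept + two-bear random intercept
    y3 <- rnorm(6, 1, 0.8)
    d3 <- data.frame(bci = y3, bear_id = rep(c("a", "b"), each = 3))
    sys3 <- build_latent_system(model_spec("t", random_intercept = TRUE), d3,
                                fit_settings(sigma_fixed = 0.8,
                                             vague_prec = 1 / vague_sd^2))
    sb <- runif(1, 0.3, 1.2)
    Z3 <- cbind(1, rep(c(1, 0), each = 3), rep(c(0, 1), each = 3))
    expect_equal(log_marginal_posterior(list(sigma = 0.8, sigma_bear = sb),
                                        sys3, include_priors = FALSE),
                 quadrature_marginal_loglik(y3, Z3, c(vague_sd, sb, sb), 0.8,
                                            nodes = c(90, 130)),
                 tolerance = 1e-6)
  }
})

test_that("latent conditional equals the dense GLS/Woodbury solution", {
  fx <- small_sim_data(seed = 31, n_bears = 40)
  d <- fx$data
  spec <- model_spec("m", fixed = "repro", smoothers = "age",
                     random_intercept = TRUE)
  # moderate vague/ridge precisions keep the covariance-route oracle
  # well-conditioned; the identity being checked is setting-independent
  st <- quick_settings(sigma_fixed = 0.8, vague_prec = 0.04, rw2_ridge = 1e-3)
  sys <- build_latent_system(spec, d, st)
  hyper <- list(sigma = 0.8, sigma_bear = 0.5, sigma_age = 0.3)

  ev <- polarcond:::eval_gaussian(sys, polarcond:::resolve_hyper(sys, hyper))

  # oracle: dense prior covariance blocks -> Woodbury posterior
  blocks <- sys$blocks
  Z <- as.matrix(do.call(cbind, lapply(blocks, `[[`, "Z")))
  Vs <- lapply(blocks, function(b) {
    switch(b$type,
           fixed = diag(25, b$size),
           smoother = solve((1 / hyper$sigma_age^2) *
                              (t(b$A) %*% rw2_precision(length(b$knots)) %*% b$A) +
                              diag(1e-3, b$size)),
           iid = diag(hyper$sigma_bear^2, b$size))
  })
  V <- as.matrix(Matrix::bdiag(Vs))
  oracle <- gls_posterior(sys$y, Z, V, hyper$sigma)
  expect_lt(max(abs(as.numeric(ev$m) - oracle$mean)), 1e-8)
  expect_lt(max(abs(chol2inv(ev$R) - oracle$cov)), 1e-8)
})

test_that("jointly rescaling response and scale hyperparameters rescales the posterior", {
  fx <- small_sim_data(seed = 32, n_bears = 30)
  d <- fx$data
  spec <- model_spec("m", fixed = "repro", random_intercept = TRUE)
  h1 <- list(sigma = 0.8, sigma_bear = 0.5)
  h2 <- list(sigma = 1.6, sigma_bear = 1.0)
  s1 <- build_latent_system(spec, d, fit_settings(sigma_fixed = 0.8))
  d2 <- d; d2$bci <- 2 * d$bci
  s2 <- build_latent_system(spec, d2, fit_settings(sigma_fixed = 1.6))
  m1 <- polarcond:::eval_gaussian(s1, polarcond:::resolve_hyper(s1, h1))$m
  m2 <- polarcond:::eval_gaussian(s2, polarcond:::resolve_hyper(s2, h2))$m
  expect_equal(2 * m1, m2, tolerance = 1e-6)
})

test_that("fitted smoothers respect the sum-to-zero constraint", {
  fx <- small_sim_data(seed = 33, n_bears = 50)
  fit <- fit_model(model_spec("m", fixed = "repro", smoothers = c("age", "day"),
                              random_intercept = TRUE),
                   fx$data, quick_settings(seed = 2))
  for (term in c("age", "day")) {
    pe <- predict_partial_effect(fit, term)
    expect_lt(abs(sum(pe$mean)), 1e-10)
  }
  pe_r <- predict_partial_effect(fit, "repro")
  expect_identical(pe_r$mean[1], 0)          # baseline contrast exactly zero
  expect_identical(pe_r$value[1], "Fc")
  expect_error(predict_partial_effect(fit, "no_such_term"), "unknown")
})

test_that("DIC effective parameters match the fixed-effect count under known variance", {
  set.seed(611)
  n <- 150
  d <- data.frame(bci = rnorm(n, 1 + 0.5 * rep(c(0, 1, 2), length.out = n), 0.7),
                  grp = factor(rep(c("a", "b", "c"), length.out = n)),
                  bear_id = sprintf("b%03d", seq_len(n)))
  fit <- fit_model(model_spec("m", fixed = "grp", random_intercept = FALSE),
                   d, fit_settings(seed = 3, sigma_fixed = 0.7, n_draws = 4000))
  dic <- compute_dic(fit)
  expect_equal(dic$p_d, 3, tolerance = 0.5)
})

test_that("WAIC matches a Monte-Carlo oracle on a conjugate toy", {
  set.seed(612)
  y <- c(0.4, -0.3, 1.1)
  sigma <- 0.6
  d <- data.frame(bci = y, bear_id = "a")
  fit <- fit_model(model_spec("m", random_intercept = FALSE), d,
                   fit_settings(seed = 5, sigma_fixed = sigma, n_draws = 4000,
                                vague_prec = 1))
  waic <- compute_waic(fit)

  # oracle: exact Gaussian posterior of the mean, huge MC sample
  post_prec <- 1 + length(y) / sigma^2
  post_mean <- sum(y) / sigma^2 / post_prec
  mu_s <- rnorm(1e6, post_mean, 1 / sqrt(post_prec))
  ll <- vapply(y, function(yi) dnorm(yi, mu_s, sigma, log = TRUE),
               numeric(1e6))
  lppd <- sum(apply(ll, 2, function(c) {
    m <- max(c); m + log(mean(exp(c - m)))
  }))
  p_mc <- sum(apply(ll, 2, var))
  expect_equal(waic$waic, -2 * (lppd - p_mc), tolerance = 0.01)
})

test_that("scaled quantile residuals are uniform when the model is right and flag regional shifts", {
  fx <- small_sim_data(seed = 34, n_bears = 80, sp_sd = 0, sp_gradient = 0)
  fit <- fit_model(model_spec("m", fixed = "repro", smoothers = "age",
                              random_intercept = TRUE),
                   fx$data, quick_settings(seed = 7))
  rr <- quantile_residuals(fit, fx$data, covariates = c("age", "repro"))
  expect_true(all(rr$residuals > 0 & rr$residuals < 1))
  expect_gt(rr$overall_ks_p, 0.01)
  expect_gt(rr$moran$p_value, 0.05)

  # shift one spatial corner of the response upward: Moran statistic reacts
  d2 <- fx$data
  shift <- d2$x_km > median(d2$x_km) & d2$y_km > median(d2$y_km)
  d2$bci <- d2$bci + 10 * shift
  fit2 <- fit_model(model_spec("m", fixed = "repro", random_intercept = TRUE),
                    d2, quick_settings(seed = 7))
  rr2 <- quantile_residuals(fit2, d2)
  expect_lt(rr2$moran$p_value, 0.05)
})

test_that("removing the spatial field matches the zero-variance field limit", {
  fx <- small_sim_data(seed = 35, n_bears = 40)
  d <- fx$data
  st <- quick_settings(sigma_fixed = 0.8)
  hyper0 <- list(sigma = 0.8, sigma_bear = 0.5)
  s_plain <- build_latent_system(model_spec("m", random_intercept = TRUE), d, st)
  s_sp <- build_latent_system(model_spec("m", random_intercept = TRUE,
                                         spatial = TRUE), d, st)
  v_plain <- log_marginal_posterior(hyper0, s_plain, include_priors = FALSE)
  v_sp <- log_marginal_posterior(c(hyper0, list(sigma_field = 1e-5, range = 100)),
                                 s_sp, include_priors = FALSE)
  expect_equal(v_plain, v_sp, tolerance = 1e-4)
})

test_that("smoother shapes agree with an independent penalized-spline fit", {
  skip_if_not_installed("mgcv")
  fx <- small_sim_data(seed = 37, n_bears = 200, sp_sd = 0, sp_gradient = 0,
                       sigma_bear = 0)
  d <- fx$data
  fit <- fit_model(model_spec("m", fixed = "repro", smoothers = "age",
                              random_intercept = FALSE),
                   d, quick_settings(seed = 8))
  pe <- predict_partial_effect(fit, "age")

  ref <- mgcv::gam(bci ~ repro + s(age, k = 8), data = d)
  ref_age <- predict(ref, newdata = data.frame(repro = factor("Fc", levels(d$repro)),
                                               age = pe$value),
                     type = "terms")[, "s(age)"]
  # same estimand up to centring; shapes must agree closely
  expect_gt(cor(pe$mean, as.numeric(ref_age)), 0.95)
  expect_lt(max(abs((pe$mean - mean(pe$mean)) -
                      (ref_age - mean(ref_age)))), 0.25)
})

test_that("fits are deterministic given data, spec and settings", {
  fx <- small_sim_data(seed = 36, n_bears = 30)
  spec <- model_spec("m", fixed = "repro", random_intercept = TRUE)
  f1 <- fit_model(spec, fx$data, quick_settings(seed = 9))
  f2 <- fit_model(spec, fx$data, quick_settings(seed = 9))
  expect_identical(f1$hyper, f2$hyper)
  expect_identical(f1$latent_mean, f2$latent_mean)
  expect_identical(compute_waic(f1), compute_waic(f2))
})
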