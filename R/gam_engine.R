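#' Structure matrix of a second-order random walk
#'
#' Returns the RW2 structure matrix \eqn{Q = D^T D}, where \eqn{D} is the
#' \eqn{(n-2) \times n} second-difference operator on a unit-spaced grid.
#' \eqn{Q} has rank \eqn{n - 2}; its null space is spanned by the constant
#' and the linear ramp, which is why RW2 smoothers shrink towards a straight
#' line rather than a constant.
#'
#' @param n_knots grid size (at least 3; smoother grids built by the package
#'   require at least 5 knots).
#' @return dense `n_knots x n_knots` structure matrix.
#' @export
rw2_precision <- function(n_knots) {
  if (n_knots < 3) {
    stop("RW2 structure needs at least 3 grid points", call. = FALSE)
  }
  D <- diff(diag(n_knots), differences = 2)
  crossprod(D)
}

#' Penalized-complexity prior on a standard deviation
#'
#' The PC prior for a scale parameter is exponential on the standard
#' deviation, calibrated through a tail statement \eqn{P(\sigma > u) =
#' \alpha}; the rate is \eqn{\lambda = -\ln(\alpha)/u}. It shrinks model
#' components towards their simpler base model (zero variance) at a
#' user-controlled rate.
#'
#' @param u scale bound, same units as the standard deviation.
#' @param alpha tail probability in (0, 1).
#' @return object of class `pc_prior`.
#' @export
pc_prior <- function(u, alpha = 0.01) {
  if (!is.finite(u) || u <= 0) stop("u must be positive", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(u = u, alpha = alpha, rate = -log(alpha) / u),
            class = "pc_prior")
}

#' Log density of a PC prior at a given scale
#'
#' @param scale standard deviation value(s), positive.
#' @param prior a [pc_prior()].
#' @return log prior density.
#' @export
pc_prior_logdensity <- function(scale, prior) {
  if (!inherits(prior, "pc_prior")) stop("not a pc_prior", call. = FALSE)
  if (any(scale <= 0)) stop("scale must be positive", call. = FALSE)
  stats::dexp(scale, rate = prior$rate, log = TRUE)
}

# PC-type prior for a Matern range: P(range < u) = alpha, density
# lambda * rho^-2 * exp(-lambda/rho) with lambda = -u * log(alpha).
pc_range_logdensity <- function(rho, u, alpha) {
  lambda <- -u * log(alpha)
  log(lambda) - 2 * log(rho) - lambda / rho
}

#' Fitting settings for the latent Gaussian engine
#'
#' @param seed integer seed controlling multi-start jitter and the posterior
#'   draws cache; recorded in the fit.
#' @param n_draws posterior draws cached for WAIC/DIC/residuals.
#' @param n_starts optimizer restarts (first start is data-driven, later
#'   ones jittered).
#' @param maxit optimizer iteration cap per start.
#' @param pc_u,pc_alpha PC-prior parameters shared by all standard-deviation
#'   hyperparameters; `pc_u = NULL` uses the empirical response standard
#'   deviation.
#' @param range_u,range_alpha PC-type prior on the Matern range;
#'   `range_u = NULL` uses 20% of the study-area diameter.
#' @param sigma_fixed if non-`NULL`, the residual standard deviation is held
#'   at this value instead of being estimated (used e.g. for known-variance
#'   checks).
#' @param n_basis integer length-2 grid of spatial basis points over the
#'   bounding box of the projected locations.
#' @param n_bins knot count for continuous (non-integer) smoother covariates.
#' @param max_integer_knots integer-valued covariates whose span exceeds this
#'   fall back to `n_bins` equally spaced knots.
#' @param vague_prec precision of the flat Gaussian prior on fixed effects.
#' @param rw2_ridge ridge added to each sum-to-zero-reduced RW2 precision
#'   block; makes the otherwise improper smoother prior proper (the retained
#'   linear null-space direction gets a vague proper prior), identical for
#'   every candidate model so information criteria remain comparable.
#' @return a `fit_settings` list.
#' @export
fit_settings <- function(seed = 1L, n_draws = 1000L, n_starts = 2L,
                         maxit = 400L, pc_u = NULL, pc_alpha = 0.01,
                         range_u = NULL, range_alpha = 0.05,
                         sigma_fixed = NULL, n_basis = c(10L, 10L),
                         n_bins = 20L, max_integer_knots = 80L,
                         vague_prec = 1e-6, rw2_ridge = 1e-8) {
  structure(list(seed = as.integer(seed), n_draws = as.integer(n_draws),
                 n_starts = as.integer(n_starts), maxit = as.integer(maxit),
                 pc_u = pc_u, pc_alpha = pc_alpha,
                 range_u = range_u, range_alpha = range_alpha,
                 sigma_fixed = sigma_fixed, n_basis = as.integer(n_basis),
                 n_bins = as.integer(n_bins),
                 max_integer_knots = as.integer(max_integer_knots),
                 vague_prec = vague_prec, rw2_ridge = rw2_ridge),
            class = "fit_settings")
}

#' Specify one candidate condition model
#'
#' @param name model label (e.g. `"M10"`).
#' @param fixed character vector of fixed-effect covariates (factors allowed;
#'   a global intercept is always included).
#' @param smoothers character vector of covariates modelled with RW2
#'   smoothers on a discretized grid.
#' @param random_intercept include a per-bear iid random intercept.
#' @param spatial include the low-rank Matern spatial random field over the
#'   projected capture locations (`x_km`, `y_km`).
#' @param response response column (default `"bci"`).
#' @param linear character subset of `smoothers` to demote to plain linear
#'   fixed effects (per-term override).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, fixed = character(), smoothers = character(),
                       random_intercept = TRUE, spatial = FALSE,
                       response = "bci", linear = character()) {
  if (length(bad <- setdiff(linear, smoothers))) {
    stop("linear override names terms not in smoothers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fixed <- c(fixed, linear)
  smoothers <- setdiff(smoothers, linear)
  if (length(dup <- intersect(fixed, smoothers))) {
    stop("covariate(s) aliased between fixed and smoother terms: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, fixed = fixed, smoothers = smoothers,
                 random_intercept = isTRUE(random_intercept),
                 spatial = isTRUE(spatial), response = response),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  terms <- c("1", x$fixed, if (length(x$smoothers)) paste0("s(", x$smoothers, ")"),
             if (x$random_intercept) "(1 | bear)", if (x$spatial) "SRF(x, y)")
  cat(sprintf("%s: %s ~ %s\n", x$name, x$response, paste(terms, collapse = " + ")))
  invisible(x)
}

# Orthonormal basis of the sum-to-zero subspace of R^k.
sum_to_zero_basis <- function(k) {
  qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
}

# Equally spaced smoother grid with nearest-knot incidence.
smoother_grid <- function(x, name, settings) {
  if (anyNA(x)) stop(sprintf("smoother covariate '%s' has missing values", name),
                     call. = FALSE)
  r <- range(x)
  if (r[2] - r[1] <= 0) {
    stop(sprintf("smoother covariate '%s' is constant", name), call. = FALSE)
  }
  integerish <- all(abs(x - round(x)) < 1e-8)
  if (integerish && (r[2] - r[1] + 1) <= settings$max_integer_knots) {
    knots <- seq(round(r[1]), round(r[2]))
  } else {
    knots <- seq(r[1], r[2], length.out = settings$n_bins)
  }
  if (length(knots) < 5) {
    stop(sprintf("smoother grid for '%s' has fewer than 5 knots", name),
         call. = FALSE)
  }
  idx <- vapply(x, function(v) which.min(abs(knots - v)), 1L)
  list(name = name, knots = knots, idx = idx)
}

# Matern covariance with smoothness nu = 1 (the alpha = 2 SPDE analogue),
# unit marginal variance.
matern1_cov <- function(d, range) {
  kappa <- sqrt(8) / range
  out <- kappa * d * besselK(kappa * d, 1)
  out[d < 1e-12] <- 1
  out
}

#' Assemble the joint latent Gaussian system for a model specification
#'
#' Builds the design incidence and prior-precision structure for all model
#' components: a dense fixed-effect design (intercept plus fixed terms,
#' checked for rank), sum-to-zero-reparameterised RW2 smoother blocks on
#' their discretized grids, the per-bear iid intercept incidence, and -- when
#' the spec carries a spatial field -- the projected capture locations and
#' basis-point grid for the low-rank Matern field (whose design depends on
#' the range hyperparameter and is therefore assembled lazily at evaluation
#' time).
#'
#' @param spec a [model_spec()].
#' @param data prepared capture data frame (covariates attached; `x_km`,
#'   `y_km` present when `spec$spatial`).
#' @param settings a [fit_settings()].
#' @return object of class `latent_system`.
#' @export
build_latent_system <- function(spec, data, settings = fit_settings()) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  y <- data[[spec$response]]
  if (is.null(y) || anyNA(y)) {
    stop(sprintf("response '%s' missing or incomplete", spec$response),
         call. = FALSE)
  }
  n <- length(y)
  for (v in c(spec$fixed, spec$smoothers)) {
    if (is.null(data[[v]])) {
      stop(sprintf("covariate '%s' not found in data", v), call. = FALSE)
    }
  }

  # fixed design: global intercept + fixed terms (factors expand to contrasts)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  factor_levels <- list()
  for (v in spec$fixed) {
    xv <- data[[v]]
    if (is.factor(xv) || is.character(xv)) {
      xv <- if (is.factor(xv)) droplevels(xv) else factor(xv)
      factor_levels[[v]] <- levels(xv)
      mm <- stats::model.matrix(~x, data.frame(x = xv))[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, levels(xv)[-1])
      X <- cbind(X, mm)
    } else {
      xm <- matrix(as.numeric(xv), ncol = 1, dimnames = list(NULL, v))
      X <- cbind(X, xm)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  blocks <- list(list(type = "fixed", label = "fixed", Z = Matrix::Matrix(X, sparse = TRUE),
                      size = ncol(X), coef_names = colnames(X)))

  for (v in spec$smoothers) {
    g <- smoother_grid(data[[v]], v, settings)
    k <- length(g$knots)
    A <- sum_to_zero_basis(k)
    Inc <- Matrix::sparseMatrix(i = seq_len(n), j = g$idx, x = 1,
                                dims = c(n, k))
    Qs <- crossprod(A, rw2_precision(k) %*% A)   # (k-1) x (k-1), still rank k-2
    blocks[[length(blocks) + 1L]] <- list(
      type = "smoother", label = v, Z = Inc %*% A, size = k - 1L,
      A = A, knots = g$knots, Qstruct = Qs,
      coef_names = paste0("s(", v, ").", seq_len(k - 1L)))
  }

  if (spec$random_intercept) {
    bear <- factor(data$bear_id)
    Zb <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(bear), x = 1,
                               dims = c(n, nlevels(bear)))
    blocks[[length(blocks) + 1L]] <- list(
      type = "iid", label = "bear", Z = Zb, size = nlevels(bear),
      levels = levels(bear),
      coef_names = paste0("bear.", levels(bear)))
  }

  spatial <- NULL
  if (spec$spatial) {
    if (is.null(data$x_km) || is.null(data$y_km)) {
      stop("spatial spec needs projected coordinates x_km/y_km (see project_locations)",
           call. = FALSE)
    }
    coords <- cbind(data$x_km, data$y_km)
    bb <- apply(coords, 2, range)
    pad <- 0.05 * pmax(bb[2, ] - bb[1, ], 1)
    gx <- seq(bb[1, 1] - pad[1], bb[2, 1] + pad[1],
              length.out = settings$n_basis[1])
    gy <- seq(bb[1, 2] - pad[2], bb[2, 2] + pad[2],
              length.out = settings$n_basis[2])
    basis <- as.matrix(expand.grid(x = gx, y = gy))
    m <- nrow(basis)
    blocks[[length(blocks) + 1L]] <- list(
      type = "spatial", label = "location", Z = NULL, size = m - 1L,
      A = sum_to_zero_basis(m),
      coef_names = paste0("srf.", seq_len(m - 1L)))
    spatial <- list(coords = coords, basis = basis,
                    d_om = as.matrix(stats::dist(rbind(coords, basis)))[
                      seq_len(n), n + seq_len(m), drop = FALSE],
                    d_mm = as.matrix(stats::dist(basis)))
  }

  hyper_names <- c(
    if (is.null(settings$sigma_fixed)) "sigma",
    if (spec$random_intercept) "sigma_bear",
    if (length(spec$smoothers)) paste0("sigma_", spec$smoothers),
    if (spec$spatial) c("sigma_field", "range"))

  pc_u <- if (is.null(settings$pc_u)) max(stats::sd(y), 1e-3) else settings$pc_u
  range_u <- settings$range_u
  if (spec$spatial && is.null(range_u)) {
    range_u <- 0.2 * max(spatial$d_mm)
  }

  # design caches: the non-spatial blocks (always the leading ones) are
  # hyperparameter-free, so their Gram matrix and projections are fixed
  Z0 <- do.call(cbind, lapply(Filter(function(b) b$type != "spatial", blocks),
                              `[[`, "Z"))
  cache <- list(Z0 = Z0, G0 = as.matrix(Matrix::crossprod(Z0)),
                b0 = as.numeric(Matrix::crossprod(Z0, y)), yty = sum(y^2))

  structure(list(y = y, n = n, spec = spec, blocks = blocks,
                 factor_levels = factor_levels,
                 spatial = spatial, hyper_names = hyper_names,
                 settings = settings, cache = cache, p0 = ncol(Z0),
                 pc = pc_prior(pc_u, settings$pc_alpha),
                 range_u = range_u, range_alpha = settings$range_alpha),
            class = "latent_system")
}

#' @export
print.latent_system <- function(x, ...) {
  cat(sprintf("latent Gaussian system: n = %d, latent dim = %d\n",
              x$n, sum(vapply(x$blocks, `[[`, 0L, "size"))))
  for (b in x$blocks) cat(sprintf("  %-9s %-12s dim %d\n", b$type, b$label, b$size))
  cat("  hyperparameters:", paste(x$hyper_names, collapse = ", "), "\n")
  invisible(x)
}

latent_dim <- function(sys) sum(vapply(sys$blocks, `[[`, 0L, "size"))

# Resolve the full natural-scale hyperparameter list (filling in a fixed
# residual sd when the settings pin it).
resolve_hyper <- function(sys, hyper) {
  hyper <- as.list(hyper)
  if (!is.null(sys$settings$sigma_fixed)) hyper$sigma <- sys$settings$sigma_fixed
  needed <- unique(c("sigma", sys$hyper_names))
  if (length(miss <- setdiff(needed, names(hyper)))) {
    stop("missing hyperparameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  hyper
}

# Core Gaussian evaluation at fixed hyperparameters: posterior precision is
# assembled densely (prior blocks plus scaled Gram matrix), its Cholesky
# yields the integrated likelihood, the posterior mean, and -- for fit
# extraction -- the posterior covariance and the spatial design. Prior
# log-determinants are accumulated block-wise (each block is small or
# diagonal), avoiding any large sparse factorization.
eval_gaussian <- function(sys, hyper) {
  sigma2 <- hyper$sigma^2
  p0 <- sys$p0
  p <- latent_dim(sys)
  Qpost <- matrix(0, p, p)
  Qpost[seq_len(p0), seq_len(p0)] <- sys$cache$G0 / sigma2
  b <- numeric(p)
  b[seq_len(p0)] <- sys$cache$b0 / sigma2
  ld_p <- 0
  Bs <- NULL
  off <- 0L
  for (blk in sys$blocks) {
    idx <- off + seq_len(blk$size)
    if (blk$type == "fixed") {
      Qpost[cbind(idx, idx)] <- Qpost[cbind(idx, idx)] + sys$settings$vague_prec
      ld_p <- ld_p + blk$size * log(sys$settings$vague_prec)
    } else if (blk$type == "smoother") {
      tau <- 1 / hyper[[paste0("sigma_", blk$label)]]^2
      Qb <- tau * blk$Qstruct + sys$settings$rw2_ridge * diag(blk$size)
      ld_p <- ld_p + 2 * sum(log(diag(chol(Qb))))
      Qpost[idx, idx] <- Qpost[idx, idx] + Qb
    } else if (blk$type == "iid") {
      tau <- 1 / hyper$sigma_bear^2
      Qpost[cbind(idx, idx)] <- Qpost[cbind(idx, idx)] + tau
      ld_p <- ld_p + blk$size * log(tau)
    } else {  # spatial (always the trailing block)
      m <- nrow(sys$spatial$basis)
      C_mm <- matern1_cov(sys$spatial$d_mm, hyper$range)
      C_om <- matern1_cov(sys$spatial$d_om, hyper$range)
      Cinv_A <- solve(C_mm + diag(1e-8, m), blk$A)
      Bs <- C_om %*% Cinv_A
      Qb <- (1 / hyper$sigma_field^2) * crossprod(blk$A, Cinv_A)
      Qb <- (Qb + t(Qb)) / 2
      ld_p <- ld_p + 2 * sum(log(diag(chol(Qb))))
      Qpost[idx, idx] <- Qpost[idx, idx] + Qb + crossprod(Bs) / sigma2
      cross <- as.matrix(Matrix::crossprod(sys$cache$Z0, Bs)) / sigma2
      Qpost[seq_len(p0), idx] <- Qpost[seq_len(p0), idx] + cross
      Qpost[idx, seq_len(p0)] <- Qpost[idx, seq_len(p0)] + t(cross)
      b[idx] <- colSums(Bs * sys$y) / sigma2
    }
    off <- off + blk$size
  }
  R <- chol(Qpost)
  ld_post <- 2 * sum(log(diag(R)))
  m_post <- backsolve(R, backsolve(R, b, transpose = TRUE))
  quad <- sys$cache$yty / sigma2 - sum(b * m_post)
  lml <- -sys$n / 2 * log(2 * pi * sigma2) +
    0.5 * (ld_p - ld_post) - 0.5 * quad
  list(lml = lml, R = R, m = m_post, Bs = Bs)
}

#' Log marginal posterior of the hyperparameters
#'
#' Integrates the latent Gaussian field out analytically: for Gaussian
#' observations \eqn{y \mid u \sim N(Zu, \sigma^2 I)} with latent prior
#' \eqn{u \sim N(0, Q_p^{-1})},
#' \deqn{\log p(y \mid \theta) = -\tfrac{n}{2}\log(2\pi\sigma^2)
#'   + \tfrac12\log|Q_p| - \tfrac12\log|Q_p + Z^TZ/\sigma^2|
#'   - \tfrac12\big(y^Ty/\sigma^2 - b^T m\big)}
#' with \eqn{b = Z^Ty/\sigma^2} and posterior mean \eqn{m}. With
#' `include_priors = TRUE` the PC hyperprior log densities are added,
#' giving the (unnormalised) log hyperparameter posterior. No sampling is
#' involved; in the Gaussian-likelihood regime this is exact.
#'
#' @param hyper named list/vector of natural-scale hyperparameters
#'   (`sigma`, `sigma_bear`, `sigma_<term>`, `sigma_field`, `range` as the
#'   spec requires).
#' @param system a [build_latent_system()] result.
#' @param include_priors add the hyperprior log densities.
#' @return scalar log density.
#' @export
log_marginal_posterior <- function(hyper, system, include_priors = TRUE) {
  hyper <- resolve_hyper(system, hyper)
  if (any(unlist(hyper) <= 0)) {
    stop("all hyperparameter scales must be positive", call. = FALSE)
  }
  val <- tryCatch(eval_gaussian(system, hyper)$lml,
                  error = function(e) NA_real_)
  if (include_priors) {
    for (nm in system$hyper_names) {
      val <- val + if (nm == "range") {
        pc_range_logdensity(hyper$range, system$range_u, system$range_alpha)
      } else {
        pc_prior_logdensity(hyper[[nm]], system$pc)
      }
    }
  }
  if (!is.finite(val)) {
    stop("non-finite log marginal posterior at hyper = ",
         paste(sprintf("%s=%.4g", names(hyper), unlist(hyper)), collapse = ", "),
         call. = FALSE)
  }
  val
}

# Run fn with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Fit a condition model by empirical-Bayes maximization
#'
#' Maximizes the log hyperparameter posterior ([log_marginal_posterior()])
#' over the log-scale hyperparameters with a multi-start Nelder--Mead search,
#' then takes the exact Gaussian conditional of the latent field at the
#' optimum. For a Gaussian likelihood this latent conditional is exact, so
#' the approximation rests only on the plug-in treatment of the (few)
#' hyperparameters. A cache of posterior draws (seeded, size
#' `settings$n_draws`) is stored for WAIC/DIC and residual diagnostics. The
#' whole procedure is deterministic given `data`, `spec` and `settings`.
#'
#' @param spec a [model_spec()].
#' @param data prepared capture data frame.
#' @param settings a [fit_settings()].
#' @return object of class `pc_fit` with latent means/sds, hyperparameter
#'   estimates, pointwise log predictive densities and the draws cache.
#' @export
fit_model <- function(spec, data, settings = fit_settings()) {
  sys <- build_latent_system(spec, data, settings)
  free <- sys$hyper_names
  y <- sys$y

  theta_to_hyper <- function(theta) {
    h <- as.list(exp(theta))
    names(h) <- free
    h
  }
  neg_obj <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 20)) return(1e10)
    val <- tryCatch(log_marginal_posterior(theta_to_hyper(theta), sys),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else -val
  }

  if (length(free)) {
    sd_y <- max(stats::sd(y), 1e-3)
    init <- log(vapply(free, function(nm) {
      switch(nm,
             sigma = 0.8 * sd_y, sigma_bear = 0.5 * sd_y,
             sigma_field = 0.5 * sd_y,
             range = if (is.null(sys$range_u)) 1 else sys$range_u,
             0.5 * sd_y)
    }, 0))
    starts <- list(init)
    if (settings$n_starts > 1) {
      jit <- with_seed(settings$seed + 1000L, function() {
        lapply(seq_len(settings$n_starts - 1L),
               function(i) init + stats::rnorm(length(init), 0, 0.7))
      })
      starts <- c(starts, jit)
    }
    best <- NULL
    trace <- list()
    for (s in starts) {
      opt <- stats::optim(s, neg_obj, method = "Nelder-Mead",
                          control = list(maxit = settings$maxit,
                                         reltol = 1e-8))
      trace[[length(trace) + 1L]] <- c(value = -opt$value, opt$par)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (!is.finite(best$value) || best$value >= 1e10) {
      stop("hyperparameter optimization failed to find a finite optimum; trace: ",
           paste(vapply(trace, function(t) sprintf("%.3f", t["value"]), ""),
                 collapse = ", "), call. = FALSE)
    }
    hyper <- theta_to_hyper(best$par)
    log_post <- -best$value
  } else {
    hyper <- list()
    log_post <- log_marginal_posterior(hyper, sys)
  }
  hyper <- resolve_hyper(sys, hyper)

  ev <- eval_gaussian(sys, hyper)
  m <- ev$m
  Sigma <- chol2inv(ev$R)
  sds <- sqrt(pmax(diag(Sigma), 0))

  coef_names <- unlist(lapply(sys$blocks, `[[`, "coef_names"))
  names(m) <- names(sds) <- coef_names

  # full design at the optimum (spatial columns depend on the fitted range)
  Z <- if (is.null(ev$Bs)) sys$cache$Z0 else cbind(sys$cache$Z0, ev$Bs)

  # draws u = m + R^{-1} z have covariance Qpost^{-1}
  S <- settings$n_draws
  draws <- with_seed(settings$seed, function() {
    m + backsolve(ev$R, matrix(stats::rnorm(length(m) * S), length(m), S))
  })
  mu_draws <- as.matrix(Z %*% draws)
  loglik <- stats::dnorm(y, mu_draws, hyper$sigma, log = TRUE)
  mu_mean <- as.numeric(Z %*% m)

  structure(list(spec = spec, system = sys, hyper = hyper,
                 latent_mean = m, latent_sd = sds, latent_cov = Sigma,
                 mu_mean = mu_mean, mu_draws = mu_draws, loglik = loglik,
                 log_posterior = log_post, seed = settings$seed,
                 n_draws = S, settings = settings),
            class = "pc_fit")
}

#' @export
print.pc_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  n = %d, latent dim = %d, log posterior = %.2f\n",
              x$system$n, length(x$latent_mean), x$log_posterior))
  h <- unlist(x$hyper)
  cat("  hyperparameters:",
      paste(sprintf("%s = %.4g", names(h), h), collapse = ", "), "\n")
  invisible(x)
}

# Index range of a block in the latent vector.
block_index <- function(sys, label) {
  sizes <- vapply(sys$blocks, `[[`, 0L, "size")
  labels <- vapply(sys$blocks, `[[`, "", "label")
  j <- match(label, labels)
  if (is.na(j)) stop(sprintf("no model term '%s'", label), call. = FALSE)
  offset <- if (j == 1) 0L else sum(sizes[seq_len(j - 1L)])
  list(block = sys$blocks[[j]], idx = offset + seq_len(sizes[j]))
}

#' Deviance information criterion of a fit
#'
#' \eqn{DIC = \bar{D} + p_D} where \eqn{\bar{D}} is the posterior mean
#' deviance over the draws cache and \eqn{p_D = \bar{D} - D(\bar{u})} is the
#' effective number of parameters (deviance at the posterior mean
#' subtracted).
#'
#' @param fit a [fit_model()] result.
#' @return list with `dic` and `p_d`.
#' @export
compute_dic <- function(fit) {
  dev_s <- -2 * colSums(fit$loglik)
  dev_at_mean <- -2 * sum(stats::dnorm(fit$system$y, fit$mu_mean,
                                       fit$hyper$sigma, log = TRUE))
  p_d <- mean(dev_s) - dev_at_mean
  if (p_d < 0.01) {
    warning("near-zero effective parameter count; degenerate fit?",
            call. = FALSE)
  }
  list(dic = mean(dev_s) + p_d, p_d = p_d)
}

#' Watanabe-Akaike information criterion of a fit
#'
#' \eqn{WAIC = -2(\mathrm{lppd} - p_{WAIC})}: the log pointwise predictive
#' density and the summed pointwise posterior variances of the log predictive
#' density, both over the draws cache.
#'
#' @param fit a [fit_model()] result.
#' @return list with `waic` and `p_waic`.
#' @export
compute_waic <- function(fit) {
  ll <- fit$loglik
  S <- ncol(ll)
  lppd <- sum(apply(ll, 1, function(r) {
    mx <- max(r)
    mx + log(mean(exp(r - mx)))
  }))
  p_waic <- sum(apply(ll, 1, stats::var))
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic)
}

#' Scaled quantile residuals and misspecification summaries
#'
#' For each observation the posterior-predictive cumulative probability of
#' the observed response is estimated from the draws cache (new observation
#' noise added, randomised to break ties), giving residuals that are iid
#' uniform on (0,1) under a well-specified model. Uniformity is summarised
#' overall and within quantile bins of each covariate
#' (Kolmogorov--Smirnov), and a Moran-type permutation statistic checks for
#' residual spatial autocorrelation when coordinates are supplied.
#'
#' @param fit a [fit_model()] result.
#' @param data the data used in fitting (for covariate/coordinate lookup);
#'   optional.
#' @param covariates covariate columns to bin residuals against.
#' @param seed RNG seed for the predictive noise and permutations.
#' @param n_bins covariate bins for the per-bin uniformity checks.
#' @return object of class `residual_report`: residual vector, per-covariate
#'   minimum bin-level KS p-values, and Moran statistic with permutation p.
#' @export
quantile_residuals <- function(fit, data = NULL, covariates = character(),
                               seed = fit$seed + 1L, n_bins = 4L) {
  y <- fit$system$y
  S <- ncol(fit$mu_draws)
  resid <- with_seed(seed, function() {
    yrep <- fit$mu_draws +
      matrix(stats::rnorm(length(fit$mu_draws), 0, fit$hyper$sigma),
             nrow(fit$mu_draws), S)
    below <- rowSums(yrep < y)
    (below + stats::runif(length(y))) / (S + 1)
  })
  ks_p <- function(r) {
    if (length(r) < 5) return(NA_real_)
    suppressWarnings(stats::ks.test(r, "punif")$p.value)
  }
  by_cov <- NULL
  if (length(covariates)) {
    by_cov <- vapply(covariates, function(v) {
      x <- data[[v]]
      bins <- if (is.factor(x) || is.character(x)) factor(x) else {
        cut(x, breaks = unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1))),
            include.lowest = TRUE)
      }
      min(vapply(split(resid, bins), ks_p, 0), na.rm = TRUE)
    }, 0)
  }
  moran <- NULL
  if (!is.null(data) && !is.null(data$x_km)) {
    moran <- with_seed(seed + 1L, function() {
      moran_statistic(resid - mean(resid), data$x_km, data$y_km)
    })
  }
  structure(list(residuals = resid, overall_ks_p = ks_p(resid),
                 by_covariate_min_ks_p = by_cov, moran = moran),
            class = "residual_report")
}

# Moran's I with inverse-distance weights and a permutation p-value.
moran_statistic <- function(z, x, y, n_perm = 199L) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  w <- 1 / (d + diag(Inf, nrow(d)))
  I_of <- function(v) {
    n <- length(v)
    n / sum(w) * sum(w * outer(v, v)) / sum(v^2)
  }
  obs <- I_of(z)
  perm <- vapply(seq_len(n_perm), function(i) I_of(sample(z)), 0)
  list(I = obs, p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("scaled quantile residuals: n = %d, overall KS p = %.3f\n",
              length(x$residuals), x$overall_ks_p))
  if (!is.null(x$by_covariate_min_ks_p)) {
    for (v in names(x$by_covariate_min_ks_p)) {
      cat(sprintf("  min bin KS p (%s): %.3f\n", v, x$by_covariate_min_ks_p[[v]]))
    }
  }
  if (!is.null(x$moran)) {
    cat(sprintf("  Moran I = %.4f (perm p = %.3f)\n", x$moran$I, x$moran$p_value))
  }
  invisible(x)
}

#' Partial effect of a model term
#'
#' For a smoother term, the posterior mean and 95% interval of the smoother
#' evaluated at its grid knots (on the sum-to-zero scale, so the
#' posterior-mean values sum to zero over the grid). For a factor fixed
#' effect, the contrasts relative to the baseline level (which is exactly
#' zero). For the spatial field, the field at the basis points.
#'
#' @param fit a [fit_model()] result.
#' @param term term name (a smoother covariate, a fixed factor such as
#'   `"repro"`, or `"location"` for the spatial field).
#' @return data frame with `value`, `mean`, `sd`, `lower95`, `upper95`.
#' @export
predict_partial_effect <- function(fit, term) {
  sys <- fit$system
  labels <- vapply(sys$blocks, `[[`, "", "label")
  if (term %in% labels && term != "fixed") {
    bi <- block_index(sys, term)
    b <- bi$block
    if (b$type == "smoother") {
      mean_k <- as.numeric(b$A %*% fit$latent_mean[bi$idx])
      V <- b$A %*% fit$latent_cov[bi$idx, bi$idx] %*% t(b$A)
      sd_k <- sqrt(pmax(diag(V), 0))
      return(data.frame(value = b$knots, mean = mean_k, sd = sd_k,
                        lower95 = mean_k - 1.96 * sd_k,
                        upper95 = mean_k + 1.96 * sd_k))
    }
    if (b$type == "spatial") {
      mean_m <- as.numeric(b$A %*% fit$latent_mean[bi$idx])
      V <- b$A %*% fit$latent_cov[bi$idx, bi$idx] %*% t(b$A)
      sd_m <- sqrt(pmax(diag(V), 0))
      return(data.frame(x_km = sys$spatial$basis[, 1],
                        y_km = sys$spatial$basis[, 2],
                        mean = mean_m, sd = sd_m,
                        lower95 = mean_m - 1.96 * sd_m,
                        upper95 = mean_m + 1.96 * sd_m))
    }
    if (b$type == "iid") {
      mean_b <- fit$latent_mean[bi$idx]
      sd_b <- fit$latent_sd[bi$idx]
      return(data.frame(value = b$levels, mean = mean_b, sd = sd_b,
                        lower95 = mean_b - 1.96 * sd_b,
                        upper95 = mean_b + 1.96 * sd_b))
    }
  }
  # fixed effects: factor contrasts vs baseline, or a slope coefficient
  fx <- sys$blocks[[1]]
  if (term %in% sys$spec$fixed && is.null(sys$factor_levels[[term]])) {
    j <- match(term, fx$coef_names)
    idx <- block_index(sys, "fixed")$idx[j]
    mean_f <- fit$latent_mean[idx]
    sd_f <- fit$latent_sd[idx]
    return(data.frame(value = term, mean = mean_f, sd = sd_f,
                      lower95 = mean_f - 1.96 * sd_f,
                      upper95 = mean_f + 1.96 * sd_f))
  }
  hit <- grep(paste0("^", term), fx$coef_names)
  hit <- setdiff(hit, 1L)
  if (term %in% sys$spec$fixed && length(hit)) {
    lv <- sub(paste0("^", term), "", fx$coef_names[hit])
    idx <- block_index(sys, "fixed")$idx[hit]
    mean_f <- c(0, fit$latent_mean[idx])
    sd_f <- c(0, fit$latent_sd[idx])
    base <- if (!is.null(sys$factor_levels[[term]])) {
      setdiff(sys$factor_levels[[term]], lv)[1]
    } else "(baseline)"
    return(data.frame(value = c(base, lv), mean = mean_f, sd = sd_f,
                      lower95 = mean_f - 1.96 * sd_f,
                      upper95 = mean_f + 1.96 * sd_f))
  }
  stop(sprintf("unknown model term '%s'", term), call. = FALSE)
}

#' Hyperparameter estimates of a fit as a table
#'
#' @param fit a [fit_model()] result.
#' @return data frame with `parameter` and `estimate` (posterior-mode,
#'   plug-in scale).
#' @export
hyper_table <- function(fit) {
  h <- unlist(fit$hyper)
  data.frame(parameter = names(h), estimate = as.numeric(h),
             row.names = NULL)
}
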