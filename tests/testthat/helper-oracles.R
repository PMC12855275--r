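# Independent numerical oracles for the latent Gaussian engine. These
# re-derive the same quantities by a different route (quadrature, dense
# covariance identities) and must never call into the engine's own
# factorizations.

# Log marginal likelihood by the dense marginal-covariance identity:
# y ~ N(0, Z V Z' + sigma^2 I). Independent of the precision-based route.
dense_marginal_loglik <- function(y, Z, V, sigma) {
  S <- Z %*% V %*% t(Z) + diag(sigma^2, length(y))
  as.numeric(-length(y) / 2 * log(2 * pi) -
               0.5 * determinant(S, logarithm = TRUE)$modulus -
               0.5 * t(y) %*% solve(S, y))
}

# GLS/Woodbury oracle for the latent posterior given hyperparameters:
# mean = V Z' (Z V Z' + s2 I)^{-1} y, cov = V - V Z' (...)^{-1} Z V.
gls_posterior <- function(y, Z, V, sigma) {
  S <- Z %*% V %*% t(Z) + diag(sigma^2, length(y))
  K <- V %*% t(Z) %*% solve(S)
  list(mean = as.numeric(K %*% y), cov = V - K %*% Z %*% V)
}

# Quadrature oracle for the integrated likelihood of a toy system with
# latent dimension 1-3: integrand prior(u) * lik(u), integrated with a
# tensor-product Gauss-Legendre rule over a box centred at an independently
# located integrand mode (optim on the integrand itself); the node count is
# refined until two rules agree, making the result self-validating.
quadrature_marginal_loglik <- function(y, Z, prior_sd, sigma,
                                       nodes = c(70, 100), tol = 5e-7) {
  q <- ncol(Z)
  stopifnot(q <= 3)
  log_f <- function(u) {
    sum(stats::dnorm(y, as.numeric(Z %*% u), sigma, log = TRUE)) +
      sum(stats::dnorm(u, 0, prior_sd, log = TRUE))
  }
  mode <- stats::optim(rep(0.1, q), function(u) -log_f(u),
                       method = "BFGS")$par
  # box half-widths from the integrand's curvature: finite-difference
  # Hessian of -log f at the mode, inverted to marginal sds (captures the
  # correlated ridge an axis-aligned crude scale would truncate)
  h <- 1e-4
  H <- matrix(0, q, q)
  for (i in seq_len(q)) for (j in seq_len(q)) {
    ei <- ej <- rep(0, q); ei[i] <- h; ej[j] <- h
    H[i, j] <- -(log_f(mode + ei + ej) - log_f(mode + ei - ej) -
                   log_f(mode - ei + ej) + log_f(mode - ei - ej)) / (4 * h^2)
  }
  scale <- sqrt(pmax(diag(solve(H)), 1e-12))
  lf0 <- log_f(mode)                                  # renormalisation
  one_rule <- function(n_nodes) {
    gl <- lapply(seq_len(q), function(j) {
      pracma::gaussLegendre(n_nodes, mode[j] - 9 * scale[j],
                            mode[j] + 9 * scale[j])
    })
    U <- as.matrix(expand.grid(lapply(gl, `[[`, "x")))
    W <- as.vector(Reduce(function(a, b) outer(a, b),
                          lapply(gl, `[[`, "w")))
    # vectorised log integrand over all grid rows
    M <- Z %*% t(U)                                   # n x N fitted means
    ll <- colSums(stats::dnorm(y, M, sigma, log = TRUE))
    lp <- colSums(stats::dnorm(t(U), 0, prior_sd, log = TRUE))
    lf <- ll + lp - lf0
    log(sum(exp(lf) * W)) + lf0
  }
  v1 <- one_rule(nodes[1])
  v2 <- one_rule(nodes[2])
  stopifnot(abs(v1 - v2) < tol)                       # rule convergence
  v2
}
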