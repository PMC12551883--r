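# Independent oracles used across the suite.

# Dense multivariate-normal log-density with the Toeplitz ARMA autocovariance
# matrix, built from base R's ARMAacf/ARMAtoMA (independent of the package's
# Kalman machinery). Handles missing values by dropping rows/columns.
dense_mvn_loglik <- function(params, x) {
  n <- length(x)
  p <- params$phi; q <- params$theta
  if (length(p) == 0 && length(q) == 0) {
    G <- diag(params$sigma2, n)
  } else {
    gamma0 <- params$sigma2 *
      sum(c(1, stats::ARMAtoMA(ar = p, ma = q, lag.max = 2000))^2)
    rho <- stats::ARMAacf(ar = p, ma = q, lag.max = n - 1)
    G <- gamma0 * stats::toeplitz(as.numeric(rho))
  }
  obs <- which(!is.na(x))
  G <- G[obs, obs, drop = FALSE]
  e <- x[obs] - params$mu
  ld <- determinant(G, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (length(obs) * log(2 * pi) + ld +
                       t(e) %*% solve(G, e)))
}

# theoretical ARMA autocovariances at lags 0..lag from base R
arma_autocov <- function(params, lag) {
  gamma0 <- params$sigma2 *
    sum(c(1, stats::ARMAtoMA(ar = params$phi, ma = params$theta,
                             lag.max = 2000))^2)
  gamma0 * as.numeric(stats::ARMAacf(ar = params$phi, ma = params$theta,
                                     lag.max = lag))
}

# random causal+invertible model away from the unit circle
random_valid_model <- function(p, q, mu = 0, sigma2 = 1) {
  m <- sample_init_rootspace(c(p, q), fit_options(gamma = 0.1))
  m$mu <- mu
  m$sigma2 <- sigma2
  m
}

# concentrated (sigma^2-profiled) log-likelihood at fixed coefficients,
# recovered from two kalman_loglik evaluations -- an enumeration oracle for
# grid searches that does not rely on the package's optimizer
concentrated_ll_oracle <- function(phi, theta, x, mu = 0) {
  n <- sum(!is.na(x))
  ll1 <- kalman_loglik(arma_params(phi = phi, theta = theta, mu = mu,
                                   sigma2 = 1), x)
  lle <- kalman_loglik(arma_params(phi = phi, theta = theta, mu = mu,
                                   sigma2 = exp(1)), x)
  S <- (2 * (lle - ll1) + n) * exp(1) / (exp(1) - 1)
  A <- -2 * ll1 - n * log(2 * pi) - S
  -0.5 * (n * (log(2 * pi) + 1 + log(S / n)) + A)
}
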