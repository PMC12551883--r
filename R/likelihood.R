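#' Univariate time-series container
#'
#' Equally spaced, possibly gappy series. Missing observations are encoded
#' as `NA`; the Kalman likelihood handles them by prediction-only steps,
#' while the conditional-sum-of-squares objective refuses them.
#'
#' @param values Numeric vector, length >= 1, with at least one non-missing
#'   entry. `NaN` is treated as missing.
#' @return An object of class `"series_data"` with elements `values` and `n`.
#' @export
series_data <- function(values) {
  values <- as.numeric(values)
  values[is.nan(values)] <- NA_real_
  if (length(values) < 1L) stop("series must contain at least one value")
  if (all(is.na(values))) stop("series must contain at least one non-missing value")
  structure(list(values = values, n = length(values)), class = "series_data")
}

as_series_data <- function(x) {
  if (inherits(x, "series_data")) return(x)
  if (is.numeric(x) || stats::is.ts(x)) return(series_data(as.numeric(x)))
  stop("cannot interpret data as a univariate series")
}

#' Companion state-space form of an ARMA model
#'
#' Builds the Harvey-style companion representation z_t = T z_(t-1) + Q w_t,
#' x_t = (1, 0, ..., 0) z_t + mu, with state dimension r = max(p, q + 1).
#' The transition matrix `T` carries the (zero-padded) AR coefficients in its
#' first column and an identity block on the superdiagonal; the loading is
#' Q = (1, theta_1, ..., theta_(r-1))'.
#'
#' @param params An [arma_params()] object.
#' @return An object of class `"arma_state_space"` with elements `T` (r x r),
#'   `Q` (length r) and `r`.
#' @export
build_state_space <- function(params) {
  stopifnot(inherits(params, "arma_params"))
  p <- length(params$phi); q <- length(params$theta)
  r <- max(p, q + 1L)
  Tm <- matrix(0, r, r)
  if (p) Tm[seq_len(p), 1] <- params$phi
  if (r > 1L) Tm[cbind(seq_len(r - 1L), seq_len(r - 1L) + 1L)] <- 1
  Q <- c(1, rep(0, r - 1L))
  if (q) Q[1L + seq_len(q)] <- params$theta
  structure(list(T = Tm, Q = Q, r = r), class = "arma_state_space")
}

#' Stationary state covariance
#'
#' Solves the discrete Lyapunov equation P = T P T' + sigma2 Q Q', which has
#' a unique symmetric positive semi-definite solution for causal models.
#' This matrix initializes both the Kalman filter and the exact stationary
#' draw used by [simulate_arma()].
#'
#' @param ss An `"arma_state_space"` (from [build_state_space()]) or an
#'   [arma_params()] object.
#' @param sigma2 White-noise variance (ignored when `ss` is an
#'   `arma_params`, whose own `sigma2` is used).
#' @return r x r symmetric matrix.
#' @export
stationary_covariance <- function(ss, sigma2 = 1) {
  if (inherits(ss, "arma_params")) {
    if (!is_causal(ss)) stop("no stationary solution: model is not causal")
    return(.stationary_cov_cpp(ss$phi, ss$theta, ss$sigma2))
  }
  stopifnot(inherits(ss, "arma_state_space"))
  Tm <- ss$T; Q <- ss$Q; r <- ss$r
  if (any(Mod(eigen(Tm, only.values = TRUE)$values) >= 1))
    stop("no stationary solution: model is not causal")
  vecP <- solve(diag(r * r) - kronecker(Tm, Tm), as.numeric(sigma2 * Q %o% Q))
  P <- matrix(vecP, r, r)
  (P + t(P)) / 2
}

#' Exact Gaussian log-likelihood via the Kalman filter
#'
#' Evaluates the joint Gaussian log-density of the observed (non-missing)
#' values under a causal ARMA model, by running the Kalman filter on the
#' companion state-space form with exact stationary initialization. Missing
#' values contribute prediction steps only. Equals the dense
#' multivariate-normal log-density with Toeplitz ARMA autocovariance matrix
#' (up to numerical tolerance), at a cost linear in n.
#'
#' @param params An [arma_params()] object with causal AR part and
#'   `sigma2 > 0`.
#' @param data A [series_data()] object or numeric vector.
#' @return Log-likelihood (natural-log units), a single number.
#' @examples
#' kalman_loglik(arma_params(), c(0, 0))  # two standard normals: -log(2*pi)
#' @export
kalman_loglik <- function(params, data) {
  stopifnot(inherits(params, "arma_params"))
  data <- as_series_data(data)
  if (!is_causal(params))
    stop("likelihood evaluation requires a causal AR polynomial")
  pieces <- .kalman_pieces_cpp(params$phi, params$theta, data$values,
                               params$mu)
  if (!isTRUE(pieces$ok)) stop("Kalman filter failed numerically")
  s2 <- params$sigma2
  -0.5 * (pieces$nobs * log(2 * pi * s2) + pieces$sumlogF + pieces$ssq / s2)
}

# concentrated pieces: returns list(loglik at sigma2hat, sigma2hat, nobs)
kalman_concentrated <- function(phi, theta, values, mu) {
  pieces <- .kalman_pieces_cpp(phi, theta, values, mu)
  if (!isTRUE(pieces$ok)) return(NULL)
  s2 <- pieces$ssq / pieces$nobs
  ll <- -0.5 * (pieces$nobs * (log(2 * pi) + 1 + log(s2)) + pieces$sumlogF)
  list(loglik = ll, sigma2 = s2, nobs = pieces$nobs)
}

#' Conditional sum of squares (CSS) objective
#'
#' Computes sum_(t=p+1)^n w_t^2, where the innovations w_t follow the ARMA
#' recursion on the de-meaned series with the pre-sample innovations
#' w_p = w_(p-1) = ... = 0. Fast but statistically inefficient; used only to
#' initialize likelihood maximization. Undefined in the presence of missing
#' values.
#'
#' @param params An [arma_params()] object (`mu` is used to de-mean).
#' @param data A [series_data()] object or numeric vector without missing
#'   values.
#' @return Non-negative scalar.
#' @export
css_objective <- function(params, data) {
  stopifnot(inherits(params, "arma_params"))
  data <- as_series_data(data)
  if (anyNA(data$values))
    stop("CSS is unavailable with missing values", call. = FALSE)
  .css_cpp(params$phi, params$theta, data$values, params$mu)$ssq
}

#' CSS parameter estimate
#'
#' Minimizes the conditional sum of squares over (phi, theta, mu) by
#' quasi-Newton search in the raw (unconstrained) coefficient space, then
#' sets sigma2 = CSS / (n - p). The minimizer may fall outside the
#' causal/invertible region; callers must check with [is_valid_arma()].
#'
#' @param data A [series_data()] object or numeric vector (no missing
#'   values).
#' @param order An [arma_order()] or `c(p, q)`.
#' @param include_mean Estimate an intercept? Default `TRUE`.
#' @return An [arma_params()] object with attributes `converged` (logical)
#'   and `css` (the minimized objective).
#' @export
css_estimate <- function(data, order, include_mean = TRUE) {
  data <- as_series_data(data)
  order <- as_arma_order(order)
  x <- data$values
  if (anyNA(x)) stop("CSS is unavailable with missing values", call. = FALSE)
  p <- order$p; q <- order$q; n <- data$n
  if (n <= p + q + 1L) stop("too few observations for CSS estimation")
  xbar <- mean(x)
  if (p + q == 0L) {
    s2 <- sum((x - if (include_mean) xbar else 0)^2) / n
    out <- arma_params(mu = if (include_mean) xbar else 0, sigma2 = s2)
    attr(out, "converged") <- TRUE
    attr(out, "css") <- s2 * n
    return(out)
  }
  # optimized on the scale 0.5 log(mean squared residual), which is better
  # conditioned than the raw sum of squares (same minimizer)
  fn <- function(par) {
    mu <- if (include_mean) par[p + q + 1L] else 0
    s <- .css_cpp(par[seq_len(p)], par[p + seq_len(q)], x, mu)$ssq
    if (!is.finite(s) || s <= 0) return(1e10)
    0.5 * log(s / (n - p))
  }
  par0 <- c(rep(0, p + q), if (include_mean) xbar)
  scl <- c(rep(1, p + q), if (include_mean) max(sd(x), 1e-8))
  opt <- optim(par0, fn, method = "BFGS",
               control = list(maxit = 200, parscale = scl))
  mu <- if (include_mean) opt$par[p + q + 1L] else 0
  css_min <- .css_cpp(opt$par[seq_len(p)], opt$par[p + seq_len(q)], x, mu)$ssq
  out <- arma_params(phi = opt$par[seq_len(p)], theta = opt$par[p + seq_len(q)],
                     mu = mu, sigma2 = max(css_min / (n - p), 1e-300))
  attr(out, "converged") <- opt$convergence == 0L
  attr(out, "css") <- css_min
  out
}
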