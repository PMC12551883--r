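#' ARMA model order
#'
#' @param p Non-negative integer, autoregressive order.
#' @param q Non-negative integer, moving-average order.
#' @return An object of class `"arma_order"` with elements `p` and `q`.
#' @examples
#' arma_order(2, 1)
#' @export
arma_order <- function(p, q) {
  p <- as.integer(p); q <- as.integer(q)
  if (length(p) != 1L || length(q) != 1L || is.na(p) || is.na(q) ||
      p < 0L || q < 0L)
    stop("'p' and 'q' must be single non-negative integers")
  structure(list(p = p, q = q), class = "arma_order")
}

as_arma_order <- function(x) {
  if (inherits(x, "arma_order")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(arma_order(x[1], x[2]))
  stop("cannot interpret 'order'; use arma_order(p, q) or c(p, q)")
}

#' ARMA parameter vector
#'
#' Bundles the full parameter set psi = (phi_1..phi_p, theta_1..theta_q, mu,
#' sigma2) of a Gaussian ARMA(p,q) model
#' \deqn{x_t = \mu + \sum_i \phi_i (x_{t-i} - \mu) + w_t + \sum_j \theta_j w_{t-j},}
#' with white-noise variance `sigma2` > 0. The AR polynomial is
#' Phi(x) = 1 - phi_1 x - ... - phi_p x^p and the MA polynomial is
#' Theta(x) = 1 + theta_1 x + ... + theta_q x^q.
#'
#' @param phi Numeric vector of AR coefficients (length p, possibly empty).
#' @param theta Numeric vector of MA coefficients (length q, possibly empty).
#' @param mu Intercept (process mean), in the units of the data.
#' @param sigma2 White-noise variance, strictly positive.
#' @return An object of class `"arma_params"`.
#' @examples
#' arma_params(phi = 1/3, theta = 2/3)
#' @export
arma_params <- function(phi = numeric(), theta = numeric(), mu = 0,
                        sigma2 = 1) {
  phi <- as.numeric(phi); theta <- as.numeric(theta)
  if (any(!is.finite(phi)) || any(!is.finite(theta)))
    stop("ARMA coefficients must be finite")
  if (!is.finite(mu)) stop("'mu' must be finite")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("'sigma2' must be > 0")
  structure(list(phi = phi, theta = theta, mu = as.numeric(mu),
                 sigma2 = as.numeric(sigma2)),
            class = "arma_params")
}

#' @export
print.arma_params <- function(x, digits = 4, ...) {
  cat(sprintf("ARMA(%d,%d) parameters\n", length(x$phi), length(x$theta)))
  if (length(x$phi)) cat("  phi:  ", paste(round(x$phi, digits), collapse = " "), "\n")
  if (length(x$theta)) cat("  theta:", paste(round(x$theta, digits), collapse = " "), "\n")
  cat(sprintf("  mu: %s  sigma2: %s\n", format(x$mu, digits = digits),
              format(x$sigma2, digits = digits)))
  invisible(x)
}

# canonical ordering: by modulus, ties broken by argument
canonical_root_order <- function(z) {
  if (length(z) == 0L) return(z)
  z[order(Mod(z), Arg(z))]
}

#' Inverted-root set of an ARMA model
#'
#' @param ar_inv Complex vector of inverted AR roots (lambda_i).
#' @param ma_inv Complex vector of inverted MA roots (nu_j).
#' @return An object of class `"root_set"`; roots are stored in canonical
#'   order (increasing modulus, then argument).
#' @export
root_set <- function(ar_inv = complex(), ma_inv = complex()) {
  structure(list(ar_inv = canonical_root_order(as.complex(ar_inv)),
                 ma_inv = canonical_root_order(as.complex(ma_inv))),
            class = "root_set")
}

#' @export
print.root_set <- function(x, digits = 4, ...) {
  cat("Inverted AR roots:", if (length(x$ar_inv)) paste(format(x$ar_inv, digits = digits), collapse = " ") else "(none)", "\n")
  cat("Inverted MA roots:", if (length(x$ma_inv)) paste(format(x$ma_inv, digits = digits), collapse = " ") else "(none)", "\n")
  invisible(x)
}

#' Inverted roots of the AR and MA polynomials
#'
#' The inverted AR roots lambda_i are the roots of
#' z^p - phi_1 z^(p-1) - ... - phi_p (equivalently, reciprocals of the roots
#' of Phi), and similarly the inverted MA roots nu_j are the roots of
#' z^q + theta_1 z^(q-1) + ... + theta_q. The model is causal (invertible)
#' exactly when all inverted AR (MA) roots lie strictly inside the unit
#' circle; root location is not checked here.
#'
#' @param params An [arma_params()] object.
#' @return A [root_set()] with roots in canonical order.
#' @examples
#' coefficients_to_inverted_roots(arma_params(phi = 1/3, theta = 2/3))
#' @export
coefficients_to_inverted_roots <- function(params) {
  stopifnot(inherits(params, "arma_params"))
  ar <- if (length(params$phi))
    polyroot(c(-rev(params$phi), 1)) else complex()
  ma <- if (length(params$theta))
    polyroot(c(rev(params$theta), 1)) else complex()
  root_set(ar_inv = ar, ma_inv = ma)
}

# expand prod_i (1 - z_i x) into ascending polynomial coefficients (1, c1, ...)
expand_inverted_roots <- function(z, tol = 1e-8) {
  coef <- as.complex(1)
  for (zi in z) coef <- c(coef, 0) - zi * c(0, coef)
  if (length(z) && max(abs(Im(coef))) > tol)
    stop("root set does not expand to a real polynomial; ",
         "non-real roots must occur in conjugate pairs")
  Re(coef)
}

#' Recover ARMA coefficients from inverted roots
#'
#' Expands Phi(x) = prod_i (1 - lambda_i x) and
#' Theta(x) = prod_j (1 - nu_j x) and reads off the coefficients under the
#' conventions Phi(x) = 1 - phi_1 x - ... and Theta(x) = 1 + theta_1 x + ....
#' Non-real roots must occur in conjugate pairs (imaginary residue of the
#' expansion above 1e-8 is an error; below, it is truncated). Inverse of
#' [coefficients_to_inverted_roots()] up to root ordering.
#'
#' @param roots A [root_set()], or a complex vector of inverted AR roots.
#' @param ma_inv Inverted MA roots when `roots` is given as a plain vector.
#' @return List with numeric components `phi` and `theta`.
#' @examples
#' inverted_roots_to_coefficients(root_set(c(1/2, 1/3), c(1/2, -2/3)))
#' @export
inverted_roots_to_coefficients <- function(roots, ma_inv = NULL) {
  if (!inherits(roots, "root_set"))
    roots <- root_set(roots, if (is.null(ma_inv)) complex() else ma_inv)
  phi <- -expand_inverted_roots(roots$ar_inv)[-1]
  theta <- expand_inverted_roots(roots$ma_inv)[-1]
  list(phi = as.numeric(phi), theta = as.numeric(theta))
}

#' Minimum cross distance between inverted AR and MA roots
#'
#' Near-coincident AR and MA roots nearly cancel, flattening the likelihood
#' surface; this distance is the quantity thresholded (>= alpha) by both
#' initialization samplers. Returns `Inf` when p = 0 or q = 0, since no
#' cancellation is possible.
#'
#' @param roots A [root_set()].
#' @return Minimum over pairs (i, j) of |lambda_i - nu_j|, or `Inf`.
#' @export
min_cross_root_distance <- function(roots) {
  stopifnot(inherits(roots, "root_set"))
  if (length(roots$ar_inv) == 0L || length(roots$ma_inv) == 0L) return(Inf)
  min(abs(outer(roots$ar_inv, roots$ma_inv, "-")))
}

# smallest pairwise distance among the pooled roots (AR and MA together);
# used by the generative-model filter, Inf when fewer than two roots
min_pooled_root_distance <- function(roots) {
  z <- c(roots$ar_inv, roots$ma_inv)
  if (length(z) < 2L) return(Inf)
  d <- abs(outer(z, z, "-"))
  min(d[upper.tri(d)])
}

#' Causality and invertibility checks
#'
#' An ARMA model is causal when all inverted AR roots have modulus strictly
#' less than one, and invertible when all inverted MA roots do.
#'
#' @param params An [arma_params()] object.
#' @return Logical scalar.
#' @examples
#' is_causal(arma_params(phi = 0.5))   # TRUE
#' is_causal(arma_params(phi = 1.0))   # FALSE: unit root
#' @export
is_causal <- function(params) {
  stopifnot(inherits(params, "arma_params"))
  if (length(params$phi) == 0L) return(TRUE)
  all(Mod(polyroot(c(-rev(params$phi), 1))) < 1)
}

#' @rdname is_causal
#' @export
is_invertible <- function(params) {
  stopifnot(inherits(params, "arma_params"))
  if (length(params$theta) == 0L) return(TRUE)
  all(Mod(polyroot(c(rev(params$theta), 1))) < 1)
}

#' @rdname is_causal
#' @export
is_valid_arma <- function(params) is_causal(params) && is_invertible(params)

# Durbin-Levinson expansion in R (reference path; the C++ kernel has its own)
dl_expand_r <- function(xi) {
  p <- length(xi)
  if (p == 0L) return(numeric())
  a <- numeric(p)
  for (i in seq_len(p)) {
    prev <- a
    a[i] <- xi[i]
    if (i > 1L)
      for (h in seq_len(i - 1L)) a[h] <- prev[h] - xi[i] * prev[i - h]
  }
  a
}

# inverse Durbin-Levinson: causal AR coefficients -> partial autocorrelations
dl_contract_r <- function(phi) {
  p <- length(phi)
  if (p == 0L) return(numeric())
  a <- phi
  xi <- numeric(p)
  for (i in rev(seq_len(p))) {
    xi[i] <- a[i]
    if (abs(xi[i]) >= 1) stop("coefficients are not strictly causal")
    if (i > 1L) {
      prev <- numeric(i - 1L)
      for (h in seq_len(i - 1L))
        prev[h] <- (a[h] + xi[i] * a[i - h]) / (1 - xi[i]^2)
      a <- prev
    }
  }
  xi
}

#' Map partial autocorrelations to ARMA coefficients
#'
#' Expands vectors of partial autocorrelations (each in (-1, 1)) through the
#' Durbin-Levinson recursion. The AR block maps directly to causal phi; the
#' MA block is expanded the same way and then negated, which lands theta in
#' the invertible region under the Theta(x) = 1 + theta_1 x + ... convention.
#'
#' @param ar_pacf,ma_pacf Numeric vectors with entries strictly inside
#'   (-1, 1).
#' @return List with components `phi` and `theta`; the result is always
#'   causal and invertible.
#' @examples
#' pacf_to_coefficients(c(0.4, 0.2))   # phi = (0.4 * (1 - 0.2), 0.2)
#' @export
pacf_to_coefficients <- function(ar_pacf = numeric(), ma_pacf = numeric()) {
  ar_pacf <- as.numeric(ar_pacf); ma_pacf <- as.numeric(ma_pacf)
  if (any(abs(ar_pacf) >= 1) || any(abs(ma_pacf) >= 1))
    stop("partial autocorrelations must lie strictly inside (-1, 1)")
  list(phi = dl_expand_r(ar_pacf), theta = -dl_expand_r(ma_pacf))
}

#' Map ARMA coefficients to partial autocorrelations
#'
#' Inverse of [pacf_to_coefficients()]; requires a strictly causal AR block
#' and strictly invertible MA block.
#'
#' @param params An [arma_params()] object.
#' @return List with components `ar_pacf` and `ma_pacf`.
#' @export
coefficients_to_pacf <- function(params) {
  stopifnot(inherits(params, "arma_params"))
  list(ar_pacf = dl_contract_r(params$phi),
       ma_pacf = dl_contract_r(-params$theta))
}

#' Simulate a stationary Gaussian ARMA series
#'
#' The latent companion state is initialized with an exact draw from its
#' stationary distribution (covariance solving P = T P T' + sigma2 Q Q'), so
#' the output is a finite stretch of the stationary process with no burn-in
#' truncation bias.
#'
#' @param params A causal, invertible [arma_params()] object.
#' @param n Number of observations, at least 1.
#' @return Numeric vector of length `n`. Reproducible under `set.seed()`.
#' @examples
#' set.seed(1)
#' x <- simulate_arma(arma_params(phi = 0.5), 200)
#' @export
simulate_arma <- function(params, n) {
  stopifnot(inherits(params, "arma_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is_valid_arma(params))
    stop("simulation requires a causal and invertible model")
  P0 <- .stationary_cov_cpp(params$phi, params$theta, params$sigma2)
  r <- nrow(P0)
  e <- eigen(P0, symmetric = TRUE)
  z0 <- e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(r))
  w <- rnorm(n, 0, sqrt(params$sigma2))
  .arma_sim_cpp(params$phi, params$theta, w, as.numeric(z0), params$mu)
}
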