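#' Fitting options
#'
#' Hyperparameters shared by the multi-start fitting algorithms.
#'
#' @param alpha Minimum acceptable Euclidean distance between inverted AR
#'   and MA roots of a sampled initialization; default 0.01. Guards against
#'   starting points with nearly cancelling roots.
#' @param gamma Annulus bound in (0, 0.5) for sampled inverted-root moduli
#'   (root-space sampler) and the bound keeping sampled coefficients /
#'   partial autocorrelations away from +-1 (Durbin-Levinson sampler);
#'   default 0.05.
#' @param M Stopping patience: the initialization loop stops once the last
#'   `M` consecutive sampled starts fail to improve the incumbent
#'   log-likelihood. Default 10.
#' @param max_inits Hard cap on the number of sampled initializations;
#'   default 100.
#' @param seed Optional integer seed; when non-`NULL` the fit is fully
#'   deterministic, including its initialization trace.
#' @param optimizer_max_iter Maximum BFGS iterations per start; default 100.
#' @param improvement_tol A start "improves" only when it beats the
#'   incumbent log-likelihood by more than this; default 1e-4. Prevents
#'   non-termination from floating-point jitter.
#' @param strict_pacf If `TRUE`, the Durbin-Levinson sampler draws partial
#'   autocorrelations from the positive range U(gamma, 1 - gamma) for block
#'   orders >= 2 instead of the default symmetric U(-1 + gamma, 1 - gamma).
#'   The symmetric default covers the whole admissible region; see the
#'   methods vignette.
#' @return An object of class `"fit_options"`.
#' @export
fit_options <- function(alpha = 0.01, gamma = 0.05, M = 10L,
                        max_inits = 100L, seed = NULL,
                        optimizer_max_iter = 100L,
                        improvement_tol = 1e-4, strict_pacf = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be > 0")
  if (!is.numeric(gamma) || gamma <= 0 || gamma >= 0.5)
    stop("'gamma' must lie in (0, 0.5)")
  if (M < 1L) stop("'M' must be a positive integer")
  if (max_inits < 0L) stop("'max_inits' must be non-negative")
  structure(list(alpha = alpha, gamma = gamma, M = as.integer(M),
                 max_inits = as.integer(max_inits),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 optimizer_max_iter = as.integer(optimizer_max_iter),
                 improvement_tol = improvement_tol,
                 strict_pacf = isTRUE(strict_pacf)),
            class = "fit_options")
}

#' Default (CSS) initialization
#'
#' Mirrors the single-initialization standard: the CSS estimate when it is
#' available and lies inside the causal/invertible region, otherwise the
#' origin (all coefficients zero, `mu` at the sample mean). A CSS estimate
#' with a non-invertible MA part is first replaced by its observationally
#' equivalent invertible representation (inverted MA roots reflected across
#' the unit circle); a non-causal AR part falls back to the origin. CSS is
#' unavailable when the series has missing values.
#'
#' @inheritParams css_estimate
#' @return An [arma_params()] object with attribute `source` equal to
#'   `"css"` or `"origin"`.
#' @export
default_init <- function(data, order, include_mean = TRUE) {
  data <- as_series_data(data)
  order <- as_arma_order(order)
  origin <- function() {
    out <- arma_params(phi = rep(0, order$p), theta = rep(0, order$q),
                       mu = if (include_mean) mean(data$values, na.rm = TRUE) else 0,
                       sigma2 = max(var(data$values, na.rm = TRUE), 1e-8))
    attr(out, "source") <- "origin"
    out
  }
  if (anyNA(data$values)) return(origin())
  est <- tryCatch(css_estimate(data, order, include_mean),
                  error = function(e) NULL)
  if (is.null(est) || !is_causal(est)) return(origin())
  if (!is_invertible(est)) {
    # a non-invertible MA estimate has an observationally equivalent
    # invertible representation: reflect the offending inverted roots
    # across the unit circle (nu -> 1/conj(nu)), as standard software does
    est <- tryCatch({
      rs <- coefficients_to_inverted_roots(est)
      out <- Mod(rs$ma_inv) >= 1
      rs$ma_inv[out] <- 1 / Conj(rs$ma_inv[out])
      th <- inverted_roots_to_coefficients(rs)$theta
      arma_params(phi = est$phi, theta = th, mu = est$mu,
                  sigma2 = est$sigma2)
    }, error = function(e) NULL)
    if (is.null(est) || !is_valid_arma(est)) return(origin())
  }
  attr(est, "source") <- "css"
  est
}

# unconstrained optimizer start from a valid (or origin) parameter point
transform_init <- function(init, p, q) {
  clamp <- function(v) pmin(pmax(v, -1 + 1e-8), 1 - 1e-8)
  xi_ar <- if (p) clamp(dl_contract_r(init$phi)) else numeric()
  xi_ma <- if (q) clamp(dl_contract_r(-init$theta)) else numeric()
  c(atanh(xi_ar), atanh(xi_ma))
}

# invert the optimizer parameterization back to coefficients
untransform_par <- function(par, p, q, include_mean) {
  clamp <- function(v) pmin(pmax(v, -1 + 1e-12), 1 - 1e-12)
  phi <- if (p) dl_expand_r(clamp(tanh(par[seq_len(p)]))) else numeric()
  theta <- if (q) -dl_expand_r(clamp(tanh(par[p + seq_len(q)]))) else numeric()
  mu <- if (include_mean) par[p + q + 1L] else 0
  list(phi = phi, theta = theta, mu = mu)
}

#' Single-initialization maximum likelihood fit
#'
#' Quasi-Newton (BFGS) maximization of the exact Kalman-filter
#' log-likelihood, started from one parameter point. Coefficients are
#' optimized in an unconstrained space via the tanh-bounded partial
#' autocorrelation transform, so every iterate -- and the returned estimate
#' -- is strictly causal and invertible. The innovation variance is
#' concentrated out analytically; the reported parameters include the
#' implied sigma2-hat.
#'
#' @param data A [series_data()] object or numeric vector.
#' @param order An [arma_order()] or `c(p, q)`.
#' @param init Starting [arma_params()]; defaults to [default_init()]. An
#'   invalid start falls back to the origin.
#' @param options A [fit_options()] object.
#' @param include_mean Estimate an intercept? Default `TRUE`.
#' @return List with elements `params` (the estimate), `loglik`,
#'   `converged` (optimizer convergence flag) and `init` (the start used).
#' @export
fit_single <- function(data, order, init = NULL, options = fit_options(),
                       include_mean = TRUE) {
  data <- as_series_data(data)
  order <- as_arma_order(order)
  p <- order$p; q <- order$q
  x <- data$values
  nobs <- sum(!is.na(x))
  if (nobs <= p + q + 1L) stop("too few non-missing observations")
  if (is.null(init)) init <- default_init(data, order, include_mean)

  if (p + q == 0L) {
    mu <- if (include_mean) mean(x, na.rm = TRUE) else 0
    s2 <- sum((x - mu)^2, na.rm = TRUE) / nobs
    params <- arma_params(mu = mu, sigma2 = s2)
    return(list(params = params, loglik = kalman_loglik(params, data),
                converged = TRUE, init = init))
  }

  valid_init <- length(init$phi) == p && length(init$theta) == q &&
    is_valid_arma(init)
  par0 <- if (valid_init) transform_init(init, p, q) else rep(0, p + q)
  if (include_mean)
    par0 <- c(par0, if (valid_init) init$mu else mean(x, na.rm = TRUE))
  scl <- c(rep(1, p + q), if (include_mean) max(sd(x, na.rm = TRUE), 1e-8))
  obj <- function(par) .arma_obj_cpp(par, x, p, q, include_mean, TRUE)
  opt <- optim(par0, obj, method = "BFGS",
               control = list(maxit = options$optimizer_max_iter,
                              parscale = scl))
  co <- untransform_par(opt$par, p, q, include_mean)
  conc <- kalman_concentrated(co$phi, co$theta, x, co$mu)
  if (is.null(conc)) stop("likelihood evaluation failed at the optimum")
  params <- arma_params(phi = co$phi, theta = co$theta, mu = co$mu,
                        sigma2 = conc$sigma2)
  list(params = params, loglik = conc$loglik,
       converged = opt$convergence == 0L, init = init)
}

# sample the inverted roots of one polynomial per the root-space scheme:
# pairs declared real w.p. 1/2; real pairs get i.i.d. U(gamma, 1-gamma)
# magnitudes with equal signs w.p. 1/2; complex pairs get a uniform angle on
# (0, pi) and a U(gamma, 1-gamma) radius; an odd leftover root is real with
# a random sign.
sample_poly_roots <- function(k, gamma) {
  if (k == 0L) return(complex())
  roots <- complex()
  for (pair in seq_len(k %/% 2L)) {
    if (runif(1) < 0.5) {                       # real pair
      m <- runif(2, gamma, 1 - gamma)
      s1 <- if (runif(1) < 0.5) 1 else -1
      s2 <- if (runif(1) < 0.5) s1 else -s1
      roots <- c(roots, complex(real = c(s1 * m[1], s2 * m[2])))
    } else {                                    # conjugate pair
      tau <- runif(1, 0, pi)
      r <- runif(1, gamma, 1 - gamma)
      z <- complex(modulus = r, argument = tau)
      roots <- c(roots, z, Conj(z))
    }
  }
  if (k %% 2L == 1L) {
    tau <- sample(c(0, pi), 1L)
    r <- runif(1, gamma, 1 - gamma)
    roots <- c(roots, complex(real = r * cos(tau)))
  }
  roots
}

#' Random initialization by uniform inverted-root sampling
#'
#' Draws causal, invertible starting values by sampling the inverted AR and
#' MA roots directly inside the annulus gamma <= |z| <= 1 - gamma. Root
#' pairs are declared real with probability 1/2 so that coefficient signs
#' are balanced (an all-complex scheme could never produce, e.g., phi_2 > 0
#' in an AR(2)); draws are rejected until every AR/MA root pair is at least
#' `alpha` apart.
#'
#' @param order An [arma_order()] or `c(p, q)`.
#' @param options A [fit_options()] (uses `alpha` and `gamma`).
#' @return An [arma_params()] object (with `mu = 0`, `sigma2 = 1`).
#' @export
sample_init_rootspace <- function(order, options = fit_options()) {
  order <- as_arma_order(order)
  for (try in seq_len(1000L)) {
    rs <- root_set(sample_poly_roots(order$p, options$gamma),
                   sample_poly_roots(order$q, options$gamma))
    if (min_cross_root_distance(rs) >= options$alpha) {
      co <- inverted_roots_to_coefficients(rs)
      return(arma_params(phi = co$phi, theta = co$theta))
    }
  }
  stop("root-space sampler exceeded the resampling cap")
}

#' Random initialization by Durbin-Levinson sampling
#'
#' Draws causal, invertible starting values through the partial
#' autocorrelation parameterization. When a block has order 1 its single
#' coefficient is sampled directly from U(-1 + gamma, 1 - gamma); otherwise
#' partial autocorrelations are drawn and expanded through the
#' Durbin-Levinson recursion (MA entries negated, matching the
#' Theta(x) = 1 + theta_1 x + ... convention). Draws are rejected until the
#' inverted AR and MA roots of the implied polynomials are at least `alpha`
#' apart.
#'
#' @inheritParams sample_init_rootspace
#' @return An [arma_params()] object (with `mu = 0`, `sigma2 = 1`).
#' @export
sample_init_pacf <- function(order, options = fit_options()) {
  order <- as_arma_order(order)
  g <- options$gamma
  draw_block <- function(k, negate) {
    if (k == 0L) return(numeric())
    if (k == 1L) {
      co <- runif(1, -1 + g, 1 - g)   # coefficient sampled directly
      return(co)
    }
    xi <- if (options$strict_pacf) runif(k, g, 1 - g)
          else runif(k, -1 + g, 1 - g)
    if (negate) -dl_expand_r(xi) else dl_expand_r(xi)
  }
  for (try in seq_len(1000L)) {
    phi <- draw_block(order$p, negate = FALSE)
    theta <- draw_block(order$q, negate = TRUE)
    cand <- arma_params(phi = phi, theta = theta)
    rs <- coefficients_to_inverted_roots(cand)
    if (min_cross_root_distance(rs) >= options$alpha) return(cand)
  }
  stop("Durbin-Levinson sampler exceeded the resampling cap")
}

#' Multi-start maximum likelihood fit
#'
#' Fits the model once from the default (CSS or origin) initialization, then
#' repeatedly from random causal/invertible starting values until the last
#' `M` consecutive starts fail to improve the incumbent log-likelihood by
#' more than `improvement_tol` (or `max_inits` starts have been tried). The
#' returned fit maximizes the log-likelihood over all starts, so it can
#' never be worse than the single-initialization baseline.
#'
#' @param data A [series_data()] object or numeric vector.
#' @param order An [arma_order()] or `c(p, q)`.
#' @param method `"rootspace"` (inverted-root sampler), `"pacf"`
#'   (Durbin-Levinson sampler), or `"baseline"` (no random starts; the
#'   existing-software standard).
#' @param options A [fit_options()] object.
#' @param include_mean Estimate an intercept? Default `TRUE`.
#' @param se Compute Fisher-information standard errors? Default `TRUE`;
#'   simulation studies turn this off for speed.
#' @param baseline_fit Optional precomputed result of the default-start fit
#'   (as returned by [fit_single()]); avoids refitting it when several
#'   methods are compared on one dataset.
#' @return An object of class `"arma_fit"`: a list with `params`, `loglik`,
#'   `aic`, `se`, `n_inits`, `init_trace` (one record per start: start
#'   parameters, convergence flag, achieved log-likelihood),
#'   `best_init_index`, `method`, `order`, `n`, `data`.
#' @examples
#' set.seed(3)
#' x <- simulate_arma(arma_params(phi = 0.6, theta = 0.3), 100)
#' fit <- multistart_fit(x, c(1, 1), method = "rootspace",
#'                       options = fit_options(seed = 1, M = 5))
#' fit$loglik
#' @export
multistart_fit <- function(data, order,
                           method = c("rootspace", "pacf", "baseline"),
                           options = fit_options(), include_mean = TRUE,
                           se = TRUE, baseline_fit = NULL) {
  method <- match.arg(method)
  data <- as_series_data(data)
  order <- as_arma_order(order)
  if (!is.null(options$seed)) set.seed(options$seed)

  fit0 <- if (is.null(baseline_fit))
    fit_single(data, order, init = NULL, options = options,
               include_mean = include_mean)
  else baseline_fit
  trace <- list(list(init = fit0$init, converged = fit0$converged,
                     loglik = fit0$loglik))
  best <- fit0
  best_idx <- 1L
  n_inits <- 0L

  if (method != "baseline" && options$max_inits > 0L &&
      order$p + order$q > 0L) {
    sampler <- if (method == "rootspace") sample_init_rootspace
               else sample_init_pacf
    mu0 <- if (include_mean) mean(data$values, na.rm = TRUE) else 0
    fails <- 0L
    while (fails < options$M && n_inits < options$max_inits) {
      init <- sampler(order, options)
      init$mu <- mu0
      n_inits <- n_inits + 1L
      fit_k <- tryCatch(
        fit_single(data, order, init = init, options = options,
                   include_mean = include_mean),
        error = function(e) NULL)
      if (is.null(fit_k)) {
        trace[[n_inits + 1L]] <- list(init = init, converged = FALSE,
                                      loglik = NA_real_)
        fails <- fails + 1L
        next
      }
      trace[[n_inits + 1L]] <- list(init = init, converged = fit_k$converged,
                                    loglik = fit_k$loglik)
      if (fit_k$loglik > best$loglik + options$improvement_tol) {
        best <- fit_k
        best_idx <- n_inits + 1L
        fails <- 0L
      } else {
        if (fit_k$loglik > best$loglik) { best <- fit_k; best_idx <- n_inits + 1L }
        fails <- fails + 1L
      }
    }
  }

  out <- structure(
    list(params = best$params, loglik = best$loglik,
         aic = aic(best$loglik, order$p, order$q, with_intercept = include_mean),
         se = NULL, n_inits = n_inits, init_trace = trace,
         best_init_index = best_idx, method = method, order = order,
         n = data$n, include_mean = include_mean, data = data,
         converged = best$converged, options = options),
    class = "arma_fit")
  if (se) out$se <- tryCatch(fisher_standard_errors(out, data),
                             error = function(e) NULL)
  out
}

#' @export
print.arma_fit <- function(x, digits = 4, ...) {
  cat(sprintf("ARMA(%d,%d) fit by multi-start maximum likelihood (method: %s)\n",
              x$order$p, x$order$q, x$method))
  est <- c(x$params$phi, x$params$theta,
           if (x$include_mean) x$params$mu)
  nm <- c(if (x$order$p) paste0("ar", seq_len(x$order$p)),
          if (x$order$q) paste0("ma", seq_len(x$order$q)),
          if (x$include_mean) "intercept")
  tab <- rbind(estimate = est)
  if (!is.null(x$se)) tab <- rbind(tab, s.e. = x$se)
  colnames(tab) <- nm
  print(round(tab, digits))
  cat(sprintf("sigma^2 = %s,  log-likelihood = %.6f,  AIC = %.6f\n",
              format(x$params$sigma2, digits = digits), x$loglik, x$aic))
  cat(sprintf("starts: 1 default + %d sampled; best from start %d\n",
              x$n_inits, x$best_init_index))
  invisible(x)
}

#' @export
logLik.arma_fit <- function(object, ...) {
  structure(object$loglik,
            df = object$order$p + object$order$q + 1L + object$include_mean,
            class = "logLik")
}

#' @export
coef.arma_fit <- function(object, ...) {
  est <- c(object$params$phi, object$params$theta,
           if (object$include_mean) object$params$mu)
  names(est) <- c(if (object$order$p) paste0("ar", seq_len(object$order$p)),
                  if (object$order$q) paste0("ma", seq_len(object$order$q)),
                  if (object$include_mean) "intercept")
  est
}
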