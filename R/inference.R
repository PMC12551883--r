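#' Akaike information criterion
#'
#' AIC = -2 * loglik + 2 * d, with d = p + q + 2 when an intercept is
#' estimated (coefficients, intercept, and the innovation-variance
#' estimate), or d = p + q + 1 without one.
#'
#' @param loglik Maximized log-likelihood.
#' @param p,q Model orders.
#' @param with_intercept Was an intercept estimated? Default `TRUE`.
#' @return AIC value.
#' @export
aic <- function(loglik, p, q, with_intercept = TRUE) {
  d <- p + q + 1L + as.integer(with_intercept)
  -2 * loglik + 2 * d
}

# raw-space concentrated negative log-likelihood over
# (phi, theta[, mu]); the AR block must stay causal, the MA block is
# unconstrained (the filter is defined for non-invertible MA parts, which
# matters for curvature evaluation at boundary estimates such as theta ~ 1)
raw_nll_fn <- function(x, p, q, include_mean) {
  function(par) .arma_obj_cpp(par, x, p, q, include_mean, FALSE)
}

raw_par_of_fit <- function(fit) {
  c(fit$params$phi, fit$params$theta, if (fit$include_mean) fit$params$mu)
}

# central-difference Hessian; step = cube root of machine epsilon times the
# parameter scale
num_hessian <- function(fn, par) {
  d <- length(par)
  h <- .Machine$double.eps^(1/3) * pmax(abs(par), 1)
  H <- matrix(NA_real_, d, d)
  f0 <- fn(par)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h[i])
    H[i, i] <- (fn(par + ei) + fn(par - ei) - 2 * f0) / h[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- replace(numeric(d), j, h[j])
      H[i, j] <- H[j, i] <-
        (fn(par + ei + ej) - fn(par + ei - ej) -
           fn(par - ei + ej) + fn(par - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Fisher-information standard errors
#'
#' Standard errors from the inverse of the numerically differentiated
#' Hessian of the negative profile (sigma2-concentrated) log-likelihood at
#' the MLE, in the raw coefficient space -- the same construction whose
#' output is printed by standard ARMA software. Entries are for the
#' coefficients and the intercept; sigma2 is excluded. These SEs are
#' untrustworthy near boundaries or nearly cancelling roots, which is
#' precisely when profile intervals ([profile_ci()]) disagree with them.
#'
#' @param fit An `"arma_fit"` object (from [multistart_fit()]) or a list
#'   with `params`, `include_mean`.
#' @param data The series the model was fitted to.
#' @return Named numeric vector of standard errors (length p + q + 1 with
#'   intercept). `NA` entries, with a warning, when the Hessian is not
#'   positive definite.
#' @export
fisher_standard_errors <- function(fit, data) {
  data <- as_series_data(data)
  p <- length(fit$params$phi); q <- length(fit$params$theta)
  include_mean <- isTRUE(fit$include_mean)
  par <- c(fit$params$phi, fit$params$theta, if (include_mean) fit$params$mu)
  nm <- c(if (p) paste0("ar", seq_len(p)), if (q) paste0("ma", seq_len(q)),
          if (include_mean) "intercept")
  if (length(par) == 0L) return(setNames(numeric(), character()))
  H <- num_hessian(raw_nll_fn(data$values, p, q, include_mean), par)
  se <- rep(NA_real_, length(par))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0)) {
    dg <- if (!is.null(V)) diag(V) else rep(-1, length(par))
    ok <- is.finite(dg) & dg > 0
    se[ok] <- sqrt(dg[ok])
    warning("Hessian is not positive definite; some standard errors are NA ",
            "(possible boundary estimate or parameter redundancy)")
  } else {
    se <- sqrt(diag(V))
  }
  setNames(se, nm)
}

#' Likelihood-ratio threshold on the log-likelihood-difference scale
#'
#' For Delta = ll_1 - ll_0 with 2 * Delta ~ chi-squared(df) under the null,
#' the rejection cutoff at `level` is qchisq(level, df) / 2 (1.92 for the
#' usual 95%, 1 df) and E(Delta | H0) = df / 2.
#'
#' @param level Confidence/significance level in (0, 1).
#' @param df Degrees of freedom (number of constrained parameters).
#' @return An object of class `"lr_threshold"` with `level`, `df`,
#'   `delta_cutoff`, and `e_delta_h0`.
#' @examples
#' lr_threshold(0.95, 1)$delta_cutoff   # 1.92
#' @export
lr_threshold <- function(level, df = 1L) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("'level' must lie in (0, 1)")
  structure(list(level = level, df = as.integer(df),
                 delta_cutoff = qchisq(level, df) / 2,
                 e_delta_h0 = df / 2),
            class = "lr_threshold")
}

# maximize the log-likelihood over the remaining parameters with coefficient
# `idx` (1..p+q, AR block first) held at `value`; completions are restricted
# to the causal/invertible region. Warm-started Nelder-Mead on the raw scale.
profile_refit <- function(x, p, q, include_mean, idx, value, start_rest,
                          maxit = 500L) {
  nfree <- length(start_rest)
  assemble <- function(rest) append(rest, value, after = idx - 1L)
  check_valid <- function(par) {
    phi <- par[seq_len(p)]; theta <- par[p + seq_len(q)]
    (p == 0L || all(Mod(polyroot(c(-rev(phi), 1))) < 1)) &&
      (q == 0L || all(Mod(polyroot(c(rev(theta), 1))) < 1))
  }
  fn <- function(rest) {
    par <- assemble(rest)
    if (!check_valid(par)) return(1e10)
    .arma_obj_cpp(par, x, p, q, include_mean, FALSE)
  }
  if (nfree == 0L) {
    v <- fn(numeric())
    return(list(nll = v, rest = numeric(), feasible = v < 1e9))
  }
  f0 <- fn(start_rest)
  if (f0 >= 1e9) {
    # start infeasible for this grid value; nudge toward the origin
    start_rest <- start_rest * 0.5
    f0 <- fn(start_rest)
    if (f0 >= 1e9) return(list(nll = 1e10, rest = start_rest, feasible = FALSE))
  }
  opt <- if (nfree == 1L)
    optim(start_rest, fn, method = "Brent",
          lower = start_rest - (2 + abs(start_rest)),
          upper = start_rest + (2 + abs(start_rest)))
  else optim(start_rest, fn, method = "Nelder-Mead",
             control = list(maxit = maxit, reltol = 1e-10))
  list(nll = opt$value, rest = opt$par, feasible = opt$value < 1e9)
}

#' Profile-likelihood confidence interval
#'
#' Profiles one coefficient over a grid (holding it fixed and re-maximizing
#' the likelihood over all remaining parameters at each point), and returns
#' the level-`level` interval from Wilks' theorem: all values whose profile
#' log-likelihood lies within qchisq(level, 1) / 2 of the maximum. The grid
#' spans +-5 Fisher standard errors around the MLE (41 points), is extended
#' adaptively towards the causal/invertible boundary when the cutoff has not
#' been crossed, and the endpoints are refined by bisection. When the
#' profile never drops below the cutoff before reaching the boundary of the
#' valid region, the interval is one-sided and flagged.
#'
#' @param data Series (numeric vector or [series_data()]).
#' @param order An [arma_order()] or `c(p, q)`.
#' @param param_index Index of the profiled parameter in
#'   (phi_1..phi_p, theta_1..theta_q, mu), i.e. 1..p+q for the
#'   coefficients, or p+q+1 for the intercept when one is estimated.
#' @param level Confidence level, default 0.95.
#' @param options A [fit_options()] object (passed to the full fit).
#' @param fit Optional precomputed `"arma_fit"` for the full model.
#' @param method Multi-start method for the full fit.
#' @param include_mean Estimate an intercept? Default `TRUE`.
#' @param n_grid Grid resolution, default 41.
#' @return List with `curve` (class `"profile_curve"`: `param_index`,
#'   `grid`, `profile_ll`) and `interval` (class `"conf_interval"`:
#'   `lower`, `upper`, `level`, `method = "profile"`, `estimate`,
#'   `boundary_lower`, `boundary_upper`).
#' @export
profile_ci <- function(data, order, param_index, level = 0.95,
                       options = fit_options(), fit = NULL,
                       method = "rootspace", include_mean = TRUE,
                       n_grid = 41L) {
  data <- as_series_data(data)
  order <- as_arma_order(order)
  p <- order$p; q <- order$q
  npar <- p + q + as.integer(include_mean)
  if (param_index < 1L || param_index > npar)
    stop("'param_index' must index a coefficient in 1..(p+q)",
         if (include_mean) " or p+q+1 for the intercept")
  if (is.null(fit))
    fit <- multistart_fit(data, order, method = method, options = options,
                          include_mean = include_mean, se = TRUE)
  cutoff <- lr_threshold(level, 1L)$delta_cutoff
  llhat <- fit$loglik
  full <- c(fit$params$phi, fit$params$theta,
            if (include_mean) fit$params$mu)
  center <- full[param_index]
  se <- if (!is.null(fit$se) && is.finite(fit$se[param_index]))
    fit$se[param_index] else 0.1
  se <- max(se, 1e-3)
  x <- data$values
  nobs <- sum(!is.na(x))
  const <- -0.5 * nobs * (log(2 * pi) + 1)   # concentrated-likelihood offset

  rest_hat <- full[-param_index]
  step <- 10 * se / (n_grid - 1)

  walk <- function(direction) {
    vals <- numeric(); lls <- numeric()
    rest <- rest_hat
    v <- center
    boundary <- TRUE                 # becomes FALSE once cutoff is crossed
    max_steps <- (n_grid - 1L) %/% 2L + 100L
    for (s in seq_len(max_steps)) {
      v <- v + direction * step
      pr <- profile_refit(x, p, q, include_mean, param_index, v, rest)
      if (!pr$feasible) break        # left the valid region
      rest <- pr$rest
      ll <- const - pr$nll
      vals <- c(vals, v); lls <- c(lls, ll)
      if (llhat - ll > cutoff) { boundary <- FALSE; break }
    }
    list(vals = vals, lls = lls, boundary = boundary)
  }

  lo <- walk(-1); hi <- walk(+1)
  grid <- c(rev(lo$vals), center, hi$vals)
  prof <- c(rev(lo$lls), llhat, hi$lls)

  bisect_end <- function(v_in, v_out, rest) {
    for (i in seq_len(60L)) {
      if (abs(v_out - v_in) < 1e-4) break
      mid <- (v_in + v_out) / 2
      pr <- profile_refit(x, p, q, include_mean, param_index, mid, rest)
      ll <- if (pr$feasible) const - pr$nll else -Inf
      if (llhat - ll <= cutoff) v_in <- mid else v_out <- mid
      if (pr$feasible) rest <- pr$rest
    }
    v_in
  }

  if (!lo$boundary && length(lo$vals)) {
    k <- length(lo$vals)
    lower <- bisect_end(if (k >= 2) lo$vals[k - 1] else center,
                        lo$vals[k], rest_hat)
  } else lower <- if (length(lo$vals)) min(lo$vals) else center
  if (!hi$boundary && length(hi$vals)) {
    k <- length(hi$vals)
    upper <- bisect_end(if (k >= 2) hi$vals[k - 1] else center,
                        hi$vals[k], rest_hat)
  } else upper <- if (length(hi$vals)) max(hi$vals) else center

  curve <- structure(list(param_index = param_index, grid = grid,
                          profile_ll = prof), class = "profile_curve")
  interval <- structure(list(lower = lower, upper = upper, level = level,
                             method = "profile", estimate = center,
                             boundary_lower = lo$boundary,
                             boundary_upper = hi$boundary),
                        class = "conf_interval")
  list(curve = curve, interval = interval)
}

#' @export
print.conf_interval <- function(x, digits = 4, ...) {
  cat(sprintf("%.0f%% %s confidence interval: [%s, %s]%s\n",
              100 * x$level, x$method,
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              if (isTRUE(x$boundary_lower) || isTRUE(x$boundary_upper))
                "  (reaches validity boundary)" else ""))
  invisible(x)
}

#' AIC table over a grid of model orders
#'
#' Fits every order (p, q) in {0..P} x {0..Q} with the requested method and
#' tabulates maximized log-likelihoods and AIC values. Individual cell
#' failures are recorded as `NA` rather than aborting the table. With a
#' seeded `options`, each cell uses a seed derived deterministically from
#' it, so the table is reproducible.
#'
#' @param data Series (numeric vector or [series_data()]).
#' @param P,Q Maximum AR and MA orders, default 3.
#' @param method `"baseline"`, `"rootspace"` or `"pacf"` (see
#'   [multistart_fit()]).
#' @param options A [fit_options()] object.
#' @param include_mean Estimate intercepts? Default `TRUE`.
#' @return An object of class `"aic_table"`: a data frame with columns `p`,
#'   `q`, `loglik`, `aic`, `converged`, plus attributes `P`, `Q`, `method`.
#' @export
aic_table <- function(data, P = 3L, Q = 3L, method = "baseline",
                      options = fit_options(), include_mean = TRUE) {
  data <- as_series_data(data)
  cells <- expand.grid(q = 0:Q, p = 0:P)[, c("p", "q")]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    p <- cells$p[i]; q <- cells$q[i]
    opts <- options
    if (!is.null(opts$seed))
      opts$seed <- (opts$seed + 1009L * p + 101L * q) %% .Machine$integer.max
    f <- tryCatch(
      multistart_fit(data, c(p, q), method = method, options = opts,
                     include_mean = include_mean, se = FALSE),
      error = function(e) NULL)
    if (is.null(f))
      data.frame(p = p, q = q, loglik = NA_real_, aic = NA_real_,
                 converged = FALSE)
    else data.frame(p = p, q = q, loglik = f$loglik, aic = f$aic,
                    converged = f$converged)
  })
  out <- do.call(rbind, res)
  structure(out, P = P, Q = Q, method = method, class = c("aic_table",
                                                          "data.frame"))
}

#' @export
print.aic_table <- function(x, digits = 1, ...) {
  P <- attr(x, "P"); Q <- attr(x, "Q")
  m <- matrix(NA_real_, P + 1L, Q + 1L,
              dimnames = list(paste0("AR", 0:P), paste0("MA", 0:Q)))
  for (i in seq_len(nrow(x))) m[x$p[i] + 1L, x$q[i] + 1L] <- x$aic[i]
  cat(sprintf("AIC table (method: %s)\n", attr(x, "method")))
  print(round(m, digits))
  viol <- consistency_violations(x)
  if (nrow(viol))
    cat(sprintf("WARNING: %d nested-model log-likelihood inconsistenc%s\n",
                nrow(viol), if (nrow(viol) == 1L) "y" else "ies"))
  else cat("Table is consistent (no nested-model inconsistencies).\n")
  invisible(x)
}

#' Nested-model consistency audit of an AIC table
#'
#' A model (p1, q1) is nested in (p2, q2) when p1 <= p2 and q1 <= q2. Under
#' exact likelihood maximization the larger model can never have a lower
#' maximized log-likelihood; any such pair is evidence of an optimization
#' failure. A table is called consistent when this list is empty.
#'
#' @param table An `"aic_table"`.
#' @param tol Log-likelihood slack, default 1e-6.
#' @return Data frame with columns `p_small`, `q_small`, `p_large`,
#'   `q_large`, `deficit` (log-likelihood of the smaller model minus that of
#'   the larger one, always > `tol`).
#' @export
consistency_violations <- function(table, tol = 1e-6) {
  stopifnot(is.data.frame(table))
  out <- data.frame(p_small = integer(), q_small = integer(),
                    p_large = integer(), q_large = integer(),
                    deficit = numeric())
  n <- nrow(table)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    nested <- table$p[i] <= table$p[j] && table$q[i] <= table$q[j] &&
      (table$p[i] < table$p[j] || table$q[i] < table$q[j])
    if (!nested) next
    if (is.na(table$loglik[i]) || is.na(table$loglik[j])) next
    deficit <- table$loglik[i] - table$loglik[j]
    if (deficit > tol)
      out[nrow(out) + 1L, ] <- list(table$p[i], table$q[i],
                                    table$p[j], table$q[j], deficit)
  }
  out
}

#' Parametric bootstrap of refitted coefficients
#'
#' Simulates `n_boot` series of length `n` from the fitted model and refits
#' a (possibly different) order to each, recording the estimated
#' coefficients. Useful for diagnosing boundary pile-up and multimodality
#' (e.g. the MA(1) coefficient piling up near 1 when an over-specified
#' ARMA(2,1) is refit to AR(1) data).
#'
#' @param fit An `"arma_fit"` object (its `params` and `n` define the
#'   generator), or an [arma_params()] object together with `n`.
#' @param order_refit Order to refit on each simulated series; defaults to
#'   the generator's own order.
#' @param n_boot Number of bootstrap replicates.
#' @param method Fit method for the refits, default `"baseline"`.
#' @param options A [fit_options()] object.
#' @param n Series length; defaults to `fit$n`.
#' @param include_mean Estimate intercepts in the refits? Default `TRUE`.
#' @return Matrix with `n_boot` rows and columns (coefficients, intercept,
#'   converged); failed refits appear as `NA` rows.
#' @export
bootstrap_coefficients <- function(fit, order_refit = NULL, n_boot = 100L,
                                   method = "baseline",
                                   options = fit_options(), n = NULL,
                                   include_mean = TRUE) {
  params <- if (inherits(fit, "arma_fit")) fit$params else fit
  stopifnot(inherits(params, "arma_params"))
  if (is.null(n)) n <- if (inherits(fit, "arma_fit")) fit$n
                       else stop("'n' required when 'fit' is arma_params")
  if (is.null(order_refit))
    order_refit <- c(length(params$phi), length(params$theta))
  order_refit <- as_arma_order(order_refit)
  if (!is.null(options$seed)) set.seed(options$seed)
  opts <- options; opts$seed <- NULL   # RNG flows through one stream
  p <- order_refit$p; q <- order_refit$q
  nm <- c(if (p) paste0("ar", seq_len(p)), if (q) paste0("ma", seq_len(q)),
          if (include_mean) "intercept", "converged")
  out <- matrix(NA_real_, n_boot, length(nm), dimnames = list(NULL, nm))
  for (b in seq_len(n_boot)) {
    xb <- simulate_arma(params, n)
    fb <- tryCatch(
      multistart_fit(xb, order_refit, method = method, options = opts,
                     include_mean = include_mean, se = FALSE),
      error = function(e) NULL)
    if (is.null(fb)) next
    out[b, ] <- c(fb$params$phi, fb$params$theta,
                  if (include_mean) fb$params$mu, as.numeric(fb$converged))
  }
  out
}
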