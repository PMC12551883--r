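# AIC, Fisher SEs, profile intervals, consistency audit, bootstrap.

test_that("aic applies the d = p + q + 2 rule", {
  expect_equal(aic(0, 0, 0), 4)
  # back-derived from a published-style table cell: ll = 24.45, ARMA(2,2)
  # with intercept (d = 6) -> AIC = -36.9
  expect_equal(aic(24.45, 2, 2), -36.9)
  expect_equal(aic(10, 1, 1, with_intercept = FALSE), -20 + 2 * 3)
  # one log-lik unit with d fixed moves AIC by exactly -2
  expect_equal(aic(11, 2, 1) - aic(10, 2, 1), -2)
})

test_that("lr_threshold reproduces the chi-squared arithmetic", {
  t1 <- lr_threshold(0.95, 1)
  expect_equal(t1$delta_cutoff, 1.92, tolerance = 0.005)
  expect_equal(t1$e_delta_h0, 0.5)
  expect_equal(lr_threshold(0.95, 2)$delta_cutoff, 2.996, tolerance = 0.001)
  expect_error(lr_threshold(1.2), "level")
})

test_that("fisher_standard_errors matches closed forms", {
  set.seed(31)
  y <- rnorm(500, 1, 2)
  f <- multistart_fit(y, c(0, 0), method = "baseline", se = TRUE)
  # intercept-only model: se(mu) = sigma-hat / sqrt(n)
  expect_equal(unname(f$se["intercept"]),
               sqrt(f$params$sigma2 / 500), tolerance = 0.02)

  phi <- 0.6; n <- 5000
  x <- simulate_arma(arma_params(phi = phi), n)
  f1 <- multistart_fit(x, c(1, 0), method = "baseline", se = TRUE)
  # classical asymptotic s.e. sqrt((1 - phi^2)/n)
  expect_equal(unname(f1$se["ar1"]), sqrt((1 - phi^2) / n),
               tolerance = 0.15)
})

test_that("profile interval matches exact normal theory for the mean", {
  set.seed(32)
  n <- 150
  y <- rnorm(n, 5, 2)
  pr <- profile_ci(y, c(0, 0), 1, level = 0.95,
                   options = fit_options(seed = 1))
  mu <- mean(y); s <- sqrt(mean((y - mu)^2))
  # for Gaussian data the mu-profile interval is mean +- ~1.96 s/sqrt(n)
  expect_equal(pr$interval$lower, mu - 1.96 * s / sqrt(n), tolerance = 0.01)
  expect_equal(pr$interval$upper, mu + 1.96 * s / sqrt(n), tolerance = 0.01)
  expect_false(pr$interval$boundary_lower)
  expect_false(pr$interval$boundary_upper)
})

test_that("profile curve and interval obey their invariants", {
  set.seed(33)
  x <- simulate_arma(arma_params(phi = 0.5, theta = 0.3), 90)
  fit <- multistart_fit(x, c(1, 1), options = fit_options(seed = 2, M = 3),
                        se = TRUE)
  pr95 <- profile_ci(x, c(1, 1), 2, level = 0.95, fit = fit)
  # profile never exceeds the global maximum
  expect_lte(max(pr95$curve$profile_ll), fit$loglik + 1e-6)
  # interval contains the MLE
  th <- fit$params$theta
  expect_lte(pr95$interval$lower, th)
  expect_gte(pr95$interval$upper, th)
  # widening the level widens the interval
  pr80 <- profile_ci(x, c(1, 1), 2, level = 0.80, fit = fit)
  expect_lte(pr95$interval$lower, pr80$interval$lower + 1e-6)
  expect_gte(pr95$interval$upper, pr80$interval$upper - 1e-6)
})

test_that("MA(1) profile interval has near-nominal coverage at theta = 0", {
  set.seed(34)
  hits <- 0; nrep <- 60
  for (i in 1:nrep) {
    x <- rnorm(60)   # theta = 0 white noise
    pr <- tryCatch(profile_ci(x, c(0, 1), 1, level = 0.95,
                              options = fit_options(M = 2)),
                   error = function(e) NULL)
    if (is.null(pr)) next
    hits <- hits + (pr$interval$lower <= 0 && pr$interval$upper >= 0)
  }
  # 95% nominal; allow 4 sigma binomial slack at 60 replicates
  expect_gt(hits / nrep, 0.95 - 4 * sqrt(0.05 * 0.95 / nrep))
})

test_that("aic_table fits the grid and respects nesting against (0,0)", {
  set.seed(35)
  x <- rnorm(150, 2)
  tab <- aic_table(x, 2, 2, method = "rootspace",
                   options = fit_options(seed = 4, M = 3))
  expect_equal(nrow(tab), 9L)
  expect_true(all(is.finite(tab$aic)))
  ll0 <- tab$loglik[tab$p == 0 & tab$q == 0]
  # the white-noise cell is closed-form; every larger model must reach at
  # least its log-likelihood, so AIC can exceed AIC(0,0) by at most 2(p+q)
  expect_true(all(tab$loglik >= ll0 - 1e-6))
  a0 <- tab$aic[tab$p == 0 & tab$q == 0]
  expect_true(all(tab$aic <= a0 + 2 * (tab$p + tab$q) + 1e-6))
})

test_that("consistency_violations agrees with a brute-force oracle", {
  brute <- function(tb, tol = 1e-6) {
    out <- 0L
    for (i in seq_len(nrow(tb))) for (j in seq_len(nrow(tb))) {
      if (i == j) next
      if (tb$p[i] <= tb$p[j] && tb$q[i] <= tb$q[j] &&
          !(tb$p[i] == tb$p[j] && tb$q[i] == tb$q[j]) &&
          !is.na(tb$loglik[i]) && !is.na(tb$loglik[j]) &&
          tb$loglik[i] > tb$loglik[j] + tol)
        out <- out + 1L
    }
    out
  }
  set.seed(36)
  for (i in 1:20) {
    tb <- expand.grid(p = 0:3, q = 0:3)
    tb$loglik <- cumsum(runif(16, -0.5, 1))[order(order(tb$p + tb$q))] +
      rnorm(16, sd = 0.8)
    tb$aic <- -2 * tb$loglik + 2 * (tb$p + tb$q + 2)
    v <- consistency_violations(tb)
    expect_equal(nrow(v), brute(tb))
    if (nrow(v)) expect_true(all(v$deficit > 1e-6))
  }
  # a perfectly monotone table is consistent
  tb <- expand.grid(p = 0:2, q = 0:2)
  tb$loglik <- tb$p + tb$q
  expect_equal(nrow(consistency_violations(tb)), 0L)
})

test_that("bootstrap refits are valid and centered (white noise)", {
  set.seed(37)
  B <- bootstrap_coefficients(arma_params(mu = 3, sigma2 = 4), c(0, 0),
                              n_boot = 60, n = 100,
                              options = fit_options(seed = 6))
  expect_equal(mean(B[, "intercept"]), 3, tolerance = 3 * 2 / sqrt(100 * 60))
  expect_equal(sd(B[, "intercept"]), 2 / sqrt(100), tolerance = 0.25)
})

test_that("over-specified refits of AR(1) data pile theta1 near 1", {
  set.seed(38)
  gen <- arma_params(phi = 0.79, mu = 176.5, sigma2 = 0.01)
  B <- bootstrap_coefficients(gen, c(2, 1), n_boot = 80, n = 155,
                              method = "rootspace",
                              options = fit_options(seed = 7, M = 3))
  expect_gt(mean(B[, "ma1"] > 0.9, na.rm = TRUE), 0.10)
  # every refit must itself be causal
  caus <- apply(B, 1, function(row)
    is_causal(arma_params(phi = row[c("ar1", "ar2")])))
  expect_true(all(caus, na.rm = TRUE))
})
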