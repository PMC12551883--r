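# Single-start MLE, default initialization, the two samplers, multistart.

test_that("fit_single recovers closed forms and honors the ascent contract", {
  set.seed(21)
  y <- rnorm(300, 4, 2)
  f <- fit_single(y, c(0, 0))
  expect_equal(f$params$mu, mean(y), tolerance = 1e-10)
  expect_equal(f$params$sigma2, mean((y - mean(y))^2), tolerance = 1e-10)
  expect_true(f$converged)

  truth <- arma_params(phi = 0.6)
  x <- simulate_arma(truth, 1000)
  f1 <- fit_single(x, c(1, 0))
  expect_lt(abs(f1$params$phi - 0.6), 0.1)
  expect_true(is_valid_arma(f1$params))

  # starting at the truth can only go up
  f2 <- fit_single(x, c(1, 0), init = truth)
  expect_gte(f2$loglik, kalman_loglik(arma_params(phi = 0.6, mu = 0,
                                                  sigma2 = f2$params$sigma2),
                                      x) - 1e-6)
})

test_that("default_init follows the CSS-then-origin rule", {
  set.seed(22)
  x <- simulate_arma(arma_params(phi = 0.5), 400)
  init <- default_init(x, c(1, 0))
  expect_identical(attr(init, "source"), "css")
  expect_true(is_valid_arma(init))

  # strongly trending series pushes the CSS AR(1) solution outside the
  # causal region -> origin
  tr <- 1.05^(1:80)
  init2 <- default_init(tr, c(1, 0))
  expect_identical(attr(init2, "source"), "origin")
  expect_equal(init2$phi, 0)
  expect_equal(init2$mu, mean(tr))

  # missing data -> CSS unavailable -> origin
  x[5] <- NA
  init3 <- default_init(x, c(1, 0))
  expect_identical(attr(init3, "source"), "origin")
})

test_that("root-space sampler respects its construction guarantees", {
  set.seed(23)
  opts <- fit_options(alpha = 0.01, gamma = 0.05)
  ok_valid <- TRUE; ok_mod <- TRUE; ok_dist <- TRUE
  for (i in 1:2000) {
    p <- sample(0:3, 1); q <- sample(0:3, 1)
    if (p + q == 0) next
    m <- sample_init_rootspace(c(p, q), opts)
    rs <- coefficients_to_inverted_roots(m)
    mods <- Mod(c(rs$ar_inv, rs$ma_inv))
    ok_valid <- ok_valid && is_valid_arma(m)
    ok_mod <- ok_mod && all(mods >= opts$gamma - 1e-8) &&
      all(mods <= 1 - opts$gamma + 1e-8)
    ok_dist <- ok_dist && min_cross_root_distance(rs) >= opts$alpha
  }
  expect_true(ok_valid)
  expect_true(ok_mod)
  expect_true(ok_dist)
})

test_that("root-space AR(2) draws have the designed coefficient sign mix", {
  # with pairs real w.p. 1/2 and real pairs same-signed w.p. 1/2:
  # phi1 = z1 + z2 is sign-balanced (P = 1/2), while phi2 = -z1 z2 > 0
  # only for real opposite-signed pairs (P = 1/4); an all-complex sampler
  # would give P(phi2 > 0) = 0
  set.seed(24)
  n <- 10000
  draws <- replicate(n, sample_init_rootspace(c(2, 0))$phi)
  expect_lt(abs(mean(draws[1, ] > 0) - 0.5), 5 * sqrt(0.25 / n))
  expect_lt(abs(mean(draws[2, ] > 0) - 0.25), 5 * sqrt(0.1875 / n))
})

test_that("Durbin-Levinson sampler is valid and uniform for order 1", {
  set.seed(25)
  opts <- fit_options(alpha = 0.01, gamma = 0.05)
  ok <- TRUE
  for (i in 1:2000) {
    p <- sample(0:3, 1); q <- sample(0:3, 1)
    if (p + q == 0) next
    m <- sample_init_pacf(c(p, q), opts)
    rs <- coefficients_to_inverted_roots(m)
    ok <- ok && is_valid_arma(m) &&
      min_cross_root_distance(rs) >= opts$alpha
  }
  expect_true(ok)

  # p = 1: coefficient drawn directly from U(-1+gamma, 1-gamma)
  draws <- replicate(3000, sample_init_pacf(c(1, 0), opts)$phi)
  ks <- suppressWarnings(stats::ks.test(draws, "punif", -0.95, 0.95))
  expect_gt(ks$p.value, 0.001)

  # strict mode restricts PACFs for block orders >= 2 to (gamma, 1-gamma)
  opts_strict <- fit_options(strict_pacf = TRUE)
  m <- sample_init_pacf(c(3, 0), opts_strict)
  expect_true(all(coefficients_to_pacf(m)$ar_pacf > 0))
})

test_that("multistart never loses to the baseline and is deterministic", {
  set.seed(26)
  x <- simulate_arma(arma_params(phi = 0.5, theta = 0.4), 120)
  base <- multistart_fit(x, c(1, 1), method = "baseline",
                         options = fit_options(seed = 5), se = FALSE)
  expect_equal(base$n_inits, 0L)
  for (meth in c("rootspace", "pacf")) {
    ms <- multistart_fit(x, c(1, 1), method = meth,
                         options = fit_options(seed = 5, M = 4), se = FALSE)
    expect_gte(ms$loglik, base$loglik)
    ms2 <- multistart_fit(x, c(1, 1), method = meth,
                          options = fit_options(seed = 5, M = 4), se = FALSE)
    expect_identical(ms$loglik, ms2$loglik)
    expect_identical(ms$init_trace, ms2$init_trace)
  }
  # baseline is identical to multistart with max_inits = 0
  ms0 <- multistart_fit(x, c(1, 1), method = "rootspace",
                        options = fit_options(seed = 5, max_inits = 0),
                        se = FALSE)
  expect_identical(ms0$loglik, base$loglik)
})

test_that("a larger patience M never decreases the log-likelihood", {
  set.seed(27)
  x <- simulate_arma(arma_params(phi = c(0.4, -0.3), theta = c(0.5, 0.2)), 60)
  lls <- sapply(c(2L, 5L, 10L), function(M)
    multistart_fit(x, c(2, 2), method = "rootspace",
                   options = fit_options(seed = 9, M = M), se = FALSE)$loglik)
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("multistart escapes a local optimum on a bimodal MA(1) instance", {
  # seed pre-screened with the dense theta-grid enumeration oracle: the
  # single CSS-initialized fit lands on a local maximum
  set.seed(114)
  x <- simulate_arma(arma_params(theta = 0.9), 50)
  base <- fit_single(x, c(0, 1), include_mean = FALSE)
  grid <- seq(-0.98, 0.98, by = 0.005)
  grid_max <- max(sapply(grid, function(th)
    concentrated_ll_oracle(numeric(), th, x)))
  expect_lt(base$loglik, grid_max - 0.2)   # baseline is trapped
  ms <- multistart_fit(x, c(0, 1), method = "rootspace",
                       include_mean = FALSE,
                       options = fit_options(seed = 1), se = FALSE)
  expect_gt(ms$loglik, base$loglik + 0.2)
  expect_gte(ms$loglik, grid_max - 1e-3)
})

test_that("fit options are validated", {
  expect_error(fit_options(gamma = 0.6), "gamma")
  expect_error(fit_options(alpha = -1), "alpha")
  expect_error(fit_options(M = 0), "M")
  expect_error(fit_single(rnorm(3), c(1, 1)), "too few")
})
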