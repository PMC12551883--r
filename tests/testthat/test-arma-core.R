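# Parameterization, root algebra, PACF transform, simulation.

test_that("coefficients_to_inverted_roots matches factoring oracle", {
  # ARMA(1,1): 1 - x/3 has root 3 -> inverted 1/3; 1 + 2x/3 -> inverted -2/3
  rs <- coefficients_to_inverted_roots(arma_params(phi = 1/3, theta = 2/3))
  expect_equal(rs$ar_inv, complex(real = 1/3), tolerance = 1e-10)
  expect_equal(rs$ma_inv, complex(real = -2/3), tolerance = 1e-10)

  # ARMA(2,2) sharing the root 1/2 with the model above
  rs2 <- coefficients_to_inverted_roots(
    arma_params(phi = c(5/6, -1/6), theta = c(1/6, -1/3)))
  expect_equal(sort(Re(rs2$ar_inv)), c(1/3, 1/2), tolerance = 1e-10)
  expect_equal(sort(Re(rs2$ma_inv)), c(-2/3, 1/2), tolerance = 1e-10)
  expect_equal(max(abs(Im(c(rs2$ar_inv, rs2$ma_inv)))), 0, tolerance = 1e-10)

  # white noise: no roots
  rs0 <- coefficients_to_inverted_roots(arma_params())
  expect_length(rs0$ar_inv, 0)
  expect_length(rs0$ma_inv, 0)
})

test_that("inverted_roots_to_coefficients inverts the root map", {
  co <- inverted_roots_to_coefficients(root_set(c(1/2, 1/3), c(1/2, -2/3)))
  expect_equal(co$phi, c(5/6, -1/6), tolerance = 1e-10)
  expect_equal(co$theta, c(1/6, -1/3), tolerance = 1e-10)

  expect_equal(inverted_roots_to_coefficients(root_set(0.7))$phi, 0.7)

  # unmatched complex root must be rejected
  expect_error(inverted_roots_to_coefficients(root_set(complex(real = 0.3,
                                                               imaginary = 0.4))),
               "conjugate")
})

test_that("root <-> coefficient round trip is the identity (property)", {
  set.seed(101)
  worst <- 0
  for (i in 1:50) {
    p <- sample(0:5, 1); q <- sample(0:5, 1)
    m <- sample_init_rootspace(c(p, q), fit_options(gamma = 0.02))
    rs <- coefficients_to_inverted_roots(m)
    co <- inverted_roots_to_coefficients(rs)
    worst <- max(worst, abs(c(co$phi - m$phi, co$theta - m$theta, 0)))
  }
  expect_lt(worst, 1e-8)
})

test_that("min_cross_root_distance handles shared roots and empty sides", {
  rs <- coefficients_to_inverted_roots(
    arma_params(phi = c(5/6, -1/6), theta = c(1/6, -1/3)))
  expect_equal(min_cross_root_distance(rs), 0, tolerance = 1e-10)
  expect_identical(min_cross_root_distance(root_set(ma_inv = c(0.5))), Inf)
  expect_identical(min_cross_root_distance(root_set(ar_inv = c(0.5))), Inf)
  expect_equal(min_cross_root_distance(root_set(0.3, -0.3)), 0.6)
})

test_that("causality and invertibility are strict unit-circle conditions", {
  expect_true(is_causal(arma_params(phi = 1/3)))
  expect_false(is_causal(arma_params(phi = 1.0)))   # unit root excluded
  expect_true(is_causal(arma_params(phi = c(5/6, -1/6))))
  expect_true(is_invertible(arma_params(theta = 2/3)))
  expect_false(is_invertible(arma_params(theta = 1.0)))
  expect_true(is_valid_arma(arma_params()))
})

test_that("pacf_to_coefficients matches the hand recursion", {
  expect_equal(pacf_to_coefficients(0.37)$phi, 0.37)
  a <- 0.4; b <- -0.55
  expect_equal(pacf_to_coefficients(c(a, b))$phi, c(a * (1 - b), b))
  # MA block: same expansion, negated
  expect_equal(pacf_to_coefficients(ma_pacf = c(a, b))$theta,
               -c(a * (1 - b), b))
  expect_error(pacf_to_coefficients(1.0), "inside")
})

test_that("pacf map always lands in the valid region and inverts (property)", {
  set.seed(202)
  all_valid <- TRUE
  worst <- 0
  for (i in 1:2000) {
    p <- sample(1:4, 1); q <- sample(0:4, 1)
    xi_ar <- runif(p, -0.999, 0.999)
    xi_ma <- runif(q, -0.999, 0.999)
    co <- pacf_to_coefficients(xi_ar, xi_ma)
    m <- arma_params(phi = co$phi, theta = co$theta)
    all_valid <- all_valid && is_causal(m) && is_invertible(m)
    back <- coefficients_to_pacf(m)
    worst <- max(worst, abs(c(back$ar_pacf - xi_ar, back$ma_pacf - xi_ma, 0)))
  }
  expect_true(all_valid)
  expect_lt(worst, 1e-8)
})

test_that("AR(2) from a conjugate pair always has phi2 = -|z|^2 < 0", {
  set.seed(303)
  worst <- 0; all_neg <- TRUE
  for (i in 1:200) {
    z <- complex(modulus = runif(1, 0.05, 0.95), argument = runif(1, 1e-3, pi - 1e-3))
    co <- inverted_roots_to_coefficients(root_set(c(z, Conj(z))))
    worst <- max(worst, abs(co$phi[2] + Mod(z)^2))
    all_neg <- all_neg && co$phi[2] < 0
  }
  expect_lt(worst, 1e-10)
  expect_true(all_neg)
})

test_that("simulate_arma reproduces stationary moments", {
  set.seed(404)
  n <- 1e5
  # white noise
  x <- simulate_arma(arma_params(), n)
  expect_lt(abs(var(x) - 1), 3 * sqrt(2 / n))
  # AR(1): lag-1 autocorrelation 0.5
  x <- simulate_arma(arma_params(phi = 0.5), n)
  r1 <- cor(x[-1], x[-n])
  expect_lt(abs(r1 - 0.5), 3 * sqrt((1 - 0.25) / n))
  # MA(1): variance sigma2 (1 + theta^2) = 1.25
  x <- simulate_arma(arma_params(theta = 0.5), n)
  expect_lt(abs(var(x) - 1.25), 3 * 1.25 * sqrt(2 / n))
})

test_that("simulated autocovariances match the theoretical oracle at lags 0..3", {
  set.seed(505)
  m <- arma_params(phi = c(0.6, -0.2), theta = c(0.4), mu = 3, sigma2 = 2)
  n <- 2e5
  x <- simulate_arma(m, n)
  g_theory <- arma_autocov(m, 3)
  xc <- x - mean(x)
  for (h in 0:3) {
    g_hat <- mean(xc[1:(n - h)] * xc[(1 + h):n])
    expect_lt(abs(g_hat - g_theory[h + 1]), 5 * g_theory[1] / sqrt(n / 10))
  }
})

test_that("simulation is reproducible and validates inputs", {
  set.seed(7); a <- simulate_arma(arma_params(phi = 0.5), 20)
  set.seed(7); b <- simulate_arma(arma_params(phi = 0.5), 20)
  expect_identical(a, b)
  expect_error(simulate_arma(arma_params(phi = 1.2), 10), "causal")
  expect_error(arma_params(sigma2 = -1), "sigma2")
})
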