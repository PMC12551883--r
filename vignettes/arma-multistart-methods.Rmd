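---
title: "Multi-start maximum likelihood for ARMA models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-start maximum likelihood for ARMA models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and the estimation problem

A zero-mean weakly stationary process $\{x_t\}$ is ARMA($p$,$q$) when

$$x_t = \phi_1 x_{t-1} + \dots + \phi_p x_{t-p} + w_t + \theta_1 w_{t-1}
  + \dots + \theta_q w_{t-q},$$

with $\{w_t\}$ Gaussian white noise of variance $\sigma^2_w$. `armamle`
additionally estimates an intercept $\mu$, applying the recursion to
$x_t - \mu$. Writing $\Phi(x) = 1 - \phi_1 x - \dots - \phi_p x^p$ and
$\Theta(x) = 1 + \theta_1 x + \dots + \theta_q x^q$, the model is *causal*
and *invertible* when all roots of $\Phi$ and $\Theta$ lie outside the
complex unit circle — equivalently, when all *inverted* roots
($\lambda_i$ for the AR side, $\nu_j$ for the MA side) lie strictly inside
it. Estimation is by maximizing the exact Gaussian likelihood, evaluated by
the Kalman filter on the companion state-space form
$z_t = T z_{t-1} + Q w_t$, $x_t = (1,0,\dots,0) z_t + \mu$, with state
dimension $r = \max(p, q+1)$ and the filter initialized at the exact
stationary distribution (the solution of $P = TPT' + \sigma^2 QQ'$).

The difficulty this package addresses is that the ARMA log-likelihood is
often multimodal — especially for mixed models, short series, and
over-specified orders where AR and MA roots nearly cancel (if
$\lambda_i = \nu_j$ the factors cancel and the model collapses to a smaller
order; nearly equal roots flatten the surface the same way). The standard
single initialization — the conditional-sum-of-squares (CSS) estimate, or
the origin when the CSS point is unusable — then converges to a local
maximum in a non-negligible fraction of datasets. The remedy implemented
here is a multiple-initialization search over random starting points drawn
*inside* the causal/invertible region.

## The two initialization samplers

**Root-space sampling** (`sample_init_rootspace()`) draws the inverted
roots directly, in pairs. Each pair is declared real with probability 1/2;
real pairs get independent $U(\gamma, 1-\gamma)$ magnitudes and equal signs
with probability 1/2; complex pairs get an angle $\tau \sim U(0,\pi)$ and a
radius $U(\gamma, 1-\gamma)$, closed under conjugation; an odd leftover
root is real with a random sign. Coefficients are recovered by expanding
the polynomials. Sampling in an annulus ($\gamma \le |z| \le 1-\gamma$,
default $\gamma = 0.05$) avoids degenerate and near-unit-root starts. The
real/complex mixing matters: an all-complex sampler could never produce,
e.g., $\phi_2 = -\lambda_1\lambda_2 > 0$ in an AR(2). Note the achieved
sign mix: $\phi_1$ is sign-balanced, while $\phi_2 > 0$ occurs with
probability 1/4 (only real, opposite-signed pairs give it); claims that the
pair *product* is sign-balanced under this scheme do not survive the
algebra, and our tests assert the derived 1/4.

**Durbin-Levinson sampling** (`sample_init_pacf()`) draws partial
autocorrelations and expands them through the Durbin-Levinson recursion
$\xi_{i,h} = \xi_{i-1,h} - \xi_{i,i}\,\xi_{i-1,i-h}$, which maps
$(-1,1)^p$ bijectively onto the causal region (MA entries are negated to
land in the invertible region under the $\Theta(x) = 1 + \theta_1 x +
\dots$ convention). A block of order 1 samples its single coefficient
directly from $U(-1+\gamma, 1-\gamma)$. For blocks of order $\ge 2$ we
sample each $\xi_{i,i}$ from the symmetric range $U(-1+\gamma, 1-\gamma)$:
a positive-only range (available as `fit_options(strict_pacf = TRUE)` for
strict reproduction) cannot reach every admissible model, which would
defeat the purpose of the sampler. This was a genuinely open design point;
we chose coverage of the full region as the default.

Both samplers reject draws whose minimum Euclidean distance between
inverted AR and MA roots falls below $\alpha$ (default 0.01), excluding
nearly cancelling — hence nearly redundant — starting models. The distance
is $+\infty$ by convention when $p = 0$ or $q = 0$, where cancellation is
impossible.

## The fitting loop

`multistart_fit()` first fits from the default initialization: the CSS
estimate when the series is complete and the estimate is causal (a
non-invertible MA part is replaced by its observationally equivalent
invertible reflection, as standard software does), otherwise the origin —
in particular, missing data always start at the origin, since CSS is
undefined across gaps. It then repeatedly draws a random start, fits, and
stops once the last $M$ consecutive starts (default 10, capped at
`max_inits = 100`) fail to improve the incumbent log-likelihood by more
than `improvement_tol = 1e-4`; the tolerance guards against
non-terminating floating-point jitter, a point on which we had to make our
own choice. The returned fit maximizes over all starts, so by construction
it can never be worse than the single-initialization baseline
(`method = "baseline"` reproduces that baseline exactly). With a fixed
`seed` the whole trace is reproducible, and because $M$ only decides when
to stop — never which starts are drawn — the explored set under a smaller
$M$ is a prefix of that under a larger one, making the achieved
log-likelihood monotone in $M$ under a common seed.

Each individual fit maximizes the concentrated log-likelihood
($\sigma^2_w$ profiled out analytically, halving no dimensions but
removing one) by BFGS in an unconstrained space: coefficients are
tanh-bounded partial autocorrelations expanded through Durbin-Levinson, so
every optimizer iterate is strictly causal and invertible. This mirrors
the transformation used by the standard software whose single-start
behaviour we use as the baseline, and we kept that software's optimizer
tolerances (BFGS, `maxit = 100`, default relative tolerance) so that the
baseline arm of every comparison is representative rather than
artificially weak or strong. During development we verified head-to-head
on simulated study data that the single-start fit and the reference
implementation agree to six decimals on typical series and disagree
symmetrically (wins ≈ losses) on hard multimodal ones.

## Numerical choices

* **Stationary initialization.** Both the filter and `simulate_arma()`
  start from an exact draw of the stationary state distribution; the
  simulator therefore has no burn-in hyperparameter and no truncation
  bias, and matches the likelihood's own view of the process.
* **Steady-state filtering.** Once successive predicted state covariances
  agree to a relative $10^{-12}$, the filter freezes the gain and runs in
  $O(r)$ per observation. Disabled when the series has missing values
  (a skipped update perturbs the covariance recursion). This is purely a
  speed optimization; the acceptance suite checks the filter against a
  dense multivariate-normal oracle to $10^{-6}$.
* **Innovation-variance floor** at $10^{-12}$ prevents `log(0)` at
  near-degenerate points the optimizer may visit.
* **Missing values** are `NA` sentinels: the Kalman filter does
  prediction-only steps, CSS refuses them.
* **Conjugate-pair tolerance.** Root multisets whose polynomial expansion
  has imaginary residue above $10^{-8}$ are rejected; below that it is
  truncated.
* **CSS internals.** The CSS stage minimizes $\tfrac12\log(\text{mean
  squared residual})$ — the reference software's better-conditioned scale,
  with the same minimizer — and reports $\hat\sigma^2 = \mathrm{CSS}/(n-p)$;
  the divisor is immaterial because $\sigma^2$ is re-estimated at the MLE
  stage.

## Inference

**Fisher standard errors** come from the inverse numerical Hessian
(central differences, step $\varepsilon^{1/3}$ times parameter scale) of
the concentrated negative log-likelihood at the MLE, in raw coefficient
space — the construction whose output standard software prints. They are
reported for coefficients and intercept only, matching that output; a
non-positive-definite Hessian yields `NA`s with a warning, which is itself
diagnostic of boundary estimates or parameter redundancy.

**Profile-likelihood intervals** (`profile_ci()`) re-maximize all other
parameters at each grid value of one coefficient (41 points spanning ±5
Fisher SEs, extended adaptively, endpoints refined by bisection to
$10^{-4}$) and cut at $\chi^2_1(\text{level})/2$ below the maximum — 1.92
at 95%. Completions are restricted to the causal/invertible region; when
the profile never drops below the cutoff before the region's edge the
interval is one-sided and flagged. Near boundaries and near-cancelling
roots the quadratic approximation behind Fisher intervals fails while the
profile construction does not, which is why the coverage study compares
them.

**AIC tables** use $\mathrm{AIC} = -2\hat\ell + 2d$ with $d = p+q+2$ when
an intercept is estimated (the extra parameter being the variance). A
table is *inconsistent* when some model nested in another (componentwise
$p_1 \le p_2$, $q_1 \le q_2$) shows a higher maximized log-likelihood —
impossible under exact maximization, so a direct audit of optimization
quality. "Nested" is taken as the standard componentwise partial order.

## The simulation studies and what a green test establishes

`sample_generative_model()` draws study truth: a causal, invertible model
with **all pairwise distances among the pooled inverted roots ≥ 0.1**
(the stricter reading of "between all roots", which also excludes
near-repeated roots and hence all parameter redundancies) and all moduli
≤ 0.95 (`boundary_margin = 0.05`; "not near boundary conditions" was
unquantified, and 0.05 matches the samplers' annulus). Generative
$\sigma^2 = 1$, $\mu = 0$ — the likelihood geometry is location/scale
equivariant, so this is harmless — while all study fits estimate an
intercept, mirroring $d = p+q+2$.

The three harnesses reproduce, at configurable scale:

1. **Improvement study** — orders $(p,q) \in \{1,2,3\}^2$, lengths
   $n \in \{50,100,500,1000\}$, one series per generated model, true-order
   fits; records how often and by how much each sampler beats the
   single-start baseline.
2. **Consistency study** — 4×4 AIC tables per dataset; fraction of tables
   with a nested-model inconsistency, for the baseline and for multistart
   at each patience $M$ (in the $M$-sweep, "$M = 1$" is read as the plain
   single-start procedure and reported as the baseline row).
3. **Coverage study** — per generative model, repeated datasets with
   Bonferroni-adjusted joint intervals for the coefficients (each at level
   $1 - 0.05/(p+q)$; coefficients only, matching what standard software
   reports SEs for; a white-noise cell audits $\mu$ instead), comparing
   Fisher and profile constructions on attainment of nominal coverage.

The defaults are reduced-scale (100 models per cell rather than 1000; the
acceptance script uses 50, and its single-cell and consistency portions
100 and 10, chosen from runtime measurements to fit a single-CPU budget).
Consequences to keep in mind: reproduced rates carry binomial Monte-Carlo
error of a few percentage points, and the reference values these studies
are compared against come from runs whose exact generative-parameter
distribution is not public, so they are tolerance targets, not exact
oracles. Our runs land close to them (pooled improvement ≈ 23%,
hardest-cell ≈ 61%, per-sampler ≈ 21% and 20%, median gain ≈ 0.77,
baseline inconsistency ≈ 42%). A green suite
establishes that the engine maximizes the exact likelihood correctly
(dense-oracle agreement), that multistart dominates the baseline by
construction, and that the reproduced aggregate rates fall within
Monte-Carlo-plus-reproduction tolerance of the reference values — not that
any real dataset resembles the Gaussian-ARMA ideal; real series bring
model misspecification, which these simulations deliberately exclude.

## Known limitations

* Pure-ARMA only: no differencing, seasonal polynomials, or exogenous
  regressors.
* The likelihood assumes Gaussian innovations; the engine is exact under
  that assumption, not robust to heavy tails or outliers.
* Profile refits use derivative-free search warm-started along the grid;
  pathological profiles (multiple disconnected level sets) are traced
  only as far as the walk explores.
* Multistart raises cost roughly in proportion to the number of starts;
  it is aimed at the small-to-moderate $n$ regime where single starts
  fail most and compute is cheapest.
* A higher likelihood is not automatically a scientifically better model —
  it can sit near a boundary or a near-cancellation; the bootstrap and
  profile tools exist precisely to scrutinize such fits.
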