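#' Simulation-study configuration
#'
#' Describes one of the three experiments quantifying the behaviour of
#' single- versus multiple-initialization fitting: the likelihood
#' improvement study, the AIC-table consistency study, and the confidence
#' interval coverage study. The full-scale design uses orders (p, q) in
#' \{1,2,3\}^2, lengths n in \{50, 100, 500, 1000\} and 1000 models per
#' cell; the defaults here are reduced-scale (100 models per cell) so the
#' studies run on a laptop, at the cost of wider Monte-Carlo error.
#'
#' @param orders Data frame or matrix with columns `p` and `q`; defaults to
#'   all of \{1,2,3\}^2.
#' @param sizes Series lengths; default `c(50, 100, 500, 1000)`.
#' @param n_models Generative models (and datasets) per (order, size) cell;
#'   default 100.
#' @param n_reps_per_model Datasets per model in the coverage study;
#'   default 25.
#' @param methods Multi-start methods to compare; default both samplers.
#' @param M_values Stopping-patience values swept by the consistency study.
#' @param seed Master seed; every replicate derives its own seed from it.
#' @param min_root_distance Minimum pairwise distance among the pooled
#'   inverted roots of a generative model; default 0.1.
#' @param boundary_margin Keep generative root moduli below
#'   `1 - boundary_margin`; default 0.05.
#' @param options A [fit_options()] used for all fits (its `seed` is
#'   ignored; seeding is governed by `seed`).
#' @param P,Q AIC-table extent for the consistency study; default 3.
#' @param level Nominal joint coverage level for the coverage study.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(orders = expand.grid(p = 1:3, q = 1:3),
                         sizes = c(50L, 100L, 500L, 1000L),
                         n_models = 100L, n_reps_per_model = 25L,
                         methods = c("rootspace", "pacf"),
                         M_values = c(10L), seed = 1L,
                         min_root_distance = 0.1, boundary_margin = 0.05,
                         options = fit_options(), P = 3L, Q = 3L,
                         level = 0.95) {
  orders <- as.data.frame(orders)
  stopifnot(all(c("p", "q") %in% names(orders)), n_models >= 1,
            n_reps_per_model >= 1, min_root_distance >= 0,
            boundary_margin >= 0)
  structure(list(orders = orders, sizes = as.integer(sizes),
                 n_models = as.integer(n_models),
                 n_reps_per_model = as.integer(n_reps_per_model),
                 methods = match.arg(methods, c("rootspace", "pacf"),
                                     several.ok = TRUE),
                 M_values = as.integer(M_values), seed = as.integer(seed),
                 min_root_distance = min_root_distance,
                 boundary_margin = boundary_margin, options = options,
                 P = as.integer(P), Q = as.integer(Q), level = level),
            class = "study_config")
}

# deterministic per-replicate seed stream, kept below 2^31
replicate_seed <- function(seed, cell, rep) {
  (as.numeric(seed) * 7919 + cell * 104729 + rep * 7577) %% 2147483629
}

#' Draw a generative ARMA model for the simulation studies
#'
#' Samples a causal, invertible model via the inverted-root sampler,
#' rejecting until (i) all pairwise distances among the pooled AR and MA
#' inverted roots -- both across and within polynomials -- are at least
#' `min_root_distance`, excluding parameter redundancies and near-repeated
#' roots, and (ii) all root moduli are at most `1 - boundary_margin`. The
#' returned model has `mu = 0` and `sigma2 = 1`.
#'
#' @param order An [arma_order()] or `c(p, q)`.
#' @param min_root_distance Minimum pooled pairwise root distance,
#'   default 0.1.
#' @param boundary_margin Margin from the unit circle, default 0.05.
#' @param gamma Inner annulus bound for the sampler, default 0.05.
#' @return An [arma_params()] object.
#' @export
sample_generative_model <- function(order, min_root_distance = 0.1,
                                    boundary_margin = 0.05, gamma = 0.05) {
  order <- as_arma_order(order)
  g <- max(gamma, boundary_margin)
  opts <- fit_options(alpha = min_root_distance, gamma = g)
  for (try in seq_len(5000L)) {
    cand <- tryCatch(sample_init_rootspace(order, opts),
                     error = function(e) NULL)
    if (is.null(cand)) next
    rs <- coefficients_to_inverted_roots(cand)
    if (min_pooled_root_distance(rs) >= min_root_distance &&
        all(Mod(c(rs$ar_inv, rs$ma_inv)) <= 1 - boundary_margin))
      return(cand)
  }
  stop("generative-model sampler exceeded the rejection cap")
}

#' Likelihood-improvement study
#'
#' For each (order, n) cell, draws `n_models` generative models and one
#' Gaussian series from each, fits the true order once from the default
#' (CSS) initialization and with each multi-start sampler, and records
#' whether and by how much each sampler improves the log-likelihood
#' (improvement means exceeding the baseline by more than the improvement
#' tolerance).
#'
#' @param config A [study_config()].
#' @param progress Print per-cell progress lines? Default `FALSE`.
#' @return An object of class `"improvement_study"`: list with `replicates`
#'   (one row per dataset: cell indices, baseline and per-method
#'   log-likelihoods, improvement flags, gain) and `summary` (pooled and
#'   per-cell improvement proportions, median and IQR of positive gains).
#' @export
run_improvement_study <- function(config = study_config(),
                                  progress = FALSE) {
  opts <- config$options; opts$seed <- NULL
  tol <- opts$improvement_tol
  cells <- merge(config$orders, data.frame(n = config$sizes))
  rows <- vector("list", nrow(cells) * config$n_models)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    p <- cells$p[ci]; q <- cells$q[ci]; n <- cells$n[ci]
    if (progress)
      message(sprintf("cell (p=%d, q=%d, n=%d)", p, q, n))
    for (m in seq_len(config$n_models)) {
      set.seed(replicate_seed(config$seed, ci, m))
      gen <- sample_generative_model(c(p, q), config$min_root_distance,
                                     config$boundary_margin)
      x <- simulate_arma(gen, n)
      base <- tryCatch(
        fit_single(x, c(p, q), init = NULL, options = opts),
        error = function(e) NULL)
      if (is.null(base)) next
      lls <- c(baseline = base$loglik)
      for (meth in config$methods) {
        f <- tryCatch(
          multistart_fit(x, c(p, q), method = meth, options = opts,
                         se = FALSE, baseline_fit = base),
          error = function(e) NULL)
        lls[meth] <- if (is.null(f)) NA_real_ else f$loglik
      }
      ll_ms <- suppressWarnings(max(lls[config$methods], na.rm = TRUE))
      k <- k + 1L
      rows[[k]] <- data.frame(
        p = p, q = q, n = n, model = m,
        ll_baseline = lls[["baseline"]],
        ll_rootspace = if ("rootspace" %in% config$methods)
          lls[["rootspace"]] else NA_real_,
        ll_pacf = if ("pacf" %in% config$methods)
          lls[["pacf"]] else NA_real_,
        improved_any = is.finite(ll_ms) && ll_ms > lls[["baseline"]] + tol,
        improved_rootspace = "rootspace" %in% config$methods &&
          is.finite(lls[["rootspace"]]) &&
          lls[["rootspace"]] > lls[["baseline"]] + tol,
        improved_pacf = "pacf" %in% config$methods &&
          is.finite(lls[["pacf"]]) &&
          lls[["pacf"]] > lls[["baseline"]] + tol,
        gain = if (is.finite(ll_ms)) max(ll_ms - lls[["baseline"]], 0)
               else NA_real_)
    }
  }
  reps <- do.call(rbind, rows[seq_len(k)])
  gains <- reps$gain[reps$improved_any & is.finite(reps$gain)]
  per_cell <- aggregate(cbind(improved_any, improved_rootspace,
                              improved_pacf) ~ p + q + n,
                        data = reps, FUN = mean)
  summary <- list(
    n_datasets = nrow(reps),
    prop_any = mean(reps$improved_any),
    prop_rootspace = mean(reps$improved_rootspace),
    prop_pacf = mean(reps$improved_pacf),
    median_gain = if (length(gains)) median(gains) else NA_real_,
    iqr_gain = if (length(gains)) unname(quantile(gains, c(0.25, 0.75)))
               else c(NA_real_, NA_real_),
    per_cell = per_cell)
  structure(list(replicates = reps, summary = summary, config = config),
            class = "improvement_study")
}

#' @export
print.improvement_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Likelihood-improvement study: %d datasets\n", s$n_datasets))
  cat(sprintf("  improved by either sampler: %.1f%%\n", 100 * s$prop_any))
  cat(sprintf("  root-space sampler alone:   %.1f%%\n", 100 * s$prop_rootspace))
  cat(sprintf("  Durbin-Levinson alone:      %.1f%%\n", 100 * s$prop_pacf))
  cat(sprintf("  median gain (improved):     %.2f  (IQR %.2f-%.2f)\n",
              s$median_gain, s$iqr_gain[1], s$iqr_gain[2]))
  invisible(x)
}

#' AIC-table consistency study
#'
#' For each generated dataset, builds the (P+1) x (Q+1) AIC table with
#' single-initialization fits and with the root-space multi-start algorithm
#' at each configured stopping patience M, and records whether each table
#' contains a nested-model log-likelihood inconsistency. The baseline
#' corresponds to M = 1 in the sense of "standard procedure, no random
#' restarts".
#'
#' @param config A [study_config()]; `orders`, `sizes` and `n_models`
#'   control the replication, `M_values` the patience sweep.
#' @param progress Print progress lines? Default `FALSE`.
#' @return An object of class `"consistency_study"`: list with `replicates`
#'   (per dataset: inconsistency flags for baseline and each M) and
#'   `summary` (inconsistency rates).
#' @export
run_consistency_study <- function(config = study_config(),
                                  progress = FALSE) {
  opts <- config$options
  cells <- merge(config$orders, data.frame(n = config$sizes))
  rows <- vector("list", nrow(cells) * config$n_models)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    p <- cells$p[ci]; q <- cells$q[ci]; n <- cells$n[ci]
    if (progress) message(sprintf("cell (p=%d, q=%d, n=%d)", p, q, n))
    for (m in seq_len(config$n_models)) {
      rs <- replicate_seed(config$seed, ci + 5000, m)
      set.seed(rs)
      gen <- sample_generative_model(c(p, q), config$min_root_distance,
                                     config$boundary_margin)
      x <- simulate_arma(gen, n)
      opts_b <- opts; opts_b$seed <- rs + 1
      tb <- aic_table(x, config$P, config$Q, method = "baseline",
                      options = opts_b)
      rec <- data.frame(p = p, q = q, n = n, model = m,
                        inconsistent_baseline =
                          nrow(consistency_violations(tb)) > 0L)
      for (M in config$M_values) {
        opts_m <- opts; opts_m$M <- as.integer(M); opts_m$seed <- rs + 2
        tm <- aic_table(x, config$P, config$Q, method = "rootspace",
                        options = opts_m)
        rec[[paste0("inconsistent_M", M)]] <-
          nrow(consistency_violations(tm)) > 0L
      }
      k <- k + 1L
      rows[[k]] <- rec
    }
  }
  reps <- do.call(rbind, rows[seq_len(k)])
  rates <- colMeans(reps[grep("^inconsistent", names(reps))])
  structure(list(replicates = reps,
                 summary = list(n_datasets = nrow(reps),
                                inconsistency_rates = rates),
                 config = config),
            class = "consistency_study")
}

#' @export
print.consistency_study <- function(x, ...) {
  cat(sprintf("AIC-table consistency study: %d datasets\n",
              x$summary$n_datasets))
  r <- x$summary$inconsistency_rates
  for (nm in names(r))
    cat(sprintf("  %-24s %.1f%% inconsistent\n", nm, 100 * r[nm]))
  invisible(x)
}

#' Confidence-interval coverage study
#'
#' For each generative model, simulates `n_reps_per_model` datasets, fits
#' each with the root-space multi-start algorithm, and forms
#' Bonferroni-adjusted joint confidence intervals for the coefficients --
#' each individual interval at level 1 - (1 - level) / (p + q) -- by both
#' the Fisher-information and the profile-likelihood constructions. Records
#' whether all coefficient intervals simultaneously cover the truth, the
#' per-model coverage rates, and the proportion of models attaining nominal
#' coverage under each construction.
#'
#' @param config A [study_config()]; keep `n_models` and
#'   `n_reps_per_model` small, as each profile interval requires many
#'   refits.
#' @param progress Print progress lines? Default `FALSE`.
#' @return An object of class `"coverage_study"`: list with `replicates`,
#'   `per_model` (coverage rates) and `summary` (attainment proportions).
#' @export
run_coverage_study <- function(config = study_config(), progress = FALSE) {
  opts <- config$options; opts$seed <- NULL
  cells <- merge(config$orders, data.frame(n = config$sizes))
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    p <- cells$p[ci]; q <- cells$q[ci]; n <- cells$n[ci]
    if (progress) message(sprintf("cell (p=%d, q=%d, n=%d)", p, q, n))
    # Bonferroni across the p+q coefficient intervals; a white-noise cell
    # (p = q = 0) audits the intercept instead
    d <- max(p + q, 1L)
    audit_mu <- p + q == 0L
    adj_level <- 1 - (1 - config$level) / d
    zq <- qnorm(1 - (1 - adj_level) / 2)
    for (m in seq_len(config$n_models)) {
      set.seed(replicate_seed(config$seed, ci + 10000, m))
      gen <- if (audit_mu) arma_params()
             else sample_generative_model(c(p, q), config$min_root_distance,
                                          config$boundary_margin)
      truth <- if (audit_mu) gen$mu else c(gen$phi, gen$theta)
      for (rep in seq_len(config$n_reps_per_model)) {
        x <- simulate_arma(gen, n)
        fit <- tryCatch(
          multistart_fit(x, c(p, q), method = "rootspace", options = opts,
                         se = TRUE),
          error = function(e) NULL)
        if (is.null(fit)) next
        est <- if (audit_mu) fit$params$mu
               else c(fit$params$phi, fit$params$theta)
        idx <- if (audit_mu) p + q + 1L else seq_len(p + q)
        se <- fit$se[idx]
        cover_f <- if (!is.null(se) && all(is.finite(se)))
          all(abs(est - truth) <= zq * se) else FALSE
        cover_p <- TRUE
        for (j in seq_along(idx)) {
          pc <- tryCatch(
            profile_ci(x, c(p, q), idx[j], level = adj_level, options = opts,
                       fit = fit),
            error = function(e) NULL)
          if (is.null(pc)) { cover_p <- NA; break }
          if (truth[j] < pc$interval$lower - 1e-8 ||
              truth[j] > pc$interval$upper + 1e-8) { cover_p <- FALSE; break }
        }
        rows[[length(rows) + 1L]] <-
          data.frame(p = p, q = q, n = n, model = m, rep = rep,
                     cover_fisher = cover_f, cover_profile = cover_p)
      }
    }
  }
  reps <- do.call(rbind, rows)
  per_model <- aggregate(cbind(cover_fisher, cover_profile) ~ p + q + n + model,
                         data = reps, FUN = function(v) mean(v, na.rm = TRUE))
  summary <- list(
    n_models = nrow(per_model),
    attain_fisher = mean(per_model$cover_fisher >= config$level),
    attain_profile = mean(per_model$cover_profile >= config$level),
    mean_cover_fisher = mean(reps$cover_fisher, na.rm = TRUE),
    mean_cover_profile = mean(reps$cover_profile, na.rm = TRUE))
  structure(list(replicates = reps, per_model = per_model,
                 summary = summary, config = config),
            class = "coverage_study")
}

#' @export
print.coverage_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Coverage study: %d generative models\n", s$n_models))
  cat(sprintf("  attaining nominal coverage, Fisher:  %.1f%%\n",
              100 * s$attain_fisher))
  cat(sprintf("  attaining nominal coverage, profile: %.1f%%\n",
              100 * s$attain_profile))
  invisible(x)
}
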