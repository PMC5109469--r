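# Circular second-order trend state-space model for the 24-h baseline.
#
# Observation model, for a recording with K bins per day and D days:
#   Y_t ~ Normal(alpha_{k(t)}, sigma1^2),  k(t) = t mod K
# Baseline smoothness prior (intrinsic, circular over time of day):
#   eta_k = alpha_k - 2 alpha_{k-1} + alpha_{k-2} ~ Normal(0, sigma2^2),
# with indices wrapped modulo K, so the baseline is a function of time of
# day only and day 1's fit predicts later days.
#
# Given (sigma1, sigma2) the model is linear-Gaussian, so alpha can be
# marginalized exactly. With complete data the posterior precision of alpha
# is circulant and all linear algebra reduces to FFTs; with missing points
# a dense Cholesky fallback is used. MCMC therefore only has to explore the
# 1-5 scale parameters (random-walk Metropolis on the log scale), and alpha
# is drawn exactly from its Gaussian conditional for each kept iteration.

#' Circular second difference of a baseline vector
#'
#' Returns `eta` with `eta_k = alpha_k - 2 alpha_(k-1) + alpha_(k-2)`,
#' indices taken modulo K, i.e. the trend innovations implied by a baseline.
#'
#' @param alpha numeric vector of length K >= 3.
#' @return Numeric vector of length K.
#' @export
circular_second_difference <- function(alpha) {
  K <- length(alpha)
  if (K < 3L) stop_tm("need K >= 3")
  im1 <- c(K, seq_len(K - 1L))        # k-1 (wrapped)
  im2 <- c(K - 1L, K, seq_len(K - 2L)) # k-2 (wrapped)
  alpha - 2 * alpha[im1] + alpha[im2]
}

# Eigenvalues of t(L) %*% L for the circular second-difference operator L.
csd_eigenvalues <- function(K) (2 * sin(pi * (0:(K - 1)) / K))^4

# Dense t(L) %*% L, built through the operator itself.
csd_crossprod <- function(K) {
  L <- vapply(seq_len(K), function(j) {
    e <- numeric(K); e[j] <- 1; circular_second_difference(e)
  }, numeric(K))
  crossprod(L)
}

#' MCMC settings for the baseline trend model
#'
#' @param n_chains number of chains.
#' @param n_warmup,n_samples warmup and kept iterations per chain.
#' @param seed integer seed; chains derive child seeds from it.
#' @param sigma2_mode `"estimate"` (hierarchical fit) or `"fixed"`.
#' @param sigma2_fixed value of sigma2 when fixed. Defaults (when `NULL` at
#'   fit time) are 0.01877 degC for body temperature and 0.00650 ml/g/hr for
#'   VO2 per time bin, the package's calibration values for the default grid.
#' @param sigma1_fixed optionally fix the observation-noise SD as well
#'   (useful for validation against the closed-form Gaussian posterior).
#' @param sigma1_max,sigma2_max upper bounds of the uniform priors on the
#'   scales, in the variable's native units.
#' @param rhat_threshold convergence cutoff for split R-hat warnings.
#' @param max_alpha_draws cap on stored baseline draws (thinned evenly).
#' @return A `trend_fit_config` list.
#' @export
trend_fit_config <- function(n_chains = 4L, n_warmup = 1000L, n_samples = 1000L,
                             seed = 1L, sigma2_mode = c("fixed", "estimate"),
                             sigma2_fixed = NULL, sigma1_fixed = NULL,
                             sigma1_max = 10, sigma2_max = 1,
                             rhat_threshold = 1.01, max_alpha_draws = 1000L) {
  sigma2_mode <- match.arg(sigma2_mode)
  stopifnot(n_chains >= 1, n_warmup >= 0, n_samples > 0)
  structure(list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 sigma2_mode = sigma2_mode, sigma2_fixed = sigma2_fixed,
                 sigma1_fixed = sigma1_fixed, sigma1_max = sigma1_max,
                 sigma2_max = sigma2_max, rhat_threshold = rhat_threshold,
                 max_alpha_draws = as.integer(max_alpha_draws)),
            class = "trend_fit_config")
}

default_sigma2 <- function(variable) {
  switch(variable, tb = 0.01877, vo2 = 0.00650,
         stop_tm("unknown variable: ", variable))
}

# Sufficient statistics of one recording for the marginal likelihood.
trend_suffstats <- function(series, variable) {
  y <- series[[variable]]
  K <- series$K
  k_idx <- ((seq_along(y) - 1L) %% K) + 1L
  obs <- !is.na(y)
  if (sum(obs) < K) stop_tm("fewer observations than K; cannot fit baseline")
  n_k <- tabulate(k_idx[obs], nbins = K)
  sum_k <- vapply(seq_len(K), function(k) sum(y[obs & k_idx == k]), 0)
  list(K = K, n = sum(obs), n_k = n_k, sum_k = sum_k,
       ss = sum(y[obs]^2), complete = all(n_k == n_k[1]),
       y = y, k_idx = k_idx)
}

# Log marginal likelihood of one recording given the scales (terms constant
# in sigma1/sigma2 are dropped). st: trend_suffstats output.
trend_marginal_ll <- function(st, sigma1, sigma2) {
  K <- st$K
  if (st$complete) {
    lam <- csd_eigenvalues(K) / sigma2^2 + st$n_k[1] / sigma1^2
    b <- st$sum_k / sigma1^2
    bhat2 <- Mod(stats::fft(b))^2
    quad <- sum(bhat2 / lam) / K
    -st$n * log(sigma1) - (K - 1) * log(sigma2) -
      0.5 * sum(log(lam)) - st$ss / (2 * sigma1^2) + 0.5 * quad
  } else {
    Q <- csd_crossprod(K) / sigma2^2
    diag(Q) <- diag(Q) + st$n_k / sigma1^2
    ch <- chol(Q)
    b <- st$sum_k / sigma1^2
    w <- backsolve(ch, b, transpose = TRUE)
    -st$n * log(sigma1) - (K - 1) * log(sigma2) -
      sum(log(diag(ch))) - st$ss / (2 * sigma1^2) + 0.5 * sum(w^2)
  }
}

# Exact draw from alpha | y, sigma1, sigma2 (and its mean if requested).
trend_conditional_alpha <- function(st, sigma1, sigma2, n_draws = 1L) {
  K <- st$K
  b <- st$sum_k / sigma1^2
  if (st$complete) {
    lam <- csd_eigenvalues(K) / sigma2^2 + st$n_k[1] / sigma1^2
    mu <- Re(stats::fft(stats::fft(b) / lam, inverse = TRUE)) / K
    draws <- matrix(0, n_draws, K)
    for (i in seq_len(n_draws)) {
      zhat <- stats::fft(stats::rnorm(K))
      draws[i, ] <- mu + Re(stats::fft(zhat / sqrt(lam), inverse = TRUE)) / K
    }
  } else {
    Q <- csd_crossprod(K) / sigma2^2
    diag(Q) <- diag(Q) + st$n_k / sigma1^2
    ch <- chol(Q)
    mu <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
    draws <- matrix(0, n_draws, K)
    for (i in seq_len(n_draws)) {
      draws[i, ] <- mu + backsolve(ch, stats::rnorm(K))
    }
  }
  list(mean = mu, draws = draws)
}

# Generic componentwise random-walk Metropolis on the log scale.
# logpost takes the parameter vector on its natural (positive) scale and
# must return -Inf outside the prior support. Proposal scales adapt toward
# 44% acceptance during warmup only.
mh_scales <- function(logpost, init, n_chains, n_warmup, n_samples, seed) {
  p <- length(init)
  draws <- array(NA_real_, c(n_samples, p, n_chains),
                 dimnames = list(NULL, names(init), NULL))
  for (ch in seq_len(n_chains)) {
    set.seed(child_seed(seed, paste0("mh-chain-", ch)))
    theta <- log(init) + stats::runif(p, -0.3, 0.3)
    prop_sd <- rep(0.2, p)
    acc <- rep(0L, p); tries <- rep(0L, p)
    lp <- logpost(exp(theta)) + sum(theta)
    if (!is.finite(lp)) { theta <- log(init); lp <- logpost(exp(theta)) + sum(theta) }
    for (it in seq_len(n_warmup + n_samples)) {
      for (j in seq_len(p)) {
        cand <- theta
        cand[j] <- cand[j] + stats::rnorm(1, 0, prop_sd[j])
        lp_cand <- logpost(exp(cand)) + sum(cand)
        tries[j] <- tries[j] + 1L
        if (is.finite(lp_cand) && log(stats::runif(1)) < lp_cand - lp) {
          theta <- cand; lp <- lp_cand; acc[j] <- acc[j] + 1L
        }
      }
      if (it <= n_warmup && it %% 50L == 0L) {
        rate <- acc / pmax(tries, 1L)
        prop_sd <- prop_sd * exp(rate - 0.44)
        acc[] <- 0L; tries[] <- 0L
      }
      if (it > n_warmup) draws[it - n_warmup, , ch] <- exp(theta)
    }
  }
  draws
}

mcmc_diagnostics <- function(draws) {
  # draws: iterations x params x chains
  params <- dimnames(draws)[[2]]
  data.frame(
    param = params,
    rhat = vapply(seq_along(params), function(j) split_rhat(draws[, j, ]), 0),
    ess = vapply(seq_along(params), function(j) ess_basic(draws[, j, ]), 0),
    row.names = NULL)
}

check_convergence <- function(diag_df, threshold, what) {
  bad <- diag_df$param[!is.na(diag_df$rhat) & diag_df$rhat > threshold]
  if (length(bad))
    warning(sprintf("%s: split R-hat above %.3f for %s", what, threshold,
                    paste(bad, collapse = ", ")), call. = FALSE)
  invisible(length(bad) == 0L)
}

check_bounds <- function(draws_vec, upper, what) {
  if (mean(draws_vec > 0.99 * upper) > 0.01)
    warning(sprintf("%s: posterior mass accumulates at the prior upper bound %g; widen it",
                    what, upper), call. = FALSE)
  invisible(NULL)
}

new_trend_posterior <- function(variable, K, zt, alpha_draws, sigma1_draws,
                                sigma2_draws, sigma2_fixed, diagnostics,
                                config, animal_ids) {
  structure(list(variable = variable, K = K, zt = zt,
                 alpha_draws = alpha_draws, sigma1_draws = sigma1_draws,
                 sigma2_draws = sigma2_draws, sigma2_fixed = sigma2_fixed,
                 diagnostics = diagnostics, config = config,
                 animal_ids = animal_ids),
            class = "trend_posterior")
}

#' @export
print.trend_posterior <- function(x, ...) {
  cat(sprintf("<trend_posterior> %s, K=%d, %s animal(s)\n", x$variable, x$K,
              length(x$animal_ids)))
  s1 <- as.matrix(x$sigma1_draws)
  cat(sprintf("  sigma1 median: %s\n",
              paste(signif(apply(s1, 2, median), 4), collapse = ", ")))
  if (!is.null(x$sigma2_draws))
    cat(sprintf("  sigma2 median: %.5g\n", median(x$sigma2_draws)))
  else cat(sprintf("  sigma2 fixed at %.5g\n", x$sigma2_fixed))
  invisible(x)
}

#' Estimate the trend-innovation scale sigma2 from a calibration cohort
#'
#' Hierarchical fit across several multi-day recordings of non-torpid
#' animals: each animal has its own baseline `alpha` (length K, shared by
#' all its days) and observation-noise SD `sigma1`; a single `sigma2`
#' (the SD of the circular second differences of `alpha`) is shared by the
#' cohort. Uniform priors on all scales. The fitted posterior median of
#' `sigma2` is what [fit_baseline()] then holds fixed to enable single-day
#' baseline estimation.
#'
#' @param recordings list of [metabolic_ts()], each with D >= 2 full days.
#' @param variable `"tb"` or `"vo2"`.
#' @param config a [trend_fit_config()] with `sigma2_mode = "estimate"`.
#' @return A `trend_posterior` with per-animal `sigma1_draws` (matrix),
#'   `sigma2_draws`, thinned per-animal `alpha_draws` (list of matrices)
#'   and split R-hat / ESS diagnostics.
#' @export
fit_sigma2 <- function(recordings, variable = c("tb", "vo2"),
                       config = trend_fit_config(sigma2_mode = "estimate")) {
  variable <- match.arg(variable)
  if (inherits(recordings, "metabolic_ts")) recordings <- list(recordings)
  if (config$sigma2_mode != "estimate")
    stop_tm("fit_sigma2 requires sigma2_mode = \"estimate\"")
  lapply(recordings, function(s) if (s$D < 2L)
    stop_tm("each calibration recording needs at least 2 full days"))
  A <- length(recordings)
  sts <- lapply(recordings, trend_suffstats, variable = variable)
  K <- sts[[1]]$K
  if (any(vapply(sts, `[[`, 0L, "K") != K)) stop_tm("recordings must share K")

  # moment-based inits
  s1_init <- vapply(sts, function(st) {
    ybar <- st$sum_k / pmax(st$n_k, 1L)
    resid2 <- st$ss - sum(st$n_k * ybar^2)
    sqrt(max(resid2 / max(st$n - K, 1), 1e-6))
  }, 0)
  s2_init <- max(mean(vapply(sts, function(st) {
    ybar <- st$sum_k / pmax(st$n_k, 1L)
    sd(circular_second_difference(ybar))
  }, 0)) / 2, 1e-4)
  init <- c(setNames(pmin(s1_init, config$sigma1_max / 2),
                     paste0("sigma1[", seq_len(A), "]")),
            sigma2 = min(s2_init, config$sigma2_max / 2))

  logpost <- function(par) {
    s1 <- par[seq_len(A)]; s2 <- par[A + 1L]
    if (any(s1 <= 0) || any(s1 > config$sigma1_max) ||
        s2 <= 0 || s2 > config$sigma2_max) return(-Inf)
    sum(vapply(seq_len(A), function(a)
      trend_marginal_ll(sts[[a]], s1[a], s2), 0))
  }
  draws <- mh_scales(logpost, init, config$n_chains, config$n_warmup,
                     config$n_samples, config$seed)
  diag_df <- mcmc_diagnostics(draws)
  check_convergence(diag_df, config$rhat_threshold, paste("fit_sigma2", variable))

  flat <- do.call(rbind, lapply(seq_len(config$n_chains), function(ch) draws[, , ch]))
  colnames(flat) <- dimnames(draws)[[2]]
  sigma2_draws <- flat[, A + 1L]
  check_bounds(sigma2_draws, config$sigma2_max, "sigma2")

  # thinned exact conditional baseline draws per animal
  n_keep <- min(config$max_alpha_draws, nrow(flat))
  idx <- unique(round(seq(1, nrow(flat), length.out = n_keep)))
  set.seed(child_seed(config$seed, "alpha-draws"))
  alpha_draws <- lapply(seq_len(A), function(a) {
    out <- matrix(0, length(idx), K)
    for (i in seq_along(idx)) {
      out[i, ] <- trend_conditional_alpha(sts[[a]], flat[idx[i], a],
                                          flat[idx[i], A + 1L])$draws
    }
    out
  })
  zt <- (recordings[[1]]$t[seq_len(K)] / 60) %% 24
  new_trend_posterior(variable, K, zt, alpha_draws,
                      sigma1_draws = flat[, seq_len(A), drop = FALSE],
                      sigma2_draws = sigma2_draws, sigma2_fixed = NULL,
                      diagnostics = diag_df, config = config,
                      animal_ids = vapply(recordings, `[[`, "", "animal_id"))
}

#' Fit the single-day baseline with sigma2 fixed
#'
#' Posterior over the 24-h baseline `alpha` and the observation-noise SD
#' `sigma1` from one day of data, with the trend-innovation scale `sigma2`
#' held at a calibration value (see [fit_sigma2()]). This is the model that
#' lets a single day's recording predict the following days' metabolism.
#'
#' @param day1 a [metabolic_ts()] with exactly one full day.
#' @param variable `"tb"` or `"vo2"`.
#' @param config a [trend_fit_config()] with `sigma2_mode = "fixed"`. When
#'   `sigma2_fixed` is `NULL` the per-variable default is used. When
#'   `sigma1_fixed` is set, only `alpha` is sampled (exact draws).
#' @return A `trend_posterior` with `alpha_draws` (draws x K), `sigma1_draws`
#'   and diagnostics.
#' @export
fit_baseline <- function(day1, variable = c("tb", "vo2"),
                         config = trend_fit_config()) {
  variable <- match.arg(variable)
  stopifnot(inherits(day1, "metabolic_ts"))
  if (day1$D != 1L) stop_tm("fit_baseline expects exactly one full day; use subset_days()")
  if (config$sigma2_mode != "fixed") stop_tm("fit_baseline requires sigma2_mode = \"fixed\"")
  sigma2 <- config$sigma2_fixed %||% default_sigma2(variable)
  st <- trend_suffstats(day1, variable)
  K <- st$K

  if (!is.null(config$sigma1_fixed)) {
    n_draws <- config$n_chains * config$n_samples
    set.seed(child_seed(config$seed, "alpha-fixed-sigma1"))
    ca <- trend_conditional_alpha(st, config$sigma1_fixed, sigma2,
                                  n_draws = n_draws)
    sigma1_draws <- rep(config$sigma1_fixed, n_draws)
    diag_df <- data.frame(param = "sigma1", rhat = 1, ess = n_draws)
    return(new_trend_posterior(variable, K, (day1$t[seq_len(K)] / 60) %% 24,
                               ca$draws, sigma1_draws, NULL, sigma2, diag_df,
                               config, day1$animal_id))
  }

  ybar <- st$sum_k / pmax(st$n_k, 1L)
  init <- c(sigma1 = min(max(sd(diff(ybar)) / sqrt(2), 1e-3),
                         config$sigma1_max / 2))
  logpost <- function(par) {
    if (par[1] <= 0 || par[1] > config$sigma1_max) return(-Inf)
    trend_marginal_ll(st, par[1], sigma2)
  }
  draws <- mh_scales(logpost, init, config$n_chains, config$n_warmup,
                     config$n_samples, config$seed)
  diag_df <- mcmc_diagnostics(draws)
  check_convergence(diag_df, config$rhat_threshold,
                    paste("fit_baseline", day1$animal_id, variable))
  sigma1_draws <- as.vector(draws[, 1, ])
  check_bounds(sigma1_draws, config$sigma1_max, "sigma1")

  n_keep <- min(config$max_alpha_draws, length(sigma1_draws))
  idx <- unique(round(seq(1, length(sigma1_draws), length.out = n_keep)))
  set.seed(child_seed(config$seed, "alpha-draws"))
  alpha_draws <- matrix(0, length(idx), K)
  for (i in seq_along(idx)) {
    alpha_draws[i, ] <- trend_conditional_alpha(st, sigma1_draws[idx[i]],
                                                sigma2)$draws
  }
  new_trend_posterior(variable, K, (day1$t[seq_len(K)] / 60) %% 24,
                      alpha_draws, sigma1_draws[idx], NULL, sigma2, diag_df,
                      config, day1$animal_id)
}

#' Exact Gaussian posterior of the baseline given fixed scales
#'
#' With `sigma1` and `sigma2` fixed the model is linear-Gaussian, so the
#' posterior of `alpha` has a closed form through a banded-plus-corner
#' precision system. Intended as an independent verification oracle for the
#' MCMC fit; built with dense base-R linear algebra, deliberately sharing no
#' code with the sampler's FFT path.
#'
#' @param day1 a [metabolic_ts()] (any number of days).
#' @param variable `"tb"` or `"vo2"`.
#' @param sigma1,sigma2 fixed positive scales.
#' @return `list(mean, cov)` for the K baseline values.
#' @export
exact_gaussian_posterior <- function(day1, variable = c("tb", "vo2"),
                                     sigma1, sigma2) {
  variable <- match.arg(variable)
  stopifnot(sigma1 > 0, sigma2 > 0)
  y <- day1[[variable]]
  K <- day1$K
  k_idx <- ((seq_along(y) - 1L) %% K) + 1L
  obs <- !is.na(y)
  L <- vapply(seq_len(K), function(j) {
    e <- numeric(K); e[j] <- 1; circular_second_difference(e)
  }, numeric(K))
  Q <- crossprod(L) / sigma2^2
  n_k <- tabulate(k_idx[obs], nbins = K)
  diag(Q) <- diag(Q) + n_k / sigma1^2
  b <- vapply(seq_len(K), function(k) sum(y[obs & k_idx == k]), 0) / sigma1^2
  covm <- solve(Q)
  list(mean = as.vector(covm %*% b), cov = covm)
}

#' Posterior predictive band for the observable
#'
#' For each time-of-day bin, the equal-tailed interval of the posterior
#' predictive distribution of a new observation (baseline draw plus fresh
#' Gaussian observation noise) at the requested credible mass. The band is
#' periodic in time of day, so it applies to any later day of the same
#' animal.
#'
#' @param post a single-animal `trend_posterior`.
#' @param level credible mass in (0, 1), e.g. 0.999.
#' @return A `predictive_band` with `lower` and `upper` (length K).
#' @export
predictive_band <- function(post, level = 0.999) {
  stopifnot(inherits(post, "trend_posterior"))
  if (level <= 0 || level >= 1) stop_tm("level must be in (0,1)")
  if (is.list(post$alpha_draws) && !is.matrix(post$alpha_draws))
    stop_tm("predictive_band needs a single-animal posterior; index alpha_draws first")
  mu <- post$alpha_draws
  s1 <- post$sigma1_draws
  if (length(s1) != nrow(mu)) {
    # sigma1 draws were kept unthinned; align by even thinning
    s1 <- s1[unique(round(seq(1, length(s1), length.out = nrow(mu))))]
    if (length(s1) != nrow(mu)) s1 <- rep_len(s1, nrow(mu))
  }
  p_lo <- (1 - level) / 2
  lower <- mixture_quantile(mu, s1, p_lo)
  upper <- mixture_quantile(mu, s1, 1 - p_lo)
  structure(list(level = level, K = post$K, zt = post$zt,
                 lower = lower, upper = upper, variable = post$variable,
                 animal_id = post$animal_ids[1]),
            class = "predictive_band")
}

#' @export
print.predictive_band <- function(x, ...) {
  cat(sprintf("<predictive_band> %s, %.2f%% credible mass, K=%d, mean half-width %.3g\n",
              x$variable, 100 * x$level, x$K, mean(x$upper - x$lower) / 2))
  invisible(x)
}

#' Fraction of held-out observations inside a predictive band
#'
#' @param series held-out [metabolic_ts()] (e.g. days 2-3).
#' @param band a [predictive_band()] on the same K-grid.
#' @param variable `"tb"` or `"vo2"`; defaults to the band's variable.
#' @param days optional day indices of `series` to evaluate.
#' @return Fraction in `[0, 1]` of non-missing points with
#'   `lower <= Y <= upper`.
#' @export
band_coverage <- function(series, band, variable = band$variable, days = NULL) {
  stopifnot(inherits(series, "metabolic_ts"), inherits(band, "predictive_band"))
  if (series$K != band$K) stop_tm("grid mismatch: series K=", series$K,
                                  " vs band K=", band$K)
  y <- series[[variable]]
  keep <- !is.na(y)
  if (!is.null(days)) keep <- keep & series$day_index %in% days
  if (!any(keep)) stop_tm("no evaluable points in the requested window")
  k_idx <- ((seq_along(y) - 1L) %% series$K) + 1L
  inside <- y[keep] >= band$lower[k_idx[keep]] & y[keep] <= band$upper[k_idx[keep]]
  mean(inside)
}
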