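# Brute-force circular second difference via explicit modulo arithmetic,
# independent of the vectorized implementation.
csd_bruteforce <- function(alpha) {
  K <- length(alpha)
  sapply(seq_len(K), function(k) {
    wrap <- function(i) ((i - 1) %% K) + 1
    alpha[k] - 2 * alpha[wrap(k - 1)] + alpha[wrap(k - 2)]
  })
}

test_that("circular second difference matches brute-force index arithmetic", {
  expect_equal(circular_second_difference(rep(3.7, 10)), rep(0, 10))
  expect_error(circular_second_difference(c(1, 2)), "K >= 3")
  set.seed(1)
  for (K in c(3, 5, 12, 240)) {
    a <- rnorm(K)
    eta <- circular_second_difference(a)
    expect_equal(eta, csd_bruteforce(a))
    expect_equal(sum(eta), 0, tolerance = 1e-10)  # telescoping on a cycle
  }
  # impulse response at K = 5
  expect_equal(circular_second_difference(c(0, 1, 0, 0, 0)),
               csd_bruteforce(c(0, 1, 0, 0, 0)))
})

test_that("exact Gaussian posterior has the right limiting behaviour", {
  cfg <- synthetic_config(seed = 21, D = 1, bin_width = 120,
                          sigma1 = c(tb = 0.3, vo2 = 0.25))
  day1 <- simulate_baseline_day(cfg, 1)
  # sigma2 -> infinity: prior vanishes, posterior mean -> observed values
  ex <- exact_gaussian_posterior(day1, "tb", sigma1 = 0.3, sigma2 = 1e5)
  expect_equal(ex$mean, day1$tb, tolerance = 1e-4)
  # sigma2 -> 0 with the circular constraint: only constants have zero
  # circular second differences, so alpha collapses to the grand mean
  ex0 <- exact_gaussian_posterior(day1, "tb", sigma1 = 0.3, sigma2 = 1e-4)
  expect_equal(ex0$mean, rep(mean(day1$tb), day1$K), tolerance = 1e-3)
})

test_that("MCMC baseline agrees with the closed-form oracle on K = 24", {
  cfg <- synthetic_config(seed = 31, D = 1, bin_width = 60,
                          sigma1 = c(tb = 0.3, vo2 = 0.25))
  day1 <- simulate_baseline_day(cfg, 1)
  ex <- exact_gaussian_posterior(day1, "tb", sigma1 = 0.3, sigma2 = 0.01877)
  fb <- fit_baseline(day1, "tb",
                     trend_fit_config(seed = 5, sigma1_fixed = 0.3,
                                      sigma2_fixed = 0.01877))
  pm <- colMeans(fb$alpha_draws)
  mcse <- apply(fb$alpha_draws, 2, sd) / sqrt(nrow(fb$alpha_draws))
  expect_lt(max(abs(pm - ex$mean) / mcse), 3)
  # draw covariance consistent with the oracle's marginal SDs
  expect_equal(apply(fb$alpha_draws, 2, sd), sqrt(diag(ex$cov)),
               tolerance = 0.15)
})

test_that("fit_baseline is deterministic and recovers a flat baseline", {
  cfg <- synthetic_config(seed = 41, D = 1, bin_width = 30,
                          circadian = list(tb = c(mesor = 36, amplitude = 0, acrophase = 0),
                                           vo2 = c(mesor = 3, amplitude = 0, acrophase = 0)),
                          sigma2 = c(tb = 0, vo2 = 0))
  day1 <- simulate_baseline_day(cfg, 1)
  f1 <- fit_baseline(day1, "tb", trend_fit_config(seed = 2, n_chains = 2,
                                                  n_warmup = 300, n_samples = 400))
  f2 <- fit_baseline(day1, "tb", trend_fit_config(seed = 2, n_chains = 2,
                                                  n_warmup = 300, n_samples = 400))
  expect_identical(f1$alpha_draws, f2$alpha_draws)
  expect_identical(f1$sigma1_draws, f2$sigma1_draws)
  # flat truth: posterior mean approximately flat at the sample mean
  pm <- colMeans(f1$alpha_draws)
  expect_lt(max(abs(pm - mean(day1$tb))), 0.25)
  expect_error(fit_baseline(simulate_baseline_day(synthetic_config(seed = 1, D = 2, bin_width = 60)), "tb"),
               "one full day")
})

test_that("hierarchical sigma2 fit is scale-equivariant and detects the degenerate limit", {
  cfg <- synthetic_config(seed = 51, D = 2, bin_width = 24,
                          sigma1 = c(tb = 0.3, vo2 = 0.25))
  recs <- lapply(1:2, function(a) simulate_baseline_day(cfg, a))
  tcfg <- trend_fit_config(sigma2_mode = "estimate", seed = 8, n_chains = 2,
                           n_warmup = 400, n_samples = 600)
  f <- fit_sigma2(recs, "tb", tcfg)
  recs2x <- lapply(recs, function(r) { r$tb <- 2 * r$tb; r })
  f2x <- fit_sigma2(recs2x, "tb", tcfg)
  expect_equal(median(f2x$sigma2_draws) / median(f$sigma2_draws), 2,
               tolerance = 0.1)
  expect_equal(median(f2x$sigma1_draws[, 1]) / median(f$sigma1_draws[, 1]), 2,
               tolerance = 0.1)
  # sigma2 = 0 data (flat truth): posterior mass near the lower boundary
  cfg0 <- synthetic_config(seed = 52, D = 2, bin_width = 24,
                           circadian = list(tb = c(mesor = 36.5, amplitude = 0, acrophase = 18),
                                            vo2 = c(mesor = 3.5, amplitude = 0, acrophase = 18)),
                           sigma2 = c(tb = 0, vo2 = 0))
  recs0 <- lapply(1:2, function(a) simulate_baseline_day(cfg0, a))
  f0 <- fit_sigma2(recs0, "tb", tcfg)
  expect_lt(median(f0$sigma2_draws), 0.25 * median(f$sigma2_draws))
  expect_error(fit_sigma2(recs, "tb", trend_fit_config()), "estimate")
})

test_that("sigma2 is recovered inside its 89% HPDI across replicates", {
  hits <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    cfg <- synthetic_config(seed = 600 + i, D = 3, bin_width = 6)
    recs <- lapply(1:2, function(a) simulate_baseline_day(cfg, a))
    f <- fit_sigma2(recs, "tb",
                    trend_fit_config(sigma2_mode = "estimate", seed = 700 + i,
                                     n_chains = 2, n_warmup = 400,
                                     n_samples = 600))
    h <- hpdi(f$sigma2_draws, 0.89)
    if (h[1] <= 0.01877 && 0.01877 <= h[2]) hits <- hits + 1L
  }
  expect_gte(hits, 0.8 * n_rep)
})

test_that("predictive band reduces to known quantiles in degenerate cases", {
  # sigma1 = 0: band degenerates to the alpha quantile band
  set.seed(3)
  K <- 12
  adraws <- matrix(rnorm(500 * K, 36, 0.5), 500, K)
  post <- structure(list(variable = "tb", K = K, zt = (0:11) * 2,
                         alpha_draws = adraws,
                         sigma1_draws = rep(1e-9, 500),
                         sigma2_draws = NULL, sigma2_fixed = 0.01,
                         diagnostics = NULL, config = NULL,
                         animal_ids = "x"), class = "trend_posterior")
  b <- predictive_band(post, 0.9)
  expect_equal(b$lower, apply(adraws, 2, quantile, 0.05, type = 1),
               tolerance = 1e-4, ignore_attr = TRUE)
  # standard-normal predictive at level 0.999: half-width ~ 3.29
  post$alpha_draws <- matrix(0, 500, K)
  post$sigma1_draws <- rep(1, 500)
  b2 <- predictive_band(post, 0.999)
  expect_equal(b2$upper, rep(qnorm(0.9995), K), tolerance = 1e-4)
  expect_equal(b2$lower, rep(-qnorm(0.9995), K), tolerance = 1e-4)
  # band widens monotonically with level
  b3 <- predictive_band(post, 0.99)
  expect_true(all(b3$upper < b2$upper) && all(b3$lower > b2$lower))
  expect_error(predictive_band(post, 1.2), "level")
})

test_that("band coverage counts points and rejects mismatched grids", {
  ser <- make_series(D = 2, bin_width = 60, noise = 0.1, seed = 4)
  wide <- flat_band(24, -100, 100, "tb")
  expect_equal(band_coverage(ser, wide), 1)
  none <- flat_band(24, 50, 60, "tb")
  expect_equal(band_coverage(ser, none), 0)
  bad <- flat_band(48, -100, 100, "tb")
  expect_error(band_coverage(ser, bad), "grid mismatch")
  ser2 <- ser; ser2$tb[] <- NA
  expect_error(band_coverage(ser2, wide), "no evaluable points")
})

test_that("predictive bands are calibrated across simulated datasets", {
  # 50 strictly in-model datasets at K = 24 (flat profile + circular RW2
  # deviation + noise): the 95% band built from day 1 should exclude about
  # 5% of day-2 points (pooled binomial check). A cosine profile would be
  # out-of-model at this coarse grid (its curvature exceeds sigma2), so the
  # truth is drawn from the trend prior itself.
  excluded <- 0L; total <- 0L
  flat <- list(tb = c(mesor = 36.5, amplitude = 0, acrophase = 18),
               vo2 = c(mesor = 3.5, amplitude = 0, acrophase = 18))
  for (i in 1:50) {
    cfg <- synthetic_config(seed = 900 + i, D = 2, bin_width = 60,
                            circadian = flat,
                            sigma1 = c(tb = 0.3, vo2 = 0.25))
    ser <- simulate_baseline_day(cfg, 1)
    day1 <- subset_days(ser, 1)
    fb <- fit_baseline(day1, "tb",
                       trend_fit_config(seed = 950 + i, sigma1_fixed = 0.3,
                                        n_samples = 500, n_chains = 2))
    b <- predictive_band(fb, 0.95)
    cov <- band_coverage(ser, b, days = 2)
    excluded <- excluded + round((1 - cov) * 24)
    total <- total + 24L
  }
  p_hat <- excluded / total
  # 4 binomial SDs around 0.05 plus slack for band-estimation noise
  expect_lt(abs(p_hat - 0.05), 4 * sqrt(0.05 * 0.95 / total) + 0.01)
})
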