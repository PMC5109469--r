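# Independent brute-force HPDI: scan every window of the sorted sample.
hpdi_bruteforce <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  gap <- max(1L, min(n - 1L, round(n * mass)))
  best <- c(-Inf, Inf)
  for (i in seq_len(n - gap)) {
    if (x[i + gap] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + gap])
  }
  best
}

test_that("hpdi matches the brute-force shortest-window oracle", {
  expect_equal(hpdi(1:100, 0.89), c(1, 90))
  expect_equal(diff(hpdi(1:100, 0.89)), 89, ignore_attr = TRUE)
  set.seed(7)
  for (x in list(rnorm(501), rexp(333), rlnorm(1000), c(rep(5, 200), rnorm(100)))) {
    for (mass in c(0.5, 0.89, 0.95)) {
      expect_equal(hpdi(x, mass), hpdi_bruteforce(x, mass))
    }
  }
  # symmetric unimodal sample: HPDI ~ equal-tailed interval
  z <- rnorm(20000)
  expect_equal(hpdi(z, 0.89), quantile(z, c(0.055, 0.945)), tolerance = 0.05,
               ignore_attr = TRUE)
  # point mass: zero width
  expect_equal(diff(hpdi(rep(2.5, 200), 0.89)), 0, ignore_attr = TRUE)
  expect_error(hpdi(1:200, 1.5), "mass")
  expect_error(hpdi(1:10, 0.89), "100 draws")
})

test_that("q10 follows its closed form and invariances", {
  expect_equal(q10(4, 2, 38, 28)$q10, 2)
  expect_equal(q10(5, 2, 36, 28)$q10, 2.5^1.25)
  expect_equal(q10(5, 2, 36, 28)$q10, 3.1435837, tolerance = 1e-6)
  # scale invariance in the rates
  expect_equal(q10(5 * 3.7, 2 * 3.7, 36, 28)$q10, q10(5, 2, 36, 28)$q10)
  expect_error(q10(5, 2, 36, 36), "equal temperatures")
  expect_error(q10(-1, 2, 36, 28), "positive")
})

test_that("oxygen-to-energy conversion is exact and linear", {
  e <- o2_to_energy(1)
  expect_equal(e$cal, 5.3)
  expect_equal(e$J, 22.1752)
  expect_equal(o2_to_energy(0)$J, 0)
  expect_equal(o2_to_energy(7)$cal, 7 * o2_to_energy(1)$cal)
  expect_error(o2_to_energy(-1), "non-negative")
})

fake_fit <- function(slope, intercept, resid = 0.1, sign = "+slope*TA") {
  n <- max(length(slope), length(intercept))
  structure(list(slope_draws = rep_len(slope, n),
                 intercept_draws = rep_len(intercept, n),
                 residual_sd_draws = rep_len(resid, n),
                 sign_convention = sign, diagnostics = NULL, n = n),
            class = "linear_fit_posterior")
}

test_that("derived H and T_R satisfy the elimination identity draw-wise", {
  expect_equal(derive_H(fake_fit(1, 0), fake_fit(2, 0, sign = "-slope*TA")),
               rep(2, 1))
  expect_equal(derive_TR(fake_fit(1, 0), fake_fit(1, 36, sign = "-slope*TA")),
               rep(36, 1))
  expect_error(derive_H(fake_fit(rep(1, 5), 0), fake_fit(rep(2, 4), 0)),
               "mismatch")
  # for random (a1, b1, a2, b2): the eliminated T_B line equals the
  # thermogenesis line H (T_R - T_B) at arbitrary T_B
  set.seed(12)
  a1 <- rlnorm(100, -2, 0.3); b1 <- runif(100, 30, 36)
  a2 <- rlnorm(100, -1.5, 0.3); b2 <- runif(100, 2, 9)
  ftb <- fake_fit(a1, b1); fvo <- fake_fit(a2, b2, sign = "-slope*TA")
  H <- derive_H(ftb, fvo); TR <- derive_TR(ftb, fvo)
  tb_probe <- runif(100, 25, 40)
  for (i in seq_len(100)) {
    lhs <- -(a2[i] / a1[i]) * tb_probe + (a2[i] * b1[i] / a1[i] + b2[i])
    rhs <- H[i] * (TR[i] - tb_probe)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # VO2 at T_B = T_R is zero for every draw
  expect_equal(H * (TR - TR), rep(0, 100))
})

test_that("T_B regression recovers a nearly noise-free line and shifts correctly", {
  tab <- simulate_minimal_table(c(a1 = 0.25, b1 = 24, a2 = 0.2, b2 = 8),
                                n_per_ta = 3,
                                residual_sd = c(tb = 0.01, vo2 = 0.01),
                                seed = 3)
  f <- fit_tb_regression(tab, n_chains = 2, n_warmup = 500, n_samples = 500,
                         seed = 4)
  expect_equal(mean(f$slope_draws), 0.25, tolerance = 0.02)
  expect_equal(mean(f$intercept_draws), 24, tolerance = 0.1)
  # adding 5 degC to every T_A shifts b1 by -5 a1 and leaves a1 unchanged
  tab5 <- tab; tab5$ta <- tab5$ta + 5
  f5 <- fit_tb_regression(tab5, n_chains = 2, n_warmup = 500, n_samples = 500,
                          seed = 4)
  expect_equal(mean(f5$slope_draws), mean(f$slope_draws), tolerance = 0.02)
  expect_equal(mean(f5$intercept_draws) - mean(f$intercept_draws),
               -5 * 0.25, tolerance = 0.1)
  expect_error(fit_tb_regression(tab[tab$ta == 12, ]), "3 distinct")
})

test_that("VO2 regression keeps its sign convention and slope ordering", {
  tab_n <- simulate_minimal_table(c(a1 = 0.043, b1 = 34.9, a2 = 0.203, b2 = 7.99),
                                  n_per_ta = 4,
                                  residual_sd = c(tb = 0.1, vo2 = 0.1), seed = 5)
  tab_t <- simulate_minimal_table(c(a1 = 0.257, b1 = 24.7, a2 = 0.103, b2 = 3.55),
                                  n_per_ta = 4,
                                  residual_sd = c(tb = 0.1, vo2 = 0.1), seed = 6,
                                  state = "torpid")
  fn <- fit_vo2_regression(tab_n, n_chains = 2, n_warmup = 500, n_samples = 500,
                           seed = 7)
  ft <- fit_vo2_regression(tab_t, n_chains = 2, n_warmup = 500, n_samples = 500,
                           seed = 8)
  expect_true(all(fn$slope_draws > 0))  # positive by prior support
  expect_equal(mean(fn$slope_draws), 0.203, tolerance = 0.03)
  # torpid-scale data give a flatter fitted slope than normal-scale data
  expect_lt(mean(ft$slope_draws), mean(fn$slope_draws))
})

test_that("conductance fit recovers the slope and is scale-equivariant", {
  set.seed(9)
  grad <- runif(30, 4, 25)
  rows <- data.frame(gradient = grad, vo2 = 0.228 * grad + rnorm(30, 0, 0.05))
  f <- fit_conductance(rows, n_chains = 2, n_warmup = 500, n_samples = 500,
                       seed = 10)
  expect_equal(mean(f$g_draws), 0.228, tolerance = 0.01)
  rows2 <- data.frame(gradient = 2 * grad, vo2 = rows$vo2)
  f2 <- fit_conductance(rows2, n_chains = 2, n_warmup = 500, n_samples = 500,
                        seed = 10)
  expect_equal(mean(f2$g_draws), 0.114, tolerance = 0.006)
  # non-positive gradients are dropped with a warning
  rows3 <- rbind(rows, data.frame(gradient = c(-1, 0), vo2 = c(1, 1)))
  expect_warning(fit_conductance(rows3, n_chains = 2, n_warmup = 200,
                                 n_samples = 200, seed = 11), "dropped")
})

test_that("torpid regression recovery stays inside its own HPDI", {
  tab <- simulate_minimal_table(c(a1 = 0.257, b1 = 24.7, a2 = 0.103, b2 = 3.55),
                                n_per_ta = 8,
                                residual_sd = c(tb = 0.4, vo2 = 0.15), seed = 13,
                                state = "torpid")
  f <- fit_tb_regression(tab, n_chains = 2, n_warmup = 500, n_samples = 750,
                         seed = 14)
  h <- hpdi(f$slope_draws)
  expect_true(h[1] <= 0.257 && 0.257 <= h[2])
})

test_that("predictive check flags extra thermogenesis and narrows with n", {
  fit <- fake_fit(rep(0.257, 2000) + rnorm(2000, 0, 0.01),
                  rep(24.7, 2000) + rnorm(2000, 0, 0.1),
                  resid = rep(0.4, 2000))
  at8 <- 0.257 * 8 + 24.7
  ok <- predictive_check_low_ta(fit, 8, 6, at8, seed = 1)
  expect_false(ok$exceeds_upper)
  hot <- predictive_check_low_ta(fit, 8, 6, at8 + 1.5, seed = 1)
  expect_true(hot$exceeds_upper)   # constructed positive control
  wide <- predictive_check_low_ta(fit, 8, 2, at8, seed = 2)
  narrow <- predictive_check_low_ta(fit, 8, 200, at8, seed = 2)
  expect_lt(diff(narrow$hpdi), diff(wide$hpdi))
  expect_error(predictive_check_low_ta(fit, 8, 0, at8), "n_new")
})

test_that("state-shift summary reproduces the printed percentage arithmetic", {
  normal <- list(g_draws = rep(0.228, 200), h_draws = rep(5.1, 200),
                 tr_draws = rep(36.6, 200))
  torpid <- list(g_draws = rep(0.144, 200), h_draws = rep(0.437, 200),
                 tr_draws = rep(32.8, 200))
  ss <- summarize_state_shift(normal, torpid)
  expect_equal(round(ss$g_reduction_pct), 37)
  expect_equal(ss$tr_drop_means, 36.6 - 32.8)
  expect_equal(ss$gh_ratio[["normal"]], 0.228 / 5.1)
  expect_equal(ss$gh_ratio[["torpid"]], 0.144 / 0.437)
  expect_equal(round(ss$gh_ratio[["torpid"]], 2), 0.33)
  # identical states: all shifts zero
  ss0 <- summarize_state_shift(normal, normal)
  expect_equal(ss0$h_reduction_pct, 0)
  expect_equal(ss0$tr_drop_means, 0)
})
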