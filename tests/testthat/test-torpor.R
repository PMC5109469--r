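test_that("detection rules apply strict lower-outlier logic", {
  K <- 24
  ser <- make_series(D = 2, bin_width = 60,
                     tb_fun = function(zt) rep(36, length(zt)),
                     vo2_fun = function(zt) rep(3, length(zt)))
  # craft day-2 values: below both bounds, below tb only, at the bound
  ser$tb[K + 1] <- 30; ser$vo2[K + 1] <- 1      # below both
  ser$tb[K + 2] <- 30; ser$vo2[K + 2] <- 3      # below tb only
  ser$tb[K + 3] <- 33; ser$vo2[K + 3] <- 2      # exactly at the bounds
  btb <- flat_band(K, 33, 39, "tb")
  bvo <- flat_band(K, 2, 4, "vo2")
  m <- detect_torpor(ser, btb, bvo, detection_rule("joint"))
  expect_true(m$flags[K + 1])
  expect_false(m$flags[K + 2])
  expect_false(m$flags[K + 3])   # ties with the bound are not torpor
  m_tb <- detect_torpor(ser, btb, bvo, detection_rule("tb_only"))
  expect_true(all(m$flags <= m_tb$flags))  # joint mask subset of tb-only
  # day 1 is never flagged (training day)
  ser$tb[1] <- 20; ser$vo2[1] <- 0.1
  m2 <- detect_torpor(ser, btb, bvo, detection_rule("joint"))
  expect_false(m2$flags[1])
  # missing data never flagged
  ser$tb[K + 1] <- NA
  m3 <- detect_torpor(ser, btb, bvo, detection_rule("joint"))
  expect_false(m3$flags[K + 1])
})

test_that("fixed-threshold mode uses a strict inequality", {
  ser <- make_series(D = 2, bin_width = 480,
                     tb_fun = function(zt) rep(36, length(zt)))
  ser$tb[4:6] <- c(36, 30.9, 31.0)
  m <- detect_torpor(ser, rule = detection_rule("fixed_threshold", threshold_tb = 31),
                     evaluated_days = 2)
  expect_equal(m$flags[4:6], c(FALSE, TRUE, FALSE))
  expect_error(detection_rule("fixed_threshold"), "threshold_tb")
  expect_error(detection_rule("joint", threshold_tb = 31), "only meaningful")
})

test_that("lowering the credible level can only grow the mask", {
  cfg <- synthetic_config(seed = 61, D = 2, bin_width = 60)
  ser <- simulate_baseline_day(cfg, 1)
  fb <- lapply(c(tb = "tb", vo2 = "vo2"), function(v)
    fit_baseline(subset_days(ser, 1), v,
                 trend_fit_config(seed = 6, n_chains = 2, n_warmup = 200,
                                  n_samples = 400)))
  for (lv in c(0.999, 0.99)) {
    b_tb <- predictive_band(fb$tb, lv); b_vo <- predictive_band(fb$vo2, lv)
    m <- detect_torpor(ser, b_tb, b_vo, detection_rule("joint", level = lv))
    if (lv == 0.999) wide <- m$flags else narrow <- m$flags
  }
  expect_true(all(wide <= narrow))
})

test_that("episodes are maximal runs with correct durations and depths", {
  ser <- make_series(D = 2, bin_width = 6)
  flags <- rep(FALSE, length(ser$t))
  flags[241:246] <- c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  eps <- torpor_episodes(mask_from_flags(flags), ser)
  expect_equal(nrow(eps), 2L)
  expect_equal(eps$duration, c(12, 6))
  st <- torpor_stats(eps)
  expect_equal(st$total_torpor_min, 18)
  expect_equal(st$mean_episode_min, 9)
  expect_equal(st$n_episodes, 2L)
  expect_true(st$entered_torpor)
  # empty mask
  st0 <- torpor_stats(torpor_episodes(mask_from_flags(rep(FALSE, length(ser$t))), ser))
  expect_false(st0$entered_torpor)
  expect_equal(st0$total_torpor_min, 0)
  # induction-rate arithmetic: 6 of 11 entering = 54.5%
  entered <- c(rep(TRUE, 6), rep(FALSE, 5))
  expect_equal(round(100 * mean(entered), 1), 54.5)
})

test_that("minimal metabolic point breaks ties by earliest time", {
  ser <- make_series(D = 1, bin_width = 360)
  ser$tb <- c(36, 35, 35, 37)
  ser$vo2 <- c(3, 2.8, 2.5, 3.1)
  mp <- minimal_metabolic_point(ser)
  expect_equal(mp$time, ser$t[2])
  expect_equal(mp$min_tb, 35)
  expect_equal(mp$vo2_at_min_tb, 2.8)
  expect_error(minimal_metabolic_point(ser, window = c(5000, 6000)),
               "no eligible")
  # dark-phase window of day 1 covers ZT 12-24
  ser2 <- make_series(D = 2, bin_width = 60)
  w <- dark_phase_window(ser2, 1)
  expect_equal(w, c(720, 1440))
})

test_that("detector finds injected bouts and their plateau depth", {
  # wander-free cohort so that scheduled bouts are the only outliers
  cfg <- synthetic_config(seed = 71, n_animals = 2, ta_grid = c(12, 20),
                          bin_width = 30,
                          tr_modulation = c(amplitude = 1.0, acrophase = 18,
                                            wander_sd = 0))
  co <- simulate_cohort(cfg)
  for (id in names(co$recordings)) {
    ser <- co$recordings[[id]]
    fb <- lapply(c(tb = "tb", vo2 = "vo2"), function(v)
      fit_baseline(subset_days(ser, 1), v,
                   trend_fit_config(seed = child_seed(71, paste0(id, v)),
                                    n_chains = 2, n_warmup = 200,
                                    n_samples = 400)))
    m <- detect_torpor(ser, predictive_band(fb$tb), predictive_band(fb$vo2))
    tt <- attr(ser, "torpor_truth")
    # the scheduled bout is found: most interior points flagged, and the
    # detected minimum sits near the mechanistic plateau
    deep <- tt$mask & c(rep(FALSE, tt$path_index[1] - 1),
                        (attr(ser, "truth")$tb_base[tt$path_index] - tt$tb_path) >= 5)
    expect_gt(sum(m$flags & deep) / max(sum(deep), 1), 0.95)
    mp <- minimal_metabolic_point(ser, mask = m)
    ta <- co$truth[[id]]$ta
    expect_equal(mp$min_tb, min(tt$tb_path), tolerance = 0.01 + 4 * 0.1)
    eps <- torpor_episodes(m, ser)
    expect_gte(nrow(eps), 1L)
  }
})

test_that("compare_definitions tabulates all four rules", {
  cfg <- synthetic_config(seed = 81, n_animals = 1, ta_grid = 12, bin_width = 60,
                          tr_modulation = c(amplitude = 1.0, acrophase = 18,
                                            wander_sd = 0))
  co <- simulate_cohort(cfg)
  ser <- co$recordings[[1]]
  fb <- lapply(c(tb = "tb", vo2 = "vo2"), function(v)
    fit_baseline(subset_days(ser, 1), v,
                 trend_fit_config(seed = 9, n_chains = 2, n_warmup = 200,
                                  n_samples = 300)))
  tab <- compare_definitions(ser, predictive_band(fb$tb), predictive_band(fb$vo2))
  expect_equal(tab$definition, c("fixed_31", "fixed_34", "tb_only", "joint"))
  expect_true(all(tab$total_torpor_min[tab$definition == "joint"] <=
                  tab$total_torpor_min[tab$definition == "tb_only"]))
  expect_true(all(tab$entered_torpor))
})
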