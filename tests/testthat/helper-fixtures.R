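# Shared fixtures, built in code at test time.

make_series <- function(D = 3, bin_width = 6, tb_fun = function(zt) 36.5 + cos(2 * pi * (zt - 18) / 24),
                        vo2_fun = function(zt) 3.5 + cos(2 * pi * (zt - 18) / 24),
                        noise = 0, ta = 16, seed = 1, animal_id = "fix") {
  set.seed(seed)
  K <- 1440 / bin_width
  t <- (seq_len(K * D) - 1) * bin_width
  zt <- (t / 60) %% 24
  metabolic_ts(animal_id, t,
               tb = tb_fun(zt) + rnorm(length(t), 0, noise),
               vo2 = pmax(0, vo2_fun(zt) + rnorm(length(t), 0, noise)),
               ta = ta)
}

# flat band helper for detector unit tests
flat_band <- function(K, lower, upper, variable, level = 0.999) {
  structure(list(level = level, K = K, zt = (seq_len(K) - 1) * 24 / K,
                 lower = rep(lower, K), upper = rep(upper, K),
                 variable = variable, animal_id = "fix"),
            class = "predictive_band")
}

mask_from_flags <- function(flags, days = 2:3) {
  structure(list(flags = flags, rule = detection_rule(),
                 evaluated_days = days, animal_id = "fix"),
            class = "torpor_mask")
}
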