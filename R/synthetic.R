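# Mechanistic synthetic-data generator.
#
# Two layers:
#  * simulate_baseline_day(): recordings drawn exactly from the circular
#    second-order trend observation model (circadian profile + circular RW2
#    deviation + Gaussian noise) - the in-model benchmark for the baseline
#    fitter and the detector's false-positive calibration.
#  * simulate_cohort(): fasting-induced torpor experiments in which the
#    baseline follows the steady state of the thermoregulatory feedback
#    model with a circadian set-point modulation, and torpor bouts are
#    integrated from the heat-balance ODE
#        dT_B/dt = (H (T_R - T_B) - G (T_B - T_A)) / C
#    with regime switching between normal and torpid (G, H, T_R). Torpor
#    depth therefore scales with T_A exactly as the steady state
#        T_B* = (H T_R + G T_A) / (G + H)
#    dictates, and minimal metabolic points lie on the thermogenesis line
#    VO2 = H (T_R - T_B), which is what the downstream regressions assume.

#' Ground-truth configuration for the synthetic-data generator
#'
#' Defaults define the study conditions used throughout the package's
#' recovery experiments; see the methods vignette for the rationale behind
#' each value.
#'
#' @param seed master seed; every simulated object derives a child seed.
#' @param n_animals animals per ambient temperature in a cohort.
#' @param D days per recording (fasting on day 2 of 3).
#' @param bin_width minutes per bin (must divide 1440).
#' @param ta ambient temperature (degC) for single-animal baseline days.
#' @param ta_grid cohort ambient temperatures (degC).
#' @param circadian per-variable cosine baseline for
#'   [simulate_baseline_day()]: named vectors `c(mesor, amplitude,
#'   acrophase)` (acrophase in ZT hours).
#' @param sigma1 per-variable observation-noise SD for trend-model days.
#' @param sigma2 per-variable circular trend-innovation SD per bin.
#' @param normal_state,torpid_state named `c(G, H, T_R)` triples
#'   (ml/g/hr/degC, ml/g/hr/degC, degC).
#' @param C heat capacity in ml O2-equivalent/g/degC; affects transients
#'   only, never the steady state.
#' @param tr_modulation circadian modulation of the set-point used by
#'   [simulate_cohort()]: `amplitude` (degC), `acrophase` (ZT hours) and
#'   `wander_sd` (degC, slow smooth within-recording set-point wander).
#' @param obs_noise per-variable instrument noise SD in cohort recordings.
#' @param bout_entry_zt range (ZT hours) of torpor-bout entry on the
#'   fasting day.
#' @param bout_duration_hr range of bout durations (hours).
#' @param residual_sd_minima per-variable residual SD for
#'   [simulate_minimal_table()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_animals = 8L, D = 3L, bin_width = 6,
                             ta = 16, ta_grid = c(8, 12, 16, 20, 24),
                             circadian = list(tb = c(mesor = 36.5, amplitude = 1.0, acrophase = 18),
                                              vo2 = c(mesor = 3.5, amplitude = 1.0, acrophase = 18)),
                             sigma1 = c(tb = 0.3, vo2 = 0.25),
                             sigma2 = c(tb = 0.01877, vo2 = 0.00650),
                             normal_state = c(G = 0.228, H = 5.1, T_R = 36.6),
                             torpid_state = c(G = 0.144, H = 0.437, T_R = 32.8),
                             C = 0.655,
                             tr_modulation = c(amplitude = 1.0, acrophase = 18, wander_sd = 0.3),
                             obs_noise = c(tb = 0.1, vo2 = 0.15),
                             bout_entry_zt = c(12, 16),
                             bout_duration_hr = c(4, 8),
                             residual_sd_minima = c(tb = 0.2, vo2 = 0.15)) {
  stopifnot(all(sigma1 >= 0), all(sigma2 >= 0), all(obs_noise >= 0),
            all(residual_sd_minima > 0), C > 0,
            all(normal_state[c("G", "H")] > 0),
            all(torpid_state[c("G", "H")] > 0))
  if (torpid_state[["T_R"]] > normal_state[["T_R"]])
    stop_tm("torpid T_R must not exceed normal T_R")
  K <- as.integer(round(1440 / bin_width))
  if (abs(K * bin_width - 1440) > 1e-9) stop_tm("bin_width must divide 1440")
  structure(list(seed = as.integer(seed), n_animals = as.integer(n_animals),
                 D = as.integer(D), bin_width = bin_width, K = K, ta = ta,
                 ta_grid = ta_grid, circadian = circadian, sigma1 = sigma1,
                 sigma2 = sigma2, normal_state = normal_state,
                 torpid_state = torpid_state, C = C,
                 tr_modulation = tr_modulation, obs_noise = obs_noise,
                 bout_entry_zt = bout_entry_zt,
                 bout_duration_hr = bout_duration_hr,
                 residual_sd_minima = residual_sd_minima),
            class = "synthetic_config")
}

cosine_profile <- function(zt, pars) {
  pars[["mesor"]] + pars[["amplitude"]] * cos(2 * pi * (zt - pars[["acrophase"]]) / 24)
}

# Draw a circular baseline deviation whose second differences are iid
# N(0, sigma2^2) projected on the solvable (zero-sum) subspace; the
# zero-mean solution of L d = eta via the circulant spectrum of L.
rw2_circular_deviation <- function(K, sigma2) {
  if (sigma2 == 0) return(numeric(K))
  eta <- stats::rnorm(K, 0, sigma2)
  eta <- eta - mean(eta)
  cvec <- c(1, -2, 1, rep(0, K - 3))
  lam <- stats::fft(cvec)
  ehat <- stats::fft(eta)
  dhat <- ehat / lam
  dhat[1] <- 0 + 0i
  Re(stats::fft(dhat, inverse = TRUE)) / K
}

#' Simulate an in-model multi-day baseline recording
#'
#' One animal, D days. The 24-h baseline is the circadian cosine profile
#' plus a circular second-order (RW2) deviation with per-bin innovation SD
#' `sigma2`, shared by all days of the animal; each day receives fresh
#' Gaussian observation noise with SD `sigma1`. This is exactly the
#' generative model assumed by [fit_baseline()] / [fit_sigma2()].
#'
#' @param config a [synthetic_config()].
#' @param animal animal index (drives the child seed).
#' @return A [metabolic_ts()]; the noise-free truth is attached as
#'   `attr(x, "truth")` (`alpha_tb`, `alpha_vo2` of length K).
#' @export
simulate_baseline_day <- function(config, animal = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(child_seed(config$seed, paste0("baseline-animal-", animal)))
  K <- config$K; D <- config$D
  zt <- (seq_len(K) - 1L) * config$bin_width / 60
  alpha <- list()
  y <- list()
  for (v in c("tb", "vo2")) {
    prof <- cosine_profile(zt, config$circadian[[v]])
    alpha[[v]] <- prof + rw2_circular_deviation(K, config$sigma2[[v]])
    y[[v]] <- rep(alpha[[v]], D) + stats::rnorm(K * D, 0, config$sigma1[[v]])
  }
  y$vo2 <- pmax(y$vo2, 0)
  out <- metabolic_ts(animal_id = paste0("sim", animal),
                      t = (seq_len(K * D) - 1L) * config$bin_width,
                      tb = y$tb, vo2 = y$vo2, ta = config$ta)
  attr(out, "truth") <- list(alpha_tb = alpha$tb, alpha_vo2 = alpha$vo2,
                             sigma1 = config$sigma1, sigma2 = config$sigma2)
  out
}

# Forward-integrate the heat-balance ODE over a time grid (minutes),
# with per-point parameter vectors; explicit stepping with sub-steps small
# enough for the fast normal-regime dynamics.
integrate_heat_balance <- function(t_min, tb0, G, H, TR, ta, C, substep_hr = 0.01) {
  n <- length(t_min)
  stopifnot(length(G) == n, length(H) == n, length(TR) == n, length(ta) == n)
  tb <- numeric(n)
  tb[1] <- tb0
  for (i in seq_len(n - 1L)) {
    dt_hr <- (t_min[i + 1L] - t_min[i]) / 60
    n_sub <- max(1L, ceiling(dt_hr / substep_hr))
    h <- dt_hr / n_sub
    x <- tb[i]
    for (s in seq_len(n_sub)) {
      x <- x + h * (H[i] * (TR[i] - x) - G[i] * (x - ta[i])) / C
    }
    tb[i + 1L] <- x
  }
  tb
}

#' Steady-state body temperature of the heat-balance model
#'
#' `T_B = (H T_R + G T_A) / (G + H)`: the equilibrium the regime-switched
#' ODE relaxes to, and the depth a sufficiently long torpor bout reaches.
#'
#' @param G heat conductance (ml/g/hr/degC).
#' @param H feedback gain (ml/g/hr/degC).
#' @param T_R set-point temperature (degC).
#' @param T_A ambient temperature (degC).
#' @return Steady-state body temperature (degC).
#' @export
steady_state_tb <- function(G, H, T_R, T_A) {
  if (any(G + H <= 0)) stop_tm("G + H must be positive")
  (H * T_R + G * T_A) / (G + H)
}

#' Inject mechanistic torpor bouts into a recording
#'
#' Within each scheduled bout the thermoregulatory regime switches to the
#' torpid `(G, H, T_R)` and body temperature is integrated forward from the
#' heat-balance ODE; after the bout the normal regime restores euthermia
#' (the mechanistic segment ends once T_B recovers to within 0.2 degC of
#' the baseline, or after 4 h). VO2 in the mechanistic segment is
#' `max(0, H (T_R - T_B))` plus observation noise.
#'
#' @param series a [metabolic_ts()] whose fasting day has
#'   `food_available = FALSE` and which carries a noise-free baseline in
#'   `attr(series, "truth")` (as produced by [simulate_baseline_day()]).
#' @param config a [synthetic_config()].
#' @param bouts data frame with columns `start_min`, `duration_min`
#'   (experiment-clock minutes); every bout must lie within the fasting day.
#' @return The modified [metabolic_ts()]; `attr(x, "torpor_truth")` holds
#'   the scheduled-bout mask, the bout table, and the noise-free T_B path.
#' @export
simulate_torpor_bouts <- function(series, config, bouts) {
  stopifnot(inherits(series, "metabolic_ts"), inherits(config, "synthetic_config"))
  truth <- attr(series, "truth")
  if (is.null(truth)) stop_tm("series carries no noise-free baseline (attr 'truth')")
  if (!any(!series$food_available)) stop_tm("no fasting day flagged in series")
  fast_rng <- range(series$t[!series$food_available])
  fast_lo <- fast_rng[1]; fast_hi <- fast_rng[2] + series$bin_width
  if (any(bouts$start_min < fast_lo |
          bouts$start_min + bouts$duration_min > fast_hi))
    stop_tm("every bout must lie within the fasting day")
  bouts <- bouts[order(bouts$start_min), , drop = FALSE]

  set.seed(child_seed(config$seed, paste0("bouts-", series$animal_id)))
  K <- series$K
  k_of <- function(i) ((i - 1L) %% K) + 1L
  base_tb <- truth$alpha_tb[k_of(seq_along(series$t))]
  base_vo2 <- truth$alpha_vo2[k_of(seq_along(series$t))]
  sig <- truth$sigma1 %||% config$sigma1

  in_bout <- rep(FALSE, length(series$t))
  for (b in seq_len(nrow(bouts))) {
    in_bout <- in_bout | (series$t >= bouts$start_min[b] &
                          series$t < bouts$start_min[b] + bouts$duration_min[b])
  }
  if (!any(in_bout)) {
    attr(series, "torpor_truth") <- list(mask = in_bout, bouts = bouts[0, ],
                                         tb_path = numeric(0),
                                         path_index = integer(0))
    return(series)
  }
  # mechanistic segment: first bout entry -> recovery after last bout
  i0 <- which(in_bout)[1]
  i_last <- max(which(in_bout))
  n_pt <- length(series$t)
  ns <- config$normal_state; ts_ <- config$torpid_state
  seg <- i0:n_pt
  G <- ifelse(in_bout[seg], ts_[["G"]], ns[["G"]])
  H <- ifelse(in_bout[seg], ts_[["H"]], ns[["H"]])
  TR <- ifelse(in_bout[seg], ts_[["T_R"]], ns[["T_R"]])
  tb_path <- integrate_heat_balance(series$t[seg], base_tb[i0], G, H, TR,
                                    series$ta[seg], config$C)
  # segment end: recovered to baseline after the last bout (max 4 h)
  after <- which(seg > i_last & (tb_path >= base_tb[seg] - 0.2 |
                                 series$t[seg] - series$t[i_last] > 240))
  i_end <- if (length(after)) seg[after[1]] else n_pt
  use <- seg <= i_end
  idx <- seg[use]
  series$tb[idx] <- tb_path[use] + stats::rnorm(length(idx), 0, sig[["tb"]])
  series$vo2[idx] <- pmax(0, H[use] * (TR[use] - tb_path[use]) +
                             stats::rnorm(length(idx), 0, sig[["vo2"]]))
  attr(series, "truth") <- truth
  attr(series, "torpor_truth") <- list(mask = in_bout, bouts = bouts,
                                       tb_path = tb_path, path_index = seg)
  series
}

# Smooth slow set-point wander over the whole recording: random low-order
# Fourier series (periods >= ~6 h), scaled to the requested SD.
tr_wander <- function(t_min, sd) {
  if (sd == 0) return(numeric(length(t_min)))
  total <- max(t_min) + (t_min[2] - t_min[1])
  jmax <- max(1L, floor(total / 360))
  w <- numeric(length(t_min))
  for (j in seq_len(jmax)) {
    w <- w + stats::rnorm(1) * cos(2 * pi * j * t_min / total) +
         stats::rnorm(1) * sin(2 * pi * j * t_min / total)
  }
  w * sd / sqrt(jmax)
}

#' Simulate a fasting-induced torpor cohort
#'
#' For each ambient temperature in `ta_grid`, `n_animals` three-day
#' recordings: day 1 baseline with food, fasting from day 2 ZT0 for 24 h,
#' refeeding at day 3 ZT0. The non-torpid baseline follows the steady state
#' of the normal-regime feedback model under a circadian set-point
#' modulation; each animal receives one scheduled torpor bout on the
#' fasting day, integrated mechanistically (see [simulate_torpor_bouts()]).
#'
#' @param config a [synthetic_config()].
#' @return A list with `recordings` (list of [metabolic_ts()]), `truth`
#'   (per-animal list: scheduled mask, bout table, ta) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  recordings <- list()
  truth <- list()
  ns <- config$normal_state
  mod <- config$tr_modulation
  for (ta in config$ta_grid) {
    for (a in seq_len(config$n_animals)) {
      id <- sprintf("ta%g_m%d", ta, a)
      set.seed(child_seed(config$seed, paste0("cohort-", id)))
      n <- config$K * config$D
      t_min <- (seq_len(n) - 1L) * config$bin_width
      zt <- (t_min / 60) %% 24
      tr_base <- ns[["T_R"]] +
        mod[["amplitude"]] * cos(2 * pi * (zt - mod[["acrophase"]]) / 24) +
        tr_wander(t_min, mod[["wander_sd"]])
      tb_base <- (ns[["H"]] * tr_base + ns[["G"]] * ta) / (ns[["G"]] + ns[["H"]])
      vo2_base <- ns[["H"]] * (tr_base - tb_base)
      tb <- tb_base + stats::rnorm(n, 0, config$obs_noise[["tb"]])
      vo2 <- pmax(0, vo2_base + stats::rnorm(n, 0, config$obs_noise[["vo2"]]))
      food <- rep(TRUE, n)
      food[t_min >= 1440 & t_min < 2880] <- FALSE
      ser <- metabolic_ts(id, t_min, tb, vo2, ta, food_available = food)
      attr(ser, "truth") <- list(alpha_tb = tb_base[seq_len(config$K)],
                                 alpha_vo2 = vo2_base[seq_len(config$K)],
                                 tb_base = tb_base, vo2_base = vo2_base,
                                 tr_base = tr_base, sigma1 = config$obs_noise)
      entry_zt <- stats::runif(1, config$bout_entry_zt[1], config$bout_entry_zt[2])
      dur_hr <- stats::runif(1, config$bout_duration_hr[1], config$bout_duration_hr[2])
      start_min <- 1440 + round(entry_zt * 60 / config$bin_width) * config$bin_width
      dur_min <- round(dur_hr * 60 / config$bin_width) * config$bin_width
      dur_min <- min(dur_min, 2880 - start_min)
      bouts <- data.frame(start_min = start_min, duration_min = dur_min)
      ser <- simulate_cohort_bouts(ser, config, bouts, tb_base, vo2_base, tr_base)
      recordings[[id]] <- ser
      truth[[id]] <- list(mask = attr(ser, "torpor_truth")$mask,
                          bouts = bouts, ta = ta)
    }
  }
  list(recordings = recordings, truth = truth, config = config)
}

# Cohort variant of bout injection. The circadian/wander set-point
# modulation is a normal-regime phenomenon (active thermogenesis drive);
# inside a bout the collapsed feedback targets the bare torpid T_R, so the
# torpid thermogenesis line observed at the minima carries the state's own
# set-point rather than a modulation-shifted one.
simulate_cohort_bouts <- function(series, config, bouts, tb_base, vo2_base, tr_base) {
  ns <- config$normal_state; ts_ <- config$torpid_state
  n <- length(series$t)
  in_bout <- rep(FALSE, n)
  for (b in seq_len(nrow(bouts))) {
    in_bout <- in_bout | (series$t >= bouts$start_min[b] &
                          series$t < bouts$start_min[b] + bouts$duration_min[b])
  }
  if (!any(in_bout)) {
    attr(series, "torpor_truth") <- list(mask = in_bout, bouts = bouts[0, ],
                                         tb_path = numeric(0),
                                         path_index = integer(0))
    return(series)
  }
  i0 <- which(in_bout)[1]
  i_last <- max(which(in_bout))
  seg <- i0:n
  dev <- tr_base - ns[["T_R"]]   # circadian + wander component
  G <- ifelse(in_bout[seg], ts_[["G"]], ns[["G"]])
  H <- ifelse(in_bout[seg], ts_[["H"]], ns[["H"]])
  TR <- ifelse(in_bout[seg], ts_[["T_R"]], ns[["T_R"]] + dev[seg])
  tb_path <- integrate_heat_balance(series$t[seg], tb_base[i0], G, H, TR,
                                    series$ta[seg], config$C)
  after <- which(seg > i_last & (tb_path >= tb_base[seg] - 0.2 |
                                 series$t[seg] - series$t[i_last] > 240))
  i_end <- if (length(after)) seg[after[1]] else n
  use <- seg <= i_end
  idx <- seg[use]
  series$tb[idx] <- tb_path[use] + stats::rnorm(length(idx), 0, config$obs_noise[["tb"]])
  series$vo2[idx] <- pmax(0, H[use] * (TR[use] - tb_path[use]) +
                             stats::rnorm(length(idx), 0, config$obs_noise[["vo2"]]))
  attr(series, "torpor_truth") <- list(mask = in_bout, bouts = bouts,
                                       tb_path = tb_path, path_index = seg)
  series
}

#' Convert thermoregulatory parameters to minimal-point line coefficients
#'
#' Under the steady-state heat balance, the minimal T_B and VO2 across
#' ambient temperatures follow `min T_B = a1 T_A + b1` and
#' `min VO2 = -a2 T_A + b2` with
#' `a1 = G/(G+H)`, `b1 = H T_R/(G+H)`, `a2 = G H/(G+H)`,
#' `b2 = G H T_R/(G+H)`.
#'
#' @param G,H,T_R thermoregulatory parameters.
#' @return Named vector `c(a1, b1, a2, b2)`.
#' @export
thermo_to_lines <- function(G, H, T_R) {
  s <- G + H
  c(a1 = G / s, b1 = H * T_R / s, a2 = G * H / s, b2 = G * H * T_R / s)
}

#' Simulate a minimal-metabolism table
#'
#' Rows of per-animal minimal metabolic points across ambient temperatures,
#' generated from the two linear relationships (optionally implied by a
#' `(G, H, T_R)` triple via [thermo_to_lines()]) plus Gaussian residuals.
#'
#' @param true_params either `c(a1, b1, a2, b2)` or `c(G, H, T_R)` (named).
#' @param n_per_ta animals per ambient temperature.
#' @param residual_sd named per-variable residual SD `c(tb, vo2)`.
#' @param seed integer seed.
#' @param ta_grid ambient temperatures (degC).
#' @param state label for the `state` column.
#' @return A data frame with columns `animal_id`, `ta`, `state`, `min_tb`,
#'   `vo2_at_min`.
#' @export
simulate_minimal_table <- function(true_params, n_per_ta = 6L,
                                   residual_sd = c(tb = 0.2, vo2 = 0.15),
                                   seed = 1L, ta_grid = c(12, 16, 20, 24),
                                   state = "normal") {
  if (any(residual_sd < 0)) stop_tm("residual_sd must be non-negative")
  if (all(c("G", "H", "T_R") %in% names(true_params))) {
    true_params <- thermo_to_lines(true_params[["G"]], true_params[["H"]],
                                   true_params[["T_R"]])
  }
  stopifnot(all(c("a1", "b1", "a2", "b2") %in% names(true_params)))
  set.seed(child_seed(seed, "minimal-table"))
  rows <- expand.grid(animal = seq_len(n_per_ta), ta = ta_grid)
  n <- nrow(rows)
  data.frame(animal_id = sprintf("ta%g_m%d", rows$ta, rows$animal),
             ta = rows$ta, state = state,
             min_tb = true_params[["a1"]] * rows$ta + true_params[["b1"]] +
               stats::rnorm(n, 0, residual_sd[["tb"]]),
             vo2_at_min = -true_params[["a2"]] * rows$ta + true_params[["b2"]] +
               stats::rnorm(n, 0, residual_sd[["vo2"]]),
             stringsAsFactors = FALSE)
}
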