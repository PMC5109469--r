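# Thermoregulatory parameter estimation.
#
# From minimal metabolic points across ambient temperatures:
#   min T_B  =  a1 T_A + b1          (T_B line)
#   min VO2  = -a2 T_A + b2          (VO2 line)
#   VO2      =  G (T_B - T_A)        (conduction law, no intercept)
# Eliminating T_A between the two lines gives the thermogenesis line
# VO2 = H (T_R - T_B) with H = a2 / a1 and T_R = b1 + a1 b2 / a2, computed
# draw-wise from the paired posterior draws of the two regressions.
# Priors follow the study design: log-normal(0, 1) on the positive slopes
# a1, a2 and G; uniform on the intercepts and residual scales.

jags_seed_inits <- function(n_chains, seed) {
  lapply(seq_len(n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = child_seed(seed, paste0("jags-chain-", ch))))
}

run_jags <- function(model, data, params, n_chains = 4L, n_warmup = 1000L,
                     n_samples = 1000L, seed = 1L) {
  m <- rjags::jags.model(textConnection(model), data = data,
                         inits = jags_seed_inits(n_chains, seed),
                         n.chains = n_chains, n.adapt = 500, quiet = TRUE)
  stats::update(m, n_warmup, progress.bar = "none")
  s <- rjags::coda.samples(m, params, n.iter = n_samples,
                           progress.bar = "none")
  draws <- do.call(rbind, lapply(s, as.matrix))
  diag_df <- data.frame(param = colnames(draws),
                        rhat = NA_real_, ess = NA_real_)
  if (n_chains >= 2L) {
    gd <- try(coda::gelman.diag(s, autoburnin = FALSE,
                                multivariate = FALSE)$psrf[, 1], silent = TRUE)
    if (!inherits(gd, "try-error")) diag_df$rhat <- gd[diag_df$param]
  }
  es <- try(coda::effectiveSize(s), silent = TRUE)
  if (!inherits(es, "try-error")) diag_df$ess <- es[diag_df$param]
  list(draws = draws, diagnostics = diag_df)
}

new_linear_fit <- function(slope, intercept, resid_sd, sign_convention,
                           diagnostics, n) {
  structure(list(slope_draws = as.numeric(slope),
                 intercept_draws = as.numeric(intercept),
                 residual_sd_draws = as.numeric(resid_sd),
                 sign_convention = sign_convention,
                 diagnostics = diagnostics, n = n),
            class = "linear_fit_posterior")
}

#' @export
print.linear_fit_posterior <- function(x, ...) {
  hs <- hpdi(x$slope_draws)
  cat(sprintf("<linear_fit_posterior> (%s), n=%d\n", x$sign_convention, x$n))
  cat(sprintf("  slope mean %.4g, 89%% HPDI [%.4g, %.4g]; intercept mean %.4g\n",
              mean(x$slope_draws), hs[1], hs[2], mean(x$intercept_draws)))
  invisible(x)
}

check_table_rows <- function(rows, what) {
  if (length(unique(rows$ta)) < 3L)
    stop_tm(what, ": need rows spanning at least 3 distinct ambient temperatures")
  invisible(rows)
}

#' Bayesian fit of the minimal-T_B line
#'
#' `min_tb = a1 * T_A + b1 + Normal(0, sigma)`, with a log-normal(0,1)
#' prior on the slope `a1` (positive by construction: minimal T_B rises
#' with T_A), uniform priors on `b1` and `sigma`.
#'
#' @param rows minimal-metabolism rows for one state (columns `ta`,
#'   `min_tb`), spanning at least 3 distinct T_A values.
#' @param n_chains,n_warmup,n_samples,seed MCMC settings.
#' @return A `linear_fit_posterior` with `sign_convention = "+slope*TA"`.
#' @export
fit_tb_regression <- function(rows, n_chains = 4L, n_warmup = 1000L,
                              n_samples = 1000L, seed = 1L) {
  check_table_rows(rows, "fit_tb_regression")
  model <- "model {
    for (i in 1:N) { y[i] ~ dnorm(a * ta[i] + b, tau) }
    a ~ dlnorm(0, 1)
    b ~ dunif(-200, 200)
    tau <- pow(sigma, -2)
    sigma ~ dunif(0, 100)
  }"
  fit <- run_jags(model, list(y = rows$min_tb, ta = rows$ta, N = nrow(rows)),
                  c("a", "b", "sigma"), n_chains, n_warmup, n_samples, seed)
  new_linear_fit(fit$draws[, "a"], fit$draws[, "b"], fit$draws[, "sigma"],
                 "+slope*TA", fit$diagnostics, nrow(rows))
}

#' Bayesian fit of the minimal-VO2 line
#'
#' `min_vo2 = -a2 * T_A + b2 + Normal(0, sigma)`: minimal VO2 falls as T_A
#' rises, and `a2` is the positive magnitude of that slope, with a
#' log-normal(0,1) prior; uniform priors on `b2` and `sigma`.
#'
#' @inheritParams fit_tb_regression
#' @param rows rows with columns `ta`, `vo2_at_min`.
#' @return A `linear_fit_posterior` with `sign_convention = "-slope*TA"`.
#' @export
fit_vo2_regression <- function(rows, n_chains = 4L, n_warmup = 1000L,
                               n_samples = 1000L, seed = 1L) {
  check_table_rows(rows, "fit_vo2_regression")
  model <- "model {
    for (i in 1:N) { y[i] ~ dnorm(-a * ta[i] + b, tau) }
    a ~ dlnorm(0, 1)
    b ~ dunif(-200, 200)
    tau <- pow(sigma, -2)
    sigma ~ dunif(0, 100)
  }"
  fit <- run_jags(model, list(y = rows$vo2_at_min, ta = rows$ta, N = nrow(rows)),
                  c("a", "b", "sigma"), n_chains, n_warmup, n_samples, seed)
  new_linear_fit(fit$draws[, "a"], fit$draws[, "b"], fit$draws[, "sigma"],
                 "-slope*TA", fit$diagnostics, nrow(rows))
}

#' Bayesian no-intercept fit of the heat-conduction law
#'
#' `vo2 = G * (tb - ta) + Normal(0, sigma)`: in steady state all oxygen
#' consumption balances the conductive heat loss across the body-ambient
#' gradient, so the line is forced through the origin. Log-normal(0,1)
#' prior on G. Rows with a non-positive gradient are dropped with a
#' warning rather than sign-flipped.
#'
#' @param rows rows with columns `min_tb`, `ta`, `vo2_at_min` (or a data
#'   frame with `gradient` and `vo2` columns).
#' @inheritParams fit_tb_regression
#' @return A `conductance_posterior` with `g_draws`, `residual_sd_draws`.
#' @export
fit_conductance <- function(rows, n_chains = 4L, n_warmup = 1000L,
                            n_samples = 1000L, seed = 1L) {
  if (all(c("gradient", "vo2") %in% names(rows))) {
    grad <- rows$gradient; vo2 <- rows$vo2
  } else {
    grad <- rows$min_tb - rows$ta; vo2 <- rows$vo2_at_min
  }
  bad <- grad <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive body-ambient gradient dropped",
            call. = FALSE)
    grad <- grad[!bad]; vo2 <- vo2[!bad]
  }
  if (length(grad) < 3L) stop_tm("need at least 3 usable rows")
  model <- "model {
    for (i in 1:N) { y[i] ~ dnorm(G * x[i], tau) }
    G ~ dlnorm(0, 1)
    tau <- pow(sigma, -2)
    sigma ~ dunif(0, 100)
  }"
  fit <- run_jags(model, list(y = vo2, x = grad, N = length(grad)),
                  c("G", "sigma"), n_chains, n_warmup, n_samples, seed)
  structure(list(g_draws = as.numeric(fit$draws[, "G"]),
                 residual_sd_draws = as.numeric(fit$draws[, "sigma"]),
                 diagnostics = fit$diagnostics, n = length(grad)),
            class = "conductance_posterior")
}

#' @export
print.conductance_posterior <- function(x, ...) {
  h <- hpdi(x$g_draws)
  cat(sprintf("<conductance_posterior> G mean %.4g ml/g/hr/degC, 89%% HPDI [%.4g, %.4g], n=%d\n",
              mean(x$g_draws), h[1], h[2], x$n))
  invisible(x)
}

check_paired <- function(fit_tb, fit_vo2) {
  stopifnot(inherits(fit_tb, "linear_fit_posterior"),
            inherits(fit_vo2, "linear_fit_posterior"))
  if (length(fit_tb$slope_draws) != length(fit_vo2$slope_draws))
    stop_tm("draw-count mismatch between the two regression posteriors")
  invisible(NULL)
}

#' Feedback gain H from the paired regression posteriors
#'
#' Eliminating T_A between the two minimal-point lines yields the
#' thermogenesis line `VO2 = H (T_R - T_B)` with `H = a2 / a1`, evaluated
#' draw-wise on index-paired posterior draws.
#'
#' @param fit_tb,fit_vo2 `linear_fit_posterior`s for the same state.
#' @return Numeric vector of H draws (ml/g/hr/degC).
#' @export
derive_H <- function(fit_tb, fit_vo2) {
  check_paired(fit_tb, fit_vo2)
  fit_vo2$slope_draws / fit_tb$slope_draws
}

#' Set-point temperature T_R from the paired regression posteriors
#'
#' `T_R = b1 + a1 b2 / a2` (the T_B at which the derived thermogenesis
#' line reaches zero VO2), evaluated draw-wise.
#'
#' @inheritParams derive_H
#' @return Numeric vector of T_R draws (degC).
#' @export
derive_TR <- function(fit_tb, fit_vo2) {
  check_paired(fit_tb, fit_vo2)
  fit_tb$intercept_draws +
    fit_tb$slope_draws * fit_vo2$intercept_draws / fit_vo2$slope_draws
}

#' Derived thermoregulatory posterior
#'
#' Bundles the draw-wise H and T_R (and G/H when a conductance posterior
#' is supplied) with posterior-mean + 89% HPDI summaries.
#'
#' @inheritParams derive_H
#' @param g_post optional `conductance_posterior` for the same state.
#' @param mass HPDI credible mass.
#' @return A `thermo_derived` list with `h_draws`, `tr_draws`,
#'   `gh_ratio_draws` and a `summaries` data frame.
#' @export
thermo_derived <- function(fit_tb, fit_vo2, g_post = NULL, mass = 0.89) {
  h <- derive_H(fit_tb, fit_vo2)
  tr <- derive_TR(fit_tb, fit_vo2)
  gh <- NULL
  if (!is.null(g_post)) gh <- rep_len(g_post$g_draws, length(h)) / h
  summ <- function(nm, d) {
    hp <- hpdi(d, mass)
    data.frame(param = nm, mean = mean(d), hpdi_low = hp[1], hpdi_high = hp[2])
  }
  summaries <- rbind(summ("H", h), summ("T_R", tr),
                     if (!is.null(gh)) summ("G_over_H", gh))
  structure(list(h_draws = h, tr_draws = tr, gh_ratio_draws = gh,
                 summaries = summaries, mass = mass),
            class = "thermo_derived")
}

#' @export
print.thermo_derived <- function(x, ...) {
  cat("<thermo_derived>\n")
  print(x$summaries, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of the sorted draws containing the
#' requested posterior mass.
#'
#' @param draws numeric sample vector (>= 100 draws).
#' @param mass credible mass in (0,1); 0.89 by convention here.
#' @return `c(low, high)`.
#' @export
hpdi <- function(draws, mass = 0.89) {
  if (mass <= 0 || mass >= 1) stop_tm("mass must be in (0,1)")
  n <- length(draws)
  if (n < 100L) stop_tm("need at least 100 draws for an HPDI")
  x <- sort(draws)
  gap <- max(1L, min(n - 1L, round(n * mass)))
  i <- which.min(x[(gap + 1L):n] - x[seq_len(n - gap)])
  c(x[i], x[i + gap])
}

#' Q10 temperature coefficient of oxygen consumption
#'
#' `Q10 = (vo2_normal / vo2_torpid)^(10 / (tb_normal - tb_torpid))`,
#' computed in the log domain. Values clearly above ~2-3 indicate active
#' metabolic suppression beyond the passive thermodynamic effect.
#'
#' @param vo2_normal,vo2_torpid positive oxygen consumption rates
#'   (ml/g/hr) in the two states.
#' @param tb_normal,tb_torpid body temperatures (degC) in the two states;
#'   must differ.
#' @param ta optional ambient temperature label carried into the result.
#' @return A `q10_result` list with `q10` and the inputs.
#' @export
q10 <- function(vo2_normal, vo2_torpid, tb_normal, tb_torpid, ta = NA_real_) {
  if (any(c(vo2_normal, vo2_torpid) <= 0)) stop_tm("rates must be positive")
  if (tb_normal == tb_torpid) stop_tm("Q10 undefined for equal temperatures")
  val <- exp(10 / (tb_normal - tb_torpid) * (log(vo2_normal) - log(vo2_torpid)))
  structure(list(ta = ta, q10 = val,
                 inputs = c(vo2_normal = vo2_normal, vo2_torpid = vo2_torpid,
                            tb_normal = tb_normal, tb_torpid = tb_torpid)),
            class = "q10_result")
}

#' @export
print.q10_result <- function(x, ...) {
  cat(sprintf("<q10_result> Q10 = %.3f%s\n", x$q10,
              if (is.na(x$ta)) "" else sprintf(" at T_A = %g degC", x$ta)))
  invisible(x)
}

#' Oxygen volume to energy conversion
#'
#' 5.3 cal of energy per ml O2 consumed; 1 cal = 4.184 J.
#'
#' @param ml_o2 non-negative oxygen volume (ml).
#' @return `list(cal, J)`.
#' @export
o2_to_energy <- function(ml_o2) {
  if (any(ml_o2 < 0)) stop_tm("oxygen volume must be non-negative")
  cal <- 5.3 * ml_o2
  list(cal = cal, J = 4.184 * cal)
}

#' Posterior predictive check at a probe ambient temperature
#'
#' For each posterior draw of a fitted line, the sampling distribution of
#' the mean of `n_new` new observations at `ta_probe` (linear predictor
#' plus residual noise averaged over `n_new`). Reports the 89% HPDI of
#' that distribution and whether the observed mean falls above it -- the
#' signature of extra thermogenesis kicking in below the fitted range.
#'
#' @param fit a `linear_fit_posterior`.
#' @param ta_probe probe ambient temperature (degC; typically 8).
#' @param n_new number of new animals averaged (>= 1).
#' @param observed_mean observed mean at the probe temperature.
#' @param mass HPDI credible mass.
#' @param seed seed for the predictive noise.
#' @return A list: `hpdi`, `exceeds_upper`, `below_lower`, `draws`,
#'   `observed_mean`.
#' @export
predictive_check_low_ta <- function(fit, ta_probe, n_new, observed_mean,
                                    mass = 0.89, seed = 1L) {
  stopifnot(inherits(fit, "linear_fit_posterior"))
  if (n_new < 1) stop_tm("n_new must be at least 1")
  pred <- if (fit$sign_convention == "+slope*TA") {
    fit$slope_draws * ta_probe + fit$intercept_draws
  } else {
    -fit$slope_draws * ta_probe + fit$intercept_draws
  }
  set.seed(child_seed(seed, "predictive-check"))
  draws <- pred + stats::rnorm(length(pred), 0,
                               fit$residual_sd_draws / sqrt(n_new))
  hp <- hpdi(draws, mass)
  list(hpdi = hp, exceeds_upper = observed_mean > hp[2],
       below_lower = observed_mean < hp[1], draws = draws,
       observed_mean = observed_mean)
}

#' Summarize the normal-to-torpid shift of the thermoregulatory system
#'
#' Percent changes of the posterior-mean G, H and T_R between states
#' (ratios of posterior means), the G/H ratio per state, and -- because
#' the two conventions can diverge for skewed posteriors -- the mean of
#' draw-wise ratios alongside each ratio of means.
#'
#' @param normal,torpid lists with elements `g_draws` (optional),
#'   `h_draws`, `tr_draws` for each state.
#' @return A `state_shift` list.
#' @export
summarize_state_shift <- function(normal, torpid) {
  pct_drop <- function(a, b) 100 * (1 - b / a)
  out <- list(
    h_mean = c(normal = mean(normal$h_draws), torpid = mean(torpid$h_draws)),
    h_reduction_pct = pct_drop(mean(normal$h_draws), mean(torpid$h_draws)),
    tr_mean = c(normal = mean(normal$tr_draws), torpid = mean(torpid$tr_draws)),
    tr_drop_means = mean(normal$tr_draws) - mean(torpid$tr_draws),
    tr_drop_mean_of_diffs = mean(rep_len(normal$tr_draws, max(length(normal$tr_draws), length(torpid$tr_draws))) -
                                 rep_len(torpid$tr_draws, max(length(normal$tr_draws), length(torpid$tr_draws)))),
    h_drop_means = mean(normal$h_draws) - mean(torpid$h_draws))
  if (!is.null(normal$g_draws) && !is.null(torpid$g_draws)) {
    gn <- mean(normal$g_draws); gt <- mean(torpid$g_draws)
    out$g_mean <- c(normal = gn, torpid = gt)
    out$g_reduction_pct <- pct_drop(gn, gt)
    out$gh_ratio <- c(normal = gn / mean(normal$h_draws),
                      torpid = gt / mean(torpid$h_draws))
    out$gh_ratio_mean_of_draws <- c(
      normal = mean(rep_len(normal$g_draws, length(normal$h_draws)) / normal$h_draws),
      torpid = mean(rep_len(torpid$g_draws, length(torpid$h_draws)) / torpid$h_draws))
  }
  structure(out, class = "state_shift")
}

#' @export
print.state_shift <- function(x, ...) {
  cat("<state_shift>\n")
  if (!is.null(x$g_reduction_pct))
    cat(sprintf("  G: %.3f -> %.3f (heat-loss reduction %.0f%%)\n",
                x$g_mean[1], x$g_mean[2], x$g_reduction_pct))
  cat(sprintf("  H: %.3f -> %.3f ml/g/hr/degC (%.1f%% reduction)\n",
              x$h_mean[1], x$h_mean[2], x$h_reduction_pct))
  cat(sprintf("  T_R: %.2f -> %.2f degC (drop %.2f degC)\n",
              x$tr_mean[1], x$tr_mean[2], x$tr_drop_means))
  if (!is.null(x$gh_ratio))
    cat(sprintf("  G/H: %.3f -> %.3f\n", x$gh_ratio[1], x$gh_ratio[2]))
  invisible(x)
}
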