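# End-to-end orchestration: simulate -> fit baselines -> detect ->
# minimal table -> thermoregulatory fits -> report.

#' Pipeline configuration
#'
#' Nested defaults for a full synthetic run; any subset can be overridden
#' via arguments or a YAML file ([read_pipeline_config()]).
#'
#' @param seed master seed; every stage derives child seeds from it.
#' @param synthetic list of overrides passed to [synthetic_config()].
#' @param trend list: `n_chains`, `n_warmup`, `n_samples` for baseline fits.
#' @param detection list: `level` (credible mass), `mode` (see
#'   [detection_rule()]).
#' @param thermo list: `ta_fit` (ambient temperatures used for parameter
#'   estimation; the coldest probe temperature is excluded and used for the
#'   predictive check), `ta_probe`, `n_chains`, `n_warmup`, `n_samples`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            synthetic = list(),
                            trend = list(n_chains = 2L, n_warmup = 400L,
                                         n_samples = 600L),
                            detection = list(level = 0.999, mode = "joint"),
                            thermo = list(ta_fit = c(12, 16, 20, 24),
                                          ta_probe = 8, n_chains = 4L,
                                          n_warmup = 1000L, n_samples = 1000L)) {
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 trend = trend, detection = detection, thermo = thermo),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_tm("no such config file: ", path)
  y <- yaml::read_yaml(path)
  base <- pipeline_config()
  for (nm in intersect(names(y), names(base))) {
    if (is.list(base[[nm]]) && is.list(y[[nm]])) {
      base[[nm]][names(y[[nm]])] <- y[[nm]]
    } else {
      base[[nm]] <- y[[nm]]
    }
  }
  base$seed <- as.integer(base$seed)
  base
}

# Tiny stable config fingerprint (djb2 over the deparsed config).
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 5381
  for (cc in utf8ToInt(s)) h <- (h * 33 + cc) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full torpor-analysis pipeline on a simulated cohort
#'
#' Simulates a fasting-induced torpor cohort, fits each animal's day-1
#' baseline for both variables, applies the detection rule to days 2-3,
#' builds the minimal-metabolism table, fits the thermoregulatory
#' parameters per state, and assembles a report with baseline coverage,
#' torpor statistics, induction rates, fitted and derived parameter
#' summaries, Q10 per ambient temperature, and the low-T_A predictive
#' check.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, recordings, masks, the
#'   minimal table, the report JSON and the run manifest are written there.
#' @return A `torpor_report` list (see the methods vignette for the
#'   structure).
#' @export
run_torpor_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  syn_args <- config$synthetic
  syn_args$seed <- child_seed(config$seed, "simulate")
  syn <- do.call(synthetic_config, syn_args)
  cohort <- simulate_cohort(syn)
  tr <- config$trend
  level <- config$detection$level

  animals <- names(cohort$recordings)
  baselines <- list(); bands <- list(); masks <- list()
  stats_by_animal <- list(); coverage_by_animal <- list()
  max_rhat <- 0; convergence_ok <- TRUE
  for (id in animals) {
    ser <- cohort$recordings[[id]]
    day1 <- subset_days(ser, 1L)
    fits <- list()
    for (v in c("tb", "vo2")) {
      cfg <- trend_fit_config(n_chains = tr$n_chains, n_warmup = tr$n_warmup,
                              n_samples = tr$n_samples,
                              seed = child_seed(config$seed, paste0("fit-", id, "-", v)))
      fits[[v]] <- fit_baseline(day1, v, cfg)
      rh <- max(fits[[v]]$diagnostics$rhat, na.rm = TRUE)
      max_rhat <- max(max_rhat, rh)
      if (rh > 1.05) convergence_ok <- FALSE
    }
    baselines[[id]] <- fits
    bands[[id]] <- list(tb = predictive_band(fits$tb, level),
                        vo2 = predictive_band(fits$vo2, level))
    masks[[id]] <- detect_torpor(ser, bands[[id]]$tb, bands[[id]]$vo2,
                                 detection_rule(config$detection$mode, level))
    eps <- torpor_episodes(masks[[id]], ser)
    stats_by_animal[[id]] <- torpor_stats(eps)
    # baseline quality: held-out coverage outside detected torpor
    keep <- !masks[[id]]$flags & ser$day_index > 1L
    cov_v <- vapply(c("tb", "vo2"), function(v) {
      y <- ser[[v]]; k <- ((seq_along(y) - 1L) %% ser$K) + 1L
      b <- bands[[id]][[v]]
      ok <- keep & !is.na(y)
      mean(y[ok] >= b$lower[k[ok]] & y[ok] <= b$upper[k[ok]])
    }, 0)
    coverage_by_animal[[id]] <- cov_v
  }

  ta_of <- vapply(animals, function(id) cohort$truth[[id]]$ta, 0)
  entered <- vapply(animals, function(id) stats_by_animal[[id]]$entered_torpor, NA)
  induction <- vapply(sort(unique(ta_of)), function(ta) {
    mean(entered[ta_of == ta]) * 100
  }, 0)
  names(induction) <- paste0("ta_", sort(unique(ta_of)))

  minimal <- build_minimal_table(cohort$recordings, masks)

  th <- config$thermo
  fit_state <- function(state) {
    rows <- minimal[minimal$state == state & minimal$ta %in% th$ta_fit, ]
    if (nrow(rows) < 3L || length(unique(rows$ta)) < 3L) return(NULL)
    sd_st <- child_seed(config$seed, paste0("thermo-", state))
    ftb <- fit_tb_regression(rows, th$n_chains, th$n_warmup, th$n_samples, sd_st)
    fvo <- fit_vo2_regression(rows, th$n_chains, th$n_warmup, th$n_samples,
                              child_seed(config$seed, paste0("thermo-vo2-", state)))
    gp <- fit_conductance(rows, th$n_chains, th$n_warmup, th$n_samples,
                          child_seed(config$seed, paste0("thermo-g-", state)))
    list(fit_tb = ftb, fit_vo2 = fvo, g = gp,
         derived = thermo_derived(ftb, fvo, gp))
  }
  normal_fit <- fit_state("normal")
  torpid_fit <- fit_state("torpid")
  notices <- character(0)
  if (is.null(torpid_fit))
    notices <- c(notices, "torpid-state fit skipped: too few torpid minimal points")
  if (!convergence_ok)
    notices <- c(notices, "MCMC convergence warning: max split R-hat above 1.05")

  shift <- NULL
  if (!is.null(normal_fit) && !is.null(torpid_fit)) {
    shift <- summarize_state_shift(
      list(g_draws = normal_fit$g$g_draws, h_draws = normal_fit$derived$h_draws,
           tr_draws = normal_fit$derived$tr_draws),
      list(g_draws = torpid_fit$g$g_draws, h_draws = torpid_fit$derived$h_draws,
           tr_draws = torpid_fit$derived$tr_draws))
  }

  # Q10 per ambient temperature from group-mean minimal points
  q10_by_ta <- list()
  for (ta in sort(unique(minimal$ta))) {
    nr <- minimal[minimal$state == "normal" & minimal$ta == ta, ]
    tr_rows <- minimal[minimal$state == "torpid" & minimal$ta == ta, ]
    if (nrow(nr) && nrow(tr_rows) &&
        mean(nr$vo2_at_min) > 0 && mean(tr_rows$vo2_at_min) > 0 &&
        mean(nr$min_tb) != mean(tr_rows$min_tb)) {
      q10_by_ta[[paste0("ta_", ta)]] <-
        q10(mean(nr$vo2_at_min), mean(tr_rows$vo2_at_min),
            mean(nr$min_tb), mean(tr_rows$min_tb), ta = ta)$q10
    }
  }

  # predictive check at the probe temperature (extra-thermogenesis flag)
  pred_check <- NULL
  probe_rows <- minimal[minimal$state == "torpid" & minimal$ta == th$ta_probe, ]
  if (!is.null(torpid_fit) && nrow(probe_rows) >= 2L) {
    pc_tb <- predictive_check_low_ta(torpid_fit$fit_tb, th$ta_probe,
                                     nrow(probe_rows), mean(probe_rows$min_tb),
                                     seed = child_seed(config$seed, "pc-tb"))
    pc_vo2 <- predictive_check_low_ta(torpid_fit$fit_vo2, th$ta_probe,
                                      nrow(probe_rows), mean(probe_rows$vo2_at_min),
                                      seed = child_seed(config$seed, "pc-vo2"))
    pred_check <- list(ta_probe = th$ta_probe, n = nrow(probe_rows),
                       tb = pc_tb[c("hpdi", "observed_mean", "exceeds_upper")],
                       vo2 = pc_vo2[c("hpdi", "observed_mean", "exceeds_upper")])
  }

  report <- structure(list(
    seed = config$seed, config_hash = config_hash(config),
    n_animals = length(animals),
    coverage = coverage_by_animal,
    coverage_pooled = colMeans(do.call(rbind, coverage_by_animal)),
    torpor_stats = lapply(stats_by_animal, unclass),
    induction_rate_pct = induction,
    minimal_table = minimal,
    fits = list(normal = normal_fit, torpid = torpid_fit),
    state_shift = if (!is.null(shift)) unclass(shift),
    q10 = q10_by_ta,
    predictive_check = pred_check,
    max_rhat = max_rhat, convergence_ok = convergence_ok,
    notices = notices), class = "torpor_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (id in animals) {
      f <- file.path(out_dir, paste0("recording_", id, ".csv"))
      write_recording(cohort$recordings[[id]], f)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "masks.csv")
    utils::write.csv(do.call(rbind, lapply(animals, function(id)
      data.frame(animal_id = id, time_min = cohort$recordings[[id]]$t,
                 flag = masks[[id]]$flags))), f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "minimal_table.csv")
    utils::write.csv(minimal, f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_json(report), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, f)
    manifest <- list(seed = config$seed, config_hash = report$config_hash,
                     package_version = as.character(utils::packageVersion("torpormeter")),
                     files = files, max_rhat = max_rhat,
                     convergence_ok = convergence_ok)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    attr(report, "manifest") <- manifest
  }
  report
}

# JSON-friendly projection of a report (draws dropped, summaries kept).
report_json <- function(report) {
  fits <- lapply(report$fits, function(f) {
    if (is.null(f)) return(NULL)
    list(a_mean = mean(f$fit_tb$slope_draws),
         a_hpdi = hpdi(f$fit_tb$slope_draws),
         b_mean = mean(f$fit_tb$intercept_draws),
         a2_mean = mean(f$fit_vo2$slope_draws),
         a2_hpdi = hpdi(f$fit_vo2$slope_draws),
         b2_mean = mean(f$fit_vo2$intercept_draws),
         G_mean = mean(f$g$g_draws), G_hpdi = hpdi(f$g$g_draws),
         derived = f$derived$summaries)
  })
  list(seed = report$seed, config_hash = report$config_hash,
       n_animals = report$n_animals,
       coverage_pooled = as.list(report$coverage_pooled),
       induction_rate_pct = as.list(report$induction_rate_pct),
       q10 = report$q10, fits = fits, state_shift = report$state_shift,
       predictive_check = report$predictive_check,
       max_rhat = report$max_rhat, convergence_ok = report$convergence_ok,
       notices = report$notices)
}

#' Render a pipeline report as human-readable text
#'
#' @param report a `torpor_report` from [run_torpor_pipeline()].
#' @return Invisibly, the character vector of rendered lines (also printed).
#' @export
report_render <- function(report) {
  stopifnot(inherits(report, "torpor_report"))
  ln <- c(sprintf("torpormeter report (seed %d, config %s)",
                  report$seed, report$config_hash),
          sprintf("animals: %d; pooled held-out coverage: tb %.3f, vo2 %.3f",
                  report$n_animals, report$coverage_pooled[["tb"]],
                  report$coverage_pooled[["vo2"]]),
          "induction rate (%):",
          paste0("  ", names(report$induction_rate_pct), ": ",
                 signif(report$induction_rate_pct, 3)))
  if (length(report$q10))
    ln <- c(ln, "Q10 by ambient temperature:",
            paste0("  ", names(report$q10), ": ",
                   signif(unlist(report$q10), 4)))
  for (state in names(report$fits)) {
    f <- report$fits[[state]]
    if (is.null(f)) next
    ln <- c(ln, sprintf("%s state:", state),
            sprintf("  a1 %.4g  b1 %.4g  a2 %.4g  b2 %.4g  G %.4g",
                    mean(f$fit_tb$slope_draws), mean(f$fit_tb$intercept_draws),
                    mean(f$fit_vo2$slope_draws), mean(f$fit_vo2$intercept_draws),
                    mean(f$g$g_draws)),
            sprintf("  H %.4g [%.4g, %.4g]  T_R %.4g [%.4g, %.4g] (89%% HPDI)",
                    f$derived$summaries$mean[1], f$derived$summaries$hpdi_low[1],
                    f$derived$summaries$hpdi_high[1],
                    f$derived$summaries$mean[2], f$derived$summaries$hpdi_low[2],
                    f$derived$summaries$hpdi_high[2]))
  }
  if (!is.null(report$state_shift)) {
    ss <- report$state_shift
    ln <- c(ln, sprintf("state shift: G reduction %.0f%%; H reduction %.1f%%; T_R drop %.2f degC; G/H %.3f -> %.3f",
                        ss$g_reduction_pct %||% NA, ss$h_reduction_pct,
                        ss$tr_drop_means, ss$gh_ratio[1] %||% NA,
                        ss$gh_ratio[2] %||% NA))
  }
  if (!is.null(report$predictive_check)) {
    pc <- report$predictive_check
    ln <- c(ln, sprintf("predictive check at T_A = %g: observed tb mean %.2f vs HPDI [%.2f, %.2f]%s",
                        pc$ta_probe, pc$tb$observed_mean, pc$tb$hpdi[1],
                        pc$tb$hpdi[2],
                        if (isTRUE(pc$tb$exceeds_upper)) " (exceeds: extra thermogenesis)" else ""))
  }
  if (length(report$notices)) ln <- c(ln, paste("note:", report$notices))
  cat(ln, sep = "\n")
  invisible(ln)
}

#' @export
print.torpor_report <- function(x, ...) { report_render(x); invisible(x) }
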