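# Torpor detection: joint lower outliers from the predictive bands,
# episode extraction and summary statistics, minimal metabolic points.

#' Detection rule for daily torpor
#'
#' @param mode `"joint"` (both T_B and VO2 below their lower band edge;
#'   the package's primary definition), `"tb_only"`, `"vo2_only"`, or
#'   `"fixed_threshold"` (a conventional fixed T_B cut-off).
#' @param level credible mass of the predictive band used by the
#'   band-based modes.
#' @param threshold_tb fixed T_B threshold in degC; required iff
#'   `mode = "fixed_threshold"` (conventional choices: 31 or 34).
#' @return A `detection_rule` list.
#' @export
detection_rule <- function(mode = c("joint", "tb_only", "vo2_only", "fixed_threshold"),
                           level = 0.999, threshold_tb = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_threshold" && is.null(threshold_tb))
    stop_tm("fixed_threshold mode requires threshold_tb")
  if (mode != "fixed_threshold" && !is.null(threshold_tb))
    stop_tm("threshold_tb is only meaningful in fixed_threshold mode")
  if (level <= 0 || level >= 1) stop_tm("level must be in (0,1)")
  structure(list(mode = mode, level = level, threshold_tb = threshold_tb),
            class = "detection_rule")
}

#' Flag torpor time points
#'
#' Strict lower-outlier test on the evaluated days: in `"joint"` mode a
#' point is torpor iff its T_B is strictly below the lower edge of the T_B
#' band AND its VO2 strictly below the lower edge of the VO2 band.
#' Points with a missing value in any required variable are never flagged.
#'
#' @param series a [metabolic_ts()].
#' @param band_tb,band_vo2 [predictive_band()]s from the same animal's
#'   baseline-day fit (not needed in `fixed_threshold` mode).
#' @param rule a [detection_rule()].
#' @param evaluated_days day indices to evaluate (default: all days after
#'   day 1, the baseline training day).
#' @return A `torpor_mask`: logical `flags` per point plus the rule and the
#'   evaluated day range.
#' @export
detect_torpor <- function(series, band_tb = NULL, band_vo2 = NULL,
                          rule = detection_rule(),
                          evaluated_days = NULL) {
  stopifnot(inherits(series, "metabolic_ts"), inherits(rule, "detection_rule"))
  if (is.null(evaluated_days)) evaluated_days <- setdiff(unique(series$day_index), 1L)
  if (!length(evaluated_days)) stop_tm("no days to evaluate")
  n <- length(series$t)
  k_idx <- ((seq_len(n) - 1L) %% series$K) + 1L
  chk_band <- function(band) {
    if (is.null(band)) stop_tm("rule '", rule$mode, "' needs the corresponding band")
    if (band$K != series$K) stop_tm("band/series grid mismatch")
    if (abs(band$level - rule$level) > 1e-12)
      stop_tm("band level ", band$level, " does not match rule level ", rule$level)
    band
  }
  below_tb <- function() {
    b <- chk_band(band_tb); !is.na(series$tb) & series$tb < b$lower[k_idx]
  }
  below_vo2 <- function() {
    b <- chk_band(band_vo2); !is.na(series$vo2) & series$vo2 < b$lower[k_idx]
  }
  flags <- switch(rule$mode,
    joint = below_tb() & below_vo2(),
    tb_only = below_tb(),
    vo2_only = below_vo2(),
    fixed_threshold = !is.na(series$tb) & series$tb < rule$threshold_tb)
  flags[!(series$day_index %in% evaluated_days)] <- FALSE
  structure(list(flags = flags, rule = rule, evaluated_days = evaluated_days,
                 animal_id = series$animal_id),
            class = "torpor_mask")
}

#' Extract torpor episodes from a mask
#'
#' Maximal runs of consecutive flagged points; no gap merging and no
#' minimum duration by default (a single-bin interruption therefore splits
#' an episode). Per-episode depth statistics are read from the series.
#'
#' @param mask a `torpor_mask` (from [detect_torpor()]).
#' @param series the matching [metabolic_ts()].
#' @return A data frame with one row per episode: `start`, `end` (time
#'   stamps of the first/last flagged bin), `duration` (minutes,
#'   `end - start + bin_width`), `min_tb`, `vo2_at_min_tb`.
#' @export
torpor_episodes <- function(mask, series) {
  stopifnot(inherits(mask, "torpor_mask"), inherits(series, "metabolic_ts"))
  if (length(mask$flags) != length(series$t)) stop_tm("mask/series length mismatch")
  r <- rle(mask$flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- data.frame(start = numeric(0), end = numeric(0), duration = numeric(0),
                    min_tb = numeric(0), vo2_at_min_tb = numeric(0))
  for (j in runs) {
    idx <- starts[j]:ends[j]
    tb <- series$tb[idx]
    imin <- idx[which.min(tb)]  # first occurrence on ties
    out <- rbind(out, data.frame(
      start = series$t[starts[j]], end = series$t[ends[j]],
      duration = series$t[ends[j]] - series$t[starts[j]] + series$bin_width,
      min_tb = series$tb[imin], vo2_at_min_tb = series$vo2[imin]))
  }
  out
}

#' Per-animal torpor summary statistics
#'
#' @param episodes episode data frame from [torpor_episodes()].
#' @return A `torpor_stats` list: `total_torpor_min`, `n_episodes`,
#'   `mean_episode_min`, `entered_torpor`, `min_tb_overall`,
#'   `vo2_at_min_tb`.
#' @export
torpor_stats <- function(episodes) {
  n <- nrow(episodes)
  if (n == 0L) {
    return(structure(list(total_torpor_min = 0, n_episodes = 0L,
                          mean_episode_min = NA_real_, entered_torpor = FALSE,
                          min_tb_overall = NA_real_, vo2_at_min_tb = NA_real_),
                     class = "torpor_stats"))
  }
  imin <- which.min(episodes$min_tb)
  structure(list(total_torpor_min = sum(episodes$duration), n_episodes = n,
                 mean_episode_min = mean(episodes$duration),
                 entered_torpor = TRUE,
                 min_tb_overall = episodes$min_tb[imin],
                 vo2_at_min_tb = episodes$vo2_at_min_tb[imin]),
            class = "torpor_stats")
}

#' @export
print.torpor_stats <- function(x, ...) {
  cat(sprintf("<torpor_stats> %d episode(s), total %g min, min T_B %.2f degC\n",
              x$n_episodes, x$total_torpor_min,
              if (is.na(x$min_tb_overall)) NA else x$min_tb_overall))
  invisible(x)
}

#' Minimal metabolic point of a window
#'
#' The time point minimizing T_B within a window of interest (first
#' occurrence on ties), with VO2 read at that same time. With a mask the
#' search is restricted to flagged (torpid) points.
#'
#' @param series a [metabolic_ts()].
#' @param window numeric `c(from, to)` in experiment-clock minutes
#'   (half-open, `from <= t < to`), or `NULL` for the whole series.
#' @param mask optional `torpor_mask` restricting eligible points.
#' @return `list(time, min_tb, vo2_at_min_tb)`.
#' @export
minimal_metabolic_point <- function(series, window = NULL, mask = NULL) {
  stopifnot(inherits(series, "metabolic_ts"))
  elig <- !is.na(series$tb)
  if (!is.null(window)) elig <- elig & series$t >= window[1] & series$t < window[2]
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "torpor_mask"))
    elig <- elig & mask$flags
  }
  if (!any(elig)) stop_tm("no eligible points in the requested window")
  idx <- which(elig)
  imin <- idx[which.min(series$tb[idx])]
  list(time = series$t[imin], min_tb = series$tb[imin],
       vo2_at_min_tb = series$vo2[imin])
}

#' Dark-phase window of one day
#'
#' Convenience accessor: the experiment-clock minute range of the
#' lights-off phase of a given day, for use as the "normal status" minimal
#' metabolic window.
#'
#' @param series a [metabolic_ts()].
#' @param day day index.
#' @return `c(from, to)` in minutes.
#' @export
dark_phase_window <- function(series, day = 1L) {
  sel <- series$day_index == day & !series$lights_on
  if (!any(sel)) stop_tm("no dark-phase points on day ", day)
  c(min(series$t[sel]), max(series$t[sel]) + series$bin_width)
}

#' Build the minimal-metabolism table from a detected cohort
#'
#' One "normal" row per animal (minimal metabolic point of the dark phase
#' of the baseline day) and, for animals that entered torpor, one "torpid"
#' row (minimal metabolic point over the detected torpor mask).
#'
#' @param recordings list of [metabolic_ts()].
#' @param masks list of `torpor_mask` aligned with `recordings`.
#' @param baseline_day baseline day index (default 1).
#' @return A minimal-metabolism data frame (`animal_id`, `ta`, `state`,
#'   `min_tb`, `vo2_at_min`).
#' @export
build_minimal_table <- function(recordings, masks, baseline_day = 1L) {
  stopifnot(length(recordings) == length(masks))
  rows <- list()
  for (i in seq_along(recordings)) {
    ser <- recordings[[i]]
    ta <- mean(ser$ta)
    mp <- minimal_metabolic_point(ser, dark_phase_window(ser, baseline_day))
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = ser$animal_id, ta = ta, state = "normal",
      min_tb = mp$min_tb, vo2_at_min = mp$vo2_at_min_tb,
      stringsAsFactors = FALSE)
    if (any(masks[[i]]$flags)) {
      mpt <- minimal_metabolic_point(ser, mask = masks[[i]])
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = ser$animal_id, ta = ta, state = "torpid",
        min_tb = mpt$min_tb, vo2_at_min = mpt$vo2_at_min_tb,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare torpor definitions on one recording
#'
#' Evaluates the fixed 31 degC and 34 degC thresholds, the T_B-only band
#' rule and the joint band rule on the same recording and tabulates the
#' summary statistics of each.
#'
#' @param series a [metabolic_ts()].
#' @param band_tb,band_vo2 [predictive_band()]s from the baseline-day fit.
#' @param level credible mass of the bands.
#' @return A data frame with one row per definition.
#' @export
compare_definitions <- function(series, band_tb, band_vo2, level = 0.999) {
  defs <- list(
    fixed_31 = detection_rule("fixed_threshold", threshold_tb = 31),
    fixed_34 = detection_rule("fixed_threshold", threshold_tb = 34),
    tb_only = detection_rule("tb_only", level = level),
    joint = detection_rule("joint", level = level))
  out <- lapply(names(defs), function(nm) {
    m <- detect_torpor(series, band_tb, band_vo2, defs[[nm]])
    st <- torpor_stats(torpor_episodes(m, series))
    data.frame(definition = nm, total_torpor_min = st$total_torpor_min,
               n_episodes = st$n_episodes,
               mean_episode_min = st$mean_episode_min,
               entered_torpor = st$entered_torpor,
               min_tb_overall = st$min_tb_overall,
               vo2_at_min_tb = st$vo2_at_min_tb, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
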