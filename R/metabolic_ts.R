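# Core data container for one animal's multi-day metabolic recording,
# plus CSV I/O and re-binning.

#' Construct a metabolic time series
#'
#' A regular-grid, zeitgeber-time-aligned multi-day recording of core body
#' temperature and oxygen consumption for one animal. Time stamp 0 is ZT0
#' (lights-on) of day 1; the day convention is that a day starts at ZT0.
#' Missing observations are carried as `NA` and are dropped from all
#' likelihoods downstream; they are never imputed.
#'
#' @param animal_id opaque label for the animal.
#' @param t time stamps in minutes from experiment start; must form a
#'   strictly increasing regular grid starting at 0.
#' @param tb core body temperature (degC); `NA` = missing.
#' @param vo2 mass-specific oxygen consumption (ml O2/g/hr), non-negative
#'   where present; `NA` = missing.
#' @param ta ambient temperature (degC); scalar or per-point vector.
#' @param lights_on logical per point; defaults to ZT 0-12 on.
#' @param food_available logical per point; defaults to all `TRUE`.
#' @param bin_width sampling interval in minutes; must divide 1440.
#' @return An object of class `metabolic_ts`: a list with the fields above
#'   plus `zt` (zeitgeber time, hours in `[0, 24)`), `day_index` (1-based),
#'   `K` (points per day) and `D` (number of full days).
#' @export
metabolic_ts <- function(animal_id, t, tb, vo2, ta,
                         lights_on = NULL, food_available = NULL,
                         bin_width = NULL) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) stop_tm("need at least two time points")
  dt <- diff(t)
  if (any(dt <= 0)) stop_tm("time grid must be strictly increasing (duplicate or non-monotone time stamps)")
  if (max(abs(dt - dt[1])) > 1e-8) stop_tm("time grid must be regular; re-bin explicitly with bin_series()")
  bw <- bin_width %||% dt[1]
  if (abs(bw - dt[1]) > 1e-8) stop_tm("declared bin_width disagrees with the time grid")
  if (abs(1440 / bw - round(1440 / bw)) > 1e-8) stop_tm("bin_width must divide 1440 minutes")
  K <- as.integer(round(1440 / bw))
  if (n %% K != 0L) stop_tm("recording must contain whole days (length a multiple of K = ", K, ")")
  D <- n %/% K

  ta <- as.numeric(ta)
  if (length(ta) == 1L) ta <- rep(ta, n)
  zt <- (t / 60) %% 24
  day_index <- as.integer(t %/% 1440) + 1L
  if (is.null(lights_on)) lights_on <- zt < 12
  if (is.null(food_available)) food_available <- rep(TRUE, n)

  tb <- as.numeric(tb); vo2 <- as.numeric(vo2)
  stopifnot(length(tb) == n, length(vo2) == n, length(ta) == n,
            length(lights_on) == n, length(food_available) == n)
  if (any(!is.finite(tb) & !is.na(tb))) stop_tm("tb must be finite where present")
  if (any(vo2 < 0, na.rm = TRUE)) stop_tm("vo2 must be non-negative where present")

  structure(list(animal_id = as.character(animal_id), t = t, zt = zt,
                 day_index = day_index, tb = tb, vo2 = vo2, ta = ta,
                 lights_on = as.logical(lights_on),
                 food_available = as.logical(food_available),
                 bin_width = bw, K = K, D = D),
            class = "metabolic_ts")
}

#' @export
print.metabolic_ts <- function(x, ...) {
  cat(sprintf("<metabolic_ts> animal %s: %d days x %d bins (%g min), T_A %.1f degC\n",
              x$animal_id, x$D, x$K, x$bin_width, mean(x$ta)))
  cat(sprintf("  tb: %d/%d observed, range %.2f-%.2f; vo2: %d/%d observed, range %.3f-%.3f\n",
              sum(!is.na(x$tb)), length(x$tb),
              suppressWarnings(min(x$tb, na.rm = TRUE)),
              suppressWarnings(max(x$tb, na.rm = TRUE)),
              sum(!is.na(x$vo2)), length(x$vo2),
              suppressWarnings(min(x$vo2, na.rm = TRUE)),
              suppressWarnings(max(x$vo2, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.data.frame.metabolic_ts <- function(x, ...) {
  data.frame(time_min = x$t, zt = x$zt, day_index = x$day_index,
              tb_c = x$tb, vo2_mlghr = x$vo2, ta_c = x$ta,
              lights_on = x$lights_on, food_available = x$food_available)
}

#' Experiment protocol for a fasting-induced torpor recording
#'
#' @param ta_target ambient temperature set point (degC).
#' @param fasting_day day on which food is removed at ZT0 for 24 h.
#' @param baseline_day day used for baseline fitting.
#' @return An `experiment_protocol` list.
#' @export
experiment_protocol <- function(ta_target, fasting_day = 2L, baseline_day = 1L) {
  if (fasting_day <= baseline_day)
    stop_tm("fasting_day must come after baseline_day")
  structure(list(ta_target = ta_target, fasting_day = as.integer(fasting_day),
                 baseline_day = as.integer(baseline_day)),
            class = "experiment_protocol")
}

# default CSV schema: package column name -> file column name
default_schema <- function() {
  c(time = "time_min", tb = "tb_c", vo2 = "vo2_mlghr", ta = "ta_c",
    lights_on = "lights_on", food_available = "food_available")
}

#' Read a recording CSV
#'
#' Expected columns (renameable through `schema`): `time_min`, `tb_c`,
#' `vo2_mlghr`, `ta_c` and optionally `lights_on`, `food_available`.
#' Empty cells or `"."` denote missing values.
#'
#' @param path CSV file path.
#' @param animal_id label; defaults to the file base name.
#' @param schema named character vector mapping the fields `time`, `tb`,
#'   `vo2`, `ta` (and optionally `lights_on`, `food_available`) to column
#'   names in the file.
#' @return A [metabolic_ts()].
#' @export
read_recording <- function(path, animal_id = NULL, schema = default_schema()) {
  if (!file.exists(path)) stop_tm("no such file: ", path)
  df <- utils::read.csv(path, na.strings = c("", ".", "NA"),
                        stringsAsFactors = FALSE)
  need <- c("time", "tb", "vo2", "ta")
  miss <- setdiff(need, names(schema))
  if (length(miss)) stop_tm("schema must map: ", paste(miss, collapse = ", "))
  absent <- setdiff(unname(schema[need]), names(df))
  if (length(absent))
    stop_tm("missing required column(s): ", paste(absent, collapse = ", "))
  get_opt <- function(field, default) {
    cn <- schema[field]
    if (!is.na(cn) && cn %in% names(df)) df[[cn]] else default
  }
  metabolic_ts(animal_id = animal_id %||% sub("\\.[^.]*$", "", basename(path)),
               t = df[[schema[["time"]]]],
               tb = df[[schema[["tb"]]]],
               vo2 = df[[schema[["vo2"]]]],
               ta = df[[schema[["ta"]]]],
               lights_on = get_opt("lights_on", NULL),
               food_available = get_opt("food_available", NULL))
}

#' Write a recording CSV
#'
#' Full double precision; missing values are written as empty cells.
#'
#' @param series a [metabolic_ts()].
#' @param path output path.
#' @export
write_recording <- function(series, path) {
  stopifnot(inherits(series, "metabolic_ts"))
  df <- as.data.frame(series)
  df$zt <- NULL; df$day_index <- NULL
  fmt <- function(v) {
    if (is.numeric(v)) {
      out <- vapply(v, function(z) if (is.na(z)) "" else sprintf("%.17g", z), "")
    } else {
      out <- as.character(v)
      out[is.na(out)] <- ""
    }
    out
  }
  out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-bin a recording to a coarser grid
#'
#' Within-bin arithmetic mean over the observed points of each variable;
#' bins whose inputs are all missing stay missing. `lights_on` and
#' `food_available` are taken from the first point of each bin.
#'
#' @param series a [metabolic_ts()].
#' @param new_bin_width target bin width (minutes); must be an integer
#'   multiple of the current one.
#' @return A re-binned [metabolic_ts()].
#' @export
bin_series <- function(series, new_bin_width) {
  stopifnot(inherits(series, "metabolic_ts"))
  r <- new_bin_width / series$bin_width
  if (abs(r - round(r)) > 1e-8 || r < 1)
    stop_tm("new_bin_width must be an integer multiple of ", series$bin_width)
  r <- as.integer(round(r))
  if (r == 1L) return(series)
  n <- length(series$t)
  grp <- rep(seq_len(n %/% r), each = r)[seq_len(n)]
  mean_na <- function(v) {
    out <- tapply(v, grp, function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
    as.numeric(out)
  }
  first_of <- function(v) as.vector(tapply(v, grp, function(z) z[1]))
  metabolic_ts(animal_id = series$animal_id,
               t = series$t[seq(1, n, by = r)],
               tb = mean_na(series$tb), vo2 = mean_na(series$vo2),
               ta = mean_na(series$ta),
               lights_on = as.logical(first_of(series$lights_on)),
               food_available = as.logical(first_of(series$food_available)))
}

# Subset whole days from a series (1-based day indices).
#' Extract whole days from a recording
#' @param series a [metabolic_ts()].
#' @param days integer vector of day indices to keep (must be contiguous).
#' @return A [metabolic_ts()] re-anchored so its first kept day starts at ZT0.
#' @export
subset_days <- function(series, days) {
  stopifnot(inherits(series, "metabolic_ts"))
  days <- sort(unique(as.integer(days)))
  if (length(days) > 1 && any(diff(days) != 1L))
    stop_tm("days must be contiguous")
  keep <- series$day_index %in% days
  if (!any(keep)) stop_tm("no such days in series")
  metabolic_ts(animal_id = series$animal_id,
               t = series$t[keep] - (days[1] - 1L) * 1440,
               tb = series$tb[keep], vo2 = series$vo2[keep],
               ta = series$ta[keep], lights_on = series$lights_on[keep],
               food_available = series$food_available[keep])
}
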