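# Hourly growing degree day engine with cardinal-temperature capping.
#
# An hour at temperature T contributes max(0, min(T, T_u) - T_b) degree-hours
# (GDH); a day's GDD is its 24 GDH summed and divided by 24. Accumulation over
# a stage interval counts the start date's 24 hours and excludes the end
# date's, which makes stage-wise GDD exactly additive.

#' Cardinal temperature pair
#'
#' @param t_base base temperature \eqn{T_b} in degrees Celsius: no heat
#'   accumulates at or below it.
#' @param t_upper upper threshold \eqn{T_u} in degrees Celsius: accumulation
#'   is held at `t_upper - t_base` above it. Use `NULL` (or `Inf`) for an
#'   uncapped engine, as in base-temperature scans.
#' @return object of class `thermal_thresholds`.
#' @examples
#' thermal_thresholds(5, 30)   # 'Flame Seedless' cardinal temperatures
#' thermal_thresholds(5)       # uncapped
#' @export
thermal_thresholds <- function(t_base, t_upper = NULL) {
  if (is.null(t_upper) || identical(t_upper, "none") || is.na(t_upper)) {
    t_upper <- Inf
  }
  t_base <- as.numeric(t_base); t_upper <- as.numeric(t_upper)
  stopifnot(length(t_base) == 1, length(t_upper) == 1, is.finite(t_base))
  if (t_base >= t_upper) {
    stop(sprintf(
      "thermal_thresholds: t_base (%g) must be strictly below t_upper (%g)",
      t_base, t_upper), call. = FALSE)
  }
  structure(list(t_base = t_base, t_upper = t_upper),
            class = "thermal_thresholds")
}

#' @export
print.thermal_thresholds <- function(x, ...) {
  cat(sprintf("<thermal_thresholds> T_b = %g C, T_u = %s\n", x$t_base,
              if (is.finite(x$t_upper)) paste0(x$t_upper, " C") else "none"))
  invisible(x)
}

#' Degree-hours contributed by one hourly temperature
#'
#' Returns 0 for `t_h <= t_base`, `t_h - t_base` in the linear region and
#' `t_upper - t_base` above the cap. Vectorised over `t_h`.
#'
#' @param t_h hourly temperature(s), degrees Celsius.
#' @param thresholds a [thermal_thresholds()].
#' @return degree-hours (same length as `t_h`).
#' @export
hourly_contribution <- function(t_h, thresholds) {
  stopifnot(inherits(thresholds, "thermal_thresholds"))
  pmin(pmax(t_h - thresholds$t_base, 0), thresholds$t_upper - thresholds$t_base)
}

# Internal: temperatures of every hour of `date` (00:00..23:00); errors if
# the day is not fully covered.
day_hours <- function(series, date) {
  date <- as.Date(date)
  from <- as.POSIXct(paste(date, "00:00"), tz = "UTC")
  idx <- which(series$time >= from & series$time < from + 86400)
  if (length(idx) != 24) {
    stop(sprintf("missing hourly data: %s has %d of 24 records",
                 format(date), length(idx)), call. = FALSE)
  }
  series$temp_c[idx]
}

#' Growing degree days for one calendar day
#'
#' Sum of the day's 24 hourly contributions divided by 24.
#'
#' @param series an [hourly_series()] covering the day completely.
#' @param date calendar date.
#' @param thresholds a [thermal_thresholds()].
#' @return degree-days (scalar).
#' @export
daily_gdd <- function(series, date, thresholds) {
  stopifnot(inherits(series, "hourly_series"))
  sum(hourly_contribution(day_hours(series, date), thresholds)) / 24
}

#' Accumulate growing degree days over a date range
#'
#' One entry per date in `[start, end]` inclusive; the series must cover
#' every hour of the range (run [fill_gaps()] first if needed).
#'
#' @param series an [hourly_series()].
#' @param start,end first and last dates accumulated (both inclusive).
#' @param thresholds a [thermal_thresholds()].
#' @return object of class `gdd_accumulation`: data frame with columns
#'   `date`, `gdh` (degree-hours), `gdd` (degree-days, `gdh/24`) and
#'   `cumulative` (running GDD total).
#' @export
accumulate_gdd <- function(series, start, end, thresholds) {
  stopifnot(inherits(series, "hourly_series"),
            inherits(thresholds, "thermal_thresholds"))
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("accumulate_gdd: start after end", call. = FALSE)
  from <- as.POSIXct(paste(start, "00:00"), tz = "UTC")
  to <- as.POSIXct(paste(end, "23:00"), tz = "UTC")
  idx <- which(series$time >= from & series$time <= to)
  n_days <- as.integer(end - start) + 1L
  if (length(idx) != 24L * n_days) {
    # name the first incomplete day for the error message
    have <- table(as.Date(series$time[idx], tz = "UTC"))
    want <- seq(start, end, by = "day")
    bad <- want[!(as.character(want) %in% names(have)) |
                  have[as.character(want)] != 24]
    stop(sprintf("accumulate_gdd: incomplete coverage, first missing day %s",
                 format(bad[1])), call. = FALSE)
  }
  gdh_hourly <- hourly_contribution(series$temp_c[idx], thresholds)
  day <- rep(seq(start, end, by = "day"), each = 24)
  gdh <- as.numeric(rowsum(gdh_hourly, group = as.integer(day)))
  out <- data.frame(date = seq(start, end, by = "day"),
                    gdh = gdh, gdd = gdh / 24, cumulative = cumsum(gdh / 24))
  attr(out, "thresholds") <- thresholds
  class(out) <- c("gdd_accumulation", "data.frame")
  out
}

#' @export
print.gdd_accumulation <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "<gdd_accumulation> %s .. %s (%d days), total %.1f GDD (T_b=%g, T_u=%s)\n",
    format(x$date[1]), format(x$date[nrow(x)]), nrow(x),
    x$cumulative[nrow(x)], th$t_base,
    if (is.finite(th$t_upper)) th$t_upper else "none"))
  invisible(x)
}

#' Total GDD of an accumulation
#'
#' @param accum a `gdd_accumulation`.
#' @return final cumulative degree-days.
#' @export
total_gdd <- function(accum) {
  stopifnot(inherits(accum, "gdd_accumulation"))
  accum$cumulative[nrow(accum)]
}

#' Write a GDD accumulation to CSV (`date,gdh,gdd,cumulative`)
#'
#' @param accum a `gdd_accumulation`.
#' @param path output path.
#' @export
write_gdd_csv <- function(accum, path) {
  stopifnot(inherits(accum, "gdd_accumulation"))
  utils::write.csv(as.data.frame(accum), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Heat units and duration between two phenological stages
#'
#' Accumulates from the first stage's date (inclusive) to the day before the
#' second stage's date, so stage intervals are additive: bud break to bloom
#' plus bloom to harvest equals bud break to harvest exactly. `days` is the
#' plain date difference.
#'
#' @param series an [hourly_series()] covering the interval.
#' @param phen a [season_phenology()].
#' @param from_stage,to_stage stage names among `"bud_break"`,
#'   `"full_bloom"`, `"harvest"`.
#' @param thresholds a [thermal_thresholds()].
#' @return list with `gdd` (degree-days) and `days` (integer).
#' @export
gdd_between_stages <- function(series, phen, from_stage = "bud_break",
                               to_stage = "harvest", thresholds) {
  stopifnot(inherits(phen, "season_phenology"))
  from <- stage_date(phen, from_stage)
  to <- stage_date(phen, to_stage)
  if (is.na(from) || is.na(to)) {
    stop(sprintf("gdd_between_stages: stage date missing (%s or %s)",
                 from_stage, to_stage), call. = FALSE)
  }
  if (from >= to) {
    stop("gdd_between_stages: from_stage date must precede to_stage date",
         call. = FALSE)
  }
  acc <- accumulate_gdd(series, from, to - 1, thresholds)
  list(gdd = total_gdd(acc), days = as.integer(to - from))
}
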