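# Hourly temperature series: reading, validation, gap repair, daily summaries
# and slot-wise reference years.

#' Construct an hourly temperature series
#'
#' An `hourly_series` is a data frame with columns `time` (POSIXct, naive
#' local time stored as UTC so no daylight-saving arithmetic ever applies),
#' `temp_c` (air temperature, degrees Celsius) and `imputed` (logical, TRUE
#' for gap-filled values). Timestamps must be strictly increasing on whole
#' hours; temperatures must fall inside the plausibility window.
#'
#' @param time POSIXct (or coercible) timestamps, one per hour.
#' @param temp_c numeric temperatures in degrees Celsius.
#' @param site site label, e.g. `"open_field"` or `"greenhouse"`.
#' @param imputed logical vector marking interpolated records.
#' @param plausibility length-2 numeric, allowed temperature window in
#'   degrees Celsius. Default `c(-30, 60)` catches sensor glitches while
#'   accepting greenhouse extremes.
#' @param require_hours minimum number of records (default 24).
#' @return object of class `hourly_series`.
#' @export
hourly_series <- function(time, temp_c, site = "unknown",
                          imputed = rep(FALSE, length(time)),
                          plausibility = c(-30, 60),
                          require_hours = 24L) {
  time <- as.POSIXct(time, tz = "UTC")
  if (anyNA(time)) {
    stop("hourly_series: unparseable timestamps", call. = FALSE)
  }
  if (length(time) != length(temp_c)) {
    stop("hourly_series: time and temp_c lengths differ", call. = FALSE)
  }
  if (length(time) < require_hours) {
    stop(sprintf("hourly_series: need at least %d records, got %d",
                 require_hours, length(time)), call. = FALSE)
  }
  secs <- as.numeric(time)
  if (any(secs %% 3600 != 0)) {
    stop("hourly_series: timestamps must fall on whole hours", call. = FALSE)
  }
  if (anyDuplicated(secs)) {
    dup <- format(time[duplicated(secs)][1], "%Y-%m-%dT%H:%M")
    stop(sprintf("hourly_series: duplicate timestamp %s", dup), call. = FALSE)
  }
  o <- order(secs)
  time <- time[o]; temp_c <- as.numeric(temp_c)[o]; imputed <- imputed[o]
  bad <- which(!is.na(temp_c) &
                 (temp_c < plausibility[1] | temp_c > plausibility[2]))
  if (length(bad) > 0) {
    stop(sprintf(
      "hourly_series: %d temperature(s) outside plausibility window [%g, %g] C, first at %s (%g C)",
      length(bad), plausibility[1], plausibility[2],
      format(time[bad[1]], "%Y-%m-%dT%H:%M"), temp_c[bad[1]]), call. = FALSE)
  }
  out <- data.frame(time = time, temp_c = temp_c, imputed = imputed)
  attr(out, "site") <- site
  attr(out, "plausibility") <- plausibility
  class(out) <- c("hourly_series", "data.frame")
  out
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf("<hourly_series> site=%s, %d records, %s .. %s, %d imputed\n",
              attr(x, "site"), nrow(x),
              format(x$time[1], "%Y-%m-%d %H:%M"),
              format(x$time[nrow(x)], "%Y-%m-%d %H:%M"),
              sum(x$imputed)))
  invisible(x)
}

#' Read an hourly weather CSV
#'
#' Expects header columns `timestamp` (ISO-8601 to the hour, e.g.
#' `2005-03-01T00:00`) and `temp_c`. Rows are sorted by time; duplicate
#' timestamps and implausible temperatures are rejected.
#'
#' @param path path to the CSV file.
#' @param site site label attached to the series.
#' @inheritParams hourly_series
#' @return an [hourly_series()].
#' @export
read_hourly_csv <- function(path, plausibility = c(-30, 60),
                            site = "unknown") {
  if (!file.exists(path)) {
    stop(sprintf("weather file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "temp_c")
  if (!all(need %in% names(raw))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  tm <- parse_hour_stamp(raw$timestamp)
  if (anyNA(tm)) {
    line <- which(is.na(tm))[1] + 1L   # +1 for the header line
    stop(sprintf("%s: unparseable timestamp at line %d: '%s'",
                 path, line, raw$timestamp[which(is.na(tm))[1]]),
         call. = FALSE)
  }
  tv <- suppressWarnings(as.numeric(raw$temp_c))
  if (anyNA(tv)) {
    line <- which(is.na(tv))[1] + 1L
    stop(sprintf("%s: unparseable temperature at line %d: '%s'",
                 path, line, raw$temp_c[which(is.na(tv))[1]]), call. = FALSE)
  }
  hourly_series(tm, tv, site = site, plausibility = plausibility)
}

#' Write an hourly series to CSV
#'
#' @param series an [hourly_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hourly_csv <- function(series, path) {
  stopifnot(inherits(series, "hourly_series"))
  df <- data.frame(timestamp = format(series$time, "%Y-%m-%dT%H:%M"),
                   temp_c = series$temp_c)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ISO-8601 hour stamps in a handful of tolerated spellings.
parse_hour_stamp <- function(x) {
  x <- trimws(as.character(x))
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M", "%Y-%m-%dT%H",
            "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d %H")
  out <- rep(as.POSIXct(NA), length(x))
  left <- rep(TRUE, length(x))
  for (f in fmts) {
    if (!any(left)) break
    p <- as.POSIXct(x[left], tz = "UTC", format = f)
    hit <- !is.na(p)
    idx <- which(left)[hit]
    out[idx] <- p[hit]
    left[idx] <- FALSE
  }
  out
}

#' Fill short gaps in an hourly series by linear interpolation
#'
#' Missing hours spanning at most `max_gap` hours are linearly interpolated
#' between the neighbouring observed values and flagged `imputed = TRUE`.
#' A longer gap is an error: the series cannot honestly support degree-day
#' accumulation across it.
#'
#' @param series an [hourly_series()].
#' @param max_gap maximum number of consecutive missing hours to repair.
#' @return a gap-free [hourly_series()].
#' @export
fill_gaps <- function(series, max_gap = 6L) {
  stopifnot(inherits(series, "hourly_series"), max_gap >= 1)
  secs <- as.numeric(series$time)
  dh <- diff(secs) / 3600
  gaps <- which(dh > 1)
  if (length(gaps) == 0) return(series)
  too_big <- gaps[dh[gaps] - 1 > max_gap]
  if (length(too_big) > 0) {
    g <- too_big[1]
    stop(sprintf(
      "unrecoverable gap of %d missing hour(s) between %s and %s (max_gap = %d)",
      as.integer(dh[g] - 1),
      format(series$time[g], "%Y-%m-%dT%H:%M"),
      format(series$time[g + 1], "%Y-%m-%dT%H:%M"), as.integer(max_gap)),
      call. = FALSE)
  }
  full <- seq(series$time[1], series$time[nrow(series)], by = "1 hour")
  obs <- match(as.numeric(series$time), as.numeric(full))
  temp <- rep(NA_real_, length(full))
  temp[obs] <- series$temp_c
  imput <- rep(TRUE, length(full))
  imput[obs] <- series$imputed
  filled <- stats::approx(as.numeric(full)[obs], series$temp_c,
                          xout = as.numeric(full))$y
  temp[is.na(temp)] <- filled[is.na(temp)]
  hourly_series(full, temp, site = attr(series, "site"), imputed = imput,
                plausibility = attr(series, "plausibility"))
}

#' Daily minimum, mean and maximum temperatures
#'
#' Summarises each complete day (all 24 hourly records present) of a series.
#' Incomplete days are omitted with a warning.
#'
#' @param series an [hourly_series()].
#' @return data frame with columns `date`, `t_min`, `t_mean`, `t_max`.
#' @export
daily_stats <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  day <- as.Date(series$time, tz = "UTC")
  cnt <- table(day)
  complete <- names(cnt)[cnt == 24]
  dropped <- names(cnt)[cnt != 24]
  if (length(dropped) > 0) {
    warning(sprintf("daily_stats: omitting %d incomplete day(s): %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
  }
  keep <- day %in% as.Date(complete)
  if (!any(keep)) {
    return(data.frame(date = as.Date(character()), t_min = numeric(),
                      t_mean = numeric(), t_max = numeric()))
  }
  d <- day[keep]; v <- series$temp_c[keep]
  out <- data.frame(
    date = as.Date(names(tapply(v, d, min)), tz = "UTC"),
    t_min = as.numeric(tapply(v, d, min)),
    t_mean = as.numeric(tapply(v, d, mean)),
    t_max = as.numeric(tapply(v, d, max))
  )
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

# (month, day, hour) slot key on a 365-day year, Feb 29 excluded.
ref_slot_key <- function(month, day, hour) {
  sprintf("%02d-%02d-%02d", month, day, hour)
}

ref_year_grid <- function() {
  days <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  mo <- as.integer(format(days, "%m"))
  dy <- as.integer(format(days, "%d"))
  data.frame(month = rep(mo, each = 24),
             day = rep(dy, each = 24),
             hour = rep(0:23, times = 365))
}

#' Build a slot-wise average reference year
#'
#' Averages one or more years of hourly data slot by slot over
#' (month, day, hour). Feb 29 records are dropped; the result is defined on
#' a 365-day year (8760 slots). Every slot must be covered by at least one
#' input year.
#'
#' @param series_list list of [hourly_series()] (one or more years of data;
#'   a single multi-year series is also accepted).
#' @param kind label for the reference year: `"average"` (default),
#'   `"tmy"` or `"observed"`.
#' @return object of class `reference_year`: data frame `month`, `day`,
#'   `hour`, `temp_c` with 8760 rows.
#' @export
build_average_year <- function(series_list, kind = "average") {
  if (inherits(series_list, "hourly_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1)
  tm <- do.call(c, lapply(series_list, function(s) s$time))
  tv <- unlist(lapply(series_list, function(s) s$temp_c), use.names = FALSE)
  mo <- as.integer(format(tm, "%m"))
  dy <- as.integer(format(tm, "%d"))
  hr <- as.integer(format(tm, "%H"))
  keep <- !(mo == 2 & dy == 29)
  key <- ref_slot_key(mo[keep], dy[keep], hr[keep])
  means <- tapply(tv[keep], key, mean)
  grid <- ref_year_grid()
  gkey <- ref_slot_key(grid$month, grid$day, grid$hour)
  hit <- match(gkey, names(means))
  if (anyNA(hit)) {
    miss <- gkey[which(is.na(hit))[1]]
    stop(sprintf(
      "build_average_year: no data for slot month-day-hour %s (and %d more)",
      miss, sum(is.na(hit)) - 1L), call. = FALSE)
  }
  reference_year(grid$month, grid$day, grid$hour, as.numeric(means[hit]),
                 kind = kind)
}

#' Construct a reference year
#'
#' @param month,day,hour integer slot keys (Feb 29 not allowed).
#' @param temp_c hourly temperatures, degrees Celsius.
#' @param kind one of `"average"`, `"tmy"`, `"observed"`.
#' @return object of class `reference_year` (8760-row data frame).
#' @export
reference_year <- function(month, day, hour, temp_c,
                           kind = c("average", "tmy", "observed")) {
  kind <- match.arg(kind)
  df <- data.frame(month = as.integer(month), day = as.integer(day),
                   hour = as.integer(hour), temp_c = as.numeric(temp_c))
  if (any(df$month == 2 & df$day == 29)) {
    stop("reference_year: Feb 29 is not a reference-year slot", call. = FALSE)
  }
  if (nrow(df) != 8760) {
    stop(sprintf("reference_year: need 8760 slots, got %d", nrow(df)),
         call. = FALSE)
  }
  key <- ref_slot_key(df$month, df$day, df$hour)
  if (anyDuplicated(key)) {
    stop("reference_year: duplicated (month, day, hour) slot", call. = FALSE)
  }
  grid <- ref_year_grid()
  df <- df[order(df$month, df$day, df$hour), , drop = FALSE]
  if (!identical(df$month, grid$month) || !identical(df$day, grid$day) ||
      !identical(df$hour, grid$hour)) {
    stop("reference_year: slots do not cover the 365-day year", call. = FALSE)
  }
  rownames(df) <- NULL
  attr(df, "kind") <- kind
  class(df) <- c("reference_year", "data.frame")
  df
}

#' @export
print.reference_year <- function(x, ...) {
  cat(sprintf("<reference_year> kind=%s, mean %.2f C, range [%.1f, %.1f] C\n",
              attr(x, "kind"), mean(x$temp_c), min(x$temp_c), max(x$temp_c)))
  invisible(x)
}

#' Read / write a reference year CSV (`month,day,hour,temp_c`)
#'
#' @param path CSV path.
#' @param kind reference-year kind label (read only).
#' @return [reference_year()] for the reader; `path` for the writer.
#' @export
read_reference_year <- function(path, kind = "average") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("month", "day", "hour", "temp_c")
  if (!all(need %in% names(raw))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  reference_year(raw$month, raw$day, raw$hour, raw$temp_c, kind = kind)
}

#' @rdname read_reference_year
#' @param ref a [reference_year()].
#' @export
write_reference_year <- function(ref, path) {
  stopifnot(inherits(ref, "reference_year"))
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
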