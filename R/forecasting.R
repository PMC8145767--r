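# Heat-unit requirements and harvest-date forecasting.
#
# Two predictors are compared: (i) projecting the mean GDD requirement from
# bud break onto observed weather or a reference year, and (ii) the
# calendar-day baseline (bud break plus the historical mean cycle length).
# Deviations are reported as predicted minus observed (PHD - OHD) in days.

# Round half away from zero (5.4 -> 5, 5.5 -> 6); plain round() is
# round-half-even and would turn 13.5 into 14 only by accident.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Mean heat-unit requirement across seasons
#'
#' Arithmetic mean of per-season GDD totals and cycle lengths. The days mean
#' is additionally rounded half-up to an integer for use by the calendar-day
#' baseline; the unrounded value is kept.
#'
#' @param summaries a [season_summaries()] data frame.
#' @param site optional site label carried along.
#' @return object of class `heat_requirement`: list with `per_season_gdd`,
#'   `mean_gdd`, `mean_days` (integer), `mean_days_exact`, `n_seasons`,
#'   `site`.
#' @export
mean_requirement <- function(summaries, site = NA_character_) {
  if (!inherits(summaries, "season_summaries") || nrow(summaries) < 1) {
    stop("mean_requirement: need a season_summaries with >= 1 season",
         call. = FALSE)
  }
  md <- mean(summaries$days)
  structure(list(per_season_gdd = stats::setNames(summaries$gdd,
                                                  summaries$season),
                 mean_gdd = mean(summaries$gdd),
                 mean_days = as.integer(round_half_up(md)),
                 mean_days_exact = md,
                 n_seasons = nrow(summaries), site = site),
            class = "heat_requirement")
}

#' @export
print.heat_requirement <- function(x, ...) {
  cat(sprintf(
    "<heat_requirement> %d season(s)%s: mean %.1f GDD over %d days (%.2f unrounded)\n",
    x$n_seasons, if (is.na(x$site)) "" else paste0(" [", x$site, "]"),
    x$mean_gdd, x$mean_days, x$mean_days_exact))
  invisible(x)
}

#' Requirement with the target season optionally excluded
#'
#' The default reproduces the in-sample convention: the full multi-season
#' mean is applied to every season, including the target itself. Setting
#' `exclude_target = TRUE` gives an honest leave-one-out requirement.
#'
#' @param summaries a [season_summaries()] data frame.
#' @param target_season season id the requirement will be applied to.
#' @param exclude_target logical; drop the target season from the mean.
#' @return a [mean_requirement()] object.
#' @export
leave_current_out_requirement <- function(summaries, target_season,
                                          exclude_target = FALSE) {
  check_summaries(summaries)
  if (!target_season %in% summaries$season) {
    stop(sprintf("unknown target season '%s'", target_season), call. = FALSE)
  }
  if (exclude_target) {
    summaries <- summaries[summaries$season != target_season, , drop = FALSE]
    if (nrow(summaries) < 1) {
      stop("leave_current_out_requirement: no seasons left after exclusion",
           call. = FALSE)
    }
    class(summaries) <- c("season_summaries", "data.frame")
  }
  mean_requirement(summaries)
}

# Internal: daily GDD stream for up to `horizon` days starting at `start`,
# from either an hourly series or a reference year. Reference years wrap
# across Dec 31; Feb 29 holds no reference slot and contributes zero.
daily_gdd_stream <- function(reference, start, horizon, thresholds) {
  start <- as.Date(start)
  dates <- seq(start, by = "day", length.out = horizon)
  if (inherits(reference, "reference_year")) {
    key <- ref_slot_key(reference$month, reference$day, reference$hour)
    gdh <- rowsum(hourly_contribution(reference$temp_c, thresholds),
                  group = substr(key, 1, 5))
    slot_gdd <- stats::setNames(as.numeric(gdh) / 24, rownames(gdh))
    md <- format(dates, "%m-%d")
    gdd <- ifelse(md == "02-29", 0, slot_gdd[md])
    return(data.frame(date = dates, gdd = as.numeric(gdd)))
  }
  if (inherits(reference, "hourly_series")) {
    last <- as.Date(reference$time[nrow(reference)], tz = "UTC")
    dates <- dates[dates <= last]
    if (length(dates) == 0) {
      stop("reference series does not cover the start date", call. = FALSE)
    }
    acc <- accumulate_gdd(reference, start, dates[length(dates)], thresholds)
    return(data.frame(date = acc$date, gdd = acc$gdd))
  }
  stop("reference must be an hourly_series or a reference_year",
       call. = FALSE)
}

#' Predict the harvest date by GDD projection
#'
#' Accumulates degree days from the bud-break date (inclusive) along the
#' reference temperatures and returns the first date on which the cumulative
#' total reaches the requirement. A requirement of zero returns the
#' bud-break date itself. Reference years are treated as cyclic:
#' accumulation past Dec 31 continues into the same year's January slots
#' (Feb 29 contributes nothing).
#'
#' @param reference an [hourly_series()] of observed weather or a
#'   [reference_year()].
#' @param bud_break bud-break date, the starting point of accumulation.
#' @param requirement heat-unit requirement in degree-days (e.g. the
#'   multi-season mean).
#' @param thresholds a [thermal_thresholds()].
#' @param horizon maximum number of days searched (default 400).
#' @return predicted harvest `Date`.
#' @export
predict_harvest_gdd <- function(reference, bud_break, requirement,
                                thresholds, horizon = 400L) {
  stopifnot(requirement >= 0)
  bud_break <- as.Date(bud_break)
  if (requirement == 0) return(bud_break)
  stream <- daily_gdd_stream(reference, bud_break, horizon, thresholds)
  cum <- cumsum(stream$gdd)
  hit <- which(cum >= requirement)
  if (length(hit) == 0) {
    stop(sprintf(
      "predict_harvest_gdd: requirement %.1f GDD not reached within %d days (accumulated %.1f)",
      requirement, nrow(stream), cum[length(cum)]), call. = FALSE)
  }
  stream$date[hit[1]]
}

#' Predict the harvest date by the calendar-day baseline
#'
#' @param bud_break bud-break date.
#' @param mean_days historical mean number of days from bud break to
#'   harvest (integer, non-negative).
#' @return predicted harvest `Date`, `bud_break + mean_days`.
#' @export
predict_harvest_calendar <- function(bud_break, mean_days) {
  stopifnot(mean_days >= 0)
  as.Date(bud_break) + as.integer(mean_days)
}

#' Assemble a harvest-forecast table
#'
#' @param season season ids.
#' @param method forecasting method per row, `"gdd"` or `"calendar"`.
#' @param predicted predicted harvest dates (PHD).
#' @param observed observed harvest dates (OHD), `NA` when not yet known.
#' @param site optional site labels.
#' @return data frame of class `harvest_forecasts` with a `deviation_days`
#'   column (predicted minus observed, `NA` when unobserved).
#' @export
harvest_forecasts <- function(season, method, predicted, observed = NA,
                              site = NA_character_) {
  predicted <- as.Date(predicted)
  observed <- as.Date(observed)
  stopifnot(all(method %in% c("gdd", "calendar")))
  out <- data.frame(season = as.character(season), site = site,
                    method = method, predicted = predicted,
                    observed = observed,
                    deviation_days = as.integer(predicted - observed))
  rownames(out) <- NULL
  class(out) <- c("harvest_forecasts", "data.frame")
  out
}

#' Forecast accuracy: mean absolute deviation in days
#'
#' Accuracy is the mean of `|predicted - observed|` rounded half-up to whole
#' days, computed per method when several methods are present.
#'
#' @param forecasts a [harvest_forecasts()] data frame; every row must have
#'   an observed date.
#' @return list with `deviations` (the per-season table) and `accuracy`
#'   (named integer vector, one entry per method).
#' @export
evaluate_forecasts <- function(forecasts) {
  if (!inherits(forecasts, "harvest_forecasts") || nrow(forecasts) == 0) {
    stop("evaluate_forecasts: need a non-empty harvest_forecasts table",
         call. = FALSE)
  }
  if (anyNA(forecasts$observed)) {
    stop("evaluate_forecasts: every forecast needs an observed date",
         call. = FALSE)
  }
  acc <- tapply(abs(forecasts$deviation_days), forecasts$method, mean)
  acc <- stats::setNames(as.integer(round_half_up(as.numeric(acc))),
                         names(acc))
  list(deviations = forecasts, accuracy = acc)
}

#' Write a forecast table to CSV
#' (`season,site,method,predicted,observed,deviation_days`)
#'
#' @param forecasts a [harvest_forecasts()] data frame.
#' @param path output path.
#' @export
write_forecast_csv <- function(forecasts, path) {
  stopifnot(inherits(forecasts, "harvest_forecasts"))
  df <- as.data.frame(forecasts)
  df$predicted <- format(df$predicted)
  df$observed <- ifelse(is.na(df$observed), "none", format(df$observed))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
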