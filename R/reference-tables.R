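# Packaged reference tables for 'Flame Seedless' table grape, transcribed
# from the published El Ejido (Almeria, SE Spain) field trials: open-field
# and plastic-greenhouse seasons 2003 and 2005-2008, with 2009 as the
# forward-validation season. The underlying hourly station records were
# never deposited, so these per-season values are consumed as inputs; all
# table-level arithmetic (means, CVs, deviations, accuracies) is recomputed
# by the package.

flame_file <- function(name) {
  path <- system.file("extdata", name, package = "grapeheat")
  if (path == "") stop(sprintf("packaged fixture %s not found", name),
                       call. = FALSE)
  path
}

#' Reference heat requirements of 'Flame Seedless'
#'
#' Per-season GDD (cardinal temperatures 5/30 C) and durations for the
#' bud break-full bloom and full bloom-harvest stages, open field and
#' greenhouse.
#'
#' @return data frame with columns `site`, `season`,
#'   `gdd_budbreak_bloom`, `days_budbreak_bloom`, `gdd_bloom_harvest`,
#'   `days_bloom_harvest`, `gdd_total`, `days_total`.
#' @export
flame_heat_requirements <- function() {
  df <- utils::read.csv(flame_file("flame_heat_requirements.csv"),
                        stringsAsFactors = FALSE)
  df$season <- as.character(df$season)
  df
}

#' Reference observed and predicted harvest dates of 'Flame Seedless'
#'
#' Observed harvest dates (first sampling with maturation index above 18)
#' and the harvest dates predicted by GDD projection and by the
#' calendar-day baseline, per season and site.
#'
#' @return data frame with columns `site`, `season`, `observed`,
#'   `predicted_gdd`, `predicted_calendar` (Date).
#' @export
flame_harvest_dates <- function() {
  df <- utils::read.csv(flame_file("flame_harvest_dates.csv"),
                        stringsAsFactors = FALSE)
  df$season <- as.character(df$season)
  for (cl in c("observed", "predicted_gdd", "predicted_calendar")) {
    df[[cl]] <- as.Date(df[[cl]])
  }
  df
}

#' Greenhouse forecasts recalibrated with the greenhouse mean requirement
#'
#' Greenhouse harvest predictions using the greenhouse-derived mean
#' requirement (1542 GDD) and mean cycle length (130 days) instead of the
#' open-field values.
#'
#' @return data frame with columns `season`, `observed`, `gdd_total`,
#'   `predicted_gdd`, `days_total`, `predicted_calendar`.
#' @export
flame_greenhouse_recalibration <- function() {
  df <- utils::read.csv(flame_file("flame_greenhouse_recalibrated.csv"),
                        stringsAsFactors = FALSE)
  df$season <- as.character(df$season)
  for (cl in c("observed", "predicted_gdd", "predicted_calendar")) {
    df[[cl]] <- as.Date(df[[cl]])
  }
  df
}

#' Forward-validation forecasts for season 2009
#'
#' Harvest dates predicted for the hold-out 2009 season by projecting the
#' mean requirement onto an average year and onto a typical meteorological
#' year, against the observed dates.
#'
#' @return data frame with columns `site`, `season`, `reference`,
#'   `predicted`, `observed`.
#' @export
flame_next_season_forecasts <- function() {
  df <- utils::read.csv(flame_file("flame_2009_forecasts.csv"),
                        stringsAsFactors = FALSE)
  df$season <- as.character(df$season)
  df$predicted <- as.Date(df$predicted)
  df$observed <- as.Date(df$observed)
  df
}

#' Season summaries from the reference heat-requirement table
#'
#' Converts one site/stage slice of [flame_heat_requirements()] into a
#' [season_summaries()] object so the variability criteria and requirement
#' means can be applied to the published per-season totals verbatim.
#'
#' @param site `"open_field"` or `"greenhouse"`.
#' @param stage `"total"`, `"budbreak_bloom"` or `"bloom_harvest"`.
#' @return a [season_summaries()] (interval mean temperatures unknown,
#'   `NA`).
#' @export
flame_summaries <- function(site = c("open_field", "greenhouse"),
                            stage = c("total", "budbreak_bloom",
                                      "bloom_harvest")) {
  site <- match.arg(site)
  stage <- match.arg(stage)
  df <- flame_heat_requirements()
  df <- df[df$site == site, , drop = FALSE]
  cols <- switch(stage,
                 total = c("gdd_total", "days_total"),
                 budbreak_bloom = c("gdd_budbreak_bloom",
                                    "days_budbreak_bloom"),
                 bloom_harvest = c("gdd_bloom_harvest",
                                   "days_bloom_harvest"))
  season_summaries(season = df$season, days = df[[cols[2]]],
                   gdd = df[[cols[1]]])
}

#' Harvest forecasts from the reference harvest-date table
#'
#' Converts [flame_harvest_dates()] (or the recalibrated greenhouse table)
#' into a [harvest_forecasts()] object with both methods stacked.
#'
#' @param site `"open_field"` or `"greenhouse"`.
#' @param recalibrated logical; use the greenhouse-requirement
#'   recalibration table (greenhouse only).
#' @return a [harvest_forecasts()] data frame.
#' @export
flame_forecasts <- function(site = c("open_field", "greenhouse"),
                            recalibrated = FALSE) {
  site <- match.arg(site)
  if (recalibrated) {
    if (site != "greenhouse") {
      stop("recalibrated forecasts exist only for the greenhouse",
           call. = FALSE)
    }
    df <- flame_greenhouse_recalibration()
    df$site <- "greenhouse"
  } else {
    df <- flame_harvest_dates()
    df <- df[df$site == site, , drop = FALSE]
  }
  harvest_forecasts(
    season = rep(df$season, 2),
    site = rep(df$site, 2),
    method = rep(c("gdd", "calendar"), each = nrow(df)),
    predicted = c(df$predicted_gdd, df$predicted_calendar),
    observed = rep(df$observed, 2))
}
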