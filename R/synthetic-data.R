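# Synthetic hourly weather and thermally consistent phenology with known
# ground truth.
#
# Weather is an annual sinusoid (minimum mid-January) plus a diurnal
# sinusoid (minimum pre-dawn), a per-year level shift for inter-annual
# variability, and AR(1) hourly noise. Phenology is generated by the exact
# thermal-time rule of a virtual cultivar, so estimators can be validated
# against parameters that are known to be true.

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Describe a synthetic weather scenario
#'
#' Defaults emulate the El Ejido (Almeria) open-field station climate: an
#' annual mean around 18.5 C with the coolest weeks in January, a daily
#' temperature range of about 10 C (15 C under plastic cover), about 1 C of
#' season-to-season level variability, and persistent (AR(1)) hourly noise.
#'
#' @param annual_mean long-term mean temperature, degrees Celsius.
#' @param annual_amplitude half peak-to-trough amplitude of the annual
#'   cycle, degrees Celsius (seasonal monthly means span roughly
#'   `annual_mean +/- annual_amplitude`).
#' @param diurnal_amplitude daily temperature range (max minus min),
#'   degrees Celsius.
#' @param noise_sd marginal standard deviation of the hourly noise,
#'   degrees Celsius.
#' @param ar_coefficient AR(1) coefficient of the hourly noise, in `[0, 1)`.
#'   Hourly weather noise is strongly persistent; white noise would be
#'   unrealistically rough.
#' @param interannual_sd standard deviation of the per-year level shift,
#'   degrees Celsius; set 0 for identical years.
#' @param year_offsets optional explicit per-year level shifts (length
#'   `n_years`), overriding the random draw; useful for deterministic
#'   between-season contrast.
#' @param site `"open_field"` or `"greenhouse"` (label only).
#' @param n_years number of simulated calendar years.
#' @param seed integer seed; identical scenarios generate identical weather.
#' @return object of class `weather_scenario`.
#' @export
weather_scenario <- function(annual_mean = 18.5, annual_amplitude = 7,
                             diurnal_amplitude = 10, noise_sd = 1.5,
                             ar_coefficient = 0.9, interannual_sd = 1,
                             year_offsets = NULL,
                             site = c("open_field", "greenhouse"),
                             n_years = 5L, seed = 1L) {
  site <- match.arg(site)
  stopifnot(annual_amplitude >= 0, diurnal_amplitude >= 0, noise_sd >= 0,
            ar_coefficient >= 0, ar_coefficient < 1, interannual_sd >= 0,
            n_years >= 1)
  if (!is.null(year_offsets) && length(year_offsets) != n_years) {
    stop("weather_scenario: year_offsets must have length n_years",
         call. = FALSE)
  }
  structure(list(annual_mean = annual_mean,
                 annual_amplitude = annual_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 noise_sd = noise_sd, ar_coefficient = ar_coefficient,
                 interannual_sd = interannual_sd, year_offsets = year_offsets,
                 site = site, n_years = as.integer(n_years),
                 seed = as.integer(seed)),
            class = "weather_scenario")
}

#' Greenhouse variant of the default scenario
#'
#' Plastic cover widens the daily range to about 15 C and lifts the mean
#' slightly; everything else matches [weather_scenario()] defaults.
#'
#' @param ... overrides passed to [weather_scenario()].
#' @return a `weather_scenario`.
#' @export
greenhouse_scenario <- function(...) {
  args <- list(annual_mean = 19.5, diurnal_amplitude = 15,
               site = "greenhouse")
  args[names(list(...))] <- list(...)
  do.call(weather_scenario, args)
}

#' Generate synthetic hourly weather
#'
#' One full calendar year of hourly temperatures per simulated year:
#' annual sinusoid with its minimum in mid-January, diurnal sinusoid with
#' its minimum just before dawn (05:00) and maximum in late afternoon, a
#' per-year level shift, and AR(1) noise. Deterministic given the scenario
#' (including its seed).
#'
#' @param scenario a [weather_scenario()].
#' @param start_year first simulated calendar year (default 2001).
#' @return named list of [hourly_series()], one per year, names
#'   `"<year>"`.
#' @export
generate_weather <- function(scenario, start_year = 2001L) {
  stopifnot(inherits(scenario, "weather_scenario"))
  years <- seq(as.integer(start_year), length.out = scenario$n_years)
  with_seed(scenario$seed, {
    offsets <- if (!is.null(scenario$year_offsets)) {
      scenario$year_offsets
    } else if (scenario$interannual_sd > 0) {
      stats::rnorm(scenario$n_years, 0, scenario$interannual_sd)
    } else {
      rep(0, scenario$n_years)
    }
    out <- lapply(seq_along(years), function(k) {
      yr <- years[k]
      t0 <- as.POSIXct(sprintf("%d-01-01 00:00", yr), tz = "UTC")
      t1 <- as.POSIXct(sprintf("%d-12-31 23:00", yr), tz = "UTC")
      tm <- seq(t0, t1, by = "1 hour")
      n <- length(tm)
      n_days <- n / 24
      frac_day <- (as.numeric(tm) - as.numeric(t0)) / 86400
      hour <- (as.numeric(tm) / 3600) %% 24
      annual <- -scenario$annual_amplitude *
        cos(2 * pi * (frac_day - 14.5) / n_days)
      diurnal <- -(scenario$diurnal_amplitude / 2) *
        cos(2 * pi * (hour - 5) / 24)
      noise <- if (scenario$noise_sd > 0) {
        z <- stats::rnorm(n, 0,
                          scenario$noise_sd *
                            sqrt(1 - scenario$ar_coefficient^2))
        as.numeric(stats::filter(z, scenario$ar_coefficient,
                                 method = "recursive",
                                 init = stats::rnorm(1, 0,
                                                     scenario$noise_sd)))
      } else {
        numeric(n)
      }
      hourly_series(tm,
                    scenario$annual_mean + offsets[k] + annual + diurnal +
                      noise,
                    site = scenario$site,
                    plausibility = c(-60, 80))
    })
    names(out) <- as.character(years)
    out
  })
}

#' A virtual cultivar with known thermal-time parameters
#'
#' Encodes the ground truth for validation. Defaults match the fitted
#' 'Flame Seedless' open-field values: cardinal temperatures 5/30 C and
#' stage requirements 694 GDD (bud break to full bloom) plus 939 GDD (full
#' bloom to harvest), with bud break fixed at 15 March (20 January is
#' typical under plastic cover).
#'
#' @param t_base base temperature, degrees Celsius.
#' @param t_upper upper threshold, degrees Celsius.
#' @param gdd_budbreak_to_bloom,gdd_bloom_to_harvest stage requirements in
#'   degree-days (both > 0).
#' @param bud_break_mmdd fixed bud-break date as `"MM-DD"`.
#' @return object of class `virtual_cultivar`.
#' @export
virtual_cultivar <- function(t_base = 5, t_upper = 30,
                             gdd_budbreak_to_bloom = 694,
                             gdd_bloom_to_harvest = 939,
                             bud_break_mmdd = "03-15") {
  stopifnot(t_base < t_upper, gdd_budbreak_to_bloom > 0,
            gdd_bloom_to_harvest > 0)
  structure(list(t_base = t_base, t_upper = t_upper,
                 gdd_budbreak_to_bloom = gdd_budbreak_to_bloom,
                 gdd_bloom_to_harvest = gdd_bloom_to_harvest,
                 bud_break_mmdd = bud_break_mmdd),
            class = "virtual_cultivar")
}

#' Generate phenology from weather by the cultivar's thermal-time rule
#'
#' Full bloom is the first date on which cumulative GDD from bud break
#' (inclusive) reaches the bud break-to-bloom requirement; harvest the first
#' date reaching the sum of both stage requirements. This is the exact
#' inverse of [predict_harvest_gdd()] under the same inclusive-day
#' convention.
#'
#' @param weather an [hourly_series()] covering the season.
#' @param cultivar a [virtual_cultivar()].
#' @param bud_break bud-break date; default taken from the cultivar's
#'   `bud_break_mmdd` within the weather's first year.
#' @param site site label for the phenology record.
#' @return a [season_phenology()] (season id = calendar year of bud break).
#' @export
generate_phenology <- function(weather, cultivar, bud_break = NULL,
                               site = "open_field") {
  stopifnot(inherits(weather, "hourly_series"),
            inherits(cultivar, "virtual_cultivar"))
  if (is.null(bud_break)) {
    yr <- format(weather$time[1], "%Y")
    bud_break <- as.Date(paste0(yr, "-", cultivar$bud_break_mmdd))
  }
  bud_break <- as.Date(bud_break)
  th <- thermal_thresholds(cultivar$t_base, cultivar$t_upper)
  last <- as.Date(weather$time[nrow(weather)], tz = "UTC")
  end <- min(last, bud_break + 399)
  acc <- accumulate_gdd(weather, bud_break, end, th)
  need_bloom <- cultivar$gdd_budbreak_to_bloom
  need_total <- need_bloom + cultivar$gdd_bloom_to_harvest
  ib <- which(acc$cumulative >= need_bloom)
  ih <- which(acc$cumulative >= need_total)
  if (length(ih) == 0) {
    stop(sprintf(
      "generate_phenology: requirement %.1f GDD not reached by %s (accumulated %.1f)",
      need_total, format(end), total_gdd(acc)), call. = FALSE)
  }
  bloom <- acc$date[ib[1]]
  harv <- acc$date[ih[1]]
  season <- format(bud_break, "%Y")
  if (bloom > bud_break && harv > bloom) {
    season_phenology(season, site, bud_break, bloom, harv)
  } else {
    # degenerate (near-zero requirement) boundary: stages may coincide
    structure(list(season = season, site = site, bud_break = bud_break,
                   full_bloom = bloom, harvest = harv),
              class = "season_phenology")
  }
}

#' Generate a weekly berry maturation series consistent with a harvest date
#'
#' Weekly samples ending on the harvest date, with the maturation index
#' strictly increasing, staying at or below the threshold before harvest and
#' first exceeding it exactly on the harvest-date sample, so that
#' [call_harvest()] inverts the construction.
#'
#' @param harvest harvest date (last sample).
#' @param weeks_before number of pre-harvest weekly samples (>= 1).
#' @param seed integer seed.
#' @param threshold maturation-index threshold (default 18).
#' @return a [maturation_samples()] data frame.
#' @export
generate_maturation_series <- function(harvest, weeks_before = 4L, seed = 1L,
                                       threshold = 18) {
  stopifnot(weeks_before >= 1)
  harvest <- as.Date(harvest)
  with_seed(seed, {
    w <- as.integer(weeks_before)
    dates <- harvest - 7 * (w:0)
    drops <- stats::runif(w, 0.3, 1.2)
    # pre-harvest sample k sits below the threshold by the summed
    # remaining weekly increments; the harvest sample exceeds it
    pre <- threshold - 0.05 - rev(cumsum(rev(drops)))
    mi <- c(pre, threshold + stats::runif(1, 0.1, 0.8))
    ta <- seq(1.6, 1.05, length.out = w + 1)
    maturation_samples(dates, tss = mi * ta, ta = ta)
  })
}
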