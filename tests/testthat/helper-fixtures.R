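# Shared fixtures and independent brute-force oracles. The oracles use
# plain hour/day loops with explicit conditionals so they share no code
# path with the vectorised engine they check.

const_series <- function(temp, start = "2009-03-01", days = 10,
                         site = "open_field") {
  t0 <- as.POSIXct(paste(start, "00:00"), tz = "UTC")
  tm <- seq(t0, by = "1 hour", length.out = 24 * days)
  hourly_series(tm, rep(temp, length(tm)), site = site)
}

# Hour-by-hour degree-day oracle over [start, end] inclusive.
gdd_oracle <- function(series, start, end, t_base, t_upper = Inf) {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  total <- 0
  for (d in as.list(dates)) {
    t0 <- as.POSIXct(paste(d, "00:00"), tz = "UTC")
    gdh <- 0
    for (h in 0:23) {
      temp <- series$temp_c[series$time == t0 + h * 3600]
      stopifnot(length(temp) == 1)
      if (temp <= t_base) {
        contrib <- 0
      } else if (is.finite(t_upper) && temp > t_upper) {
        contrib <- t_upper - t_base
      } else {
        contrib <- temp - t_base
      }
      gdh <- gdh + contrib
    }
    total <- total + gdh / 24
  }
  total
}

# Day-loop harvest-prediction oracle on a daily GDD rate function
# rate_fun(date) -> degree-days; returns the first date reaching `req`.
predict_oracle <- function(rate_fun, bud_break, req, max_days = 500) {
  d <- as.Date(bud_break)
  cum <- 0
  for (k in seq_len(max_days)) {
    cum <- cum + rate_fun(d)
    if (cum >= req) return(d)
    d <- d + 1
  }
  stop("predict_oracle: requirement not reached")
}

# Noise-controlled synthetic season set with known cultivar truth.
# Cool scenario: the 30 C cap essentially never binds, so uncapped
# base-temperature estimation is not confounded by the cap.
make_recovery_set <- function(noise_sd = 0, seed = 7,
                              cultivar = virtual_cultivar(),
                              annual_mean = 17, diurnal_amplitude = 8) {
  sc <- weather_scenario(annual_mean = annual_mean, annual_amplitude = 7,
                         diurnal_amplitude = diurnal_amplitude,
                         noise_sd = noise_sd, interannual_sd = 0,
                         year_offsets = c(-2, -1, 0, 1, 2), n_years = 5,
                         seed = seed)
  weather <- generate_weather(sc)
  phen <- lapply(weather, generate_phenology, cultivar = cultivar)
  names(phen) <- names(weather)
  list(weather = weather, phenology = phen)
}

# Seasons for joint (T_b, T_u) recovery. Mean level and diurnal amplitude
# are crossed so that exposure to the cap varies independently of the mean:
# with level shifts alone, raising the base and lowering the cap compensate
# almost exactly and the CV surface has a flat ridge.
paired_recovery_set <- function(noise_sd = 0.3, seed = 11,
                                cultivar = virtual_cultivar(7, 31, 694,
                                                            939)) {
  grid <- expand.grid(off = c(-2, 0, 2), da = c(8, 12, 16))
  w <- list(); p <- list()
  for (i in seq_len(nrow(grid))) {
    sc <- weather_scenario(annual_mean = 20 + grid$off[i],
                           annual_amplitude = 7,
                           diurnal_amplitude = grid$da[i],
                           noise_sd = noise_sd, interannual_sd = 0,
                           n_years = 1, seed = seed * 100 + i)
    id <- as.character(2000 + i)
    w[[id]] <- generate_weather(sc, start_year = 2000 + i)[[1]]
    p[[id]] <- generate_phenology(w[[id]], cultivar)
  }
  list(weather = w, phenology = p)
}

# Two constant-temperature seasons whose GDD at base 6 C coincide exactly
# (10 C excess x 100 d = 20 C excess x 50 d), so the CV criterion is zero
# at exactly 6 C.
cv_zero_set <- function() {
  w <- list(
    a = const_series(16, "2003-03-01", days = 120),
    b = const_series(26, "2004-03-01", days = 70))
  p <- list(
    a = season_phenology("a", "open_field", "2003-03-01",
                         harvest = as.Date("2003-03-01") + 100),
    b = season_phenology("b", "open_field", "2004-03-01",
                         harvest = as.Date("2004-03-01") + 50))
  list(weather = w, phenology = p)
}
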