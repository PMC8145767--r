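test_that("mean requirements average per-season totals with half-up day rounding", {
  s <- season_summaries(paste(1:4), days = c(133, 132, 128, 128),
                        gdd = c(1498, 1625, 1542, 1503))
  req <- mean_requirement(s, site = "greenhouse")
  expect_equal(req$mean_gdd, 1542)
  expect_equal(req$mean_days, 130L)          # 130.25 rounds down
  expect_equal(req$mean_days_exact, 130.25)
  s2 <- season_summaries(paste(1:5), days = c(62, 52, 54, 65, 71),
                         gdd = c(679, 628, 620, 703, 841))
  expect_equal(mean_requirement(s2)$mean_days, 61L)   # 60.8 rounds up
  expect_equal(mean_requirement(s2)$mean_gdd, 694.2)
})

test_that("in-sample and leave-one-out requirements behave as documented", {
  s <- season_summaries(c("a", "b"), days = c(10, 20), gdd = c(100, 200))
  full_a <- leave_current_out_requirement(s, "a")
  full_b <- leave_current_out_requirement(s, "b")
  expect_equal(full_a$mean_gdd, 150)
  expect_equal(full_b$mean_gdd, 150)         # same full mean for every target
  loo <- leave_current_out_requirement(s, "a", exclude_target = TRUE)
  expect_equal(loo$mean_gdd, 200)
  one <- season_summaries("a", days = 10, gdd = 100)
  expect_error(leave_current_out_requirement(one, "a",
                                             exclude_target = TRUE),
               "at least 2")
  expect_error(leave_current_out_requirement(s, "z"), "unknown")
})

test_that("GDD projection finds the first date reaching the requirement", {
  th <- thermal_thresholds(5, 30)
  s <- const_series(19, "2009-02-01", days = 250)
  expect_equal(predict_harvest_gdd(s, "2009-03-01", 1633, th),
               as.Date("2009-06-25"))      # 14 GDD/day, day 117
  expect_equal(predict_harvest_gdd(s, "2009-03-01", 0, th),
               as.Date("2009-03-01"))
  cold <- const_series(4, "2009-02-01", days = 250)
  expect_error(predict_harvest_gdd(cold, "2009-03-01", 100, th),
               "not reached")
  # monotone in the requirement
  d1 <- predict_harvest_gdd(s, "2009-03-01", 800, th)
  d2 <- predict_harvest_gdd(s, "2009-03-01", 1200, th)
  expect_true(d1 <= d2)
  # a uniformly warmer reference never delays the forecast
  warm <- s; warm$temp_c <- warm$temp_c + 2
  class(warm) <- class(s)
  expect_true(predict_harvest_gdd(warm, "2009-03-01", 1633, th) <=
                predict_harvest_gdd(s, "2009-03-01", 1633, th))
})

test_that("projection onto a reference year wraps Dec 31 and skips Feb 29", {
  base_year <- const_series(12, "2003-01-01", days = 365)
  ref <- build_average_year(list(base_year))   # constant 12 C: 7 GDD/day
  th <- thermal_thresholds(5, 30)
  pred <- predict_harvest_gdd(ref, "2019-11-01", 1633, th)
  oracle <- predict_oracle(function(d) {
    if (format(d, "%m-%d") == "02-29") 0 else 7
  }, "2019-11-01", 1633)
  expect_equal(pred, oracle)
  # 1633/7 = 233.28... -> 234 accumulation days; Feb 29 2020 adds one
  # calendar day to the span
  expect_equal(pred, as.Date("2019-11-01") + 234)
  # same projection started in a non-leap span needs one day less
  pred2 <- predict_harvest_gdd(ref, "2018-11-01", 1633, th)
  expect_equal(pred2, as.Date("2018-11-01") + 233)
})

test_that("calendar baseline is plain date arithmetic", {
  expect_equal(predict_harvest_calendar("2009-01-15", 130),
               as.Date("2009-05-25"))
  expect_equal(predict_harvest_calendar("2009-01-15", 0),
               as.Date("2009-01-15"))
  expect_equal(predict_harvest_calendar("2020-01-31", 30),
               as.Date("2020-03-01"))   # leap-year rollover
  expect_error(predict_harvest_calendar("2009-01-15", -1))
})

test_that("accuracy is the half-up rounded mean absolute deviation per method", {
  mk <- function(devs, method) {
    obs <- as.Date("2005-07-01") + seq_along(devs)
    harvest_forecasts(season = paste(seq_along(devs)), method = method,
                      predicted = obs + devs, observed = obs)
  }
  of <- evaluate_forecasts(mk(c(-1, 8, -6, 0, 0), "gdd"))
  expect_equal(of$accuracy[["gdd"]], 3L)
  expect_equal(of$deviations$deviation_days, c(-1, 8, -6, 0, 0))
  cal <- evaluate_forecasts(mk(c(-16, -16, -11, -11), "calendar"))
  expect_equal(cal$accuracy[["calendar"]], 14L)      # 13.5 rounds up
  expect_equal(evaluate_forecasts(mk(c(-4, 13, -5, -3, -2),
                                     "calendar"))$accuracy[["calendar"]],
               5L)                                   # 5.4 rounds down
  expect_equal(evaluate_forecasts(mk(c(0, 0, 0), "gdd"))$accuracy[["gdd"]],
               0L)
  # brute-force mean-absolute cross-check on a random table
  set.seed(31)
  devs <- sample(-15:15, 12, replace = TRUE)
  ev <- evaluate_forecasts(mk(devs, "gdd"))
  expect_equal(ev$accuracy[["gdd"]],
               as.integer(floor(mean(abs(devs)) + 0.5)))
  nf <- mk(c(1, 2), "gdd"); nf$observed[1] <- NA
  expect_error(evaluate_forecasts(nf), "observed")
})

test_that("forecasting a season's own weather with its realised GDD is exact", {
  th <- thermal_thresholds(5, 30)
  for (seed in c(2, 12, 22)) {
    w <- generate_weather(weather_scenario(n_years = 1, seed = seed))[[1]]
    phen <- generate_phenology(w, virtual_cultivar())
    realised <- total_gdd(accumulate_gdd(w, phen$bud_break, phen$harvest,
                                         th))
    expect_equal(predict_harvest_gdd(w, phen$bud_break, realised, th),
                 phen$harvest)
  }
})

test_that("forecast tables export with pending observations marked", {
  fc <- harvest_forecasts(season = c("2009", "2009"), site = "open_field",
                          method = c("gdd", "calendar"),
                          predicted = as.Date(c("2009-07-12", "2009-07-18")),
                          observed = as.Date(c("2009-07-16", NA)))
  expect_equal(fc$deviation_days, c(-4L, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_forecast_csv(fc, path)
  out <- read.csv(path)
  expect_equal(out$observed, c("2009-07-16", "none"))
})
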