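# Frozen criterion values below were computed independently from the
# definition sqrt(sum((x - mean)^2)/(n-1)) applied to the five open-field
# totals 1652, 1490, 1740, 1634, 1650 (sum of squared deviations 32548.8).

test_that("variability criteria match hand-computed values and closed forms", {
  s <- season_summaries(season = paste(2003:2007),
                        days = c(121, 104, 122, 120, 119),
                        gdd = c(1652, 1490, 1740, 1634, 1650), t_mean = 19)
  expect_equal(criterion_sd_gdd(s), sqrt(32548.8 / 4), tolerance = 1e-12)
  expect_equal(criterion_cv_gdd(s), 100 * sqrt(32548.8 / 4) / 1633.2,
               tolerance = 1e-12)
  expect_equal(criterion_sd_days(s, 5), sqrt(32548.8 / 4) / 14,
               tolerance = 1e-12)

  eq <- season_summaries(paste(1:4), days = 100, gdd = 1500, t_mean = 20)
  expect_equal(criterion_sd_gdd(eq), 0)
  expect_equal(criterion_cv_gdd(eq), 0)
  expect_equal(criterion_sd_days(eq, 5), 0)

  two <- season_summaries(c("a", "b"), days = c(10, 10), gdd = c(100, 102))
  expect_equal(criterion_sd_gdd(two), sqrt(2))

  zero <- season_summaries(c("a", "b"), days = c(10, 10), gdd = c(0, 0))
  expect_error(criterion_cv_gdd(zero), "not positive")
  expect_error(criterion_sd_days(s, 25), "not positive")
  expect_error(criterion_sd_gdd(s[1, ]), "at least 2")
})

test_that("criteria are order-invariant and CV is scale-free", {
  s <- season_summaries(paste(1:5), days = c(100, 90, 110, 95, 105),
                        gdd = c(1500, 1400, 1600, 1450, 1550), t_mean = 20)
  shuffled <- s[c(3, 1, 5, 2, 4), ]
  class(shuffled) <- class(s)
  expect_equal(criterion_sd_gdd(shuffled), criterion_sd_gdd(s))
  expect_equal(criterion_cv_gdd(shuffled), criterion_cv_gdd(s))
  scaled <- s; scaled$gdd <- s$gdd * 3.7
  expect_equal(criterion_cv_gdd(scaled), criterion_cv_gdd(s))
})

test_that("season summaries computed from weather match constant-series algebra", {
  w <- list(a = const_series(20, "2003-03-01", days = 110),
            b = const_series(20, "2004-03-01", days = 110))
  p <- list(a = season_phenology("a", "open_field", "2003-03-01",
                                 harvest = as.Date("2003-03-01") + 100),
            b = season_phenology("b", "open_field", "2004-03-01",
                                 harvest = as.Date("2004-03-01") + 100))
  s <- summarize_seasons(w, p, thermal_thresholds(5))
  expect_equal(s$days, c(100, 100))
  expect_equal(s$t_mean, c(20, 20))
  expect_equal(s$gdd, c(1500, 1500))
  # identical seasons give identical summaries
  expect_equal(s[1, -1], s[2, -1], ignore_attr = TRUE)
  # hourly engine agrees with the classical mean-temperature shortcut on
  # constant temperatures
  expect_equal(s$gdd, gdd_mean_shortcut(s$days, s$t_mean, 5))
  expect_error(summarize_seasons(w[1], p[1], thermal_thresholds(5)),
               "at least 2 seasons")
})

test_that("x-intercept estimate is analytic on noiseless linear-rate seasons", {
  # rates 1/100 and 1/50 at means 15 and 25 C give 1/d = (T - 5)/1000
  w <- list(a = const_series(15, "2003-03-01", days = 110),
            b = const_series(25, "2004-03-01", days = 60))
  p <- list(a = season_phenology("a", "open_field", "2003-03-01",
                                 harvest = as.Date("2003-03-01") + 100),
            b = season_phenology("b", "open_field", "2004-03-01",
                                 harvest = as.Date("2004-03-01") + 50))
  est <- estimate_tb("x_intercept", w, p)
  expect_equal(est$t_base, 5, tolerance = 1e-9)
  # decreasing rate with temperature has no physical intercept
  w_rev <- list(a = const_series(15, "2003-03-01", days = 60),
                b = const_series(25, "2004-03-01", days = 110))
  p_rev <- list(a = season_phenology("a", "open_field", "2003-03-01",
                                     harvest = as.Date("2003-03-01") + 50),
                b = season_phenology("b", "open_field", "2004-03-01",
                                     harvest = as.Date("2004-03-01") + 100))
  expect_error(estimate_tb("x_intercept", w_rev, p_rev), "not positive")
})

test_that("CV criterion and scan find the base that equalises season GDD", {
  set <- cv_zero_set()
  est <- estimate_tb("cv_gdd", set$weather, set$phenology,
                     search = seq(3, 12, by = 0.01))
  expect_equal(est$t_base, 6, tolerance = 0.011)
  expect_equal(est$criterion_value, 0, tolerance = 1e-9)
  curve <- scan_cv(set$weather, set$phenology, axis = "t_base",
                   range = c(3, 12), step = 1)
  expect_equal(nrow(curve), 10)
  expect_equal(scan_minimum(curve)$temperature, 6)
  expect_true(all(diff(curve$temperature) > 0))
})

test_that("upper-threshold scan is flat when the cap never binds and needs a base", {
  set <- cv_zero_set()   # constant 16 and 26 C: no hour above 26
  curve <- scan_cv(set$weather, set$phenology, axis = "t_upper",
                   fixed_other = 6, range = c(27, 45), step = 1)
  expect_equal(diff(range(curve$cv_percent)), 0, tolerance = 1e-12)
  expect_error(scan_cv(set$weather, set$phenology, axis = "t_upper"),
               "fixed_other")
  expect_error(scan_cv(set$weather, set$phenology, axis = "t_upper",
                       fixed_other = 26, range = c(25, 45)), "exceed")
})

test_that("upper-threshold scan responds when hot hours are capped", {
  # seasons hot enough that small caps truncate different amounts of heat
  set <- make_recovery_set(noise_sd = 0.5, seed = 21,
                           cultivar = virtual_cultivar(5, 30, 694, 939),
                           annual_mean = 20, diurnal_amplitude = 12)
  curve <- scan_cv(set$weather, set$phenology, axis = "t_upper",
                   fixed_other = 5, range = c(25, 45), step = 1)
  # brute-force recomputation at three grid points via summarize_seasons
  for (tu in c(25, 30, 40)) {
    s <- summarize_seasons(set$weather, set$phenology,
                           thermal_thresholds(5, tu))
    expect_equal(curve$cv_percent[curve$temperature == tu],
                 criterion_cv_gdd(s), tolerance = 1e-9)
  }
  expect_gt(curve$cv_percent[curve$temperature == 25],
            min(curve$cv_percent))
})

test_that("regression-coefficient root zeroes the refitted slope", {
  set <- make_recovery_set(noise_sd = 0, seed = 5)
  est <- estimate_tb("re", set$weather, set$phenology)
  expect_equal(est$t_base, 5, tolerance = 0.5)
  slope_at <- function(tb) {
    s <- summarize_seasons(set$weather, set$phenology,
                           thermal_thresholds(tb))
    unname(coef(lm(s$gdd ~ s$t_mean))[2])
  }
  expect_lt(abs(slope_at(est$t_base)),
            1e-6 * abs(slope_at(est$t_base + 0.1)))
})

test_that("all five estimators recover a noiseless cultivar within half a degree", {
  set <- make_recovery_set(noise_sd = 0, seed = 7)
  for (m in c("sd_gdd", "sd_days", "cv_gdd", "re", "x_intercept")) {
    est <- estimate_tb(m, set$weather, set$phenology)
    expect_lt(abs(est$t_base - 5), 0.5, label = sprintf("|%s - 5|", m))
  }
})

test_that("recovery degrades gracefully as weather noise grows", {
  noise <- c(0, 1, 3)
  mae <- sapply(noise, function(ns) {
    errs <- sapply(1:20, function(k) {
      set <- make_recovery_set(noise_sd = ns, seed = 300 + k)
      est <- estimate_tb("cv_gdd", set$weather, set$phenology,
                         search = seq(-5, 20, by = 0.05))
      abs(est$t_base - 5)
    })
    mean(errs)
  })
  expect_true(all(diff(mae) >= 0))
  expect_lt(mae[1], 0.3)
})

test_that("paired grid search recovers the constructing pair and breaks ties low", {
  set <- cv_zero_set()
  est <- paired_scan(set$weather, set$phenology, tb_range = c(3, 12),
                     tu_range = c(27, 45), step = 1)
  expect_equal(est$t_base, 6)
  # CV is zero (cap inert) for every t_upper; ties resolve to the smallest
  expect_equal(est$t_upper, 27)
  single <- paired_scan(set$weather, set$phenology, tb_range = c(4, 4),
                        tu_range = c(30, 30), step = 1)
  expect_equal(c(single$t_base, single$t_upper), c(4, 30))
  expect_error(paired_scan(set$weather, set$phenology, tb_range = c(3, 26),
                           tu_range = c(25, 45)), "below")
})

test_that("subset stability reports per-subset estimates and non-convergence", {
  w <- list(a = const_series(20, "2003-03-01", days = 110),
            b = const_series(20, "2004-03-01", days = 110),
            c = const_series(20, "2005-03-01", days = 110))
  p <- list(a = season_phenology("a", "open_field", "2003-03-01",
                                 harvest = as.Date("2003-03-01") + 100),
            b = season_phenology("b", "open_field", "2004-03-01",
                                 harvest = as.Date("2004-03-01") + 100),
            c = season_phenology("c", "open_field", "2005-03-01",
                                 harvest = as.Date("2005-03-01") + 100))
  tab <- subset_stability("sd_gdd", w, p,
                          leave_out = list("a", c("a", "b")),
                          search = seq(0, 10, by = 0.5))
  expect_equal(tab$subset, c("all", "excl:a", "excl:a+b"))
  # identical seasons: identical estimates wherever >= 2 seasons remain
  expect_equal(tab$t_base[1], tab$t_base[2])
  expect_false(tab$converged[3])   # only one season left
  expect_match(tab$note[3], "fewer than 2")

  only_full <- subset_stability("sd_gdd", w, p,
                                search = seq(0, 10, by = 0.5))
  expect_equal(nrow(only_full), 1)
  expect_equal(only_full$subset, "all")

  # noiseless synthetic cultivar: every 4-season subset hits the truth
  set <- make_recovery_set(noise_sd = 0, seed = 9)
  tab2 <- subset_stability("cv_gdd", set$weather, set$phenology,
                           leave_out = as.list(names(set$weather)[1:3]),
                           search = seq(0, 10, by = 0.05))
  expect_true(all(tab2$converged))
  expect_true(all(abs(tab2$t_base - 5) < 0.5))
})
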