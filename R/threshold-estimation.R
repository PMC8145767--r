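# Cardinal-temperature estimation.
#
# Five classical criteria for the base temperature (least SD in GDD, least SD
# in days, least CV in GDD, regression-coefficient root, x-intercept of the
# development-rate regression), coefficient-of-variation scans for either
# threshold, a paired (T_b, T_u) grid search, and a season-subset stability
# table.
#
# All grid criteria use the hourly engine. For a season's hours T_1..T_n the
# uncapped degree-hour total at base b is S(b) = sum_i max(T_i - b, 0), and
# the capped total at (b, u) is exactly S(b) - S(u): hours between b and u
# contribute T - b, hours above u contribute (T - b) - (T - u) = u - b.
# S is evaluated in O(log n) per grid point from the sorted temperatures and
# their cumulative sum, which keeps 0.01 degree grids instant while remaining
# bit-faithful to the straightforward hour loop.

# Internal: per-season interval cache used by every grid criterion.
# Holds the interval's hourly temperatures (sorted plus cumulative sum),
# duration in days and interval mean temperature.
interval_cache <- function(weather_by_season, phenology_by_season,
                           from_stage = "bud_break", to_stage = "harvest") {
  ids <- intersect(names(weather_by_season), names(phenology_by_season))
  if (length(ids) < 2) {
    stop("need at least 2 seasons with both weather and phenology",
         call. = FALSE)
  }
  lapply(stats::setNames(ids, ids), function(id) {
    phen <- phenology_by_season[[id]]
    series <- weather_by_season[[id]]
    from <- stage_date(phen, from_stage)
    to <- stage_date(phen, to_stage)
    if (is.na(from) || is.na(to) || from >= to) {
      stop(sprintf("season %s: invalid %s..%s interval", id, from_stage,
                   to_stage), call. = FALSE)
    }
    t0 <- as.POSIXct(paste(from, "00:00"), tz = "UTC")
    t1 <- as.POSIXct(paste(to, "00:00"), tz = "UTC")
    idx <- which(series$time >= t0 & series$time < t1)
    n_expect <- 24L * as.integer(to - from)
    if (length(idx) != n_expect) {
      stop(sprintf("season %s: weather covers %d of %d interval hours",
                   id, length(idx), n_expect), call. = FALSE)
    }
    v <- sort(series$temp_c[idx])
    list(season = id, v = v, csum = cumsum(v), n = length(v),
         total = sum(v), d = as.integer(to - from),
         tmean = mean(series$temp_c[idx]))
  })
}

# Internal: S(x) = sum(max(T - x, 0)) for one cached season, vectorised
# over x.
excess_sum <- function(cache, x) {
  idx <- findInterval(x, cache$v)
  below <- ifelse(idx == 0, 0, cache$csum[pmax(idx, 1)])
  (cache$total - below) - x * (cache$n - idx)
}

# Internal: season GDD at base b and cap u (u may be Inf), vectorised over b
# (and u when same length).
season_gdd_at <- function(cache, b, u = Inf) {
  s <- excess_sum(cache, b)
  if (any(is.finite(u))) s <- s - ifelse(is.finite(u), excess_sum(cache, u), 0)
  s / 24
}

#' Per-season thermal summaries over a stage interval
#'
#' For each season: interval duration in days, mean hourly temperature over
#' the interval, and GDD at the supplied thresholds (hourly engine, start
#' date inclusive, end date exclusive).
#'
#' @param weather_by_season named list of [hourly_series()] keyed by season.
#' @param phenology_by_season named list of [season_phenology()] keyed by
#'   season.
#' @param thresholds a [thermal_thresholds()].
#' @param from_stage,to_stage stage names (defaults bud break to harvest).
#' @return data frame of class `season_summaries` with columns `season`,
#'   `days`, `t_mean`, `gdd`.
#' @export
summarize_seasons <- function(weather_by_season, phenology_by_season,
                              thresholds, from_stage = "bud_break",
                              to_stage = "harvest") {
  stopifnot(inherits(thresholds, "thermal_thresholds"))
  caches <- interval_cache(weather_by_season, phenology_by_season,
                           from_stage, to_stage)
  season_summaries(
    season = vapply(caches, `[[`, "", "season"),
    days = vapply(caches, `[[`, 0L, "d"),
    t_mean = vapply(caches, `[[`, 0, "tmean"),
    gdd = vapply(caches, function(cc) {
      season_gdd_at(cc, thresholds$t_base, thresholds$t_upper)
    }, 0)
  )
}

#' Construct season summaries from precomputed values
#'
#' Accepts published or otherwise precomputed per-season totals verbatim,
#' e.g. heat-requirement tables, so the variability criteria can be applied
#' without the underlying hourly records.
#'
#' @param season season ids.
#' @param days interval durations in days.
#' @param t_mean interval mean temperatures (may be `NA` when unknown).
#' @param gdd per-season degree-day totals.
#' @return data frame of class `season_summaries`.
#' @export
season_summaries <- function(season, days, gdd, t_mean = NA_real_) {
  out <- data.frame(season = as.character(season), days = as.integer(days),
                    t_mean = as.numeric(t_mean), gdd = as.numeric(gdd))
  if (any(out$days < 1, na.rm = TRUE) || any(out$gdd < 0, na.rm = TRUE)) {
    stop("season_summaries: days must be >= 1 and gdd >= 0", call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("season_summaries", "data.frame")
  out
}

#' Variability criteria across season summaries
#'
#' `criterion_sd_gdd()` is the sample standard deviation (n-1 denominator)
#' of the per-season GDD totals. `criterion_cv_gdd()` is that SD as a
#' percentage of the mean. `criterion_sd_days()` converts the GDD spread to
#' a days-equivalent by dividing by the grand mean thermal excess
#' `mean(t_mean - t_base)` across seasons.
#'
#' @param summaries a [season_summaries()] data frame (>= 2 seasons).
#' @return scalar criterion value (degree-days, percent, or days).
#' @export
criterion_sd_gdd <- function(summaries) {
  check_summaries(summaries)
  stats::sd(summaries$gdd)
}

#' @rdname criterion_sd_gdd
#' @export
criterion_cv_gdd <- function(summaries) {
  check_summaries(summaries)
  m <- mean(summaries$gdd)
  if (m <= 0) stop("criterion_cv_gdd: mean GDD is not positive", call. = FALSE)
  100 * stats::sd(summaries$gdd) / m
}

#' @rdname criterion_sd_gdd
#' @param t_base trial base temperature, degrees Celsius.
#' @export
criterion_sd_days <- function(summaries, t_base) {
  check_summaries(summaries)
  if (anyNA(summaries$t_mean)) {
    stop("criterion_sd_days: season mean temperatures required", call. = FALSE)
  }
  div <- mean(summaries$t_mean - t_base)
  if (div <= 0) {
    stop(sprintf(
      "criterion_sd_days: grand mean excess over t_base = %g is not positive",
      t_base), call. = FALSE)
  }
  stats::sd(summaries$gdd) / div
}

check_summaries <- function(summaries) {
  if (!inherits(summaries, "season_summaries")) {
    stop("expected a season_summaries object", call. = FALSE)
  }
  if (nrow(summaries) < 2) {
    stop("need at least 2 seasons", call. = FALSE)
  }
  invisible(summaries)
}

#' Classical mean-temperature GDD shortcut
#'
#' The historical approximation `days * (t_mean - t_base)` (floored at zero).
#' Used only as an independent cross-check: on constant-temperature data it
#' must agree exactly with the hourly engine.
#'
#' @param days interval duration in days.
#' @param t_mean interval mean temperature, degrees Celsius.
#' @param t_base base temperature, degrees Celsius.
#' @return degree-days.
#' @export
gdd_mean_shortcut <- function(days, t_mean, t_base) {
  pmax(days * (t_mean - t_base), 0)
}

#' A fitted cardinal-temperature estimate
#'
#' @param method estimation method label.
#' @param t_base fitted base temperature, degrees Celsius.
#' @param criterion_value criterion value at the optimum (SD in GDD, SD in
#'   days, CV percent, regression slope, or regression intercept, depending
#'   on the method).
#' @param t_upper fitted (or fixed) upper threshold; `Inf` when uncapped.
#' @return object of class `threshold_estimate`.
#' @export
threshold_estimate <- function(method, t_base, criterion_value,
                               t_upper = Inf) {
  structure(list(method = method, t_base = t_base, t_upper = t_upper,
                 criterion_value = criterion_value),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %s: T_b = %.2f C%s (criterion %.4g)\n",
              x$method, x$t_base,
              if (is.finite(x$t_upper)) sprintf(", T_u = %.2f C", x$t_upper)
              else "", x$criterion_value))
  invisible(x)
}

#' Estimate the base temperature by one of five criteria
#'
#' Grid methods (`"sd_gdd"`, `"sd_days"`, `"cv_gdd"`) minimise their
#' criterion over the search grid, with GDD computed by the hourly engine,
#' uncapped. `"re"` finds the base temperature at which the least-squares
#' slope of per-season GDD on per-season mean temperature crosses zero (grid
#' bracketing plus linear refinement of the root). `"x_intercept"` regresses
#' the development rate `1/days` on mean temperature and returns
#' `-intercept/slope` (no grid).
#'
#' @param method one of `"sd_gdd"`, `"sd_days"`, `"cv_gdd"`, `"re"`,
#'   `"x_intercept"`.
#' @param weather_by_season named list of [hourly_series()].
#' @param phenology_by_season named list of [season_phenology()].
#' @param search numeric grid of trial base temperatures, degrees Celsius.
#'   The default covers -5 to 20 at 0.01 steps, matching two-decimal
#'   reporting precision.
#' @param from_stage,to_stage stage interval (default bud break to harvest).
#' @return a [threshold_estimate()].
#' @export
estimate_tb <- function(method = c("sd_gdd", "sd_days", "cv_gdd", "re",
                                   "x_intercept"),
                        weather_by_season, phenology_by_season,
                        search = seq(-5, 20, by = 0.01),
                        from_stage = "bud_break", to_stage = "harvest") {
  method <- match.arg(method)
  caches <- interval_cache(weather_by_season, phenology_by_season,
                           from_stage, to_stage)
  tmeans <- vapply(caches, `[[`, 0, "tmean")
  ds <- vapply(caches, `[[`, 0L, "d")

  if (method == "x_intercept") {
    rate <- 1 / ds
    fit <- stats::lm(rate ~ tmeans)
    co <- stats::coef(fit)
    if (!is.finite(co[2]) || co[2] <= 0) {
      stop("estimate_tb: development-rate regression slope is not positive; no x-intercept solution",
           call. = FALSE)
    }
    return(threshold_estimate("x_intercept",
                              t_base = unname(-co[1] / co[2]),
                              criterion_value = unname(co[1])))
  }

  search <- sort(unique(as.numeric(search)))
  if (length(search) < 2) stop("estimate_tb: search grid too small",
                               call. = FALSE)
  gmat <- vapply(caches, function(cc) season_gdd_at(cc, search),
                 numeric(length(search)))    # grid x seasons
  mu <- rowMeans(gmat)
  sdv <- sqrt(rowSums((gmat - mu)^2) / (ncol(gmat) - 1))

  if (method == "re") {
    tc <- tmeans - mean(tmeans)
    slope <- as.numeric(gmat %*% tc) / sum(tc^2)
    sgn <- sign(slope)
    flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    root_at <- which(slope == 0)
    if (length(root_at) > 0) {
      tb <- search[root_at[1]]
      return(threshold_estimate("re", tb, criterion_value = 0))
    }
    if (length(flip) == 0) {
      stop("estimate_tb: regression-coefficient criterion has no sign change in the search range",
           call. = FALSE)
    }
    i <- flip[1]
    # linear refinement between the bracketing grid points
    tb <- search[i] - slope[i] * (search[i + 1] - search[i]) /
      (slope[i + 1] - slope[i])
    crit <- slope[i] + (tb - search[i]) / (search[i + 1] - search[i]) *
      (slope[i + 1] - slope[i])
    return(threshold_estimate("re", tb, criterion_value = crit))
  }

  crit <- switch(method,
    sd_gdd = sdv,
    cv_gdd = ifelse(mu > 0, 100 * sdv / mu, Inf),
    sd_days = {
      div <- mean(tmeans) - search
      ifelse(div > 0, sdv / div, Inf)
    })
  if (all(!is.finite(crit))) {
    stop(sprintf("estimate_tb: criterion '%s' undefined over the search grid",
                 method), call. = FALSE)
  }
  i <- which.min(crit)
  threshold_estimate(method, search[i], criterion_value = crit[i])
}

#' Coefficient-of-variation scan over one cardinal temperature
#'
#' Computes the CV (percent, n-1 SD) of per-season GDD at each grid value of
#' the scanned threshold. For `axis = "t_base"` the engine runs uncapped by
#' default; for `axis = "t_upper"` the base temperature must be supplied via
#' `fixed_other` (the base is selected first, then the cap is scanned with
#' the base held fixed).
#'
#' @param weather_by_season named list of [hourly_series()].
#' @param phenology_by_season named list of [season_phenology()].
#' @param axis `"t_base"` or `"t_upper"`.
#' @param fixed_other the non-scanned threshold: `NULL`/`Inf` (uncapped) for
#'   a base scan, a base temperature for an upper scan.
#' @param range length-2 numeric scan limits, degrees Celsius. Defaults:
#'   3-12 for the base, 25-45 for the cap.
#' @param step grid step, degrees Celsius (default 1).
#' @param from_stage,to_stage stage interval.
#' @return data frame of class `cv_scan_curve` with columns `temperature`
#'   and `cv_percent`.
#' @export
scan_cv <- function(weather_by_season, phenology_by_season,
                    axis = c("t_base", "t_upper"), fixed_other = NULL,
                    range = NULL, step = 1,
                    from_stage = "bud_break", to_stage = "harvest") {
  axis <- match.arg(axis)
  stopifnot(step > 0)
  if (is.null(range)) range <- if (axis == "t_base") c(3, 12) else c(25, 45)
  stopifnot(length(range) == 2, range[1] <= range[2])
  grid <- seq(range[1], range[2], by = step)
  caches <- interval_cache(weather_by_season, phenology_by_season,
                           from_stage, to_stage)
  if (axis == "t_base") {
    tu <- if (is.null(fixed_other) || identical(fixed_other, "none"))
      Inf else as.numeric(fixed_other)
    gmat <- vapply(caches, function(cc) season_gdd_at(cc, grid, tu),
                   numeric(length(grid)))
  } else {
    if (is.null(fixed_other) || identical(fixed_other, "none")) {
      stop("scan_cv: an upper-threshold scan needs fixed_other = t_base",
           call. = FALSE)
    }
    tb <- as.numeric(fixed_other)
    if (any(grid <= tb)) {
      stop("scan_cv: scanned t_upper values must exceed the fixed t_base",
           call. = FALSE)
    }
    gmat <- vapply(caches, function(cc) season_gdd_at(cc, tb, grid),
                   numeric(length(grid)))
  }
  mu <- rowMeans(gmat)
  sdv <- sqrt(rowSums((gmat - mu)^2) / (ncol(gmat) - 1))
  out <- data.frame(temperature = grid,
                    cv_percent = ifelse(mu > 0, 100 * sdv / mu, NA_real_))
  attr(out, "axis") <- axis
  attr(out, "fixed_other") <- fixed_other
  class(out) <- c("cv_scan_curve", "data.frame")
  out
}

#' @export
print.cv_scan_curve <- function(x, ...) {
  i <- which.min(x$cv_percent)
  cat(sprintf("<cv_scan_curve> axis=%s, %d points, min CV %.2f%% at %g C\n",
              attr(x, "axis"), nrow(x), x$cv_percent[i], x$temperature[i]))
  invisible(x)
}

#' Scan-curve minimum
#'
#' @param curve a `cv_scan_curve`.
#' @return list with `temperature` and `cv_percent` at the minimum.
#' @export
scan_minimum <- function(curve) {
  stopifnot(inherits(curve, "cv_scan_curve"))
  i <- which.min(curve$cv_percent)
  list(temperature = curve$temperature[i], cv_percent = curve$cv_percent[i])
}

#' Write a CV scan curve to CSV (`temperature,cv_percent`)
#'
#' @param curve a `cv_scan_curve`.
#' @param path output path.
#' @export
write_scan_csv <- function(curve, path) {
  stopifnot(inherits(curve, "cv_scan_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Joint (T_b, T_u) grid search by least CV
#'
#' Evaluates the CV of per-season GDD over the full grid of base/upper
#' pairs and returns the pair with the smallest CV. Ties are broken toward
#' the smallest base, then the smallest cap.
#'
#' @param weather_by_season named list of [hourly_series()].
#' @param phenology_by_season named list of [season_phenology()].
#' @param tb_range,tu_range length-2 numeric grid limits, degrees Celsius.
#' @param step grid step, degrees Celsius (default 1).
#' @param from_stage,to_stage stage interval.
#' @return a [threshold_estimate()] with method `"paired_scan"`.
#' @export
paired_scan <- function(weather_by_season, phenology_by_season,
                        tb_range = c(3, 12), tu_range = c(25, 45), step = 1,
                        from_stage = "bud_break", to_stage = "harvest") {
  stopifnot(step > 0, tb_range[1] <= tb_range[2], tu_range[1] <= tu_range[2])
  tb_grid <- seq(tb_range[1], tb_range[2], by = step)
  tu_grid <- seq(tu_range[1], tu_range[2], by = step)
  if (max(tb_grid) >= min(tu_grid)) {
    stop("paired_scan: every t_base must lie below every t_upper",
         call. = FALSE)
  }
  caches <- interval_cache(weather_by_season, phenology_by_season,
                           from_stage, to_stage)
  grid <- expand.grid(t_base = tb_grid, t_upper = tu_grid,
                      KEEP.OUT.ATTRS = FALSE)   # tb varies fastest
  gmat <- vapply(caches,
                 function(cc) season_gdd_at(cc, grid$t_base, grid$t_upper),
                 numeric(nrow(grid)))
  if (!is.matrix(gmat)) gmat <- matrix(gmat, nrow = 1)
  mu <- rowMeans(gmat)
  sdv <- sqrt(rowSums((gmat - mu)^2) / (ncol(gmat) - 1))
  cv <- ifelse(mu > 0, 100 * sdv / mu, Inf)
  ord <- order(grid$t_base, grid$t_upper)
  best <- ord[which(cv[ord] == min(cv))[1]]
  threshold_estimate("paired_scan", grid$t_base[best],
                     criterion_value = cv[best], t_upper = grid$t_upper[best])
}

#' Season-subset stability of a base-temperature estimate
#'
#' Re-estimates the base temperature on the full season set and on each
#' reduced set obtained by excluding the given seasons (e.g. the coolest and
#' warmest years). Subsets on which the method fails to converge are
#' reported as such rather than dropped.
#'
#' @param method estimation method passed to [estimate_tb()].
#' @param weather_by_season named list of [hourly_series()].
#' @param phenology_by_season named list of [season_phenology()].
#' @param leave_out list of character vectors of season ids to exclude; an
#'   empty list yields the full-set estimate only.
#' @param ... further arguments passed to [estimate_tb()].
#' @return data frame with one row per subset: `method`, `subset`,
#'   `t_base`, `criterion_value`, `converged`, `note`.
#' @export
subset_stability <- function(method, weather_by_season, phenology_by_season,
                             leave_out = list(), ...) {
  subsets <- c(list(character(0)), leave_out)
  labels <- vapply(subsets, function(s) {
    if (length(s) == 0) "all" else paste0("excl:", paste(s, collapse = "+"))
  }, "")
  rows <- lapply(subsets, function(excl) {
    keep <- setdiff(intersect(names(weather_by_season),
                              names(phenology_by_season)), excl)
    if (length(keep) < 2) {
      return(list(t_base = NA_real_, criterion_value = NA_real_,
                  converged = FALSE, note = "fewer than 2 seasons retained"))
    }
    est <- tryCatch(
      estimate_tb(method, weather_by_season[keep],
                  phenology_by_season[keep], ...),
      error = function(e) conditionMessage(e))
    if (is.character(est)) {
      list(t_base = NA_real_, criterion_value = NA_real_, converged = FALSE,
           note = est)
    } else {
      list(t_base = est$t_base, criterion_value = est$criterion_value,
           converged = TRUE, note = "")
    }
  })
  data.frame(method = method, subset = labels,
             t_base = vapply(rows, `[[`, 0, "t_base"),
             criterion_value = vapply(rows, `[[`, 0, "criterion_value"),
             converged = vapply(rows, `[[`, TRUE, "converged"),
             note = vapply(rows, `[[`, "", "note"),
             row.names = NULL)
}
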