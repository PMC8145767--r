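# Phenological stage records (BBCH 09 bud break, 65 full bloom, 89 harvest),
# the maturation index, and harvest calling from weekly berry samples.

#' Phenology of one season at one site
#'
#' @param season season identifier (e.g. `"2005"`).
#' @param site `"open_field"` or `"greenhouse"`.
#' @param bud_break date of BBCH stage 09 (green tissue between bud scales,
#'   50% of buds).
#' @param full_bloom date of BBCH stage 65 (50% of flowers open).
#' @param harvest date of BBCH stage 89 (beginning of harvest), or `NA` if
#'   the season is still pending.
#' @return object of class `season_phenology`.
#' @export
season_phenology <- function(season, site = c("open_field", "greenhouse"),
                             bud_break, full_bloom = NA, harvest = NA) {
  site <- match.arg(site)
  bud_break <- as.Date(bud_break)
  full_bloom <- as.Date(full_bloom)
  harvest <- as.Date(harvest)
  if (is.na(bud_break)) {
    stop("season_phenology: bud_break is required", call. = FALSE)
  }
  if (!is.na(full_bloom) && full_bloom <= bud_break) {
    stop("season_phenology: full_bloom must follow bud_break", call. = FALSE)
  }
  if (!is.na(harvest)) {
    after <- if (!is.na(full_bloom)) full_bloom else bud_break
    if (harvest <= after) {
      stop("season_phenology: harvest must follow earlier stages",
           call. = FALSE)
    }
  }
  structure(list(season = as.character(season), site = site,
                 bud_break = bud_break, full_bloom = full_bloom,
                 harvest = harvest),
            class = "season_phenology")
}

#' @export
print.season_phenology <- function(x, ...) {
  cat(sprintf("<season_phenology> %s (%s): bud break %s, bloom %s, harvest %s\n",
              x$season, x$site, format(x$bud_break),
              ifelse(is.na(x$full_bloom), "pending", format(x$full_bloom)),
              ifelse(is.na(x$harvest), "pending", format(x$harvest))))
  invisible(x)
}

# Internal: date of a named stage.
stage_date <- function(phen, stage) {
  stopifnot(stage %in% c("bud_break", "full_bloom", "harvest"))
  phen[[stage]]
}

#' Length of the growth cycle in days
#'
#' Date difference harvest minus bud break.
#'
#' @param phen a [season_phenology()] with both dates present.
#' @return integer days.
#' @export
season_length <- function(phen) {
  stopifnot(inherits(phen, "season_phenology"))
  if (is.na(phen$harvest)) {
    stop("season_length: harvest date pending", call. = FALSE)
  }
  as.integer(phen$harvest - phen$bud_break)
}

#' Maturation index
#'
#' Ratio of total soluble solids (degrees Brix) to titratable acidity
#' (grams of tartaric acid per litre). Harvest is conventionally called when
#' the index exceeds 18.
#'
#' @param tss total soluble solids, degrees Brix (> 0).
#' @param ta titratable acidity, g/L tartaric acid (> 0).
#' @return dimensionless ratio, vectorised.
#' @export
maturation_index <- function(tss, ta) {
  if (any(!is.finite(tss)) || any(!is.finite(ta)) ||
      any(tss <= 0) || any(ta <= 0)) {
    stop("maturation_index: tss and ta must be positive and finite",
         call. = FALSE)
  }
  tss / ta
}

#' Weekly maturation samples
#'
#' @param date sample dates (strictly increasing).
#' @param tss total soluble solids per sample, degrees Brix.
#' @param ta titratable acidity per sample, g/L tartaric acid.
#' @return data frame of class `maturation_samples` with a derived `mi`
#'   column.
#' @export
maturation_samples <- function(date, tss, ta) {
  date <- as.Date(date)
  if (length(date) == 0) {
    stop("maturation_samples: no samples", call. = FALSE)
  }
  if (any(diff(date) <= 0)) {
    stop("maturation_samples: sample dates must be strictly increasing",
         call. = FALSE)
  }
  out <- data.frame(date = date, tss = as.numeric(tss), ta = as.numeric(ta),
                    mi = maturation_index(tss, ta))
  class(out) <- c("maturation_samples", "data.frame")
  out
}

#' Call the harvest date from maturation samples
#'
#' Returns the date of the first sample whose maturation index crosses the
#' threshold (strictly above by default; set `strict = FALSE` for "at or
#' above"). Returns `NA` if the threshold is never reached.
#'
#' @param samples a [maturation_samples()] data frame.
#' @param threshold maturation-index threshold (default 18).
#' @param strict logical; `TRUE` requires `mi > threshold`, `FALSE` allows
#'   equality.
#' @return a `Date`, or `NA` when the index never reaches the threshold.
#' @export
call_harvest <- function(samples, threshold = 18, strict = TRUE) {
  if (!inherits(samples, "maturation_samples") || nrow(samples) == 0) {
    stop("call_harvest: expected a non-empty maturation_samples object",
         call. = FALSE)
  }
  hit <- if (strict) samples$mi > threshold else samples$mi >= threshold
  if (!any(hit)) return(as.Date(NA))
  samples$date[which(hit)[1]]
}

#' Read a phenology CSV (`season,site,bud_break,full_bloom,harvest`)
#'
#' Empty or `NA` harvest cells are read as pending.
#'
#' @param path CSV path.
#' @return named list of [season_phenology()] keyed by season id.
#' @export
read_phenology_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("season", "site", "bud_break", "full_bloom", "harvest")
  if (!all(need %in% names(raw))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  as_date_or_na <- function(x) {
    x[x %in% c("", "NA", "pending")] <- NA
    as.Date(x)
  }
  out <- lapply(seq_len(nrow(raw)), function(i) {
    season_phenology(raw$season[i], raw$site[i],
                     as_date_or_na(raw$bud_break[i]),
                     as_date_or_na(raw$full_bloom[i]),
                     as_date_or_na(raw$harvest[i]))
  })
  names(out) <- raw$season
  out
}

#' Read a maturation CSV (`season,date,tss_brix,ta_g_per_l`)
#'
#' @param path CSV path.
#' @return named list of [maturation_samples()] keyed by season id.
#' @export
read_maturation_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("season", "date", "tss_brix", "ta_g_per_l")
  if (!all(need %in% names(raw))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  split_rows <- split(raw, raw$season)
  lapply(split_rows, function(df) {
    df <- df[order(as.Date(df$date)), , drop = FALSE]
    maturation_samples(df$date, df$tss_brix, df$ta_g_per_l)
  })
}
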