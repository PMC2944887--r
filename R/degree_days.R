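#' Daily growing degree-days by the single-sine method
#'
#' Computes the thermal time accumulated over one day, in degree-days
#' (degC day), by passing a sine wave through the daily minimum and maximum
#' temperature with a fixed 12-hour spacing between them, truncating the
#' curve below the base (development) threshold and capping it above the
#' upper threshold (the "horizontal cutoff").
#'
#' Six analytic cases arise from the position of \code{tmin} and \code{tmax}
#' relative to the thresholds:
#' \enumerate{
#'   \item whole day below the base: 0;
#'   \item whole day above the cutoff: \code{upper - base};
#'   \item whole day between thresholds: \code{(tmin + tmax)/2 - base};
#'   \item curve intercepts the base only (one arcsine intercept);
#'   \item curve intercepts the cutoff only (one arcsine intercept);
#'   \item curve intercepts both thresholds (two intercepts).
#' }
#' When a temperature equals a threshold exactly, the flatter (lower-area)
#' branch applies; the integrand is continuous there, so the value is
#' unaffected.
#'
#' @param tmin,tmax Daily minimum and maximum air temperature, degC.
#'   Vectors are recycled to a common length; every \code{tmin} must not
#'   exceed its \code{tmax} and both must be finite.
#' @param base Lower (development) threshold, degC. Default 12.
#' @param upper Upper threshold (horizontal cutoff), degC. Default 38.
#'   Must exceed \code{base}.
#' @return Numeric vector of daily degree-days, each in
#'   \code{[0, upper - base]}.
#' @examples
#' daily_degree_days(14, 22)            # fully between thresholds: 6
#' daily_degree_days(8, 20)             # base intercepted: < 6
#' daily_degree_days(10, 11)            # whole day below base: 0
#' @export
daily_degree_days <- function(tmin, tmax, base = 12, upper = 38) {
  if (length(base) != 1L || length(upper) != 1L ||
      !is.finite(base) || !is.finite(upper)) {
    stop("`base` and `upper` must be single finite temperatures", call. = FALSE)
  }
  if (base >= upper) {
    stop("`base` must be strictly below `upper`", call. = FALSE)
  }
  n <- max(length(tmin), length(tmax))
  tmin <- rep_len(as.numeric(tmin), n)
  tmax <- rep_len(as.numeric(tmax), n)
  bad <- !is.finite(tmin) | !is.finite(tmax)
  if (any(bad)) {
    stop("non-finite temperature at position ", which(bad)[1L], call. = FALSE)
  }
  if (any(tmin > tmax)) {
    stop("tmin > tmax at position ", which(tmin > tmax)[1L], call. = FALSE)
  }

  m <- (tmin + tmax) / 2   # daily mean of the sine curve
  a <- (tmax - tmin) / 2   # amplitude
  dd <- numeric(n)

  below  <- tmax <= base
  above  <- tmin >= upper
  middle <- !below & !above
  inside   <- middle & tmin >= base & tmax <= upper
  int_lo   <- middle & tmin <  base & tmax <= upper
  int_hi   <- middle & tmin >= base & tmax >  upper
  int_both <- middle & tmin <  base & tmax >  upper

  dd[above]  <- upper - base
  dd[inside] <- m[inside] - base

  clamp <- function(x) pmax(-1, pmin(1, x))
  if (any(int_lo)) {
    mi <- m[int_lo]; ai <- a[int_lo]
    t1 <- asin(clamp((base - mi) / ai))
    dd[int_lo] <- ((mi - base) * (pi / 2 - t1) + ai * cos(t1)) / pi
  }
  if (any(int_hi)) {
    mi <- m[int_hi]; ai <- a[int_hi]
    t2 <- asin(clamp((upper - mi) / ai))
    dd[int_hi] <- ((mi - base) * (t2 + pi / 2) +
                     (upper - base) * (pi / 2 - t2) - ai * cos(t2)) / pi
  }
  if (any(int_both)) {
    mi <- m[int_both]; ai <- a[int_both]
    t1 <- asin(clamp((base - mi) / ai))
    t2 <- asin(clamp((upper - mi) / ai))
    dd[int_both] <- ((mi - base) * (t2 - t1) + ai * (cos(t1) - cos(t2)) +
                       (upper - base) * (pi / 2 - t2)) / pi
  }
  dd
}

#' Season window for degree-day accumulation
#'
#' @param start,end Window bounds as \code{"mm-dd"} strings; defaults
#'   March 1 to August 31, the season over which accumulation and
#'   decade temperature comparisons are computed. Day-of-year is always
#'   1-based (Jan 1 = 1) and taken from the actual calendar, so in leap
#'   years March 1 is day 61. Alignment across years is by calendar
#'   month-day, which keeps Feb 29 out of a March-onwards window.
#' @return An object of class \code{"season_window"}.
#' @export
season_window <- function(start = "03-01", end = "08-31") {
  chk <- function(x, what) {
    if (!is.character(x) || length(x) != 1L ||
        !grepl("^[0-1][0-9]-[0-3][0-9]$", x)) {
      stop("`", what, "` must be a single \"mm-dd\" string", call. = FALSE)
    }
  }
  chk(start, "start"); chk(end, "end")
  if (start >= end) stop("window start must precede end", call. = FALSE)
  structure(list(start = start, end = end), class = "season_window")
}

# All calendar dates of `window` in `year`.
window_dates <- function(window, year) {
  seq(as.Date(sprintf("%d-%s", year, window$start)),
      as.Date(sprintf("%d-%s", year, window$end)), by = "day")
}

doy_of <- function(dates) as.POSIXlt(dates)$yday + 1L
mday_of <- function(dates) format(dates, "%m-%d")

#' Seasonal cumulative growing degree-day series
#'
#' Accumulates \code{\link{daily_degree_days}} in day order across a season
#' window. A day absent from the series (or with a missing \code{tmin} or
#' \code{tmax}) contributes 0 degree-days; how many such days there are,
#' and in which months, is recorded so that years with too much missing
#' weather can be screened out by \code{\link{year_completeness_filter}}.
#'
#' @param weather Data frame with columns \code{date} (\code{Date}),
#'   \code{tmin}, \code{tmax} (degC). All dates must belong to one year.
#' @param base,upper Thresholds, degC (defaults 12 and 38).
#' @param window A \code{\link{season_window}}.
#' @param site Optional site label carried as an attribute.
#' @return A data frame of class \code{"cum_gdd"} with columns \code{doy}
#'   (1-based day-of-year), \code{mday} (\code{"mm-dd"}), \code{daily_gdd}
#'   and \code{cum_gdd}; attributes \code{site}, \code{year}, \code{base},
#'   \code{upper}, \code{n_missing} and \code{missing_by_month}.
#' @export
season_accumulation <- function(weather, base = 12, upper = 38,
                                window = season_window(), site = NA_character_) {
  stopifnot(is.data.frame(weather),
            all(c("date", "tmin", "tmax") %in% names(weather)))
  dates <- as.Date(weather$date)
  yrs <- unique(format(dates, "%Y"))
  if (length(yrs) != 1L) {
    stop("weather series must cover exactly one year (got: ",
         paste(yrs, collapse = ", "), ")", call. = FALSE)
  }
  year <- as.integer(yrs)
  all_dates <- window_dates(window, year)

  idx <- match(all_dates, dates)
  tmin <- weather$tmin[idx]
  tmax <- weather$tmax[idx]
  present <- !is.na(idx) & is.finite(tmin) & is.finite(tmax)

  daily <- numeric(length(all_dates))
  if (any(present)) {
    daily[present] <- daily_degree_days(tmin[present], tmax[present],
                                        base = base, upper = upper)
  }
  miss_month <- table(factor(format(all_dates[!present], "%m"),
                             levels = unique(format(all_dates, "%m"))))

  out <- data.frame(doy = doy_of(all_dates),
                    mday = mday_of(all_dates),
                    daily_gdd = daily,
                    cum_gdd = cumsum(daily),
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("cum_gdd", "data.frame"),
            site = site, year = year, base = base, upper = upper,
            n_missing = sum(!present),
            missing_by_month = as.integer(miss_month) |>
              stats::setNames(names(miss_month)))
}

#' @export
print.cum_gdd <- function(x, ...) {
  cat(sprintf("Cumulative GDD series: site %s, year %s, base %g / upper %g degC\n",
              attr(x, "site"), attr(x, "year"), attr(x, "base"), attr(x, "upper")))
  cat(sprintf("  %d days (%d missing), season total %.1f GDD\n",
              nrow(x), attr(x, "n_missing"), x$cum_gdd[nrow(x)]))
  invisible(x)
}

#' Mean cumulative GDD series across years
#'
#' Per-day arithmetic mean of accumulated degree-days across several years,
#' aligned by calendar month-day (so leap years line up on March 1 and
#' Feb 29 never enters a March-August window). Used to build the baseline
#' accumulation curve that resurvey years are differenced against.
#'
#' @param series_list List of \code{"cum_gdd"} objects sharing thresholds.
#' @return A \code{"cum_gdd"} object; its \code{year} attribute is \code{NA}
#'   and a \code{years} attribute lists the years averaged.
#' @export
baseline_mean_accumulation <- function(series_list) {
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  if (!all(vapply(series_list, inherits, logical(1), "cum_gdd"))) {
    stop("all elements must be cumulative GDD series", call. = FALSE)
  }
  bases <- vapply(series_list, attr, numeric(1), "base")
  uppers <- vapply(series_list, attr, numeric(1), "upper")
  if (length(unique(bases)) != 1L || length(unique(uppers)) != 1L) {
    stop("all series must use identical thresholds", call. = FALSE)
  }
  shared <- Reduce(intersect, lapply(series_list, `[[`, "mday"))
  if (length(shared) == 0L) stop("series share no days", call. = FALSE)
  cum <- vapply(series_list,
                function(s) s$cum_gdd[match(shared, s$mday)],
                numeric(length(shared)))
  cum <- if (is.null(dim(cum))) matrix(cum, nrow = length(shared)) else cum
  daily <- vapply(series_list,
                  function(s) s$daily_gdd[match(shared, s$mday)],
                  numeric(length(shared)))
  daily <- if (is.null(dim(daily))) matrix(daily, nrow = length(shared)) else daily
  first <- series_list[[1L]]
  out <- data.frame(doy = first$doy[match(shared, first$mday)],
                    mday = shared,
                    daily_gdd = rowMeans(daily),
                    cum_gdd = rowMeans(cum),
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("cum_gdd", "data.frame"),
            site = attr(first, "site"), year = NA_integer_,
            years = vapply(series_list, attr, integer(1), "year"),
            base = bases[1L], upper = uppers[1L],
            n_missing = NA_integer_, missing_by_month = NULL)
}

#' Running GDD differential between a focal year and a baseline
#'
#' Pointwise difference, on shared calendar days, between a focal year's
#' accumulated degree-days and a baseline (typically the multi-year mean
#' from \code{\link{baseline_mean_accumulation}}). Positive values mean the
#' focal season ran thermally ahead of the baseline on that day.
#'
#' @param focal,baseline \code{"cum_gdd"} objects on a shared window.
#' @return Data frame of class \code{"gdd_diff"} with columns \code{doy},
#'   \code{mday}, \code{gdd_diff}.
#' @export
running_differential <- function(focal, baseline) {
  stopifnot(inherits(focal, "cum_gdd"), inherits(baseline, "cum_gdd"))
  shared <- intersect(focal$mday, baseline$mday)
  if (length(shared) == 0L) {
    stop("focal and baseline series share no days", call. = FALSE)
  }
  out <- data.frame(doy = focal$doy[match(shared, focal$mday)],
                    mday = shared,
                    gdd_diff = focal$cum_gdd[match(shared, focal$mday)] -
                      baseline$cum_gdd[match(shared, baseline$mday)],
                    stringsAsFactors = FALSE)
  structure(out, class = c("gdd_diff", "data.frame"),
            site = attr(focal, "site"), year = attr(focal, "year"))
}

#' First day of persistent GDD divergence
#'
#' Locates the first day on which a running differential exceeds
#' \code{epsilon} and keeps exceeding it for \code{persistence} consecutive
#' days — an operational reading of the day a focal season's accumulation
#' "begins to differ" from the baseline. The persistence requirement makes
#' the day robust to single-day noise.
#'
#' @param diff A \code{"gdd_diff"} data frame (consecutive days).
#' @param epsilon Exceedance threshold, degC day (> 0). Default 5.
#' @param persistence Required run length in days (>= 1). Default 7.
#' @return Day-of-year (integer) of the first persistent exceedance, or
#'   \code{NA} if none.
#' @export
divergence_day <- function(diff, epsilon = 5, persistence = 7) {
  stopifnot(is.data.frame(diff), "gdd_diff" %in% colnames(diff) ||
              "gdd_diff" %in% names(diff))
  if (!(epsilon > 0)) stop("`epsilon` must be positive", call. = FALSE)
  persistence <- as.integer(persistence)
  if (persistence < 1L) stop("`persistence` must be >= 1", call. = FALSE)
  exc <- diff$gdd_diff > epsilon
  r <- rle(exc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0L) return(NA_integer_)
  diff$doy[starts[hit[1L]]]
}

#' Accumulated GDD on a given day
#'
#' @param series A \code{"cum_gdd"} object.
#' @param doy Day-of-year within the series support.
#' @return Accumulated degree-days at \code{doy}.
#' @export
gdd_at_day <- function(series, doy) {
  stopifnot(inherits(series, "cum_gdd"))
  i <- match(doy, series$doy)
  if (anyNA(i)) {
    stop("day-of-year ", paste(doy[is.na(i)], collapse = ", "),
         " outside the series support", call. = FALSE)
  }
  series$cum_gdd[i]
}

#' Screen years for weather completeness
#'
#' A year is retained for baseline and decade statistics only if its season
#' window is sufficiently complete: no calendar month inside the window may
#' be missing more than \code{max_monthly_missing} days, and the window as
#' a whole no more than \code{max_season_missing}. Every exclusion is
#' reported with its reason so list-style omissions are auditable.
#'
#' @param weather_by_year Named list (names = years) of weather data frames
#'   as accepted by \code{\link{season_accumulation}}, or of
#'   \code{"cum_gdd"} objects.
#' @param window A \code{\link{season_window}}.
#' @param max_monthly_missing Maximum missing days tolerated in any month
#'   (default 3).
#' @param max_season_missing Maximum missing days tolerated over the whole
#'   window (default 10).
#' @param base,upper Thresholds forwarded when raw weather is supplied.
#' @return List with \code{included} (character years) and \code{report}
#'   (data frame: year, total_missing, worst_month, worst_month_missing,
#'   included, reason).
#' @export
year_completeness_filter <- function(weather_by_year, window = season_window(),
                                     max_monthly_missing = 3,
                                     max_season_missing = 10,
                                     base = 12, upper = 38) {
  stopifnot(is.list(weather_by_year), length(weather_by_year) >= 1L,
            !is.null(names(weather_by_year)))
  rows <- lapply(names(weather_by_year), function(yr) {
    x <- weather_by_year[[yr]]
    if (!inherits(x, "cum_gdd")) {
      x <- season_accumulation(x, base = base, upper = upper, window = window)
    }
    mm <- attr(x, "missing_by_month")
    worst <- if (length(mm)) which.max(mm) else 1L
    total <- attr(x, "n_missing")
    ok_month <- all(mm <= max_monthly_missing)
    ok_season <- total <= max_season_missing
    reason <- if (!ok_month) {
      sprintf("month %s missing %d days (> %d)",
              names(mm)[worst], mm[worst], max_monthly_missing)
    } else if (!ok_season) {
      sprintf("season missing %d days (> %d)", total, max_season_missing)
    } else ""
    data.frame(year = yr, total_missing = total,
               worst_month = if (length(mm)) names(mm)[worst] else NA_character_,
               worst_month_missing = if (length(mm)) mm[[worst]] else 0L,
               included = ok_month && ok_season, reason = reason,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(included = report$year[report$included], report = report)
}

#' Mean seasonal temperature of one year
#'
#' Average of daily temperature midpoints \code{(tmin + tmax)/2} over the
#' season window; the yearly summary compared between decades by
#' \code{\link{decade_warming_test}}. Missing days are dropped from the
#' average (not imputed).
#'
#' @inheritParams season_accumulation
#' @return Mean seasonal temperature, degC.
#' @export
seasonal_mean_temperature <- function(weather, window = season_window()) {
  stopifnot(is.data.frame(weather),
            all(c("date", "tmin", "tmax") %in% names(weather)))
  dates <- as.Date(weather$date)
  year <- as.integer(format(dates[1L], "%Y"))
  keep <- dates >= as.Date(sprintf("%d-%s", year, window$start)) &
    dates <= as.Date(sprintf("%d-%s", year, window$end))
  mid <- (weather$tmin[keep] + weather$tmax[keep]) / 2
  mean(mid[is.finite(mid)])
}
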