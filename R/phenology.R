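SURVEY_STAGES <- c("i1", "i2", "i3", "i4", "i5", "adult")

#' First verified adult appearances, screening out accidentals
#'
#' Extracts, per site, species and year, the first survey date with an adult
#' record, accepting it only if a late-instar juvenile of the same species
#' was recorded at that site on or before that date in the same year.
#' Adults with no such local developmental trail are treated as accidentals
#' (e.g. individuals blown in from lower elevations) and the search advances
#' to the next adult date satisfying the rule; if none does, the species has
#' no verified first appearance that year.
#'
#' @param records Survey data frame with columns \code{site}, \code{date},
#'   \code{species}, \code{stage} (one of \code{i1}..\code{i5},
#'   \code{adult}) and \code{count}. Rows with \code{count} 0 mark visits
#'   and never count as observations.
#' @param late_instars Which instars verify residency (default 4 and 5).
#' @return Data frame with columns \code{site}, \code{species}, \code{year},
#'   \code{doy} (verified first adult day-of-year), \code{raw_doy} (first
#'   adult day before screening) and \code{adjusted} (logical). Species-years
#'   with no verified adult are absent. Attribute \code{screened} logs every
#'   adjusted or rejected first date.
#' @export
screen_accidentals <- function(records, late_instars = c(4, 5)) {
  stopifnot(is.data.frame(records),
            all(c("site", "date", "species", "stage", "count") %in%
                  names(records)))
  bad <- !(records$stage %in% SURVEY_STAGES)
  if (any(bad)) {
    stop("unknown life stage token: ", records$stage[which(bad)[1L]],
         call. = FALSE)
  }
  records$date <- as.Date(records$date)
  records$year <- as.integer(format(records$date, "%Y"))
  late_tok <- paste0("i", late_instars)

  obs <- records[records$count > 0, , drop = FALSE]
  keys <- unique(obs[obs$stage == "adult", c("site", "species", "year")])
  if (nrow(keys) == 0L) {
    return(structure(data.frame(site = character(), species = character(),
                                year = integer(), doy = integer(),
                                raw_doy = integer(), adjusted = logical()),
                     screened = data.frame()))
  }
  log <- list()
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- obs[obs$site == k$site & obs$species == k$species &
                 obs$year == k$year, , drop = FALSE]
    adult_dates <- sort(unique(sub$date[sub$stage == "adult"]))
    late_dates <- sub$date[sub$stage %in% late_tok]
    ok <- vapply(adult_dates, function(d) any(late_dates <= d), logical(1))
    raw <- doy_of(adult_dates[1L])
    if (!any(ok)) {
      log[[length(log) + 1L]] <<- data.frame(
        site = k$site, species = k$species, year = k$year,
        raw_doy = raw, action = "rejected (no late-instar trail)",
        stringsAsFactors = FALSE)
      return(NULL)
    }
    first_ok <- adult_dates[which(ok)[1L]]
    adj <- which(ok)[1L] > 1L
    if (adj) {
      log[[length(log) + 1L]] <<- data.frame(
        site = k$site, species = k$species, year = k$year,
        raw_doy = raw,
        action = sprintf("accidental screened: moved to day %d",
                         doy_of(first_ok)),
        stringsAsFactors = FALSE)
    }
    data.frame(site = k$site, species = k$species, year = k$year,
               doy = doy_of(first_ok), raw_doy = raw, adjusted = adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site = character(), species = character(),
                      year = integer(), doy = integer(),
                      raw_doy = integer(), adjusted = logical())
  }
  out <- out[order(out$site, out$species, out$year), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, screened = if (length(log)) do.call(rbind, log)
            else data.frame())
}

#' Phenological advancement relative to a baseline survey
#'
#' For each site and species, the earliest verified first-adult day over the
#' baseline years is compared with each resurvey year's first-adult day.
#' Using the baseline minimum is conservative: a resurvey date must beat the
#' earliest historical date to register as an advancement. Because the
#' baseline survey visited weekly, only shifts exceeding the sampling
#' window (default 7 days, strict inequality) count as real change.
#'
#' @param first_appearances Data frame as returned by
#'   \code{\link{screen_accidentals}} (needs \code{site}, \code{species},
#'   \code{year}, \code{doy}).
#' @param baseline_years,resurvey_years Integer vectors of years.
#' @param window_days Sampling-window half-width in days (default 7).
#' @return Data frame with \code{site}, \code{species}, \code{baseline_doy},
#'   \code{year}, \code{doy}, \code{delta} (resurvey minus baseline;
#'   negative = earlier) and \code{exceeds_window} (\code{|delta| >
#'   window_days}). Attribute \code{dropped} logs species missing from
#'   either period.
#' @export
advancement <- function(first_appearances, baseline_years, resurvey_years,
                        window_days = 7) {
  fa <- first_appearances
  stopifnot(is.data.frame(fa),
            all(c("site", "species", "year", "doy") %in% names(fa)))
  base <- fa[fa$year %in% baseline_years, , drop = FALSE]
  cur <- fa[fa$year %in% resurvey_years, , drop = FALSE]
  key <- function(d) paste(d$site, d$species, sep = "\r")
  base_min <- tapply(base$doy, key(base), min)

  dropped <- list()
  in_base <- key(cur) %in% names(base_min)
  for (k in setdiff(unique(key(cur)), names(base_min))) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    dropped[[length(dropped) + 1L]] <- data.frame(
      site = parts[1L], species = parts[2L],
      reason = "absent from baseline years", stringsAsFactors = FALSE)
  }
  for (k in setdiff(names(base_min), unique(key(cur)))) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    dropped[[length(dropped) + 1L]] <- data.frame(
      site = parts[1L], species = parts[2L],
      reason = "absent from resurvey years", stringsAsFactors = FALSE)
  }
  cur <- cur[in_base, , drop = FALSE]
  out <- data.frame(site = cur$site, species = cur$species,
                    baseline_doy = as.integer(base_min[key(cur)]),
                    year = cur$year, doy = cur$doy,
                    stringsAsFactors = FALSE)
  out$delta <- out$doy - out$baseline_doy
  out$exceeds_window <- abs(out$delta) > window_days
  out <- out[order(out$site, out$species, out$year), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dropped = if (length(dropped)) do.call(rbind, dropped)
            else data.frame())
}

#' Mean advancement at a site in one year
#'
#' @param deltas Numeric vector of per-species timing changes (days;
#'   negative = earlier).
#' @return List with \code{mean}, \code{se} (sample SD / sqrt(n); \code{NA}
#'   when n = 1) and \code{n}.
#' @export
site_mean_advancement <- function(deltas) {
  deltas <- deltas[is.finite(deltas)]
  n <- length(deltas)
  if (n == 0L) stop("no advancement records", call. = FALSE)
  list(mean = mean(deltas),
       se = if (n >= 2L) stats::sd(deltas) / sqrt(n) else NA_real_,
       n = n)
}

#' Paired test of first-adult timing between surveys
#'
#' One-sample t test on per-species differences between the mean resurvey
#' first-adult day and the baseline earliest day. Differences are oriented
#' resurvey minus baseline, so a community-wide advancement gives a
#' negative t; the p value is two-sided.
#'
#' @param baseline_doy Per-species baseline earliest first-adult days.
#' @param resurvey_mean_doy Per-species mean resurvey first-adult days,
#'   aligned with \code{baseline_doy}.
#' @return List with \code{t}, \code{df}, \code{p}, \code{mean_diff},
#'   \code{n} and \code{zero_variance} (if TRUE the t is undefined and
#'   \code{t}/\code{p} are \code{NA}).
#' @export
paired_advancement_test <- function(baseline_doy, resurvey_mean_doy) {
  stopifnot(length(baseline_doy) == length(resurvey_mean_doy))
  ok <- is.finite(baseline_doy) & is.finite(resurvey_mean_doy)
  d <- resurvey_mean_doy[ok] - baseline_doy[ok]
  n <- length(d)
  if (n < 2L) stop("need at least two paired species", call. = FALSE)
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean_diff = mean(d), n = n, zero_variance = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = mean(d), n = n, zero_variance = FALSE)
}

#' Two-sample t test of mean seasonal temperature between decades
#'
#' Pooled-variance two-sample t test comparing yearly mean seasonal
#' temperatures (see \code{\link{seasonal_mean_temperature}}) between two
#' decades; years failing the completeness screen should be removed first.
#' The reported difference is decade B minus decade A, so warming in the
#' recent decade is positive.
#'
#' @param means_a,means_b Yearly mean seasonal temperatures (degC) for
#'   decade A (historical) and decade B (recent); each needs >= 2 years.
#' @return List with \code{mean_diff} (B - A), \code{t}, \code{df} (n1 +
#'   n2 - 2) and \code{p}.
#' @export
decade_warming_test <- function(means_a, means_b) {
  means_a <- means_a[is.finite(means_a)]
  means_b <- means_b[is.finite(means_b)]
  if (length(means_a) < 2L || length(means_b) < 2L) {
    stop("need at least two years in each decade", call. = FALSE)
  }
  md <- mean(means_b) - mean(means_a)
  df <- length(means_a) + length(means_b) - 2L
  if (stats::sd(means_a) == 0 && stats::sd(means_b) == 0) {
    # no within-decade variance: t degenerates to 0 or +-Inf
    return(list(mean_diff = md,
                t = if (md == 0) 0 else Inf * sign(md),
                df = df, p = if (md == 0) 1 else 0))
  }
  tt <- stats::t.test(means_b, means_a, var.equal = TRUE)
  list(mean_diff = mean(means_b) - mean(means_a),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Advancement versus original seasonal timing
#'
#' Linear model of per-species timing change on the species' original
#' (baseline) first-adult day-of-year, with survey year as a categorical
#' covariate when more than one resurvey year is present. A negative timing
#' slope means later-season species advanced more. F tests are marginal
#' (each term after the other), so term order is irrelevant; no interaction
#' is fitted by default.
#'
#' @param data Data frame with columns \code{delta}, \code{baseline_doy}
#'   and \code{year}.
#' @param interaction Also fit and report the timing-by-year interaction
#'   (default \code{FALSE}).
#' @return List with \code{timing_slope}, \code{timing_F}, \code{timing_p},
#'   \code{year_F}, \code{year_p} (NA for single-year fits), \code{n} and
#'   the fitted \code{model}.
#' @export
advancement_timing_model <- function(data, interaction = FALSE) {
  stopifnot(is.data.frame(data),
            all(c("delta", "baseline_doy", "year") %in% names(data)))
  data <- data[is.finite(data$delta) & is.finite(data$baseline_doy), ,
               drop = FALSE]
  multi_year <- length(unique(data$year)) > 1L
  if (multi_year) {
    data$year <- stats::relevel(factor(data$year),
                                ref = as.character(min(data$year)))
    form <- if (interaction) delta ~ baseline_doy * year
            else delta ~ baseline_doy + year
  } else {
    form <- delta ~ baseline_doy
  }
  fit <- stats::lm(form, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("degenerate (collinear) design for the timing model", call. = FALSE)
  }
  dr <- stats::drop1(fit, test = "F")
  list(timing_slope = unname(stats::coef(fit)["baseline_doy"]),
       timing_F = dr["baseline_doy", "F value"],
       timing_p = dr["baseline_doy", "Pr(>F)"],
       year_F = if (multi_year) dr["year", "F value"] else NA_real_,
       year_p = if (multi_year) dr["year", "Pr(>F)"] else NA_real_,
       n = nrow(data), model = fit)
}

#' Abundance change within the overlapping sampling window
#'
#' Seasonal totals per site, species and year are computed only from records
#' inside the site's overlap window (the part of the season sampled in both
#' survey eras), then each resurvey year's total is differenced against the
#' mean of the baseline years' totals.
#'
#' @param records Survey data frame (\code{site}, \code{date},
#'   \code{species}, \code{stage}, \code{count}).
#' @param overlap_start,overlap_end Overlap window bounds, \code{"mm-dd"}.
#' @param baseline_years,resurvey_years Integer year vectors.
#' @return Data frame with \code{site}, \code{species},
#'   \code{baseline_mean}, \code{year}, \code{total} and \code{difference}
#'   (resurvey total minus baseline mean). Species absent from the baseline
#'   are excluded and logged in attribute \code{dropped}.
#' @export
abundance_change <- function(records, overlap_start, overlap_end,
                             baseline_years, resurvey_years) {
  stopifnot(is.data.frame(records),
            all(c("site", "date", "species", "count") %in% names(records)))
  records$date <- as.Date(records$date)
  records$year <- as.integer(format(records$date, "%Y"))
  md <- format(records$date, "%m-%d")
  records <- records[md >= overlap_start & md <= overlap_end, , drop = FALSE]

  tot <- stats::aggregate(count ~ site + species + year, data = records, sum)
  base <- tot[tot$year %in% baseline_years, , drop = FALSE]
  cur <- tot[tot$year %in% resurvey_years, , drop = FALSE]
  key <- function(d) paste(d$site, d$species, sep = "\r")
  # mean over baseline *years surveyed*, counting a year with no records as 0
  bm <- tapply(base$count, key(base), sum) / length(baseline_years)

  dropped <- unique(cur[!(key(cur) %in% names(bm)), c("site", "species")])
  cur <- cur[key(cur) %in% names(bm), , drop = FALSE]
  out <- data.frame(site = cur$site, species = cur$species,
                    baseline_mean = as.numeric(bm[key(cur)]),
                    year = cur$year, total = cur$count,
                    stringsAsFactors = FALSE)
  out$difference <- out$total - out$baseline_mean
  out <- out[order(out$site, out$species, out$year), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dropped = dropped)
}

#' Rank correlation between abundance change and advancement
#'
#' Spearman rank correlation (average ranks for ties) between per-species
#' abundance change and phenological timing change, paired by site, species
#' and year. Nonparametric because abundance changes span orders of
#' magnitude.
#'
#' @param changes Output of \code{\link{abundance_change}} (or any frame
#'   with \code{site}, \code{species}, \code{year}, \code{difference}).
#' @param advancements Frame with \code{site}, \code{species}, \code{year},
#'   \code{delta}.
#' @param scope \code{"pooled"} (one correlation) or \code{"per-site"}.
#' @return Data frame with \code{scope}, \code{rho}, \code{p}, \code{n} and
#'   \code{degenerate} (TRUE when a variable is constant, leaving rho
#'   undefined). For n < 4 the p value is \code{NA}.
#' @export
abundance_advancement_correlation <- function(changes, advancements,
                                              scope = c("pooled", "per-site")) {
  scope <- match.arg(scope)
  m <- merge(changes[, c("site", "species", "year", "difference")],
             advancements[, c("site", "species", "year", "delta")],
             by = c("site", "species", "year"))
  one <- function(d, label) {
    n <- nrow(d)
    if (n < 2L || stats::sd(d$difference) == 0 || stats::sd(d$delta) == 0) {
      return(data.frame(scope = label, rho = NA_real_, p = NA_real_, n = n,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(d$difference, d$delta, method = "spearman",
                      exact = FALSE))
    data.frame(scope = label, rho = unname(ct$estimate),
               p = if (n >= 4L) ct$p.value else NA_real_, n = n,
               degenerate = FALSE, stringsAsFactors = FALSE)
  }
  if (scope == "pooled") return(one(m, "pooled"))
  do.call(rbind, lapply(split(m, m$site), function(d) one(d, d$site[1L])))
}

#' Past-versus-present GDD requirement regression
#'
#' Ordinary least squares of present (resurvey mean) at-adulthood GDDs on
#' past (baseline) at-adulthood GDDs, per site, with a t test of the null
#' that the slope equals 1. A slope indistinguishable from 1 says the
#' thermal requirement of adulthood has not changed between surveys, so any
#' timing change must come from when those GDDs are reached in the season.
#'
#' @param past,present Aligned per-species GDD values (>= 3 species).
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{t_slope_eq_1}, \code{p_slope_eq_1}, \code{n} and \code{model}.
#' @export
gdd_requirement_regression <- function(past, present) {
  ok <- is.finite(past) & is.finite(present)
  past <- past[ok]; present <- present[ok]
  if (length(past) < 3L) stop("need at least three species", call. = FALSE)
  fit <- stats::lm(present ~ past)
  sm <- summary(fit)
  b <- stats::coef(fit)[["past"]]
  se_b <- sm$coefficients["past", "Std. Error"]
  # an exact fit leaves both b - 1 and its SE at rounding level
  tol <- 1e-8 * max(1, abs(b))
  tstat <- if (se_b > tol) (b - 1) / se_b
           else if (abs(b - 1) <= tol) 0 else Inf * sign(b - 1)
  df <- fit$df.residual
  list(slope = b, intercept = stats::coef(fit)[["(Intercept)"]],
       r_squared = sm$r.squared,
       t_slope_eq_1 = tstat,
       p_slope_eq_1 = 2 * stats::pt(-abs(tstat), df),
       n = length(past), model = fit)
}

#' Community GDD requirement along elevation
#'
#' OLS of site community-mean at-adulthood GDD on site elevation. The slope
#' is reported signed (GDD per metre; negative along a cooling gradient)
#' and as a magnitude.
#'
#' @param mean_gdd Community-mean at-adulthood GDD per site (>= 3 sites).
#' @param elevation Site elevations, m.
#' @return List with \code{slope} (signed), \code{slope_magnitude},
#'   \code{intercept}, \code{r_squared}, \code{p}, \code{n} and
#'   \code{model}.
#' @export
gdd_elevation_regression <- function(mean_gdd, elevation) {
  ok <- is.finite(mean_gdd) & is.finite(elevation)
  mean_gdd <- mean_gdd[ok]; elevation <- elevation[ok]
  if (length(mean_gdd) < 3L) stop("need at least three sites", call. = FALSE)
  fit <- stats::lm(mean_gdd ~ elevation)
  sm <- summary(fit)
  b <- stats::coef(fit)[["elevation"]]
  list(slope = b, slope_magnitude = abs(b),
       intercept = stats::coef(fit)[["(Intercept)"]],
       r_squared = sm$r.squared,
       p = sm$coefficients["elevation", "Pr(>|t|)"],
       n = length(mean_gdd), model = fit)
}
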