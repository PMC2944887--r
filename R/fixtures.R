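extdata <- function(file) {
  system.file("extdata", file, package = "phenogdd", mustWork = TRUE)
}

#' Packaged resurvey advancement table
#'
#' Per-species phenology of the four-site Front Range grasshopper resurvey:
#' baseline (1959-1960) earliest adult day-of-year, per-resurvey-year timing
#' changes, and baseline at-adulthood GDD requirements.
#'
#' @return Data frame; see the file header in
#'   \code{inst/extdata/advancement_table.csv} for column semantics.
#' @export
advancement_table <- function() {
  utils::read.csv(extdata("advancement_table.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Packaged resurvey abundance table
#'
#' @return Data frame of baseline mean seasonal abundances and
#'   per-resurvey-year changes; \code{verified == "no"} flags cells garbled
#'   in the printed source.
#' @export
abundance_table <- function() {
  utils::read.csv(extdata("abundance_table.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Packaged site configuration
#'
#' @return Data frame of site elevations, overlap windows and survey years;
#'   semicolon-separated year lists are returned as-is (see
#'   \code{\link{split_years}}).
#' @export
site_config <- function() {
  utils::read.csv(extdata("site_config.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Split a semicolon-separated year list
#' @param x Character vector like \code{"1959;1960"}.
#' @return List of integer vectors.
#' @export
split_years <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE), as.integer)
}

#' Advancement table in long (one row per species-year) form
#'
#' @param tab Output of \code{\link{advancement_table}} (default).
#' @param window_days Sampling-window rule, days (default 7).
#' @return Data frame with \code{site}, \code{elevation_m}, \code{species},
#'   \code{baseline_doy}, \code{year}, \code{delta}, \code{doy} and
#'   \code{exceeds_window}; unsurveyed site-years are dropped.
#' @export
advancement_long <- function(tab = advancement_table(), window_days = 7) {
  years <- c(2006, 2007, 2008)
  out <- do.call(rbind, lapply(years, function(y) {
    col <- paste0("delta_", y)
    data.frame(site = tab$site, elevation_m = tab$elevation_m,
               species = tab$species, baseline_doy = tab$baseline_doy,
               year = y, delta = tab[[col]], stringsAsFactors = FALSE)
  }))
  out <- out[is.finite(out$delta), , drop = FALSE]
  out$doy <- out$baseline_doy + out$delta
  out$exceeds_window <- abs(out$delta) > window_days
  rownames(out) <- NULL
  out
}

#' Full resurvey statistics report
#'
#' Recomputes every statistic of the resurvey analysis from the packaged
#' tables: per-site-year mean advancements with standard errors, paired
#' timing tests, sampling-window classifications, advancement-versus-timing
#' models, abundance-change rank correlations (pooled and per site), the
#' community GDD-elevation regression, and the warming speed-up
#' arithmetic (how much a fixed GDD increase shortens development,
#' as a percentage of each requirement).
#'
#' @param window_days Sampling-window rule, days (default 7).
#' @param gdd_increase GDD increase used for the speed-up example
#'   (default 30).
#' @return Nested list of statistics, ready for JSON serialisation.
#' @export
resurvey_report <- function(window_days = 7, gdd_increase = 30) {
  tab <- advancement_table()
  long <- advancement_long(tab, window_days = window_days)
  ab <- abundance_table()

  sites <- unique(tab$site)

  by_site_year <- lapply(stats::setNames(sites, sites), function(s) {
    d <- long[long$site == s, , drop = FALSE]
    lapply(stats::setNames(sort(unique(d$year)), sort(unique(d$year))),
           function(y) {
      dd <- d$delta[d$year == y]
      m <- site_mean_advancement(dd)
      c(m, list(n_exceeding = sum(abs(dd) > window_days),
                n_delayed = sum(dd > window_days),
                n_no_change = sum(abs(dd) <= window_days)))
    })
  })

  paired <- lapply(stats::setNames(sites, sites), function(s) {
    d <- long[long$site == s, , drop = FALSE]
    mean_doy <- tapply(d$doy, d$species, mean)
    base_doy <- tapply(d$baseline_doy, d$species, function(x) x[1L])
    paired_advancement_test(as.numeric(base_doy[names(mean_doy)]),
                            as.numeric(mean_doy))
  })

  timing <- lapply(stats::setNames(sites, sites), function(s) {
    d <- long[long$site == s, , drop = FALSE]
    if (length(unique(d$species)) < 3L) return(NULL)
    m <- advancement_timing_model(d)
    m$model <- NULL
    m
  })

  # abundance-change vs advancement, on verified cells only
  ab_long <- do.call(rbind, lapply(c(2006, 2007, 2008), function(y) {
    col <- paste0("diff_", y)
    data.frame(site = ab$site, species = ab$species, year = y,
               difference = ab[[col]], verified = ab$verified,
               stringsAsFactors = FALSE)
  }))
  ab_long <- ab_long[is.finite(ab_long$difference) &
                       ab_long$verified == "yes", , drop = FALSE]
  spearman <- list(
    pooled = abundance_advancement_correlation(ab_long, long, "pooled"),
    per_site = abundance_advancement_correlation(ab_long, long, "per-site"))

  comm <- tapply(tab$gdd_baseline, tab$site, mean)
  elev <- tapply(tab$elevation_m, tab$site, function(x) x[1L])
  elev_fit <- gdd_elevation_regression(as.numeric(comm),
                                       as.numeric(elev[names(comm)]))
  elev_fit$model <- NULL

  speedup <- lapply(stats::setNames(sites, sites), function(s) {
    req <- tab$gdd_baseline[tab$site == s]
    names(req) <- tab$species[tab$site == s]
    round(gdd_increase / req * 100)
  })

  list(window_days = window_days,
       site_year = by_site_year,
       paired_tests = paired,
       timing_models = timing,
       spearman = spearman,
       elevation_regression = elev_fit,
       community_mean_gdd = as.list(comm),
       speedup_pct = speedup)
}
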