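#' At-adulthood GDD table for a candidate base threshold
#'
#' For each observed first-adult event, looks up the degree-days accumulated
#' by that day of year in that year's weather, under a given base threshold.
#'
#' @param events Data frame with columns \code{species}, \code{year},
#'   \code{doy} (first-adult day-of-year); an optional \code{site} column is
#'   carried through.
#' @param weather_by_year Named list (names = years) of weather data frames
#'   or pre-computed \code{"cum_gdd"} series.
#' @param base Candidate base threshold, degC.
#' @param upper Upper threshold, degC (default 38).
#' @param window A \code{\link{season_window}}.
#' @return The \code{events} frame with an added \code{gdd} column.
#' @export
event_gdd_table <- function(events, weather_by_year, base, upper = 38,
                            window = season_window()) {
  stopifnot(is.data.frame(events),
            all(c("species", "year", "doy") %in% names(events)),
            is.list(weather_by_year), !is.null(names(weather_by_year)))
  series <- lapply(weather_by_year, function(x) {
    if (inherits(x, "cum_gdd")) x else
      season_accumulation(x, base = base, upper = upper, window = window)
  })
  yr <- as.character(events$year)
  missing_year <- !(yr %in% names(series))
  if (any(missing_year)) {
    i <- which(missing_year)[1L]
    stop(sprintf("no weather series for species '%s', year %s",
                 events$species[i], yr[i]), call. = FALSE)
  }
  events$gdd <- vapply(seq_len(nrow(events)), function(i) {
    gdd_at_day(series[[yr[i]]], events$doy[i])
  }, numeric(1))
  events
}

#' Cross-year spread of at-adulthood GDDs
#'
#' For each species, the range (maximum minus minimum across years) of its
#' at-adulthood GDD; the total over species is the objective the base
#' threshold is calibrated against. A species observed in a single year has
#' no range and contributes 0; it is retained in the per-species table for
#' reporting.
#'
#' @param table Output of \code{\link{event_gdd_table}} (needs
#'   \code{species}, \code{year}, \code{gdd}).
#' @return List with \code{per_species} (data frame: species, n_years,
#'   spread) and \code{total}.
#' @export
cross_year_spread <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("species", "year", "gdd") %in% names(table)))
  if (nrow(table) == 0L) stop("empty at-adulthood GDD table", call. = FALSE)
  sp <- split(table, table$species)
  per <- do.call(rbind, lapply(names(sp), function(s) {
    g <- sp[[s]]$gdd
    data.frame(species = s, n_years = length(unique(sp[[s]]$year)),
               spread = if (length(g) >= 2L) max(g) - min(g) else 0,
               stringsAsFactors = FALSE)
  }))
  list(per_species = per, total = sum(per$spread))
}

#' Calibrate the base development threshold
#'
#' Evaluates a grid of candidate base thresholds and selects the one whose
#' at-adulthood GDDs are most consistent across survey years: for each
#' candidate, the per-species cross-year GDD range is totalled (within each
#' site, then summed across sites when pooling) and the candidate minimising
#' that total wins. Ties resolve to the lower temperature, with a warning.
#'
#' @param events Data frame with columns \code{species}, \code{year},
#'   \code{doy}, and optionally \code{site}.
#' @param weather Weather, one of: a named list year -> weather data frame
#'   (single site), or a named list site -> (named list year -> weather
#'   data frame) matching the \code{site} column.
#' @param grid Candidate base thresholds, degC (default \code{10:17}).
#' @param upper Upper threshold, degC (default 38).
#' @param window A \code{\link{season_window}}.
#' @param scope \code{"pooled"} (default) selects from the across-site total;
#'   \code{"per-site"} also reports each site's own minimiser.
#' @return Object of class \code{"gdd_calibration"}: list with \code{grid},
#'   \code{spread} (data frame base_c x total_spread, plus one column per
#'   site), \code{selected_base}, \code{per_site_selection},
#'   \code{tables} (per-candidate at-adulthood GDD tables), \code{tie}
#'   and \code{degenerate} flags.
#' @export
select_base_threshold <- function(events, weather, grid = 10:17, upper = 38,
                                  window = season_window(),
                                  scope = c("pooled", "per-site")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(events), length(grid) >= 1L)
  grid <- sort(unique(as.numeric(grid)))
  if (any(grid >= upper)) {
    stop("all candidate bases must lie below `upper`", call. = FALSE)
  }
  if (!"site" %in% names(events)) events$site <- "site"
  # normalise weather to site -> year -> series
  nested <- is.list(weather) && all(vapply(weather, is.list, logical(1))) &&
    !any(vapply(weather, is.data.frame, logical(1)))
  if (!nested) weather <- stats::setNames(list(weather), unique(events$site)[1L])

  sites <- unique(events$site)
  if (!all(sites %in% names(weather))) {
    stop("no weather for site(s): ",
         paste(setdiff(sites, names(weather)), collapse = ", "), call. = FALSE)
  }

  tables <- vector("list", length(grid))
  names(tables) <- as.character(grid)
  spread_mat <- matrix(NA_real_, nrow = length(grid), ncol = length(sites),
                       dimnames = list(as.character(grid), sites))
  for (k in seq_along(grid)) {
    b <- grid[k]
    tabs <- lapply(sites, function(s) {
      ev <- events[events$site == s, , drop = FALSE]
      event_gdd_table(ev, weather[[s]], base = b, upper = upper, window = window)
    })
    tables[[k]] <- do.call(rbind, tabs)
    spread_mat[k, ] <- vapply(tabs, function(t) cross_year_spread(t)$total,
                              numeric(1))
  }
  totals <- rowSums(spread_mat)
  best <- which(totals == min(totals))
  tie <- length(best) > 1L
  if (tie) {
    warning("tie in total spread; selecting the lowest candidate base",
            call. = FALSE)
  }
  degenerate <- all(totals == 0)
  if (degenerate) {
    warning("all spreads are zero (single survey year?); ",
            "selection is degenerate", call. = FALSE)
  }
  per_site_sel <- vapply(sites, function(s) {
    grid[which.min(spread_mat[, s])]
  }, numeric(1))

  spread <- data.frame(base_c = grid, total_spread = totals,
                       stringsAsFactors = FALSE)
  spread <- cbind(spread, as.data.frame(spread_mat))

  structure(list(grid = grid,
                 spread = spread,
                 selected_base = grid[best[1L]],
                 per_site_selection = per_site_sel,
                 scope = scope,
                 tables = tables,
                 tie = tie,
                 degenerate = degenerate),
            class = "gdd_calibration")
}

#' @export
print.gdd_calibration <- function(x, ...) {
  cat("Base-threshold calibration\n")
  cat(sprintf("  candidates: %s degC\n", paste(x$grid, collapse = ", ")))
  cat(sprintf("  selected base: %g degC%s%s\n", x$selected_base,
              if (x$tie) " (tie, lowest chosen)" else "",
              if (x$degenerate) " [degenerate: all spreads zero]" else ""))
  print(x$spread[, c("base_c", "total_spread")], row.names = FALSE)
  invisible(x)
}
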