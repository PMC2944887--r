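#' Read a daily weather CSV
#'
#' Expects columns \code{date} (ISO-8601), \code{tmin_c}, \code{tmax_c};
#' a blank temperature cell marks that day as missing. Dates must be
#' strictly increasing and every present row must satisfy
#' \code{tmin <= tmax}; violations are reported with the offending file
#' line number (header = line 1).
#'
#' @param path Path to the CSV file.
#' @return Weather data frame with columns \code{date}, \code{tmin},
#'   \code{tmax}.
#' @export
read_weather <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("date", "tmin_c", "tmax_c")
  if (!all(need %in% names(raw))) {
    stop("weather CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable date at line ", which(is.na(dates))[1L] + 1L,
         " of ", path, call. = FALSE)
  }
  if (any(diff(dates) <= 0)) {
    stop("dates not strictly increasing at line ",
         which(diff(dates) <= 0)[1L] + 2L, " of ", path, call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  tmin <- num(raw$tmin_c); tmax <- num(raw$tmax_c)
  bad <- which(is.finite(tmin) & is.finite(tmax) & tmin > tmax)
  if (length(bad)) {
    stop("tmin > tmax at line ", bad[1L] + 1L, " of ", path, call. = FALSE)
  }
  data.frame(date = dates, tmin = tmin, tmax = tmax)
}

#' Write a daily weather CSV
#'
#' @param weather Weather data frame (\code{date}, \code{tmin},
#'   \code{tmax}).
#' @param path Output path.
#' @export
write_weather <- function(weather, path) {
  out <- data.frame(date = format(as.Date(weather$date), "%Y-%m-%d"),
                    tmin_c = weather$tmin, tmax_c = weather$tmax)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a survey-records CSV
#'
#' Expects columns \code{site}, \code{date}, \code{species}, \code{stage}
#' (one of \code{i1}..\code{i5}, \code{adult}) and \code{count}. Zero-count
#' rows are retained (they record that a visit happened). Duplicate
#' (site, date, species, stage) rows are summed with a warning.
#'
#' @param path Path to the CSV file.
#' @return Survey records data frame.
#' @export
read_survey <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "date", "species", "stage", "count")
  if (!all(need %in% names(raw))) {
    stop("survey CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(raw$stage %in% SURVEY_STAGES)
  if (any(bad)) {
    stop("unknown stage token '", raw$stage[which(bad)[1L]], "' at line ",
         which(bad)[1L] + 1L, " of ", path, call. = FALSE)
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("unparseable date at line ", which(is.na(dates))[1L] + 1L,
         " of ", path, call. = FALSE)
  }
  raw$date <- dates
  if (anyNA(raw$count) || any(raw$count < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  key <- paste(raw$site, raw$date, raw$species, raw$stage)
  if (anyDuplicated(key)) {
    warning("duplicate (site, date, species, stage) rows summed",
            call. = FALSE)
    agg <- stats::aggregate(count ~ site + date + species + stage,
                            data = raw, sum)
    raw <- agg[order(agg$site, agg$date, agg$species, agg$stage), ]
    rownames(raw) <- NULL
  }
  raw[, need]
}

#' Write a survey-records CSV
#'
#' @param records Survey records data frame.
#' @param path Output path.
#' @export
write_survey <- function(records, path) {
  out <- records[, c("site", "date", "species", "stage", "count")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a cumulative GDD (or differential) series as CSV
#'
#' Columns \code{site}, \code{year}, \code{doy} plus \code{cum_gdd} or
#' \code{gdd_diff}; day-of-year is 1-based (Jan 1 = 1).
#'
#' @param series A \code{"cum_gdd"} or \code{"gdd_diff"} object.
#' @param path Output path.
#' @export
write_gdd_series <- function(series, path) {
  val <- if ("cum_gdd" %in% names(series)) "cum_gdd" else "gdd_diff"
  out <- data.frame(site = attr(series, "site"),
                    year = attr(series, "year"),
                    doy = series$doy)
  out[[val]] <- series[[val]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
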