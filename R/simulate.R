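#' Site climate parameters for the weather generator
#'
#' Describes a site's seasonal temperature climatology: a sinusoidal annual
#' cycle around an elevation-adjusted mean, a fixed diurnal range, and
#' independent day-to-day noise. Defaults emulate a Front Range montane
#' grassland: reference-elevation annual mean 11 degC, seasonal amplitude
#' 12 degC with the maximum near day 200 (mid-July), diurnal range 14 degC,
#' and an environmental lapse rate of 0.0065 degC per metre above the
#' 1752 m reference.
#'
#' @param site Site label.
#' @param elevation Elevation, m.
#' @param annual_mean Annual mean temperature at the reference elevation,
#'   degC.
#' @param amplitude Seasonal (annual-cycle) amplitude, degC (> 0).
#' @param diurnal_range Daily max minus min, degC (> 0).
#' @param lapse_rate Temperature lapse, degC per metre (default 0.0065).
#' @param reference_elevation Elevation at which \code{annual_mean} applies,
#'   m (default 1752).
#' @param noise_sd Day-to-day noise SD on the daily mean, degC (>= 0).
#' @param peak_doy Day-of-year of the seasonal temperature maximum
#'   (default 200).
#' @return Object of class \code{"climate_params"}.
#' @export
climate_params <- function(site = "S1", elevation = 2000, annual_mean = 11,
                           amplitude = 12, diurnal_range = 14,
                           lapse_rate = 0.0065, reference_elevation = 1752,
                           noise_sd = 2, peak_doy = 200) {
  stopifnot(amplitude > 0, diurnal_range > 0, noise_sd >= 0, elevation > 0)
  structure(list(site = site, elevation = elevation,
                 annual_mean = annual_mean, amplitude = amplitude,
                 diurnal_range = diurnal_range, lapse_rate = lapse_rate,
                 reference_elevation = reference_elevation,
                 noise_sd = noise_sd, peak_doy = peak_doy),
            class = "climate_params")
}

#' Warming scenario with seasonal onset timing
#'
#' A seasonal warming offset added to the daily mean temperature: zero
#' before \code{onset_doy}, ramping linearly over \code{ramp_days} to the
#' full \code{amount} and holding it thereafter. With \code{onset_doy =
#' NULL} the full amount applies uniformly from the start of the year —
#' the timing of onset, not just the amount, is what differentiates which
#' species advance.
#'
#' @param amount Warming amount, degC (0 = control).
#' @param onset_doy Day-of-year at which warming begins, or \code{NULL}
#'   for uniform warming.
#' @param ramp_days Length of the linear ramp to full amount, days (>= 0).
#' @return Object of class \code{"warming_scenario"}.
#' @export
warming_scenario <- function(amount = 0, onset_doy = NULL, ramp_days = 0) {
  stopifnot(ramp_days >= 0)
  structure(list(amount = amount, onset_doy = onset_doy,
                 ramp_days = ramp_days),
            class = "warming_scenario")
}

scenario_offset <- function(scenario, doy) {
  if (scenario$amount == 0) return(rep(0, length(doy)))
  if (is.null(scenario$onset_doy)) return(rep(scenario$amount, length(doy)))
  frac <- if (scenario$ramp_days == 0) {
    as.numeric(doy >= scenario$onset_doy)
  } else {
    pmin(1, pmax(0, (doy - scenario$onset_doy) / scenario$ramp_days))
  }
  scenario$amount * frac
}

#' Generate one year of synthetic daily weather
#'
#' Daily mean temperature = elevation-adjusted annual mean + seasonal
#' sinusoid + warming-scenario offset + Gaussian day-to-day noise;
#' \code{tmin}/\code{tmax} sit half a diurnal range below/above the mean,
#' so \code{tmin <= tmax} always. Output is bitwise reproducible from the
#' seed.
#'
#' @param params A \code{\link{climate_params}} object.
#' @param year Calendar year to generate.
#' @param scenario A \code{\link{warming_scenario}} (default: control).
#' @param seed Integer seed.
#' @return Weather data frame (\code{date}, \code{tmin}, \code{tmax}) for
#'   the full calendar year.
#' @export
generate_weather <- function(params, year, scenario = warming_scenario(0),
                             seed = 1) {
  stopifnot(inherits(params, "climate_params"),
            inherits(scenario, "warming_scenario"))
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  doy <- doy_of(dates)
  ndays <- length(dates)
  site_mean <- params$annual_mean -
    params$lapse_rate * (params$elevation - params$reference_elevation)
  seasonal <- params$amplitude *
    cos(2 * pi * (doy - params$peak_doy) / ndays)
  noise <- if (params$noise_sd > 0) {
    set.seed(seed)
    stats::rnorm(ndays, 0, params$noise_sd)
  } else {
    rep(0, ndays)
  }
  daily_mean <- site_mean + seasonal + scenario_offset(scenario, doy) + noise
  data.frame(date = dates,
             tmin = daily_mean - params$diurnal_range / 2,
             tmax = daily_mean + params$diurnal_range / 2)
}

#' Species profile for the survey generator
#'
#' @param species Species name.
#' @param gdd_requirement Cumulative GDD at which adults appear, degC day
#'   (> 0). The defaults used across scenarios span the range observed in
#'   montane grasshopper communities (roughly 100-500 GDD).
#' @param abundance Expected count per visit at peak (negative-binomial
#'   mean).
#' @param detectability Per-visit probability an emerged adult is detected
#'   (default 1).
#' @param dispersion Negative-binomial size parameter (default 5;
#'   overdispersed counts, matching order-of-magnitude abundance variation
#'   in field totals).
#' @return Object of class \code{"species_profile"}.
#' @export
species_profile <- function(species, gdd_requirement, abundance = 50,
                            detectability = 1, dispersion = 5) {
  stopifnot(gdd_requirement > 0, abundance > 0,
            detectability > 0, detectability <= 1, dispersion > 0)
  structure(list(species = species, gdd_requirement = gdd_requirement,
                 abundance = abundance, detectability = detectability,
                 dispersion = dispersion),
            class = "species_profile")
}

#' True adult onset day under a GDD requirement
#'
#' First day-of-year on which the season's cumulative GDD reaches the
#' requirement; \code{NA} if the season never accumulates that much.
#'
#' @param cum A \code{"cum_gdd"} series.
#' @param requirement GDD requirement, degC day.
#' @return Day-of-year or \code{NA}.
#' @export
adult_onset_day <- function(cum, requirement) {
  i <- which(cum$cum_gdd >= requirement)
  if (length(i) == 0L) return(NA_integer_)
  cum$doy[i[1L]]
}

#' Generate weekly survey records from synthetic weather
#'
#' Emulates weekly sweep-net surveys of univoltine, egg-diapausing species
#' whose adult appearance is triggered by crossing a species-specific
#' cumulative-GDD requirement. On each visit, a species is recorded as a
#' late-instar juvenile while its accumulated GDD lies between 60% and 100%
#' of its requirement (instar 4 below 80%, instar 5 above), and as an adult
#' once the requirement is met, subject to per-visit detectability. Counts
#' are negative-binomial.
#'
#' @param weather Weather data frame for one year.
#' @param species List of \code{\link{species_profile}} objects.
#' @param base,upper GDD thresholds, degC (defaults 12, 38).
#' @param window A \code{\link{season_window}}.
#' @param visit_every Days between visits (default 7).
#' @param first_visit_doy Day-of-year of the first visit (default: first
#'   window day).
#' @param seed Integer seed for counts and detection.
#' @return Survey records data frame (\code{site}, \code{date},
#'   \code{species}, \code{stage}, \code{count}) with attribute
#'   \code{true_onsets} (data frame species, onset_doy).
#' @export
generate_survey <- function(weather, species, base = 12, upper = 38,
                            window = season_window(), visit_every = 7,
                            first_visit_doy = NULL, seed = 1,
                            site = "S1") {
  stopifnot(is.list(species), length(species) >= 1L)
  if (inherits(species, "species_profile")) species <- list(species)
  cum <- season_accumulation(weather, base = base, upper = upper,
                             window = window, site = site)
  year <- attr(cum, "year")
  if (is.null(first_visit_doy)) first_visit_doy <- cum$doy[1L]
  visits <- seq(first_visit_doy, cum$doy[nrow(cum)], by = visit_every)
  visits <- visits[visits %in% cum$doy]

  set.seed(seed)
  rows <- list()
  onsets <- list()
  for (sp in species) {
    onset <- adult_onset_day(cum, sp$gdd_requirement)
    onsets[[length(onsets) + 1L]] <- data.frame(
      species = sp$species, onset_doy = onset, stringsAsFactors = FALSE)
    cg <- gdd_at_day(cum, visits)
    frac <- cg / sp$gdd_requirement
    for (k in seq_along(visits)) {
      v <- visits[k]
      if (frac[k] >= 1) {
        if (stats::runif(1) <= sp$detectability) {
          cnt <- stats::rnbinom(1, size = sp$dispersion, mu = sp$abundance)
          rows[[length(rows) + 1L]] <- data.frame(
            site = site, doy = v, species = sp$species, stage = "adult",
            count = max(1L, cnt), stringsAsFactors = FALSE)
        }
      } else if (frac[k] >= 0.6) {
        stage <- if (frac[k] >= 0.8) "i5" else "i4"
        cnt <- stats::rnbinom(1, size = sp$dispersion, mu = sp$abundance)
        rows[[length(rows) + 1L]] <- data.frame(
          site = site, doy = v, species = sp$species, stage = stage,
          count = max(1L, cnt), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = character(), doy = integer(), species = character(),
               stage = character(), count = integer())
  out$date <- as.Date(out$doy - 1L, origin = sprintf("%d-01-01", year))
  out <- out[, c("site", "date", "species", "stage", "count")]
  structure(out, true_onsets = do.call(rbind, onsets))
}

#' Warming-timing scenario with an early and a late species
#'
#' Demonstrates the seasonal-onset mechanism: the same amount of warming
#' advances different parts of the community depending on when in the
#' season it ramps up. Three years are generated for one site — a control,
#' a year with early-onset warming and a year with late-onset warming —
#' and an early species (default 100 GDD) and a late species (default 500
#' GDD) are surveyed weekly in each. Early-onset warming accelerates both
#' species; warming that starts only after the early species has already
#' emerged can advance only the late one.
#'
#' @param params A \code{\link{climate_params}} (default: a lower-montane
#'   site whose season comfortably exceeds the late species' requirement).
#' @param early_requirement,late_requirement GDD requirements (defaults
#'   100 and 500).
#' @param amount Warming amount, degC (default 3).
#' @param early_onset_doy Onset day of the early-warming year (default 60,
#'   the start of the season window).
#' @param late_onset_doy Onset day of the late-warming year (default: the
#'   control onset day of the early species, so the early species is
#'   unaffected).
#' @param ramp_days Warming ramp length, days (default 10).
#' @param seed Integer seed.
#' @param base,upper GDD thresholds.
#' @return List with \code{advancement} (data frame: species, scenario,
#'   control_doy, warmed_doy, delta, exceeds_window), the three
#'   \code{onsets}, and the \code{late_onset_doy} used.
#' @export
fig_warming_timing_scenario <- function(params = climate_params(
                                          site = "A", elevation = 2195,
                                          noise_sd = 1.5),
                                        early_requirement = 100,
                                        late_requirement = 500,
                                        amount = 3,
                                        early_onset_doy = 60,
                                        late_onset_doy = NULL,
                                        ramp_days = 10, seed = 1,
                                        base = 12, upper = 38) {
  window <- season_window()
  species <- list(
    species_profile("early_sp", early_requirement),
    species_profile("late_sp", late_requirement))

  run_year <- function(year, scenario, seed_off) {
    yr_seed <- seed + 1000L * seed_off
    w <- generate_weather(params, year, scenario, seed = yr_seed)
    sv <- generate_survey(w, species, base = base, upper = upper,
                          window = window, seed = yr_seed,
                          site = params$site)
    fa <- screen_accidentals(sv)
    stats::setNames(fa$doy[match(c("early_sp", "late_sp"), fa$species)],
                    c("early_sp", "late_sp"))
  }

  control <- run_year(2001, warming_scenario(0), 0)
  if (is.null(late_onset_doy)) late_onset_doy <- unname(control["early_sp"])
  early_warm <- run_year(2002, warming_scenario(amount, early_onset_doy,
                                                ramp_days), 1)
  late_warm <- run_year(2003, warming_scenario(amount, late_onset_doy,
                                               ramp_days), 2)

  adv <- rbind(
    data.frame(species = names(control), scenario = "early_onset",
               control_doy = unname(control),
               warmed_doy = unname(early_warm)),
    data.frame(species = names(control), scenario = "late_onset",
               control_doy = unname(control),
               warmed_doy = unname(late_warm)))
  adv$delta <- adv$warmed_doy - adv$control_doy
  adv$exceeds_window <- abs(adv$delta) > 7
  list(advancement = adv,
       onsets = list(control = control, early_onset = early_warm,
                     late_onset = late_warm),
       late_onset_doy = late_onset_doy)
}

#' Parameter-recovery experiment for base-threshold calibration
#'
#' Simulates the calibration problem end to end: two survey years of
#' synthetic weather are generated with independent day-to-day noise and a
#' fixed climatological contrast between the years, species' first-adult
#' days are set by crossing their GDD requirements under a known true base
#' threshold, and \code{\link{select_base_threshold}} is asked to recover
#' that base from the events alone. Repeated over seeds, the modal selected
#' base should equal the true one.
#'
#' Identifiability needs both ends of the season: early species (small
#' requirements, small daily increments at their onset) separate adjacent
#' candidate bases, while late species (onsets in mid-to-late summer)
#' penalise candidate bases far above the truth, whose accumulation would
#' otherwise be too sparse to discriminate. The default community therefore
#' spans requirements from 50 to 650 degC day, and the two years differ by
#' 3 degC in annual mean — without a real between-year weather difference
#' the objective is flat and no threshold is identifiable.
#'
#' @param true_base True base threshold used to generate events, degC.
#' @param seeds Integer vector of simulation seeds (default \code{1:20}).
#' @param params Site climatology (default: a lower-montane site with
#'   1 degC daily noise).
#' @param requirements Species GDD requirements (default eleven species,
#'   50-650 degC day; species a year cannot support are dropped for that
#'   year).
#' @param grid Candidate bases offered to the selector (default
#'   \code{10:17}).
#' @param upper Upper threshold, degC.
#' @param year_contrast Annual-mean difference between the two survey
#'   years, degC (default 3, applied symmetrically).
#' @return List with \code{true_base}, \code{selected} (per seed),
#'   \code{modal} and \code{recovery_rate}.
#' @export
calibration_recovery <- function(true_base, seeds = 1:20,
                                 params = climate_params(site = "S",
                                                         elevation = 2195,
                                                         noise_sd = 1),
                                 requirements = seq(50, 650, by = 60),
                                 grid = 10:17, upper = 38,
                                 year_contrast = 3) {
  run_one <- function(s) {
    yr_means <- params$annual_mean + c(-0.5, 0.5) * year_contrast
    weather <- list()
    events <- list()
    for (j in 1:2) {
      p <- params
      p$annual_mean <- yr_means[j]
      w <- generate_weather(p, 2000 + j, seed = s * 10L + j)
      weather[[as.character(2000 + j)]] <- w
      cum <- season_accumulation(w, base = true_base, upper = upper)
      events[[j]] <- data.frame(
        species = paste0("sp", seq_along(requirements)),
        year = 2000 + j,
        doy = vapply(requirements, function(r) adult_onset_day(cum, r),
                     integer(1)),
        stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, events)
    ev <- ev[is.finite(ev$doy), , drop = FALSE]
    select_base_threshold(ev, weather, grid = grid, upper = upper)$selected_base
  }
  selected <- vapply(seeds, run_one, numeric(1))
  tab <- table(selected)
  list(true_base = true_base, selected = selected,
       modal = as.numeric(names(tab)[which.max(tab)]),
       recovery_rate = mean(selected == true_base))
}

#' Simulate a full baseline-plus-resurvey study
#'
#' Runs the whole pipeline on synthetic data for one community: weekly
#' surveys in two baseline years (control climate) and in each resurvey
#' year (under a warming scenario), accidental screening, and advancement
#' relative to the earliest baseline appearance. Visit schedules share one
#' day-of-year grid across years so that timing changes are attributable to
#' phenology, not to shifted sampling.
#'
#' @param seed Integer seed; every year draws its own sub-seed from it.
#' @param params Site climatology (default: a lower-montane site,
#'   1.5 degC daily noise).
#' @param requirements Community GDD requirements (default six species,
#'   100-600 degC day).
#' @param scenario Warming scenario applied to resurvey years (default:
#'   none — a null resurvey).
#' @param baseline_years,resurvey_years Calendar years (defaults 1959-1960
#'   and 2006-2008).
#' @param base,upper GDD thresholds.
#' @param window A \code{\link{season_window}}.
#' @param first_visit_doy Shared first-visit day-of-year (default 61).
#' @return The \code{\link{advancement}} table for the resurvey years, with
#'   attribute \code{first_appearances}.
#' @export
simulate_resurvey <- function(seed = 1,
                              params = climate_params(site = "S",
                                                      elevation = 2195,
                                                      noise_sd = 1.5),
                              requirements = seq(100, 600, by = 100),
                              scenario = warming_scenario(0),
                              baseline_years = c(1959, 1960),
                              resurvey_years = c(2006, 2007, 2008),
                              base = 12, upper = 38,
                              window = season_window(),
                              first_visit_doy = 61) {
  species <- lapply(seq_along(requirements), function(i) {
    species_profile(sprintf("sp%02d", i), requirements[i])
  })
  years <- c(baseline_years, resurvey_years)
  ctrl <- warming_scenario(0)
  records <- do.call(rbind, lapply(seq_along(years), function(k) {
    y <- years[k]
    sc <- if (y %in% resurvey_years) scenario else ctrl
    yr_seed <- seed * 100L + k
    w <- generate_weather(params, y, sc, seed = yr_seed)
    generate_survey(w, species, base = base, upper = upper, window = window,
                    first_visit_doy = first_visit_doy, seed = yr_seed,
                    site = params$site)
  }))
  fa <- screen_accidentals(records)
  adv <- advancement(fa, baseline_years, resurvey_years)
  attr(adv, "first_appearances") <- fa
  adv
}
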