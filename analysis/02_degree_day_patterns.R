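#!/usr/bin/env Rscript
# Builds the baseline-versus-resurvey GDD accumulation comparison on
# synthetic weather: a two-year baseline mean, three warmed resurvey years
# whose warming ramps up at different points in the season, the running
# GDD differentials, and the day each differential becomes persistent.

library(phenogdd)
dir.create("results", showWarnings = FALSE)

p <- climate_params(site = "B1", elevation = 2591, noise_sd = 1.5)

baseline <- baseline_mean_accumulation(lapply(1:2, function(j) {
  season_accumulation(generate_weather(p, 1958 + j, seed = 600 + j),
                      site = "B1")
}))

onsets <- c(`2006` = 130, `2007` = 165, `2008` = 175)
rows <- list()
div <- list()
for (yr in names(onsets)) {
  w <- generate_weather(p, as.integer(yr),
                        warming_scenario(1.5, onset_doy = onsets[[yr]],
                                         ramp_days = 20),
                        seed = 700 + as.integer(yr) - 2005)
  cs <- season_accumulation(w, site = "B1")
  d <- running_differential(cs, baseline)
  rows[[yr]] <- data.frame(site = "B1", year = as.integer(yr),
                           doy = d$doy, gdd_diff = d$gdd_diff)
  div[[yr]] <- data.frame(year = as.integer(yr),
                          warming_onset_doy = onsets[[yr]],
                          divergence_doy = divergence_day(d),
                          season_surplus_gdd = round(d$gdd_diff[nrow(d)], 1))
}
write.csv(do.call(rbind, rows), "results/gdd_differentials.csv",
          row.names = FALSE)
div_tab <- do.call(rbind, div)
write.csv(div_tab, "results/divergence_days.csv", row.names = FALSE)

cat("Running-differential divergence under late-shifting warming onsets:\n")
print(div_tab, row.names = FALSE)
cat("\nThe persistent-divergence day tracks the configured warming onset:\n",
    "warming later in the season leaves early-season accumulation\n",
    "indistinguishable from the baseline.\n")
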