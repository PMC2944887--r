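#!/usr/bin/env Rscript
# The warming-timing mechanism, end to end on synthetic data:
# (1) null fidelity - with no warming, no species-year change exceeds the
#     weekly sampling window;
# (2) late-onset warming - later-developing species advance more, giving a
#     negative advancement-versus-original-timing slope;
# (3) a two-species scenario - early-onset warming advances both a 100- and
#     a 500-GDD species, late-onset warming only the late one.

library(phenogdd)
dir.create("results", showWarnings = FALSE)

seeds <- 1:20

null_max <- vapply(seeds, function(s) {
  max(abs(simulate_resurvey(seed = s)$delta))
}, numeric(1))

slopes <- vapply(seeds, function(s) {
  adv <- simulate_resurvey(seed = s,
                           scenario = warming_scenario(2.5, onset_doy = 165,
                                                       ramp_days = 15))
  advancement_timing_model(adv)$timing_slope
}, numeric(1))

sc <- fig_warming_timing_scenario(seed = 1)
write.csv(sc$advancement, "results/warming_timing_scenario.csv",
          row.names = FALSE)
write.csv(data.frame(seed = seeds, null_max_abs_delta = null_max,
                     late_onset_timing_slope = slopes),
          "results/warming_timing_experiments.csv", row.names = FALSE)

cat(sprintf("Null resurvey: max |timing change| = %d days over %d seeds (window = 7).\n",
            max(null_max), length(seeds)))
cat(sprintf("Late-onset warming: timing slope negative in %.0f%% of seeds (mean %.3f d/d).\n",
            100 * mean(slopes < 0), mean(slopes)))
cat("\nTwo-species scenario (deltas in days vs control year):\n")
print(sc$advancement, row.names = FALSE)
cat("\nEarly-onset warming advances both species beyond the sampling window;\n",
    "warming that starts after the early species' emergence advances only\n",
    "the late-season species.\n")
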