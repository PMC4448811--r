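#!/usr/bin/env Rscript

# Simulation 2: population response magnitude and sparseness as a function
# of stimulus centre frequency, with the contrast-sensitivity prefilter on.
#
# Produces the tuning-curve table behind the central figure: total response
# magnitude and excess kurtosis for sine gratings and filtered noise across
# a 9-point frequency grid, with the surrogate natural-image baseline. At
# the defaults the magnitude peaks at 2 c/deg for both classes -- the
# midrange band where striped patterns are judged most uncomfortable --
# while the kurtosis valley is broad over 2-4 c/deg.
#
# Scale: 20 000 neurons per stimulus and 10 noise instances per frequency,
# where the extremum locations have stabilized (the full-scale run with
# 250 000 neurons only narrows the error bars).

library(gaborpop)

dir.create("results", showWarnings = FALSE)

cfg <- experiment_config(
  simulation = 2,
  n_neurons = 20000,
  n_noise_seeds = 10,
  n_surrogate_images = 20,
  seed = 2026
)
res <- run_simulation(cfg)
print(res)

write.csv(res$table, "results/sim2_tuning_curves.csv", row.names = FALSE)
write.csv(res$details, "results/sim2_details.csv", row.names = FALSE)

for (cls in c("grating", "noise")) {
  ex <- tuning_extrema(res, cls)
  cat(sprintf(
    "%s: magnitude peak %.3g c/deg, kurtosis minimum %.3g c/deg\n",
    cls, ex$magnitude_peak, ex$kurtosis_min
  ))
}
base <- res$table[res$table$class == "surrogate", ]
cat(sprintf(
  "surrogate baseline: magnitude %.4g, kurtosis %.3g\n",
  base$mean_total_magnitude, base$mean_excess_kurtosis
))
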