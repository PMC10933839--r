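#!/usr/bin/env Rscript

# Step 2: microscopic input curves for the hydrodynamic scaling model.
#
# Two-filament simulations of clusters with 3, 4 and 8 heads over a
# logarithmic ATP grid give the strain rate epsilon([ATP]) and crosslink
# probability P_cl([ATP]); single-filament runs quantify how valency trades
# speed against processivity.
#
# Reads:  results/calibrated_rates.csv (step 1; falls back to re-running it)
# Writes: results/microscopic_curves.csv, results/valency_motility.csv

library(actonem)

dir.create("results", showWarnings = FALSE)
if (!file.exists("results/calibrated_rates.csv"))
  source("analysis/01_calibrate_motor.R")
rr <- read.csv("results/calibrated_rates.csv")
rates <- rate_constants(rr$k12, rr$k23, rr$k31_per_atp)
print(rates)

grid <- atp_grid_default(n = 20)
curves <- do.call(rbind, lapply(c(3, 4, 8), function(n) {
  message("two-filament sweep, valency ", n, " ...")
  mc <- sweep_atp(cluster_config(n), rates, grid, reps = 30, seed = 2,
                  t_max = 50, normalize = TRUE)
  cbind(n_heads = n, as.data.frame(mc))
}))
write.csv(curves, "results/microscopic_curves.csv", row.names = FALSE)

message("single-filament motility versus valency at 100 uM ATP ...")
valency <- do.call(rbind, lapply(c(3, 4, 8), function(n) {
  cl <- cluster_config(n)
  st <- single_filament_summary(
    simulate_ensemble(cl, rates, atp = 100, t_max = 50, reps = 30, seed = 3), cl)
  data.frame(n_heads = n, velocity = st$velocity, run_length = st$run_length,
             se_velocity = st$se_velocity, se_run_length = st$se_run_length)
}))
print(valency, digits = 3)
message("speed falls and processivity rises with valency: ",
        all(diff(valency$velocity) < 0) && all(diff(valency$run_length) > 0))
write.csv(valency, "results/valency_motility.csv", row.names = FALSE)

p38 <- sapply(split(curves$p_cl, curves$n_heads), mean)
message(sprintf("mean P_cl by valency: n3 = %.2f, n4 = %.2f, n8 = %.2f",
                p38[["3"]], p38[["4"]], p38[["8"]]))
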