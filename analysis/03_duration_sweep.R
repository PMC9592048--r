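#!/usr/bin/env Rscript
# Pre-optimization duration sweep: how much endurance-bout walking data does
# the PI+IMU model need? Each candidate duration (first d seconds of the
# 360 s bout) is scored by seed-averaged LOSO weighted F1 with default
# hyperparameters and no feature selection or tuning.

suppressPackageStartupMessages(library(gaitprog))
dir.create("results", showWarnings = FALSE)

co <- simulate_cohort(cohort_config(seed = 7))
sw <- run_duration_sweep(co, durations = c(10, 20, 30, 60, 120, 240, 360),
                         variant = "PI+IMU", n_seeds = 5)
write.csv(sw$table, "results/duration_sweep.csv", row.names = FALSE)

print(round(sw$table, 3), row.names = FALSE)
cat("\nSelected duration:", sw$duration, "s (ties go to the shorter bout).\n")
cat("Under the default generator the class signal is near-stationary over\n",
    "the bout (mild fatigue drift), so short and long durations perform\n",
    "within each other's seed-variability bands and a short bout suffices.\n")
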