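#!/usr/bin/env Rscript
# Extract the 71-feature table (9 PI + 5 FA + 57 IMU magnitude features)
# under both walking paradigms: the fixed 10 m distance and the first 60 s
# of the endurance bout.

suppressPackageStartupMessages(library(gaitprog))
dir.create("results", showWarnings = FALSE)

co <- simulate_cohort(cohort_config(seed = 7))

ft_dist <- extract_feature_table(co, bout_spec("fixed_distance"))
write_feature_csv(ft_dist, "results/features_fixed_distance.csv")
ft_dur <- extract_feature_table(co, bout_spec("fixed_duration", duration_s = 60))
write_feature_csv(ft_dur, "results/features_fixed_duration_60.csv")

cat("Fixed-distance table:", nrow(ft_dist), "x", ncol(ft_dist), "\n")
cat("Fixed-duration (60 s) table:", nrow(ft_dur), "x", ncol(ft_dur), "\n\n")

y <- co$patients$class_dis
sep <- function(col) {
  m <- tapply(col, y, mean)
  (m["community"] - m["household"]) / sd(col)
}
imu <- grep("^IMU", colnames(ft_dist), value = TRUE)
top <- sort(vapply(ft_dist[imu], sep, numeric(1)), decreasing = TRUE)
cat("Most class-separated IMU features (standardized mean difference,\n",
    "community minus household), fixed-distance paradigm:\n")
print(round(head(top, 8), 2))
cat("\nAmplitude-linked gyroscope features at the ankles and pelvis dominate;\n",
    "ankle sample-entropy features separate in the same direction:\n")
sampen_cols <- grep("sampen$", imu, value = TRUE)
print(round(sort(vapply(ft_dist[sampen_cols], sep, numeric(1)),
                 decreasing = TRUE)[1:3], 2))
cat("Patients who reach community ambulation move more, and more\n",
    "irregularly, already at admission. (Pelvis entropy runs the other\n",
    "way: its weak rotation signal leaves fixed sensor noise dominant,\n",
    "and noise relative to signal is larger for low-amplitude walkers.)\n")
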