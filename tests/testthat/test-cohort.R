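test_that("ambulation class follows the 0.4 m/s stratification", {
  expect_equal(as.character(assign_ambulation_class(0.17)), "household")
  expect_equal(as.character(assign_ambulation_class(0.40)), "community")
  expect_equal(as.character(assign_ambulation_class(0)), "household")
  expect_equal(as.character(assign_ambulation_class(c(0.39, 0.41), 0.4)),
               c("household", "community"))
  expect_equal(as.character(assign_ambulation_class(0.3, threshold = 0.25)),
               "community")
  expect_error(assign_ambulation_class(-0.1), "non-negative")
})

test_that("simulated recordings have the contracted shape and determinism", {
  prof <- gait_profile(0.8, 0.9, 1.6, 180, 0.15, 0.2, 0.2)
  rec <- simulate_gait_recording(prof, "ankle_unaffected", 60, 31.25, seed = 3)
  expect_equal(rec$n_samples, 1875)  # 60 * 31.25
  expect_equal(dim(rec$acc), c(1875, 3))
  expect_equal(dim(rec$gyro), c(1875, 3))
  expect_true(all(abs(rec$acc) <= 4))
  expect_true(all(abs(rec$gyro) <= 2000))

  rec2 <- simulate_gait_recording(prof, "ankle_unaffected", 60, 31.25, seed = 3)
  expect_identical(rec$acc, rec2$acc)
  expect_identical(rec$gyro, rec2$gyro)
  rec3 <- simulate_gait_recording(prof, "ankle_unaffected", 60, 31.25, seed = 4)
  expect_false(identical(rec$gyro, rec3$gyro))

  expect_error(simulate_gait_recording(prof, "pelvis", 0), "positive")
  expect_error(simulate_gait_recording(prof, "pelvis", 10, fs_hz = -1), "positive")
})

test_that("jitter-free noise-free gait is exactly periodic with the right peak", {
  # cadence 1.25 steps/s -> stride period 1.6 s = 50 samples at 31.25 Hz
  prof <- gait_profile(0.8, 0.9, 1.25, 200, 0.15, irregularity = 0, asymmetry = 0)
  rec <- simulate_gait_recording(prof, "ankle_unaffected", 32, seed = 1,
                                 noise_acc_g = 0, noise_gyro_dps = 0)
  mag <- magnitude(rec$gyro)
  lag <- 50
  n <- length(mag)
  expect_equal(cor(mag[1:(n - lag)], mag[(lag + 1):n]), 1, tolerance = 1e-12)
  # primary-axis swing peak matches the profile amplitude
  expect_equal(max(abs(rec$gyro[, 1])), 200, tolerance = 0.02)

  # affected side is attenuated by the asymmetry deficit
  prof_a <- gait_profile(0.8, 0.9, 1.25, 200, 0.15, 0, asymmetry = 0.3)
  rec_a <- simulate_gait_recording(prof_a, "ankle_affected", 32, seed = 1,
                                   noise_acc_g = 0, noise_gyro_dps = 0)
  expect_equal(max(abs(rec_a$gyro[, 1])), 140, tolerance = 0.02)

  # pelvis vertical accelerometer carries the 1 g gravity offset
  rec_p <- simulate_gait_recording(prof, "pelvis", 32, seed = 1,
                                   noise_acc_g = 0, noise_gyro_dps = 0)
  expect_equal(mean(rec_p$acc[, 3]), 1, tolerance = 0.05)
})

test_that("cohort composition follows the configured transition groups", {
  co <- simulate_cohort(cohort_config(8, 21, 4, seed = 7),
                        include_recordings = FALSE)
  expect_equal(nrow(co$patients), 33)
  # 8 household-stable + 21 community-stable + 4 improving
  expect_equal(sum(co$patients$class_dis == "community"), 25)
  expect_equal(sum(co$patients$class_dis == "household"), 8)
  expect_equal(sum(co$patients$class_adm == "household"), 12)

  # the default cohort reproduces the published discharge split
  def <- simulate_cohort(cohort_config(seed = 7), include_recordings = FALSE)
  expect_equal(nrow(def$patients), 33)
  expect_equal(sum(def$patients$class_dis == "community"), 27)
  expect_equal(sum(def$patients$class_dis == "household"), 6)

  one <- simulate_cohort(cohort_config(1, 0, 0, seed = 2),
                         include_recordings = FALSE)
  expect_equal(nrow(one$patients), 1)
  expect_equal(one$patients$class_adm, "household")
  expect_equal(one$patients$class_dis, "household")
})

test_that("discharge labels are consistent with speeds and the threshold", {
  co <- simulate_cohort(cohort_config(5, 10, 3, seed = 11),
                        include_recordings = FALSE)
  relabeled <- assign_ambulation_class(co$patients$speed_10mwt_dis_mps,
                                       co$config$label_threshold)
  expect_equal(co$patients$class_dis, as.character(relabeled))
  adm <- assign_ambulation_class(co$patients$speed_10mwt_adm_mps,
                                 co$config$label_threshold)
  expect_equal(co$patients$class_adm, as.character(adm))
})

test_that("cohort generation is deterministic given the config", {
  cfg <- cohort_config(2, 3, 1, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$recordings[["P001"]][["6mwt"]][["pelvis"]]$acc,
                   b$recordings[["P001"]][["6mwt"]][["pelvis"]]$acc)
  expect_identical(a$recordings[["P004"]][["10mwt"]][["ankle_affected"]]$gyro,
                   b$recordings[["P004"]][["10mwt"]][["ankle_affected"]]$gyro)
})

test_that("generated discharge speeds match the configured distributions", {
  # Monte-Carlo at n = 200 per group against the truncated-normal mean
  # computed by numerical integration (independent oracle).
  cfg <- cohort_config(200, 200, 0, seed = 99)
  co <- simulate_cohort(cfg, include_recordings = FALSE)
  tnorm_mean <- function(p) {
    z <- integrate(function(x) x * dnorm(x, p[1], p[2]), p[3], p[4])$value
    z / (pnorm(p[4], p[1], p[2]) - pnorm(p[3], p[1], p[2]))
  }
  for (g in c("HH", "CC")) {
    p <- if (g == "HH") cfg$groups$hh$speed_dis else cfg$groups$cc$speed_dis
    xs <- co$patients$speed_10mwt_dis_mps[co$patients$group == g]
    se <- sd(xs) / sqrt(length(xs))
    expect_lt(abs(mean(xs) - tnorm_mean(p)), 3 * se)
  }
})

test_that("higher cycle irregularity raises ankle-gyro sample entropy", {
  se_of <- function(irr, seed) {
    p <- gait_profile(0.8, 0.9, 1.6, 180, 0.15, irr, 0.2)
    r <- simulate_gait_recording(p, "ankle_unaffected", 30, seed = seed)
    sample_entropy(magnitude(r$gyro))
  }
  lo <- vapply(1:50, function(s) se_of(0.15, s), numeric(1))
  hi <- vapply(1:50, function(s) se_of(0.35, 1000 + s), numeric(1))
  p <- wilcox.test(hi, lo, alternative = "greater", exact = FALSE)$p.value
  expect_lt(p, 0.01)
})
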