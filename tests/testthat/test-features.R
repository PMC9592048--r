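test_that("magnitude is the per-sample Euclidean norm", {
  expect_equal(magnitude(3, 4, 0), 5)
  expect_equal(magnitude(0, 0, 0), 0)
  expect_equal(magnitude(1, 2, 2), 3)
  m <- matrix(c(3, 0, 4, 0, 0, 0), nrow = 2)
  expect_equal(magnitude(m), c(5, 0))
  expect_error(magnitude(1:3, 1:2, 1:3), "equal length")
  expect_error(magnitude(matrix(1, 2, 2)), "3 components")
})

test_that("magnitude-based features are invariant to sensor rotation", {
  set.seed(5)
  X <- matrix(rnorm(300 * 3), ncol = 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))  # random orthonormal rotation
  expect_equal(magnitude(X %*% R), magnitude(X), tolerance = 1e-9)
  f1 <- statistical_features(magnitude(X))
  f2 <- statistical_features(magnitude(X %*% R))
  expect_equal(f1, f2, tolerance = 1e-9)
  expect_equal(amount_of_motion(X %*% R, 31.25), amount_of_motion(X, 31.25),
               tolerance = 1e-9)
})

test_that("bout segmentation slices the contracted number of samples", {
  prof <- gait_profile(0.5, 0.6, 1.2, 150, 0.12, 0.2, 0.2)
  rec <- simulate_gait_recording(prof, "ankle_unaffected", 360, seed = 1)
  s60 <- segment_bout(rec, bout_spec("fixed_duration", duration_s = 60))
  expect_equal(s60$n_samples, 1875)
  s10 <- segment_bout(rec, bout_spec("fixed_duration", duration_s = 10))
  expect_equal(s10$n_samples, 312)  # floor(312.5)
  sd10 <- segment_bout(rec, bout_spec("fixed_distance", distance_m = 10),
                       gait_speed = 0.5)
  expect_equal(sd10$n_samples, 625)  # 20 s at 31.25 Hz
  expect_error(segment_bout(s10, bout_spec("fixed_duration", duration_s = 60)),
               "short by")
  expect_error(bout_spec("fixed_duration", duration_s = 45), "must be one of")
})

test_that("amount of motion integrates gyro magnitude over time", {
  fs <- 25
  n <- 10 * fs
  g <- cbind(rep(10, n), 0, 0)        # constant 10 deg/s magnitude for 10 s
  expect_equal(amount_of_motion(g, fs), 100)
  expect_equal(amount_of_motion(cbind(0, 0, 0)[rep(1, 50), ], fs), 0)
  # rectified sine magnitude vs an independently summed dense oracle
  t <- (0:(n - 1)) / fs
  g2 <- cbind(100 * sin(2 * pi * t), 0, 0)
  oracle <- 0
  for (i in seq_len(n)) oracle <- oracle + abs(100 * sin(2 * pi * t[i])) / fs
  expect_equal(amount_of_motion(g2, fs), oracle, tolerance = 1e-9)
  expect_error(amount_of_motion(matrix(numeric(0), 0, 3), fs), "empty")
})

test_that("amount of motion is additive and duration-linear for periodic gait", {
  prof <- gait_profile(0.8, 0.9, 1.25, 180, 0.15, 0, 0.1)
  rec <- simulate_gait_recording(prof, "ankle_unaffected", 64, seed = 2,
                                 noise_acc_g = 0, noise_gyro_dps = 0)
  a <- amount_of_motion(rec$gyro[1:1000, ], rec$fs_hz)
  b <- amount_of_motion(rec$gyro[1001:2000, ], rec$fs_hz)
  expect_equal(amount_of_motion(rec$gyro[1:2000, ], rec$fs_hz), a + b)
  # whole cycles: 1.6 s stride = 50 samples; 10 vs 20 cycles
  aom10 <- amount_of_motion(rec$gyro[1:500, ], rec$fs_hz)
  aom20 <- amount_of_motion(rec$gyro[1:1000, ], rec$fs_hz)
  expect_lt(abs(aom20 / aom10 - 2), 0.02)
})

test_that("sample entropy matches exhaustive template counting", {
  expect_equal(sample_entropy(rep(3.7, 50)), 0)
  x <- c(1, -1, 1, -1, 1, -1, 1, -1)
  expect_equal(sample_entropy(x, m = 2, r = 0.5), sampen_brute(x, 2, 0.5))
  set.seed(17)
  for (i in 1:40) {
    n <- sample(10:64, 1)
    x <- rnorm(n)
    expect_equal(sample_entropy(x, 2, 0.2), sampen_brute(x, 2, 0.2),
                 tolerance = 1e-12)
    expect_equal(sample_entropy(x, 3, 0.5), sampen_brute(x, 3, 0.5),
                 tolerance = 1e-12)
  }
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "length")
})

test_that("sample entropy orders noise above a pure tone and ignores scale", {
  set.seed(31)
  noise <- rnorm(500)
  tone <- sin(2 * pi * (1:500) / 25)
  tone <- tone / sd(tone)   # equal SD
  expect_gt(sample_entropy(noise), sample_entropy(tone))
  # affine invariance: r is a fraction of SD, so a*x + b changes nothing
  x <- rnorm(300)
  expect_equal(sample_entropy(7.3 * x + 2), sample_entropy(x), tolerance = 1e-12)
})

test_that("statistical features follow their defining formulas", {
  f <- statistical_features(rep(2.5, 20))
  expect_equal(unname(f[c("mean", "sd", "range", "rms")]), c(2.5, 0, 0, 2.5))
  f2 <- statistical_features(c(1, 2, 3, 4, 5))
  expect_equal(unname(f2["sd"]), sqrt(2.5))
  expect_equal(unname(f2["median"]), 3)
  expect_equal(unname(f2["mean"]), 3)
  expect_equal(unname(f2["iqr"]), 2)
  f3 <- statistical_features(c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2))
  expect_equal(unname(f3["skewness"]), 0, tolerance = 1e-12)
  expect_error(statistical_features(c(1, 2, 3)), "at least 4")
})

test_that("the default catalog carries 71 namespaced features", {
  cat71 <- feature_catalog()
  expect_length(cat71, 71)
  expect_false(anyDuplicated(cat71) > 0)
  expect_equal(sum(startsWith(cat71, "PI.")), 9)
  expect_equal(sum(startsWith(cat71, "FA.")), 5)
  expect_equal(sum(startsWith(cat71, "IMU.")), 57)
  expect_length(variant_features(cat71, "PI+FA"), 14)
  expect_length(variant_features(cat71, "PI+IMU"), 66)
  expect_length(variant_features(cat71, "PI"), 9)
})

test_that("feature extraction yields one catalog-ordered row per patient", {
  co <- default_test_cohort()
  ft <- default_test_features()
  expect_equal(dim(ft), c(33, 71))
  expect_equal(colnames(ft), feature_catalog())
  expect_equal(rownames(ft), co$patients$patient_id)
  expect_false(anyNA(ft))

  fa_only <- extract_feature_table(co, bout_spec("fixed_distance"),
                                   catalog = feature_catalog(pi = FALSE, imu = FALSE))
  expect_equal(colnames(fa_only), paste0("FA.", c("10MWT_adm_mps", "6MWT_adm_m",
                                                  "BBS_adm", "TUG_adm_s",
                                                  "FIMmotor_adm")))
  # repeated extraction is bit-identical
  ft2 <- extract_feature_table(co, bout_spec("fixed_distance"))
  expect_identical(as.data.frame(ft), as.data.frame(ft2))
})

test_that("patients unable to complete the 6MWT are scored 0", {
  cfg <- cohort_config(3, 1, 0, seed = 5,
                       groups = list(
                         hh = list(speed_adm = c(0.07, 0.01, 0.05, 0.10),
                                   speed_dis = c(0.2, 0.05, 0.05, 0.39)),
                         cc = list(speed_adm = c(0.8, 0.1, 0.5, 1.2),
                                   speed_dis = c(0.9, 0.1, 0.5, 1.5)),
                         hc = list(speed_adm = c(0.24, 0.06, 0.05, 0.39),
                                   speed_dis = c(0.8, 0.2, 0.45, 1.4))))
  co <- simulate_cohort(cfg)
  expect_true(all(is.na(co$patients$dist_6mwt_adm_m[co$patients$group == "HH"])))
  ft <- extract_feature_table(co, bout_spec("fixed_distance"))
  expect_equal(ft$FA.6MWT_adm_m[co$patients$group == "HH"], rep(0, 3))
  expect_gt(ft$FA.6MWT_adm_m[co$patients$group == "CC"], 0)
})
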