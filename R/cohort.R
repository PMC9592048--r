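#' Gait profile for one synthetic patient
#'
#' Bundles the kinematic parameters that drive the signal generator: admission
#' and discharge 10MWT gait speeds, cadence, peak ankle swing angular velocity,
#' pelvis acceleration amplitude, cycle-to-cycle irregularity (the knob that
#' controls sample entropy), affected-side amplitude deficit, and a fatigue
#' drift applied over long bouts.
#'
#' @param gait_speed_adm,gait_speed_dis gait speeds (m/s), non-negative.
#' @param cadence steps per second (> 0); stride frequency is `cadence / 2`.
#' @param swing_amplitude peak ankle angular velocity (deg/s), non-negative.
#' @param pelvis_acc_amplitude pelvis acceleration oscillation amplitude (g).
#' @param irregularity cycle-to-cycle timing/amplitude jitter, in \[0, 1\].
#' @param asymmetry affected-ankle amplitude deficit, in \[0, 1\]; the affected
#'   side oscillates at `(1 - asymmetry) * swing_amplitude`.
#' @param fatigue_drift fractional speed decay per minute over a long bout.
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(gait_speed_adm, gait_speed_dis, cadence,
                         swing_amplitude, pelvis_acc_amplitude,
                         irregularity, asymmetry, fatigue_drift = 0) {
  stopifnot(
    gait_speed_adm >= 0, gait_speed_dis >= 0, cadence > 0,
    swing_amplitude >= 0, pelvis_acc_amplitude >= 0,
    irregularity >= 0, irregularity <= 1,
    asymmetry >= 0, asymmetry <= 1, fatigue_drift >= 0
  )
  structure(list(
    gait_speed_adm = gait_speed_adm, gait_speed_dis = gait_speed_dis,
    cadence = cadence, swing_amplitude = swing_amplitude,
    pelvis_acc_amplitude = pelvis_acc_amplitude,
    irregularity = irregularity, asymmetry = asymmetry,
    fatigue_drift = fatigue_drift
  ), class = "gait_profile")
}

#' Classify a gait speed as household or community ambulation
#'
#' The clinical stratification used to label discharge walking function:
#' community ambulation at or above the threshold (default 0.4 m/s),
#' household below it.
#'
#' @param speed gait speed(s) in m/s; must be non-negative.
#' @param threshold stratification threshold in m/s (default 0.4).
#' @return A factor with levels `community`, `household`.
#' @examples
#' assign_ambulation_class(c(0.17, 0.4, 0))
#' @export
assign_ambulation_class <- function(speed, threshold = 0.4) {
  if (any(!is.finite(speed)) || any(speed < 0)) {
    stop("gait speed must be finite and non-negative")
  }
  ambulation_factor(ifelse(speed >= threshold, "community", "household"))
}

#' Configuration for a synthetic cohort
#'
#' Group counts follow the admission-to-discharge transition structure:
#' household-stable (household at both time points), community-stable, and
#' household-to-community (the small group that improves past the threshold
#' during inpatient rehabilitation). The default cohort of 33 patients
#' (6 + 23 + 4) carries 27 community and 6 household ambulators at discharge.
#'
#' Class-conditional gait-signal parameters (`signal`) are keyed by the
#' discharge class: patients who reach community ambulation show higher swing
#' amplitude and more irregular (higher-entropy) cycles already at admission.
#' Patient-information covariates are drawn independently of class unless
#' `pi_informative = TRUE` (an ablation switch).
#'
#' @param n_household_stable,n_community_stable,n_household_to_community
#'   group sizes (non-negative integers).
#' @param label_threshold ambulation threshold in m/s.
#' @param seed integer seed; the whole cohort is deterministic given the config.
#' @param groups per-group admission/discharge speed distributions, each a
#'   `c(mean, sd, lower, upper)` truncated normal in m/s.
#' @param signal per-discharge-class distributions for swing amplitude (deg/s),
#'   irregularity, asymmetry and fatigue drift (fraction/min).
#' @param pi_informative draw age with a class effect (for ablation tests).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_household_stable = 6,
                          n_community_stable = 23,
                          n_household_to_community = 4,
                          label_threshold = 0.4,
                          seed = 1,
                          groups = list(
                            hh = list(speed_adm = c(0.15, 0.07, 0.03, 0.35),
                                      speed_dis = c(0.22, 0.08, 0.02, 0.39)),
                            cc = list(speed_adm = c(0.75, 0.25, 0.40, 1.50),
                                      speed_dis = c(0.85, 0.22, 0.40, 1.80)),
                            hc = list(speed_adm = c(0.24, 0.06, 0.05, 0.39),
                                      speed_dis = c(0.80, 0.25, 0.45, 1.40))
                          ),
                          signal = list(
                            community = list(swing_amplitude = c(220, 30, 80, 400),
                                             irregularity = c(0.35, 0.08, 0, 1),
                                             asymmetry = c(0.15, 0.08, 0, 1),
                                             fatigue_drift = c(0.02, 0.010, 0, 0.2)),
                            household = list(swing_amplitude = c(120, 30, 40, 400),
                                             irregularity = c(0.15, 0.05, 0, 1),
                                             asymmetry = c(0.30, 0.10, 0, 1),
                                             fatigue_drift = c(0.04, 0.015, 0, 0.2))
                          ),
                          pi_informative = FALSE) {
  counts <- c(n_household_stable, n_community_stable, n_household_to_community)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("group counts must be non-negative integers")
  }
  stopifnot(label_threshold > 0)
  structure(list(
    n_household_stable = as.integer(n_household_stable),
    n_community_stable = as.integer(n_community_stable),
    n_household_to_community = as.integer(n_household_to_community),
    label_threshold = label_threshold, seed = as.integer(seed),
    groups = groups, signal = signal, pi_informative = pi_informative
  ), class = "cohort_config")
}

# Peak of the two-harmonic stride waveform sin(phi) + 0.3 sin(2 phi);
# used to normalize so that `swing_amplitude` is the actual signal peak.
WAVE_PEAK <- local({
  phi <- seq(0, 2 * pi, length.out = 20001)
  max(sin(phi) + 0.3 * sin(2 * phi))
})

stride_wave <- function(phi) (sin(phi) + 0.3 * sin(2 * phi)) / WAVE_PEAK

#' Simulate one body-worn IMU recording of walking
#'
#' Generates a quasi-periodic jittered sum-of-harmonics signal: the ankle
#' gyroscope is dominated by an oscillation at stride frequency
#' (`cadence / 2`) with peak approximately `swing_amplitude` (reduced by
#' `asymmetry` on the affected side); the pelvis accelerometer oscillates at
#' step frequency around a 1 g gravity offset on its vertical axis. Cycle
#' period and amplitude are jittered per stride in proportion to
#' `irregularity`, additive Gaussian sensor noise is applied, and an optional
#' fatigue drift slows and attenuates the gait over the bout.
#'
#' @param profile a [gait_profile()].
#' @param placement one of `"pelvis"`, `"ankle_affected"`, `"ankle_unaffected"`.
#' @param duration_s bout duration in seconds (> 0).
#' @param fs_hz sampling rate in Hz (default 31.25).
#' @param seed integer seed; the recording is deterministic given the arguments.
#' @param noise_acc_g,noise_gyro_dps additive Gaussian sensor noise SDs.
#' @param drift_per_min fractional speed decay per minute (0 disables fatigue).
#' @return An object of class `sensor_recording`: `placement`, `fs_hz`,
#'   `acc` (n x 3, g), `gyro` (n x 3, deg/s), `n_samples`.
#' @export
simulate_gait_recording <- function(profile, placement, duration_s,
                                    fs_hz = 31.25, seed = 0,
                                    noise_acc_g = 0.02, noise_gyro_dps = 2,
                                    drift_per_min = 0) {
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s must be positive")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  placement <- match.arg(placement, c("pelvis", "ankle_affected", "ankle_unaffected"))
  n <- floor(duration_s * fs_hz)
  if (n < 1) stop("duration too short for one sample at this rate")
  local_seed(seed, {
    t <- (seq_len(n) - 1) / fs_hz
    f_stride <- profile$cadence / 2
    base_T <- 1 / f_stride
    decay <- function(tt) pmax(0.2, 1 - drift_per_min * tt / 60)

    # stride-by-stride jittered cycle boundaries, per-cycle amplitude scale,
    # and per-cycle shape jitter (phase offset of the second harmonic) --
    # together these encode cycle-to-cycle gait variability
    starts <- 0; periods <- numeric(0); amps <- numeric(0); shapes <- numeric(0)
    while (starts[length(starts)] < duration_s) {
      t0 <- starts[length(starts)]
      Tk <- base_T * (1 + 0.12 * profile$irregularity * rnorm(1)) / decay(t0)
      Tk <- max(Tk, base_T * 0.3)
      Ak <- (1 + 0.25 * profile$irregularity * rnorm(1)) * decay(t0)
      periods <- c(periods, Tk)
      amps <- c(amps, max(Ak, 0.05))
      shapes <- c(shapes, 1.2 * profile$irregularity * rnorm(1))
      starts <- c(starts, t0 + Tk)
    }
    k <- findInterval(t, starts, rightmost.closed = FALSE)
    phi <- 2 * pi * ((k - 1) + (t - starts[k]) / periods[k])
    amp <- amps[k]
    shape <- shapes[k]

    side <- switch(placement,
                   ankle_affected = 1 - profile$asymmetry,
                   ankle_unaffected = 1, pelvis = NA_real_)
    A <- profile$swing_amplitude
    P <- profile$pelvis_acc_amplitude

    wave <- function(ph) (sin(ph) + 0.3 * sin(2 * ph + shape)) / WAVE_PEAK

    if (placement == "pelvis") {
      g_scale <- 0.15 * A
      gyro <- cbind(
        g_scale * amp * wave(phi + 1.2),
        0.10 * A * amp * sin(phi + 0.5),
        0.08 * A * amp * sin(2 * phi + 0.9))
      a_scale <- P
      acc <- cbind(
        0.6 * P * amp * sin(2 * phi + 0.6),          # anteroposterior, step freq
        0.4 * P * amp * sin(phi + 0.3),              # mediolateral sway, stride freq
        1 + P * amp * wave(2 * phi))                 # vertical: 1 g + step oscillation
    } else {
      g_scale <- side * A
      gyro <- cbind(
        g_scale * amp * wave(phi),                   # sagittal swing, stride freq
        0.25 * side * A * amp * sin(phi + 0.8),
        0.15 * side * A * amp * sin(2 * phi + 0.4))
      Pa <- 2.2 * P                                  # ankles move more than the pelvis
      a_scale <- side * Pa
      acc <- cbind(
        side * Pa * amp * sin(2 * phi + 1.0),
        0.5 * side * Pa * amp * sin(phi + 0.4),
        1 + side * Pa * amp * wave(2 * phi))
    }
    # continuous motor-variability noise, proportional to signal amplitude
    # and to irregularity (zero in the jitter-free limit)
    if (profile$irregularity > 0) {
      gyro <- gyro + matrix(rnorm(3 * n, 0, 0.05 * profile$irregularity * g_scale), n, 3)
      acc <- acc + matrix(rnorm(3 * n, 0, 0.05 * profile$irregularity * a_scale), n, 3)
    }
    if (noise_acc_g > 0) acc <- acc + matrix(rnorm(3 * n, 0, noise_acc_g), n, 3)
    if (noise_gyro_dps > 0) gyro <- gyro + matrix(rnorm(3 * n, 0, noise_gyro_dps), n, 3)
    acc <- pmin(pmax(acc, -4), 4)                    # device sensitivity +/- 4 g
    gyro <- pmin(pmax(gyro, -2000), 2000)            # device sensitivity +/- 2000 deg/s
    colnames(acc) <- c("ax_g", "ay_g", "az_g")
    colnames(gyro) <- c("gx_dps", "gy_dps", "gz_dps")
    structure(list(placement = placement, fs_hz = fs_hz,
                   acc = acc, gyro = gyro, n_samples = n),
              class = "sensor_recording")
  })
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %s, %d samples @ %.2f Hz (%.1f s)\n",
              x$placement, x$n_samples, x$fs_hz, x$n_samples / x$fs_hz))
  invisible(x)
}

draw4 <- function(n, p) rtnorm(n, p[1], p[2], p[3], p[4])

#' Simulate a synthetic inpatient-rehabilitation cohort
#'
#' Draws, per patient: admission and discharge 10MWT gait speeds from the
#' configured group distribution; a gait profile whose signal parameters are
#' conditioned on the discharge ambulation class (so admission walking signals
#' carry prognostic information, while admission speed alone does not separate
#' the household-to-community group); patient-information covariates (class
#' independent by default); functional-assessment scores generated from the
#' admission speed with noise; and two assessment recordings per sensor
#' placement: a 10 m walk at constant admission speed (duration
#' `10 / gait_speed_adm` s) and a 360 s endurance bout with fatigue drift.
#'
#' Patients with admission speed below 0.12 m/s are marked unable to complete
#' the 6-minute walk distance assessment (score `NA`, later imputed to 0).
#' A patient with zero admission speed would be flagged non-ambulatory and the
#' 10 m recording omitted.
#'
#' @param config a [cohort_config()].
#' @param include_recordings generate the IMU recordings (default `TRUE`);
#'   `FALSE` returns only the patient table and profiles (the table is
#'   identical either way).
#' @return An object of class `gait_cohort`: `patients` (one row per patient),
#'   `profiles` (the generating gait profiles), `recordings` (per patient, per
#'   assessment `"10mwt"`/`"6mwt"`, the three placements), and `config`.
#' @export
simulate_cohort <- function(config, include_recordings = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n_tot <- config$n_household_stable + config$n_community_stable +
    config$n_household_to_community
  if (n_tot < 1) stop("cohort must contain at least one patient")
  group <- rep(c("HH", "CC", "HC"),
               c(config$n_household_stable, config$n_community_stable,
                 config$n_household_to_community))

  local_seed(config$seed, {
    gp <- list(HH = config$groups$hh, CC = config$groups$cc, HC = config$groups$hc)
    speed_adm <- numeric(n_tot); speed_dis <- numeric(n_tot)
    for (g in unique(group)) {
      idx <- which(group == g)
      speed_adm[idx] <- draw4(length(idx), gp[[g]]$speed_adm)
      speed_dis[idx] <- draw4(length(idx), gp[[g]]$speed_dis)
    }
    class_adm <- assign_ambulation_class(speed_adm, config$label_threshold)
    class_dis <- assign_ambulation_class(speed_dis, config$label_threshold)

    # gait-signal parameters keyed by the DISCHARGE class
    sig <- config$signal
    swing <- irr <- asym <- drift <- numeric(n_tot)
    for (cl in AMBULATION_CLASSES) {
      idx <- which(class_dis == cl)
      swing[idx] <- draw4(length(idx), sig[[cl]]$swing_amplitude)
      irr[idx]   <- draw4(length(idx), sig[[cl]]$irregularity)
      asym[idx]  <- draw4(length(idx), sig[[cl]]$asymmetry)
      drift[idx] <- draw4(length(idx), sig[[cl]]$fatigue_drift)
    }
    cadence <- pmin(pmax(0.9 + 0.9 * speed_adm + rnorm(n_tot, 0, 0.08), 0.4), 2.5)
    pelv <- pmin(pmax(0.04 + 0.18 * speed_adm + rnorm(n_tot, 0, 0.02), 0.01), 0.8)

    # patient information, independent of class unless ablation is requested
    age_mean <- if (config$pi_informative) {
      ifelse(class_dis == "household", 70, 58)
    } else rep(62, n_tot)
    age <- round(rtnorm(n_tot, 0, 1) * 12 + age_mean)
    age <- pmin(pmax(age, 25), 92)
    sex <- sample(0:1, n_tot, replace = TRUE)
    height <- rtnorm(n_tot, 170, 10, 145, 198)
    weight <- rtnorm(n_tot, 80, 16, 42, 150)
    days_post <- round(rtnorm(n_tot, 12, 6, 3, 60))
    stroke_type <- sample(0:1, n_tot, replace = TRUE, prob = c(0.8, 0.2))
    affected_side <- sample(0:1, n_tot, replace = TRUE)
    assistive <- sample(0:1, n_tot, replace = TRUE, prob = c(0.45, 0.55))

    # functional assessments generated from admission speed with noise
    six_mwt <- pmax(330 * speed_adm * (1 + rnorm(n_tot, 0, 0.12)), 0)
    six_mwt[speed_adm < 0.12] <- NA_real_   # unable to complete; imputed to 0 later
    bbs <- round(pmin(pmax(56 / (1 + exp(-(speed_adm - 0.45) / 0.18)) +
                             rnorm(n_tot, 0, 4), 0), 56))
    tug <- pmin(pmax(8 + 12 / pmax(speed_adm, 0.08) + rnorm(n_tot, 0, 3), 5), 180)
    fim <- round(pmin(pmax(13 + 60 * speed_adm / (speed_adm + 0.35) +
                             rnorm(n_tot, 0, 6), 13), 91))

    pid <- sprintf("P%03d", seq_len(n_tot))
    patients <- data.frame(
      patient_id = pid, group = group,
      age = age, sex = sex, height_cm = height, weight_kg = weight,
      bmi = weight / (height / 100)^2, days_post_stroke = days_post,
      stroke_type = stroke_type, affected_side = affected_side,
      assistive_device = assistive,
      speed_10mwt_adm_mps = speed_adm, dist_6mwt_adm_m = six_mwt,
      bbs_adm = bbs, tug_adm_s = tug, fim_motor_adm = fim,
      speed_10mwt_dis_mps = speed_dis,
      class_adm = as.character(class_adm), class_dis = as.character(class_dis),
      non_ambulatory = speed_adm <= 0,
      stringsAsFactors = FALSE
    )
    profiles <- data.frame(
      patient_id = pid, gait_speed_adm = speed_adm, gait_speed_dis = speed_dis,
      cadence = cadence, swing_amplitude = swing, pelvis_acc_amplitude = pelv,
      irregularity = irr, asymmetry = asym, fatigue_drift = drift,
      stringsAsFactors = FALSE
    )
    rec_seeds <- sample.int(.Machine$integer.max - 1L, n_tot * 6L)

    recordings <- vector("list", n_tot)
    names(recordings) <- pid
    placements <- c("pelvis", "ankle_affected", "ankle_unaffected")
    for (i in if (include_recordings) seq_len(n_tot) else integer(0)) {
      prof <- gait_profile(speed_adm[i], speed_dis[i], cadence[i], swing[i],
                           pelv[i], irr[i], asym[i], drift[i])
      pr <- list()
      if (!patients$non_ambulatory[i]) {
        pr[["10mwt"]] <- lapply(seq_along(placements), function(j) {
          simulate_gait_recording(prof, placements[j], 10 / speed_adm[i],
                                  seed = rec_seeds[(i - 1) * 6 + j])
        })
        names(pr[["10mwt"]]) <- placements
      }
      pr[["6mwt"]] <- lapply(seq_along(placements), function(j) {
        simulate_gait_recording(prof, placements[j], 360,
                                seed = rec_seeds[(i - 1) * 6 + 3 + j],
                                drift_per_min = prof$fatigue_drift)
      })
      names(pr[["6mwt"]]) <- placements
      recordings[[i]] <- pr
    }
    structure(list(patients = patients, profiles = profiles,
                   recordings = recordings, config = config),
              class = "gait_cohort")
  })
}

#' @export
print.gait_cohort <- function(x, ...) {
  tab <- table(x$patients$class_dis)
  cat(sprintf("<gait_cohort> %d patients (discharge: %s)\n",
              nrow(x$patients),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}
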