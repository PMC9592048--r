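#' Euclidean magnitude of a triaxial signal
#'
#' All IMU features in the pipeline are computed from the magnitude of the
#' triaxial signals rather than per axis, which conserves features and makes
#' them invariant to device orientation.
#'
#' @param triaxial an n x 3 numeric matrix (or data frame), or the first of
#'   three equal-length component vectors.
#' @param y,z optional second and third components when `triaxial` is a vector.
#' @return Numeric vector of per-sample Euclidean norms.
#' @examples
#' magnitude(3, 4, 0)  # 5
#' @export
magnitude <- function(triaxial, y = NULL, z = NULL) {
  if (is.null(dim(triaxial))) {
    if (is.null(y) || is.null(z)) stop("supply an n x 3 matrix or three components")
    if (length(triaxial) != length(y) || length(y) != length(z)) {
      stop("triaxial components must have equal length")
    }
    triaxial <- cbind(triaxial, y, z)
  }
  triaxial <- as.matrix(triaxial)
  if (ncol(triaxial) != 3) stop("triaxial signal must have exactly 3 components")
  sqrt(rowSums(triaxial^2))
}

#' Walking-bout specification
#'
#' Two segmentation paradigms are supported: a fixed walking distance (the
#' 10 m walk test) and a fixed walking duration (an initial segment of the
#' 6-minute walk, from the set 10--360 s).
#'
#' @param paradigm `"fixed_distance"` or `"fixed_duration"`.
#' @param distance_m walk distance in m (fixed-distance paradigm).
#' @param duration_s duration in seconds; must belong to
#'   `c(10, 20, 30, 60, 90, 120, 180, 240, 300, 360)`.
#' @return An object of class `bout_spec`.
#' @export
bout_spec <- function(paradigm = c("fixed_distance", "fixed_duration"),
                      distance_m = 10, duration_s = NULL) {
  paradigm <- match.arg(paradigm)
  allowed <- c(10, 20, 30, 60, 90, 120, 180, 240, 300, 360)
  if (paradigm == "fixed_duration") {
    if (is.null(duration_s) || !duration_s %in% allowed) {
      stop("duration_s must be one of ", paste(allowed, collapse = ", "))
    }
  } else {
    stopifnot(distance_m > 0)
  }
  structure(list(paradigm = paradigm, distance_m = distance_m,
                 duration_s = duration_s), class = "bout_spec")
}

#' Segment a recording to a walking bout
#'
#' Fixed duration takes the first `floor(duration_s * fs)` samples from the
#' start of the test; fixed distance takes the first
#' `floor((distance_m / gait_speed) * fs)` samples (a constant-speed walk).
#'
#' @param recording a `sensor_recording`.
#' @param spec a [bout_spec()].
#' @param gait_speed gait speed in m/s, required for the fixed-distance paradigm.
#' @return The truncated `sensor_recording`.
#' @export
segment_bout <- function(recording, spec, gait_speed = NULL) {
  stopifnot(inherits(recording, "sensor_recording"), inherits(spec, "bout_spec"))
  n_want <- if (spec$paradigm == "fixed_duration") {
    floor(spec$duration_s * recording$fs_hz)
  } else {
    if (is.null(gait_speed) || gait_speed <= 0) {
      stop("fixed-distance segmentation needs a positive gait_speed")
    }
    floor((spec$distance_m / gait_speed) * recording$fs_hz)
  }
  if (n_want > recording$n_samples) {
    stop(sprintf("recording too short: need %d samples, have %d (short by %d)",
                 n_want, recording$n_samples, n_want - recording$n_samples))
  }
  out <- recording
  out$acc <- recording$acc[seq_len(n_want), , drop = FALSE]
  out$gyro <- recording$gyro[seq_len(n_want), , drop = FALSE]
  out$n_samples <- n_want
  out
}

#' Amount of motion: cumulative angular displacement
#'
#' Time integral (rectangular rule, `sum / fs`) of the gyroscope magnitude
#' over a bout, in degrees. Larger values indicate greater overall limb motion.
#'
#' @param gyro an n x 3 gyroscope matrix in deg/s.
#' @param fs_hz sampling rate in Hz.
#' @return Cumulative angular displacement in degrees.
#' @export
amount_of_motion <- function(gyro, fs_hz) {
  gyro <- as.matrix(gyro)
  if (nrow(gyro) < 1) stop("empty gyroscope series")
  stopifnot(fs_hz > 0)
  sum(magnitude(gyro)) / fs_hz
}

#' Sample entropy of a series
#'
#' SampEn(m, r) = -ln(A/B), where B counts ordered template pairs of length
#' `m` within Chebyshev tolerance \eqn{r \cdot SD(x)} (self-matches excluded) and A
#' the analogous count for length `m + 1`; both counts run over the first
#' `n - m` templates. Higher values indicate a more irregular signal. A
#' constant series returns 0 by convention; when no template pair extends
#' (A = 0) the `+Inf` sentinel is returned.
#'
#' @param x numeric series with `length(x) > m + 1`.
#' @param m template length (default 2).
#' @param r tolerance as a fraction of the series SD (default 0.2), the
#'   conventional parameters for physiologic signals.
#' @return Dimensionless entropy; 0 for zero-variance input; `Inf` when no
#'   extended match exists.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1) stop("series length must exceed m + 1")
  s <- sd(x)
  if (s == 0) return(0)
  .sampen_cpp(x, as.integer(m), r * s)
}

#' Summary statistics of a magnitude series
#'
#' The nine per-signal statistics used as IMU features: mean, SD (n-1
#' denominator), skewness (g1), excess kurtosis (g2), RMS, range,
#' interquartile range, median, and sample entropy.
#'
#' @param x numeric series of length >= 4.
#' @param sampen_m,sampen_r sample-entropy parameters.
#' @return Named numeric vector of the nine statistics.
#' @export
statistical_features <- function(x, sampen_m = 2, sampen_r = 0.2) {
  if (length(x) < 4) stop("need at least 4 samples for summary statistics")
  c(mean = mean(x),
    sd = sd(x),
    skewness = e1071::skewness(x, type = 1),
    kurtosis = e1071::kurtosis(x, type = 1),
    rms = sqrt(mean(x^2)),
    range = max(x) - min(x),
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    median = median(x),
    sampen = sample_entropy(x, sampen_m, sampen_r))
}

IMU_PLACEMENTS <- c("pelvis", "ankle_affected", "ankle_unaffected")
IMU_SIGNALS <- c("acc", "gyro")
IMU_STATS <- c("mean", "sd", "skewness", "kurtosis", "rms", "range",
               "iqr", "median", "sampen")
PI_FEATURES <- c("PI.age", "PI.sex", "PI.height_cm", "PI.weight_kg", "PI.bmi",
                 "PI.days_post_stroke", "PI.stroke_type", "PI.affected_side",
                 "PI.assistive_device")
FA_FEATURES <- c("FA.10MWT_adm_mps", "FA.6MWT_adm_m", "FA.BBS_adm",
                 "FA.TUG_adm_s", "FA.FIMmotor_adm")

#' Default feature catalog
#'
#' 71 features: 9 patient-information (PI), 5 functional-assessment (FA), and
#' 57 IMU features (3 sensors x 2 signals x 9 magnitude statistics, plus the
#' amount of motion per sensor). Categorical PI fields are integer coded
#' (sex: 0 male / 1 female; stroke type: 0 ischemic / 1 hemorrhagic;
#' affected side: 0 left / 1 right; assistive device: 0 no / 1 yes).
#'
#' @param pi,fa,imu include the corresponding namespace.
#' @return Character vector of namespaced feature names, in catalog order.
#' @export
feature_catalog <- function(pi = TRUE, fa = TRUE, imu = TRUE) {
  imu_names <- c(
    as.vector(vapply(IMU_PLACEMENTS, function(p) {
      as.vector(vapply(IMU_SIGNALS, function(s) {
        paste("IMU", p, s, IMU_STATS, sep = ".")
      }, character(length(IMU_STATS))))
    }, character(length(IMU_SIGNALS) * length(IMU_STATS)))),
    paste("IMU", IMU_PLACEMENTS, "gyro.aom", sep = "."))
  c(if (pi) PI_FEATURES, if (fa) FA_FEATURES, if (imu) imu_names)
}

#' Restrict a catalog to a model variant
#'
#' @param catalog a feature catalog (character vector).
#' @param variant one of `"PI"`, `"PI+FA"`, `"PI+IMU"`, `"PI+FA+IMU"`.
#' @return The catalog subset for that variant, in catalog order.
#' @export
variant_features <- function(catalog, variant) {
  variant <- match.arg(variant, c("PI", "PI+FA", "PI+IMU", "PI+FA+IMU"))
  spaces <- strsplit(variant, "+", fixed = TRUE)[[1]]
  catalog[sub("\\..*$", "", catalog) %in% spaces]
}

pi_fa_values <- function(row) {
  c(PI.age = row$age, PI.sex = row$sex, PI.height_cm = row$height_cm,
    PI.weight_kg = row$weight_kg, PI.bmi = row$bmi,
    PI.days_post_stroke = row$days_post_stroke,
    PI.stroke_type = row$stroke_type, PI.affected_side = row$affected_side,
    PI.assistive_device = row$assistive_device,
    `FA.10MWT_adm_mps` = row$speed_10mwt_adm_mps,
    `FA.6MWT_adm_m` = row$dist_6mwt_adm_m,
    FA.BBS_adm = row$bbs_adm, FA.TUG_adm_s = row$tug_adm_s,
    FA.FIMmotor_adm = row$fim_motor_adm)
}

#' Extract the patients-by-features table
#'
#' Computes, per patient, the IMU features on the magnitude series of the
#' segmented bout for each sensor and signal, copies admission assessment
#' scores (missing scores imputed to 0, the convention for patients unable to
#' complete an assessment), and integer-codes patient information. Patients
#' lacking the required recordings are excluded with a message.
#'
#' @param cohort a `gait_cohort` (or a list with `patients` and `recordings`).
#' @param spec a [bout_spec()]; fixed distance uses the 10 m walk recordings,
#'   fixed duration the 6-minute-walk recordings.
#' @param catalog feature names to produce, in order (default [feature_catalog()]).
#' @param sampen_m,sampen_r sample-entropy parameters.
#' @return A data frame (class `feature_table`), one row per patient with
#'   row names the patient ids, columns in catalog order, and attributes
#'   `paradigm` and `catalog`.
#' @export
extract_feature_table <- function(cohort, spec, catalog = feature_catalog(),
                                  sampen_m = 2, sampen_r = 0.2) {
  stopifnot(inherits(spec, "bout_spec"))
  patients <- cohort$patients
  assessment <- if (spec$paradigm == "fixed_distance") "10mwt" else "6mwt"
  need_imu <- any(startsWith(catalog, "IMU."))

  rows <- list()
  for (i in seq_len(nrow(patients))) {
    row <- patients[i, ]
    pid <- row$patient_id
    vals <- pi_fa_values(row)
    if (need_imu) {
      recs <- cohort$recordings[[pid]][[assessment]]
      if (is.null(recs) || !all(IMU_PLACEMENTS %in% names(recs))) {
        message("excluding ", pid, ": incomplete sensor data for ", assessment)
        next
      }
      for (p in IMU_PLACEMENTS) {
        bout <- segment_bout(recs[[p]], spec, gait_speed = row$speed_10mwt_adm_mps)
        for (s in IMU_SIGNALS) {
          mag <- magnitude(bout[[s]])
          st <- statistical_features(mag, sampen_m, sampen_r)
          names(st) <- paste("IMU", p, s, names(st), sep = ".")
          vals <- c(vals, st)
        }
        vals <- c(vals, stats::setNames(
          amount_of_motion(bout$gyro, bout$fs_hz),
          paste("IMU", p, "gyro.aom", sep = ".")))
      }
    }
    missing <- setdiff(catalog, names(vals))
    if (length(missing)) stop("catalog features not computable: ",
                              paste(missing, collapse = ", "))
    rows[[pid]] <- vals[catalog]
  }
  if (!length(rows)) stop("no patient had complete data")
  tab <- as.data.frame(do.call(rbind, rows))
  tab[is.na(tab)] <- 0   # missing-score rule: unable to complete -> 0
  attr(tab, "paradigm") <- spec$paradigm
  attr(tab, "catalog") <- catalog
  class(tab) <- c("feature_table", "data.frame")
  tab
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features (%s)\n",
              nrow(x), ncol(x), attr(x, "paradigm") %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
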