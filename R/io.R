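#' Write one recording as CSV
#'
#' Columns `t_s, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps`.
#' @param recording a `sensor_recording`.
#' @param path output file path.
#' @export
write_recording_csv <- function(recording, path) {
  n <- recording$n_samples
  df <- data.frame(t_s = (seq_len(n) - 1) / recording$fs_hz,
                   recording$acc, recording$gyro, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording CSV
#' @param path file written by [write_recording_csv()] (or a real export with
#'   the same schema).
#' @param placement sensor placement label.
#' @param fs_hz sampling rate; inferred from the time column when `NULL`.
#' @return A `sensor_recording`.
#' @export
read_recording_csv <- function(path, placement, fs_hz = NULL) {
  df <- read.csv(path)
  need <- c("t_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
  if (!all(need %in% colnames(df))) {
    stop("recording file ", path, " lacks columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  }
  if (is.null(fs_hz)) {
    fs_hz <- if (nrow(df) > 1) 1 / mean(diff(df$t_s)) else 31.25
  }
  structure(list(placement = placement, fs_hz = fs_hz,
                 acc = as.matrix(df[, c("ax_g", "ay_g", "az_g")]),
                 gyro = as.matrix(df[, c("gx_dps", "gy_dps", "gz_dps")]),
                 n_samples = nrow(df)),
            class = "sensor_recording")
}

#' Write a cohort (table + per-recording CSVs) to a directory
#'
#' Produces `cohort.csv` (one row per patient) and one recording file per
#' patient, assessment and placement, named
#' `<patient>_<assessment>_<placement>.csv`.
#'
#' @param cohort a `gait_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$patients, file.path(dir, "cohort.csv"), row.names = FALSE)
  for (pid in names(cohort$recordings)) {
    for (ass in names(cohort$recordings[[pid]])) {
      for (pl in names(cohort$recordings[[pid]][[ass]])) {
        write_recording_csv(cohort$recordings[[pid]][[ass]][[pl]],
                            file.path(dir, paste0(paste(pid, ass, pl, sep = "_"),
                                                  ".csv")))
      }
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort_csv()]
#'
#' Also accepts real data exports that match the same schema.
#' @param dir directory containing `cohort.csv` and recording files.
#' @param fs_hz sampling rate of the recordings.
#' @return A `gait_cohort`-shaped list (without generator profiles).
#' @export
read_cohort_csv <- function(dir, fs_hz = 31.25) {
  patients <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  recordings <- list()
  for (pid in patients$patient_id) {
    recordings[[pid]] <- list()
    for (ass in c("10mwt", "6mwt")) {
      paths <- file.path(dir, paste0(paste(pid, ass, IMU_PLACEMENTS, sep = "_"),
                                     ".csv"))
      if (all(file.exists(paths))) {
        recs <- lapply(seq_along(IMU_PLACEMENTS), function(j) {
          read_recording_csv(paths[j], IMU_PLACEMENTS[j], fs_hz)
        })
        names(recs) <- IMU_PLACEMENTS
        recordings[[pid]][[ass]] <- recs
      }
    }
  }
  structure(list(patients = patients, recordings = recordings),
            class = "gait_cohort")
}

#' Write a feature table as CSV (first column the patient id)
#' @param table a `feature_table`.
#' @param path output path.
#' @export
write_feature_csv <- function(table, path) {
  df <- data.frame(patient_id = rownames(table), as.data.frame(table),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
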