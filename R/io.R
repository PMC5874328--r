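# Plain-text trial export/import: one CSV per stream group plus a JSON
# subject-metadata file.  Formats are UTF-8, '.' decimal separator, header
# row mandatory.

#' Export a raw trial to CSV files
#'
#' Writes `<stem>_imu.csv` (time plus per-sensor quaternion and
#' acceleration columns), `<stem>_force.csv` (`time_s`, `vgrf_left_N`,
#' `vgrf_right_N`), `<stem>_refangles.csv` (time plus the six sagittal
#' angles for both reference variants, suffixed `_imu` / `_optical`) and
#' `<stem>_subject.json`.
#'
#' @param trial A `raw_trial`.
#' @param stem Output path stem (directory must exist).
#' @return Invisibly, the vector of files written.
#' @export
write_trial <- function(trial, stem) {
  stopifnot(inherits(trial, "raw_trial"))
  imu <- trial$imu
  names(imu)[1L] <- "time_s"
  force <- tibble::tibble(time_s = trial$force$time,
                          vgrf_left_N = trial$force$vgrf_left,
                          vgrf_right_N = trial$force$vgrf_right)
  ref <- trial$ref_angles_imu
  names(ref) <- c("time_s", paste0(ANGLE_CHANNELS, "_imu"))
  ref[paste0(ANGLE_CHANNELS, "_optical")] <-
    trial$ref_angles_optical[, ANGLE_CHANNELS]
  files <- paste0(stem, c("_imu.csv", "_force.csv", "_refangles.csv",
                          "_subject.json"))
  write.csv(imu, files[1L], row.names = FALSE)
  write.csv(force, files[2L], row.names = FALSE)
  write.csv(ref, files[3L], row.names = FALSE)
  write_subject(trial$subject, files[4L],
                extra = list(speed = trial$speed, imu_rate = trial$imu_rate,
                             force_rate = trial$force_rate, seed = trial$seed))
  invisible(files)
}

#' Import a raw trial written by [write_trial()]
#' @param stem Path stem used at export time.
#' @return A `raw_trial` object (without the generator's stance-event table).
#' @export
read_trial <- function(stem) {
  imu <- tibble::as_tibble(read.csv(paste0(stem, "_imu.csv")))
  names(imu)[1L] <- "time"
  force <- tibble::as_tibble(read.csv(paste0(stem, "_force.csv")))
  ref <- tibble::as_tibble(read.csv(paste0(stem, "_refangles.csv")))
  meta <- jsonlite::read_json(paste0(stem, "_subject.json"), simplifyVector = TRUE)
  subject <- subject_from_list(meta$subject)
  ref_imu <- ref[, c("time_s", paste0(ANGLE_CHANNELS, "_imu"))]
  names(ref_imu) <- c("time", ANGLE_CHANNELS)
  ref_opt <- ref[, c("time_s", paste0(ANGLE_CHANNELS, "_optical"))]
  names(ref_opt) <- c("time", ANGLE_CHANNELS)
  structure(list(
    subject = subject,
    speed = meta$speed,
    duration = nrow(force) / meta$force_rate,
    seed = meta$seed,
    imu_rate = meta$imu_rate,
    force_rate = meta$force_rate,
    imu = imu,
    force = tibble::tibble(time = force$time_s, vgrf_left = force$vgrf_left_N,
                           vgrf_right = force$vgrf_right_N),
    ref_angles_imu = ref_imu,
    ref_angles_optical = ref_opt,
    events = NULL
  ), class = "raw_trial")
}

#' Write subject metadata as JSON
#' @param subject A `subject_profile`.
#' @param path Output file.
#' @param extra Optional named list stored alongside the profile.
#' @export
write_subject <- function(subject, path, extra = NULL) {
  payload <- c(list(subject = unclass(subject)), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

subject_from_list <- function(x) {
  oc <- x$optical_offset_coeffs
  if (!is.matrix(oc)) oc <- matrix(unlist(oc), nrow = 6L, byrow = TRUE)
  dimnames(oc) <- list(ANGLE_CHANNELS, NULL)
  x$optical_offset_coeffs <- oc
  x$mounts <- lapply(x$mounts, unlist)
  for (j in names(x$angle_template_coeffs)) {
    for (p in names(x$angle_template_coeffs[[j]])) {
      x$angle_template_coeffs[[j]][[p]] <-
        lapply(x$angle_template_coeffs[[j]][[p]], unlist)
    }
  }
  structure(x, class = "subject_profile")
}
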