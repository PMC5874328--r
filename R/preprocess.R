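# Preprocessing: cropping to steady state, 20 Hz zero-phase Butterworth
# force filtering, resampling/synchronization of all streams to a common
# 120 Hz grid, and 20 N stance segmentation.

#' Crop a trial to its steady-state portion
#'
#' Removes `trim_head` seconds from the start and `trim_tail` seconds from
#' the end of every stream (IMU, force, both reference-angle variants),
#' preserving alignment.
#'
#' @param trial A `raw_trial`.
#' @param trim_head,trim_tail Seconds to remove at each end.
#' @return The cropped `raw_trial`.
#' @export
crop_steady_state <- function(trial, trim_head, trim_tail) {
  stopifnot(inherits(trial, "raw_trial"))
  if (trim_head < 0 || trim_tail < 0) {
    abort("Trim amounts must be non-negative.", class = "imu2grf_bad_trim")
  }
  if (trial$duration - trim_head - trim_tail < 5) {
    abort("Over-trimming: less than 5 s of steady-state data would remain.",
          class = "imu2grf_over_trim")
  }
  t0 <- trim_head
  t1 <- trial$duration - trim_tail
  keep <- function(df) {
    out <- df[df$time >= t0 - 1e-12 & df$time < t1 - 1e-12, , drop = FALSE]
    out$time <- out$time - t0
    out
  }
  trial$imu <- keep(trial$imu)
  trial$force <- keep(trial$force)
  trial$ref_angles_imu <- keep(trial$ref_angles_imu)
  trial$ref_angles_optical <- keep(trial$ref_angles_optical)
  if (!is.null(trial$events)) {
    ev <- trial$events
    ev$t_contact <- ev$t_contact - t0
    trial$events <- ev[ev$t_contact >= 0 & ev$t_contact + ev$stance_dur <= t1 - t0, ]
  }
  trial$duration <- t1 - t0
  trial
}

# Steady-state initial conditions for a direct-form-II-transposed filter:
# the state that reproduces a constant input exactly (DC gain preserved).
# For a direct-form-II-transposed state, steady state under constant unit
# input (and unit output, DC gain 1) satisfies z_k = sum_{j>k} (b_j - a_j).
lfilter_zi <- function(b, a) {
  n <- length(a)
  stopifnot(length(b) == n)
  d <- b[-1L] - a[-1L]
  rev(cumsum(rev(d)))
}

apply_iir <- function(b, a, x, zi) {
  # direct-form II transposed with explicit initial state
  n <- length(x)
  nz <- length(zi)
  z <- zi
  y <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    if (nz > 1L) {
      for (k in seq_len(nz - 1L)) {
        z[k] <- b[k + 1L] * xi + z[k + 1L] - a[k + 1L] * yi
      }
    }
    z[nz] <- b[nz + 1L] * xi - a[nz + 1L] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase low-pass filter for vertical ground reaction force
#'
#' Forward-backward application of a 6th-order Butterworth low-pass with a
#' 20 Hz cutoff (effective 12th-order magnitude response, zero phase lag).
#' Edges are handled by odd-reflection padding of three filter lengths with
#' steady-state initial conditions, so a constant signal passes unchanged.
#'
#' @param force Numeric force sequence (N).
#' @param fs Sampling rate in Hz (> 40).
#' @param cutoff Cutoff frequency in Hz (default 20).
#' @param order Filter order for each pass (default 6).
#' @return Filtered sequence, same length as the input.
#' @export
filter_vgrf <- function(force, fs, cutoff = 20, order = 6) {
  if (fs <= 2 * cutoff) {
    abort("`fs` must exceed twice the cutoff frequency.",
          class = "imu2grf_low_fs")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  b <- bf$b; a <- bf$a
  b <- b * (sum(a) / sum(b))   # exact unit DC gain
  padlen <- 3L * max(length(a), length(b))
  n <- length(force)
  if (n <= padlen) {
    abort(sprintf("Sequence too short to filter (need > %d samples).", padlen),
          class = "imu2grf_short_sequence")
  }
  # odd reflection about the end points
  head_pad <- 2 * force[1L] - force[(padlen + 1L):2L]
  tail_pad <- 2 * force[n] - force[(n - 1L):(n - padlen)]
  x <- c(head_pad, force, tail_pad)
  zi <- lfilter_zi(b, a)
  y <- apply_iir(b, a, x, zi * x[1L])
  y <- rev(apply_iir(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

interp_stream <- function(time, values, t_out) {
  approx(time, values, xout = t_out, rule = 2)$y
}

#' Resample and synchronize a trial to a common rate
#'
#' Places every stream on one `target_rate` time grid starting at the
#' latest common start time.  Integer-ratio streams (IMU 240 Hz -> 120 Hz)
#' are decimated by sample picking; non-integer ratios (force 1000 Hz,
#' already band-limited by the 20 Hz low-pass) are linearly interpolated.
#' Quaternions are made sign-continuous before component-wise
#' interpolation/decimation and re-normalized after; filtered forces are
#' clipped at 0 N.
#'
#' @param trial A `raw_trial`.  Force channels are filtered with
#'   [filter_vgrf()] unless `filter_force = FALSE`.
#' @param target_rate Target rate in Hz (default 120; must not exceed any
#'   source rate).
#' @param filter_force Low-pass the force channels before resampling.
#' @return A `synced_trial`: list with tibble `data` (time, quaternion and
#'   specific-force columns, `vgrf_left`/`vgrf_right` in N, and the six
#'   reference angles for each variant suffixed `_ref_imu` / `_ref_optical`),
#'   plus `rate`, `subject`, `speed` and the carried-through `events`.
#' @export
resample_trial <- function(trial, target_rate = 120, filter_force = TRUE) {
  stopifnot(inherits(trial, "raw_trial"))
  if (target_rate > trial$imu_rate || target_rate > trial$force_rate) {
    abort("`target_rate` exceeds a source stream rate.",
          class = "imu2grf_bad_rate")
  }
  t_start <- max(trial$imu$time[1L], trial$force$time[1L])
  t_end <- min(tail(trial$imu$time, 1L), tail(trial$force$time, 1L))
  t_out <- seq(t_start, t_end, by = 1 / target_rate)

  imu <- trial$imu
  ratio <- trial$imu_rate / target_rate
  decimate <- abs(ratio - round(ratio)) < 1e-9
  # sign continuity per sensor before any interpolation
  for (pre in c("pelvis_", "shankL_", "shankR_")) {
    cols <- paste0(pre, c("qw", "qx", "qy", "qz"))
    imu[cols] <- as.data.frame(enforce_sign_continuity(as.matrix(imu[cols])))
  }
  if (decimate) {
    idx <- match(round(t_out * trial$imu_rate), round(imu$time * trial$imu_rate))
    stopifnot(!anyNA(idx))
    imu_out <- imu[idx, , drop = FALSE]
    imu_out$time <- t_out
  } else {
    imu_out <- tibble::as_tibble(
      c(list(time = t_out),
        lapply(imu[, -1L], function(v) interp_stream(imu$time, v, t_out)))
    )
  }
  for (pre in c("pelvis_", "shankL_", "shankR_")) {
    cols <- paste0(pre, c("qw", "qx", "qy", "qz"))
    imu_out[cols] <- as.data.frame(quat_normalize(as.matrix(imu_out[cols])))
  }

  fl <- trial$force$vgrf_left
  fr <- trial$force$vgrf_right
  if (filter_force) {
    fl <- filter_vgrf(fl, trial$force_rate)
    fr <- filter_vgrf(fr, trial$force_rate)
  }
  fl <- pmax(interp_stream(trial$force$time, fl, t_out), 0)
  fr <- pmax(interp_stream(trial$force$time, fr, t_out), 0)

  resample_angles <- function(df) {
    if (decimate) {
      idx <- match(round(t_out * trial$imu_rate), round(df$time * trial$imu_rate))
      out <- df[idx, ANGLE_CHANNELS, drop = FALSE]
    } else {
      out <- tibble::as_tibble(lapply(df[, ANGLE_CHANNELS],
                                      function(v) interp_stream(df$time, v, t_out)))
    }
    out
  }
  ref_imu <- resample_angles(trial$ref_angles_imu)
  names(ref_imu) <- paste0(ANGLE_CHANNELS, "_ref_imu")
  ref_opt <- resample_angles(trial$ref_angles_optical)
  names(ref_opt) <- paste0(ANGLE_CHANNELS, "_ref_optical")

  data <- dplyr::bind_cols(imu_out,
                           tibble::tibble(vgrf_left = fl, vgrf_right = fr),
                           ref_imu, ref_opt)
  structure(list(
    data = data,
    rate = target_rate,
    subject = trial$subject,
    speed = trial$speed,
    events = trial$events
  ), class = "synced_trial")
}

#' @export
print.synced_trial <- function(x, ...) {
  cat(sprintf("<synced_trial %s @ %g km/h, %d samples @ %g Hz>\n",
              x$subject$subject_id, x$speed, nrow(x$data), x$rate))
  invisible(x)
}

#' Crop, filter and resample a raw trial in one step
#'
#' @param trial A `raw_trial`.
#' @param trim_head,trim_tail Seconds cropped at each end (default 0; the
#'   simulator produces steady-state trials throughout).
#' @param target_rate Common rate, Hz.
#' @return A `synced_trial`.
#' @export
preprocess_trial <- function(trial, trim_head = 0, trim_tail = 0,
                             target_rate = 120) {
  if (trim_head > 0 || trim_tail > 0) {
    trial <- crop_steady_state(trial, trim_head, trim_tail)
  }
  resample_trial(trial, target_rate = target_rate)
}
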