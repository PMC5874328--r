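# Accelerometer synthesis: second central differences of sensor positions,
# plus gravity, expressed in the sensor frame (specific force -- what an
# accelerometer physically measures), with optional white noise.

second_central_diff <- function(pos, fs) {
  n <- nrow(pos)
  acc <- matrix(0, n, 3L)
  if (n >= 3L) {
    acc[2:(n - 1L), ] <- (pos[3:n, , drop = FALSE] - 2 * pos[2:(n - 1L), , drop = FALSE] +
                            pos[1:(n - 2L), , drop = FALSE]) * fs^2
    acc[1L, ] <- acc[2L, ]
    acc[n, ] <- acc[n - 1L, ]
  }
  acc
}

#' Synthesize specific-force (accelerometer) streams
#'
#' Differentiates sensor positions twice (second central differences), adds
#' gravity, rotates the result into each sensor frame and adds white noise:
#' `f = R_global_to_sensor(p'' + g * z_hat) + noise`.  A static sensor at
#' identity orientation therefore reads `(0, 0, 9.81)` m/s^2.
#'
#' @param positions List of `n x 3` sensor position matrices (m, global
#'   frame), one per sensor.
#' @param quats List of aligned `n x 4` sensor-to-global quaternion
#'   matrices with the same names.
#' @param fs Sampling rate in Hz.
#' @param noise_scale Standard deviation of the additive white noise
#'   (m/s^2, per axis).
#' @param seed Integer seed for the noise.
#' @return A list of `n x 3` specific-force matrices (sensor frame, m/s^2),
#'   same names as `positions`.
#' @export
synthesize_accelerations <- function(positions, quats, fs, noise_scale = 0,
                                     seed = 0L) {
  stopifnot(is.list(positions), is.list(quats))
  if (!identical(names(positions), names(quats))) {
    abort("`positions` and `quats` must have identical sensor names.",
          class = "imu2grf_stream_mismatch")
  }
  ns <- vapply(positions, nrow, integer(1))
  if (length(unique(c(ns, vapply(quats, nrow, integer(1))))) != 1L) {
    abort("All position and quaternion streams must have equal length.",
          class = "imu2grf_stream_mismatch")
  }
  out <- vector("list", length(positions))
  names(out) <- names(positions)
  for (k in seq_along(positions)) {
    acc_global <- second_central_diff(positions[[k]], fs)
    acc_global[, 3L] <- acc_global[, 3L] + GRAVITY
    sf <- quat_rotate(quat_conjugate(quats[[k]]), acc_global)
    if (noise_scale > 0) {
      sf <- sf + with_local_seed(seed + 49979687L + k,
                                 matrix(rnorm(length(sf), 0, noise_scale),
                                        nrow = nrow(sf)))
    }
    out[[k]] <- sf
  }
  out
}
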