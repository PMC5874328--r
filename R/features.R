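# Feature construction for the two networks: pelvis-relative shank
# orientations (ANN 1 input), global-frame vertical free accelerations and
# joint angles (ANN 2 input per feature set), plus the min-max scalers.

#' Feature sets for the force network
#'
#' Named feature combinations for the kinetic network: `a_p` (pelvis
#' vertical acceleration only), `a_pl` (pelvis + both lower legs),
#' `theta` (six joint angles), and the combinations `a_p_theta`,
#' `a_pl_theta` (the full set, default in all evaluations).
#'
#' @format A named list; each element lists the feature column names.
#' @export
FEATURE_SETS <- list(
  a_p = "a_pelvis",
  a_pl = c("a_pelvis", "a_shank_left", "a_shank_right"),
  theta = ANGLE_CHANNELS,
  a_p_theta = c("a_pelvis", ANGLE_CHANNELS),
  a_pl_theta = c("a_pelvis", "a_shank_left", "a_shank_right", ANGLE_CHANNELS)
)

match_feature_set <- function(feature_set) {
  if (!is.character(feature_set) || length(feature_set) != 1L ||
      !feature_set %in% names(FEATURE_SETS)) {
    abort(paste0("`feature_set` must be one of: ",
                 paste(names(FEATURE_SETS), collapse = ", ")),
          class = "imu2grf_bad_feature_set")
  }
  feature_set
}

#' Global-frame vertical free acceleration from specific force
#'
#' Rotates the measured specific force into the global frame and removes
#' gravity: the z-component of `R(q) f` minus 9.81 m/s^2.  Positive values
#' mean upward free acceleration; a static sensor reads 0.
#'
#' @param q Sensor-to-global unit quaternion(s) (length-4 or `n x 4`).
#' @param specific_force Specific force in the sensor frame (length-3 or
#'   `n x 3`, m/s^2, gravity included).
#' @return Numeric scalar or vector (m/s^2).
#' @export
global_vertical_acceleration <- function(q, specific_force) {
  g_global <- quat_rotate(q, specific_force)
  if (is.null(dim(g_global))) g_global[3L] - GRAVITY else g_global[, 3L] - GRAVITY
}

quat_block <- function(data, pre) {
  as.matrix(data[paste0(pre, c("qw", "qx", "qy", "qz"))])
}

accel_block <- function(data, pre) {
  as.matrix(data[paste0(pre, c("ax", "ay", "az"))])
}

ref_angle_matrix <- function(trial, reference) {
  if (!reference %in% c("imu", "optical")) {
    abort("`reference` must be \"imu\" or \"optical\".",
          class = "imu2grf_bad_reference")
  }
  m <- as.matrix(trial$data[paste0(ANGLE_CHANNELS, "_ref_", reference)])
  colnames(m) <- ANGLE_CHANNELS
  m
}

#' Input/target matrices for the kinematic network
#'
#' Builds the first network's training pair from a synchronized trial:
#' the input is the sign-continuous pelvis-relative orientation of each
#' shank sensor (4 quaternion components per side, 8 columns), the target
#' the six sagittal joint angles of the chosen reference variant, aligned
#' row for row.
#'
#' @param trial A `synced_trial`.
#' @param reference `"imu"` or `"optical"` reference angles.
#' @return A list with `X` (`n x 8` matrix: `relL_qw ... relR_qz`), `Y`
#'   (`n x 6` angle matrix, degrees) and `time`.
#' @export
build_ann1_io <- function(trial, reference = "imu") {
  stopifnot(inherits(trial, "synced_trial"))
  qp <- quat_block(trial$data, "pelvis_")
  relL <- enforce_sign_continuity(relative_orientation(qp, quat_block(trial$data, "shankL_")))
  relR <- enforce_sign_continuity(relative_orientation(qp, quat_block(trial$data, "shankR_")))
  colnames(relL) <- paste0("relL_", c("qw", "qx", "qy", "qz"))
  colnames(relR) <- paste0("relR_", c("qw", "qx", "qy", "qz"))
  list(X = cbind(relL, relR), Y = ref_angle_matrix(trial, reference),
       time = trial$data$time)
}

#' Input/target matrices for the kinetic network
#'
#' Assembles the second network's per-sample features: joint angles (the
#' supplied estimate or reference) and/or global-frame vertical free
#' accelerations of pelvis and shank sensors, per the chosen feature set;
#' the target is per-foot vGRF normalized to body weight (zero during
#' flight).
#'
#' @param angles `n x 6` joint-angle matrix aligned with the trial samples
#'   (reference angles for training, network estimates at inference).
#' @param trial A `synced_trial`.
#' @param feature_set One of `names(FEATURE_SETS)` (default `"a_pl_theta"`).
#' @return A list with `X`, `Y` (`n x 2`, columns `vgrf_left`,
#'   `vgrf_right`, BW) and `time`.
#' @export
build_ann2_io <- function(angles, trial, feature_set = "a_pl_theta") {
  stopifnot(inherits(trial, "synced_trial"))
  feature_set <- match_feature_set(feature_set)
  cols <- FEATURE_SETS[[feature_set]]
  n <- nrow(trial$data)
  feats <- list()
  if ("a_pelvis" %in% cols) {
    feats$a_pelvis <- global_vertical_acceleration(
      quat_block(trial$data, "pelvis_"), accel_block(trial$data, "pelvis_"))
  }
  if ("a_shank_left" %in% cols) {
    feats$a_shank_left <- global_vertical_acceleration(
      quat_block(trial$data, "shankL_"), accel_block(trial$data, "shankL_"))
    feats$a_shank_right <- global_vertical_acceleration(
      quat_block(trial$data, "shankR_"), accel_block(trial$data, "shankR_"))
  }
  X <- do.call(cbind, feats)
  if (any(ANGLE_CHANNELS %in% cols)) {
    am <- as.matrix(angles)
    if (nrow(am) != n || ncol(am) != 6L) {
      abort("`angles` must align with the trial samples (n x 6).",
            class = "imu2grf_bad_angles")
    }
    colnames(am) <- ANGLE_CHANNELS
    X <- if (is.null(X)) am else cbind(X, am)
  }
  X <- X[, cols, drop = FALSE]
  bw <- trial$subject$mass * GRAVITY
  Y <- cbind(vgrf_left = trial$data$vgrf_left / bw,
             vgrf_right = trial$data$vgrf_right / bw)
  list(X = X, Y = Y, time = trial$data$time)
}

#' Fit a per-column min-max scaler
#'
#' Affine map sending each training column's minimum to -1 and maximum to
#' +1 (the conventional input mapping for function-fitting networks).
#' Constant columns map to 0 and are flagged.
#'
#' @param X Numeric matrix.
#' @return A `feature_scaler`: list with `center`, `halfrange`, `degenerate`
#'   and `columns`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  degen <- (hi - lo) < .Machine$double.eps
  half <- (hi - lo) / 2
  half[degen] <- 1
  structure(list(center = (hi + lo) / 2, halfrange = half,
                 degenerate = degen, columns = colnames(X)),
            class = "feature_scaler")
}

#' Apply or invert a fitted scaler
#' @param X Numeric matrix with the scaler's column count.
#' @param scaler A `feature_scaler` from [fit_scaler()].
#' @return The scaled matrix (values outside the training range extrapolate
#'   beyond `[-1, 1]`).
#' @export
apply_scaler <- function(X, scaler) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(scaler$center))
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$halfrange, "/")
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(X, scaler) {
  X <- as.matrix(X)
  sweep(sweep(X, 2L, scaler$halfrange, "*"), 2L, scaler$center, "+")
}
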