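# Quaternion utilities.  All quaternions are Hamilton-convention,
# scalar-first numeric vectors of length 4 (w, x, y, z) or n x 4 matrices,
# and encode sensor-to-global (body-to-world) rotations.

quat_is_matrix <- function(q) is.matrix(q) && ncol(q) == 4L

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) {
    stopifnot(length(q) == 4L)
    matrix(q, nrow = 1L)
  } else {
    stopifnot(quat_is_matrix(q))
    q
  }
}

#' Normalize quaternions to unit norm
#'
#' @param q A length-4 quaternion `(w, x, y, z)` or an `n x 4` matrix of
#'   row quaternions.
#' @return Same shape as `q`, each quaternion scaled to unit norm.
#' @export
quat_normalize <- function(q) {
  qm <- as_quat_matrix(q)
  nrm <- sqrt(rowSums(qm^2))
  if (any(nrm < 1e-12)) {
    abort("Cannot normalize a (near-)zero quaternion.", class = "imu2grf_zero_quaternion")
  }
  out <- qm / nrm
  if (is.null(dim(q))) drop(out) else out
}

#' Quaternion conjugate
#' @inheritParams quat_normalize
#' @return Same shape as `q` with the vector part negated.
#' @export
quat_conjugate <- function(q) {
  qm <- as_quat_matrix(q)
  out <- cbind(qm[, 1L], -qm[, 2L], -qm[, 3L], -qm[, 4L], deparse.level = 0)
  if (is.null(dim(q))) drop(out) else out
}

#' Hamilton product of quaternions
#'
#' Row-wise product `a %*% b`; either argument may be a single quaternion,
#' which is recycled.
#'
#' @param a,b Quaternions (length-4 vectors or `n x 4` matrices).
#' @return The Hamilton product, `n x 4` matrix (or vector if both inputs
#'   were vectors).
#' @export
quat_multiply <- function(a, b) {
  am <- as_quat_matrix(a); bm <- as_quat_matrix(b)
  n <- max(nrow(am), nrow(bm))
  if (nrow(am) == 1L && n > 1L) am <- am[rep(1L, n), , drop = FALSE]
  if (nrow(bm) == 1L && n > 1L) bm <- bm[rep(1L, n), , drop = FALSE]
  stopifnot(nrow(am) == nrow(bm))
  w1 <- am[, 1L]; x1 <- am[, 2L]; y1 <- am[, 3L]; z1 <- am[, 4L]
  w2 <- bm[, 1L]; x2 <- bm[, 2L]; y2 <- bm[, 3L]; z2 <- bm[, 4L]
  out <- cbind(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2,
    deparse.level = 0
  )
  if (is.null(dim(a)) && is.null(dim(b))) drop(out) else out
}

#' Quaternion from axis and angle
#'
#' @param axis Length-3 rotation axis (not necessarily unit).
#' @param angle_deg Rotation angle in degrees (scalar or vector).
#' @return A quaternion vector, or an `n x 4` matrix if `angle_deg` has
#'   length > 1.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  out <- cbind(cos(half), sin(half) * axis[1L], sin(half) * axis[2L],
               sin(half) * axis[3L], deparse.level = 0)
  if (length(angle_deg) == 1L) drop(out) else out
}

#' Rotate 3-vectors by quaternions
#'
#' Applies the rotation encoded by `q` (frame of `v` to global) to the rows
#' of `v`.
#'
#' @param q Quaternion(s), length-4 or `n x 4`.
#' @param v A length-3 vector or `n x 3` matrix of row vectors.
#' @return Rotated vectors, same shape as `v` (or expanded to `n x 3`).
#' @export
quat_rotate <- function(q, v) {
  qm <- as_quat_matrix(q)
  vm <- if (is.null(dim(v))) matrix(v, nrow = 1L) else v
  stopifnot(ncol(vm) == 3L)
  n <- max(nrow(qm), nrow(vm))
  if (nrow(qm) == 1L && n > 1L) qm <- qm[rep(1L, n), , drop = FALSE]
  if (nrow(vm) == 1L && n > 1L) vm <- vm[rep(1L, n), , drop = FALSE]
  w <- qm[, 1L]; x <- qm[, 2L]; y <- qm[, 3L]; z <- qm[, 4L]
  vx <- vm[, 1L]; vy <- vm[, 2L]; vz <- vm[, 3L]
  # v' = v + 2*q_vec x (q_vec x v + w*v)
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  out <- cbind(
    vx + w * tx + (y * tz - z * ty),
    vy + w * ty + (z * tx - x * tz),
    vz + w * tz + (x * ty - y * tx),
    deparse.level = 0
  )
  if (is.null(dim(v)) && is.null(dim(q))) drop(out) else out
}

#' Relative orientation of a shank sensor with respect to the pelvis
#'
#' Expresses the shank sensor frame in the pelvis sensor frame:
#' `conj(q_pelvis) * q_shank`, renormalized.  This is the orientation input
#' feature of the first network.
#'
#' @param q_pelvis,q_shank Unit quaternions (length-4 vectors or aligned
#'   `n x 4` matrices), sensor-to-global.
#' @return Unit quaternion(s) of the shank expressed in the pelvis frame.
#' @export
relative_orientation <- function(q_pelvis, q_shank) {
  pm <- as_quat_matrix(q_pelvis); sm <- as_quat_matrix(q_shank)
  chk <- function(m, nm) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm < 1e-12)) abort(paste0(nm, " contains a zero quaternion."),
                                class = "imu2grf_zero_quaternion")
    if (any(abs(nrm - 1) > 1e-6)) abort(paste0(nm, " is not unit-norm (tol 1e-6)."),
                                        class = "imu2grf_not_unit")
  }
  chk(pm, "q_pelvis"); chk(sm, "q_shank")
  quat_normalize(quat_multiply(quat_conjugate(q_pelvis), q_shank))
}

#' Enforce sign continuity of a quaternion time series
#'
#' `q` and `-q` encode the same rotation; regression targets and features
#' must be continuous, so consecutive rows are flipped to have non-negative
#' dot product and the first row to have non-negative scalar part.
#'
#' @param q An `n x 4` matrix of unit quaternions (or a single quaternion).
#' @return Same shape, sign-continuous.
#' @export
enforce_sign_continuity <- function(q) {
  qm <- as_quat_matrix(q)
  n <- nrow(qm)
  if (qm[1L, 1L] < 0) qm[1L, ] <- -qm[1L, ]
  if (n > 1L) {
    dots <- rowSums(qm[-1L, , drop = FALSE] * qm[-n, , drop = FALSE])
    # cumulative: a flip propagates to all later rows
    flip <- cumprod(ifelse(dots < 0, -1, 1))
    qm[-1L, ] <- qm[-1L, , drop = FALSE] * flip
  }
  if (is.null(dim(q))) drop(qm) else qm
}

#' Rotation matrix from a unit quaternion
#' @param q Length-4 unit quaternion.
#' @return 3 x 3 rotation matrix (body-to-global).
#' @keywords internal
quat_to_matrix <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# Rotation-vector (axis*angle, radians) from a unit quaternion; used by the
# iterative angle extraction.
quat_to_rotvec <- function(q) {
  if (q[1L] < 0) q <- -q
  vn <- sqrt(sum(q[2:4]^2))
  if (vn < 1e-14) return(c(0, 0, 0))
  2 * atan2(vn, q[1L]) * q[2:4] / vn
}

# Small random orientation perturbations: rotations about random axes with
# N(0, sd_deg) angles.  Returns n x 4 quaternion matrix.
random_small_rotations <- function(n, sd_deg) {
  if (sd_deg <= 0) {
    return(cbind(rep(1, n), 0, 0, 0))
  }
  ax <- matrix(rnorm(3L * n), ncol = 3L)
  ax <- ax / sqrt(rowSums(ax^2))
  ang <- rnorm(n, 0, sd_deg) * pi / 180
  cbind(cos(ang / 2), sin(ang / 2) * ax[, 1L], sin(ang / 2) * ax[, 2L],
        sin(ang / 2) * ax[, 3L])
}
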