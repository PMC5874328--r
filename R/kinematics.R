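# Forward kinematics of the reduced sensor chain.
#
# Per side, the shank segment orientation is the pelvis orientation composed
# with a hip rotation about the mediolateral (global-Y-in-pelvis) axis, a
# knee rotation about an axis tilted by the subject's knee-axis obliquity in
# the transverse plane, and a weak coupling of the ankle angle into shank
# roll (mounting/soft-tissue compliance).  The distinct axes make all three
# sagittal angles of a side identifiable from the single pelvis-relative
# shank quaternion, which is what guarantees that the first network's
# six-angle target is a deterministic function of its eight-column input.

HIP_AXIS <- c(0, 1, 0)

knee_axis <- function(tilt_deg) {
  a <- tilt_deg * pi / 180
  c(-sin(a), cos(a), 0)
}

ANKLE_COUPLING_AXIS <- c(0, 0, 1)

# Pelvis-relative shank *segment* rotation for vectors of angles (degrees).
chain_relative_rotation <- function(hip, knee, ankle, tilt_deg, coupling) {
  q <- quat_multiply(quat_from_axis_angle(HIP_AXIS, hip),
                     quat_from_axis_angle(knee_axis(tilt_deg), -knee))
  quat_multiply(q, quat_from_axis_angle(ANKLE_COUPLING_AXIS, coupling * ankle))
}

#' Sensor orientations and positions from joint angles
#'
#' Composes the sagittal kinematic chain (pelvis -> hip -> knee, with ankle
#' coupling into shank roll) and returns sensor-to-global quaternions and
#' sensor positions for the pelvis and both shank sensors.  Sensor
#' quaternions include the subject's fixed mounting misalignments;
#' positions are the smooth chain positions (impact transients are added by
#' the trial simulator).
#'
#' @param subject A `subject_profile`.
#' @param angles A joint-angle tibble as returned by
#'   [joint_angle_trajectory()] (six sagittal angle columns, degrees).
#' @param pelvis_pose A list with `pos` (`n x 3` pelvis positions, m) and
#'   `quat` (`n x 4` pelvis segment orientations); defaults to a static
#'   pelvis at standing height.
#' @return A list with `quat` and `pos`, each a list with elements
#'   `pelvis`, `shank_left`, `shank_right` (`n x 4` / `n x 3` matrices).
#' @export
forward_kinematics <- function(subject, angles, pelvis_pose = NULL) {
  validate_subject(subject)
  ang <- as.data.frame(angles)[, ANGLE_CHANNELS]
  if (any(!is.finite(as.matrix(ang)))) {
    abort("Joint angles must be finite.", class = "imu2grf_bad_angles")
  }
  n <- nrow(ang)
  if (is.null(pelvis_pose)) {
    pelvis_pose <- list(
      pos = matrix(rep(c(0, 0, 0.55 * subject$height), each = n), ncol = 3L),
      quat = cbind(rep(1, n), 0, 0, 0)
    )
  }
  qp <- pelvis_pose$quat
  stopifnot(nrow(qp) == n, nrow(pelvis_pose$pos) == n)

  one_side <- function(side) {
    pre <- if (side == "left") "left_" else "right_"
    hip <- ang[[paste0(pre, "hip")]]
    knee <- ang[[paste0(pre, "knee")]]
    ankle <- ang[[paste0(pre, "ankle")]]
    q_rel <- chain_relative_rotation(hip, knee, ankle,
                                     subject$knee_axis_tilt_deg,
                                     subject$ankle_coupling)
    q_seg <- quat_multiply(qp, q_rel)
    # positions down the chain
    ml <- if (side == "left") 0.09 else -0.09
    hip_pos <- pelvis_pose$pos + quat_rotate(qp, c(0, ml, -0.12))
    q_thigh <- quat_multiply(qp, quat_from_axis_angle(HIP_AXIS, hip))
    knee_pos <- hip_pos + quat_rotate(q_thigh, c(0, 0, -subject$thigh_length))
    sens_pos <- knee_pos + quat_rotate(q_seg, c(0, 0, -0.6 * subject$shank_length))
    mount <- subject$mounts[[paste0("shank_", side)]]
    list(quat = quat_multiply(q_seg, mount), pos = sens_pos)
  }

  left <- one_side("left")
  right <- one_side("right")
  list(
    quat = list(
      pelvis = quat_multiply(qp, subject$mounts$pelvis),
      shank_left = left$quat,
      shank_right = right$quat
    ),
    pos = list(
      pelvis = pelvis_pose$pos,
      shank_left = left$pos,
      shank_right = right$pos
    )
  )
}

#' Recover sagittal chain angles from pelvis-relative shank rotations
#'
#' Inverts [forward_kinematics()] for one side: given pelvis-relative shank
#' *segment* quaternions (mounting offsets removed), solves for the hip,
#' knee and ankle angles by Gauss-Newton iteration on the rotation-vector
#' residual, warm-starting each sample from the previous solution.  Used to
#' verify that the simulated orientations encode the reference angles.
#'
#' @param q_rel `n x 4` pelvis-relative shank segment quaternions.
#' @param subject A `subject_profile` (for axis obliquity and coupling).
#' @param init Optional length-3 starting angles (degrees).
#' @return An `n x 3` matrix with columns `hip`, `knee`, `ankle` (degrees).
#' @export
extract_chain_angles <- function(q_rel, subject, init = c(10, 30, 0)) {
  qm <- as_quat_matrix(q_rel)
  n <- nrow(qm)
  out <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("hip", "knee", "ankle")))
  tilt <- subject$knee_axis_tilt_deg
  coup <- subject$ankle_coupling
  h <- 1e-5

  solve_one <- function(target, start) {
    theta <- start
    resid <- Inf
    for (iter in 1:50) {
      qmod <- chain_relative_rotation(theta[1L], theta[2L], theta[3L], tilt, coup)
      r <- quat_to_rotvec(quat_multiply(quat_conjugate(qmod), target))
      resid <- sqrt(sum(r^2))
      if (resid < 1e-12) break
      J <- matrix(0, 3L, 3L)
      for (j in 1:3) {
        tp <- theta; tp[j] <- tp[j] + h
        qj <- chain_relative_rotation(tp[1L], tp[2L], tp[3L], tilt, coup)
        rj <- quat_to_rotvec(quat_multiply(quat_conjugate(qj), target))
        J[, j] <- (rj - r) / h
      }
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) break
      theta <- theta + step
      if (max(abs(step)) < 1e-10) break
    }
    # hip/knee rotate by the angle itself, so +/-360 deg is the identity;
    # the ankle enters scaled by the coupling, so its period is 360/coupling
    theta[1:2] <- ((theta[1:2] + 180) %% 360) - 180
    pa <- 360 / coup
    theta[3L] <- ((theta[3L] + pa / 2) %% pa) - pa / 2
    list(theta = theta, resid = resid)
  }

  theta_prev <- init
  # the decomposition has discrete solution branches (essentially
  # knee -> ~180 - knee with compensating hip/ankle shifts); the
  # physiologic branch keeps knee below ~90 deg and moderate hip/ankle
  plausible <- function(th) th[2L] > -30 && th[2L] < 90 && max(abs(th)) <= 120
  for (i in seq_len(n)) {
    target <- qm[i, ]
    sol <- solve_one(target, theta_prev)
    if (sol$resid > 1e-9 || !plausible(sol$theta)) {
      # enumerate every branch exactly and polish with Gauss-Newton
      cands <- lapply(chain_angle_candidates(target, tilt, coup),
                      function(s) solve_one(target, s))
      cands <- c(cands, list(sol, solve_one(target, init)))
      ok <- vapply(cands, function(cc) cc$resid < 1e-9, logical(1))
      pl <- ok & vapply(cands, function(cc) plausible(cc$theta), logical(1))
      pick <- if (any(pl)) which(pl) else if (any(ok)) which(ok) else seq_along(cands)
      good <- cands[pick]
      sol <- good[[which.min(vapply(good, function(cc)
        if (cc$resid < 1e-9) max(abs(cc$theta)) else 1e6 + cc$resid,
        numeric(1)))]]
    }
    theta_prev <- sol$theta
    out[i, ] <- sol$theta
  }
  out
}

# Exact enumeration of the chain decompositions of one target quaternion.
#
# With e_k = Rz(tilt) y_hat, the chain factors as
#   Q = Ry(h) R(e_k, -k) Rz(c*a) = Ry(h) Rz(tilt) Ry(-k) Rz(c*a - tilt),
# i.e. M(h) = Ry(-h) Q must admit a ZYZ factorization whose first angle is
# `tilt` (mod 180, covering both equivalent ZYZ representations).  That
# requires sin(phi(h) - tilt) = 0 with phi = atan2(M23, M13), which reduces
# to A + B cos(h) + C sin(h) = 0 -- at most two roots, in closed form.
chain_angle_candidates <- function(target, tilt_deg, coup) {
  Qm <- quat_to_matrix(quat_normalize(target))
  al <- tilt_deg * pi / 180
  A <- cos(al) * Qm[2L, 3L]
  B <- -sin(al) * Qm[1L, 3L]
  C <- sin(al) * Qm[3L, 3L]
  R <- sqrt(B^2 + C^2)
  if (R < 1e-12 || abs(A / R) > 1) return(list())
  delta <- atan2(C, B)
  hs <- delta + c(1, -1) * acos(max(-1, min(1, -A / R)))
  out <- list()
  for (hr in unique(round(hs, 12))) {
    Ry <- quat_to_matrix(quat_from_axis_angle(c(0, 1, 0), -hr * 180 / pi))
    M <- Ry %*% Qm
    s_th <- cos(al) * M[1L, 3L] + sin(al) * M[2L, 3L]
    if (abs(s_th) < 1e-10) next
    th <- atan2(s_th, M[3L, 3L])
    psi <- atan2(M[3L, 2L] / s_th, -M[3L, 1L] / s_th)
    out <- c(out, list(c(atan2(sin(hr), cos(hr)) * 180 / pi,
                         -th * 180 / pi,
                         (psi + al) * 180 / pi / coup)))
  }
  out
}

# Pelvis segment orientation over the stride: small pitch (double-bounce)
# and roll (once-per-stride) oscillations.
pelvis_orientation <- function(subject, phase) {
  osc <- subject$pelvis_osc
  pitch <- osc$pitch * sin(4 * pi * phase + osc$phase)
  roll <- osc$roll * sin(2 * pi * phase)
  quat_multiply(quat_from_axis_angle(c(0, 1, 0), pitch),
                quat_from_axis_angle(c(1, 0, 0), roll))
}
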