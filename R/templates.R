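# Periodic joint-angle templates.  Each joint's sagittal trajectory over the
# stride cycle is a truncated Fourier series (stored as coefficients in the
# subject profile) with a linear-in-speed modulation waveform, so that e.g.
# the stance knee-flexion maximum grows with belt speed while the template
# stays exactly periodic in stride phase.

# Periodic Gaussian bump on [0,1)
periodic_gauss <- function(phase, center, width) {
  d <- (phase - center) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  exp(-0.5 * (d / width)^2)
}

# Fit a truncated Fourier series to f evaluated on a 256-point grid.
fourier_fit <- function(f, n_harm = N_FOURIER) {
  n <- 256L
  phase <- (0:(n - 1L)) / n
  y <- f(phase)
  X <- fft(y) / n
  k <- seq_len(n_harm)
  list(a0 = Re(X[1L]), a = 2 * Re(X[k + 1L]), b = -2 * Im(X[k + 1L]))
}

# Evaluate a fitted Fourier series at arbitrary phases.
fourier_eval <- function(coeffs, phase) {
  k <- seq_along(coeffs$a)
  arg <- outer(2 * pi * phase, k)   # n x K
  drop(coeffs$a0 + cos(arg) %*% coeffs$a + sin(arg) %*% coeffs$b)
}

# Draw per-subject template coefficients (called inside make_subject's
# seeded block).  Each joint stores a `base` waveform (degrees at 12 km/h)
# and a `mod` waveform (degrees per km/h of deviation from 12 km/h).
draw_angle_templates <- function(strike_type) {
  A_st <- 30 + rnorm(1, 0, 3)       # stance knee-flexion bump amplitude
  # swing peak kept below ~88 deg: the chain's angle decomposition has a
  # second solution branch meeting the first near 90 deg knee flexion
  A_sw <- 72 + rnorm(1, 0, 4)       # swing knee-flexion bump amplitude
  A_h  <- 25 + rnorm(1, 0, 2)       # hip flexion/extension half-range
  h0   <- 10 + rnorm(1, 0, 2)
  hip_ph <- rnorm(1, 0, 0.01)
  hip_w2 <- rnorm(1, 0, 1.5)        # second-harmonic hip wobble
  psi  <- runif(1, 0, 2 * pi)
  A_po <- 14 + rnorm(1, 0, 2)       # ankle push-off plantarflexion dip
  contact_off <- switch(strike_type, rearfoot = 6, midfoot = 0, forefoot = -8) +
    rnorm(1, 0, 1)

  knee_base <- function(p) {
    8 + A_st * periodic_gauss(p, 0.14, 0.065) + A_sw * periodic_gauss(p, 0.72, 0.10)
  }
  knee_mod <- function(p) {
    0.018 * A_st * periodic_gauss(p, 0.14, 0.065) +
      0.010 * A_sw * periodic_gauss(p, 0.72, 0.10)
  }
  hip_base <- function(p) {
    h0 + A_h * cos(2 * pi * (p - 0.02 - hip_ph)) + hip_w2 * sin(4 * pi * p + psi)
  }
  hip_mod <- function(p) 0.012 * A_h * cos(2 * pi * (p - 0.02 - hip_ph))
  ankle_base <- function(p) {
    -2 + 8 * cos(2 * pi * p - 0.5) - A_po * periodic_gauss(p, 0.30, 0.07) +
      contact_off * periodic_gauss(p, 0.0, 0.05)
  }
  ankle_mod <- function(p) -0.012 * A_po * periodic_gauss(p, 0.30, 0.07)

  list(
    hip = list(base = fourier_fit(hip_base), mod = fourier_fit(hip_mod)),
    knee = list(base = fourier_fit(knee_base), mod = fourier_fit(knee_mod)),
    ankle = list(base = fourier_fit(ankle_base), mod = fourier_fit(ankle_mod))
  )
}

# Evaluate one joint template for one side.  `phase` is the left-leg stride
# phase; the right leg uses the same template shifted by half a stride plus
# the subject's asymmetry (phase offset and amplitude factor).
eval_joint <- function(subject, joint, side, speed, phase) {
  tc <- subject$angle_template_coeffs[[joint]]
  if (side == "right") {
    phase <- (phase - 0.5 - subject$asymmetry$phase) %% 1
  }
  val <- fourier_eval(tc$base, phase) + (speed - 12) * fourier_eval(tc$mod, phase)
  if (side == "right") val <- subject$asymmetry$amp * val
  val
}

#' Sagittal joint-angle trajectories over the stride cycle
#'
#' Evaluates the subject's periodic hip/knee/ankle templates at the given
#' stride phases.  The left leg makes ground contact at phase 0; the right
#' leg uses the same templates shifted by half a stride plus a small
#' subject-specific asymmetry.  The stance knee-flexion maximum scales with
#' belt speed.
#'
#' @param subject A `subject_profile`.
#' @param speed Belt speed in km/h (> 0).
#' @param phase Numeric vector of stride fractions in `[0, 1)` (values are
#'   wrapped modulo 1).
#' @return A tibble with columns `time` (phase times the stride period, s),
#'   `phase`, and the six sagittal angles in degrees, flexion positive:
#'   `left_hip`, `left_knee`, `left_ankle`, `right_hip`, `right_knee`,
#'   `right_ankle`.
#' @examples
#' s <- make_subject(1)
#' joint_angle_trajectory(s, 12, seq(0, 0.99, by = 0.01))
#' @export
joint_angle_trajectory <- function(subject, speed, phase) {
  validate_subject(subject)
  if (!is.numeric(speed) || length(speed) != 1L || speed <= 0) {
    abort("`speed` must be a single positive number (km/h).",
          class = "imu2grf_bad_speed")
  }
  phase <- phase %% 1
  T_str <- stride_period(subject, speed)
  tibble::tibble(
    time = phase * T_str,
    phase = phase,
    left_hip = eval_joint(subject, "hip", "left", speed, phase),
    left_knee = eval_joint(subject, "knee", "left", speed, phase),
    left_ankle = eval_joint(subject, "ankle", "left", speed, phase),
    right_hip = eval_joint(subject, "hip", "right", speed, phase),
    right_knee = eval_joint(subject, "knee", "right", speed, phase),
    right_ankle = eval_joint(subject, "ankle", "right", speed, phase)
  )
}
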