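# Vertical ground reaction force synthesis.
#
# Each stance is a double-humped profile: an active half-sine with peak
# `peak_vgrf_multiple` body weights plus, for rearfoot strikers, an early
# passive (impact) transient modeled as a Gaussian bump peaking 15-35 ms
# after initial contact.  The stance duty factor is derived from the peak
# multiple through impulse balance (see `derive_duty_factor`), so the
# time-averaged total force over an integer number of strides equals body
# weight.  Per-stance amplitude jitter emulates stride-to-stride variation.

# Table of all stance events of a trial.  Left contacts at k*T, right
# contacts half a stride later (plus the subject's phase asymmetry).
stance_schedule <- function(subject, speed, duration, seed = 0L) {
  T_str <- stride_period(subject, speed)
  if (duration <= 2 * T_str) {
    abort("`duration` must exceed two stride periods.", class = "imu2grf_short_trial")
  }
  d <- derive_duty_factor(subject, speed)
  peak <- peak_multiple_at_speed(subject, speed)
  n_str <- ceiling(duration / T_str) + 1L
  contacts_l <- (seq_len(n_str) - 1L) * T_str
  contacts_r <- contacts_l + (0.5 + subject$asymmetry$phase) * T_str
  sch <- tibble::tibble(
    side = rep(c("left", "right"), each = n_str),
    t_contact = c(contacts_l, contacts_r),
    stance_dur = d * T_str,
    duty = d,
    peak_multiple = peak,
    passive_amplitude = subject$passive_amplitude,
    t_passive = subject$t_passive
  )
  sch <- dplyr::arrange(sch, .data$t_contact)
  sch$jitter <- with_local_seed(seed + 15485863L,
                                1 + rnorm(nrow(sch), 0, subject$stride_jitter_sd))
  sch[sch$t_contact + sch$stance_dur <= duration + 2 * T_str, ]
}

# Deterministic (noise-free) force of one side evaluated at `times`.
eval_vgrf_schedule <- function(schedule, subject, times, side) {
  out <- numeric(length(times))
  mg <- subject$mass * GRAVITY
  sub <- schedule[schedule$side == side, ]
  for (i in seq_len(nrow(sub))) {
    ev <- sub[i, ]
    s <- (times - ev$t_contact) / ev$stance_dur
    idx <- which(s >= 0 & s <= 1)
    if (length(idx) == 0L) next
    si <- s[idx]
    prof <- ev$peak_multiple * sin(pi * si)
    if (ev$passive_amplitude > 0) {
      prof <- prof + ev$passive_amplitude *
        passive_bump((times[idx] - ev$t_contact) / ev$t_passive)
    }
    out[idx] <- out[idx] + ev$jitter * mg * prof
  }
  out
}

#' Synthesize per-foot vertical ground reaction forces
#'
#' Generates left/right vGRF traces for a steady treadmill run: zero during
#' flight, per-stance double-humped profiles whose active peak equals the
#' subject's (speed-adjusted) peak vGRF multiple, with an early passive
#' transient for rearfoot strikers.  Stance timing follows the subject's
#' cadence and impulse-balanced duty factor, so the mean total force over an
#' integer number of strides is body weight within ~2%.
#'
#' @param subject A `subject_profile`.
#' @param speed Belt speed in km/h.
#' @param duration Trial length in s (must exceed two stride periods).
#' @param fs Sampling rate in Hz (>= 200, to resolve the passive transient).
#' @param seed Integer seed for stride-to-stride jitter and measurement
#'   noise.
#' @param noise If `FALSE`, omit the additive measurement noise.
#' @return A list with `force_left`, `force_right` (numeric vectors, N),
#'   `time` (s) and `events` (the stance schedule tibble, one row per
#'   stance with contact time, duration and passive-peak offset).
#' @export
synthesize_vgrf <- function(subject, speed, duration, fs = 1000, seed = 0L,
                            noise = TRUE) {
  validate_subject(subject)
  if (fs < 200) {
    abort("`fs` must be >= 200 Hz to resolve the passive transient.",
          class = "imu2grf_low_fs")
  }
  sch <- stance_schedule(subject, speed, duration, seed = seed)
  times <- seq(0, duration - 1 / fs, by = 1 / fs)
  fl <- eval_vgrf_schedule(sch, subject, times, "left")
  fr <- eval_vgrf_schedule(sch, subject, times, "right")
  if (noise && subject$noise_scales$force_n > 0) {
    nz <- with_local_seed(seed + 32452843L, {
      list(l = rnorm(length(fl), 0, subject$noise_scales$force_n),
           r = rnorm(length(fr), 0, subject$noise_scales$force_n))
    })
    fl <- ifelse(fl > 0, pmax(fl + nz$l, 0), 0)
    fr <- ifelse(fr > 0, pmax(fr + nz$r, 0), 0)
  }
  list(force_left = fl, force_right = fr, time = times, events = sch)
}
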