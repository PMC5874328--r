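# Trial-level simulation: composes the stance schedule, pelvis dynamics
# (double integration of total force), the kinematic chain, accelerometer
# synthesis and the two kinematic reference variants into a raw trial.

cumtrapz1 <- function(x, dt) {
  n <- length(x)
  c(0, cumsum((x[-1L] + x[-n]) / 2) * dt)
}

moving_average <- function(x, window) {
  window <- max(3L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  # extend edges with nearest valid value
  ok <- which(!is.na(sm))
  sm[seq_len(ok[1L] - 1L)] <- sm[ok[1L]]
  sm[seq(ok[length(ok)] + 1L, length.out = length(sm) - ok[length(ok)])] <- sm[ok[length(ok)]]
  sm
}

# Pelvis vertical trajectory consistent with the (jittered, noise-free)
# total force: z'' = F_tot/m - g.  Velocity is detrended with a one-stride
# moving average to suppress the slow random walk caused by per-stride
# amplitude jitter.
pelvis_height_from_force <- function(f_total, mass, fs, stride_samples, height) {
  a <- f_total / mass - GRAVITY
  v <- cumtrapz1(a, 1 / fs)
  v <- v - moving_average(v, stride_samples)
  z <- cumtrapz1(v, 1 / fs)
  z - mean(z) + 0.55 * height
}

#' Simulate one synthetic treadmill-running trial
#'
#' Generates a complete raw trial for one subject at one belt speed:
#' per-foot vGRF at `force_rate`, sensor quaternions and specific forces for
#' the pelvis and both shank sensors at `imu_rate`, and two kinematic
#' reference variants (an inertial-like reference equal to the chain
#' ground truth, and an optical-like reference with a smooth
#' subject-specific offset of amplitude at most 5 degrees plus small
#' noise).  Pelvis vertical motion is obtained by double integration of the
#' total force, so pelvis acceleration and the force target are physically
#' consistent; shank positions additionally carry an impact displacement
#' transient whose acceleration peak coincides with the passive force peak.
#'
#' @param subject A `subject_profile`.
#' @param speed Belt speed in km/h.
#' @param duration Trial length in seconds (>= 10; default 180, the per-speed
#'   bout length of the emulated protocol).
#' @param seed Integer seed controlling all stochastic components.
#' @param imu_rate,force_rate Native sampling rates (Hz).
#' @return A `raw_trial` object: a list with tibbles `imu` (time plus
#'   per-sensor `qw,qx,qy,qz,ax,ay,az` columns prefixed `pelvis_`,
#'   `shankL_`, `shankR_`), `force` (`time`, `vgrf_left`, `vgrf_right` in
#'   N), `ref_angles_imu` and `ref_angles_optical` (time plus six sagittal
#'   angles, degrees), the stance `events` table, and metadata (`subject`,
#'   `speed`, `imu_rate`, `force_rate`, `seed`).
#' @examples
#' trial <- simulate_trial(make_subject(1), 12, duration = 12, seed = 1)
#' trial$force
#' @export
simulate_trial <- function(subject, speed, duration = 180, seed = 0L,
                           imu_rate = 240, force_rate = 1000) {
  validate_subject(subject)
  if (duration < 10) {
    abort("`duration` must be at least 10 s.", class = "imu2grf_short_trial")
  }
  if (force_rate <= imu_rate) {
    abort("`force_rate` must exceed `imu_rate`.", class = "imu2grf_bad_rates")
  }
  T_str <- stride_period(subject, speed)

  grf <- synthesize_vgrf(subject, speed, duration, fs = force_rate,
                         seed = seed, noise = TRUE)
  sch <- grf$events

  t_imu <- seq(0, duration - 1 / imu_rate, by = 1 / imu_rate)
  n <- length(t_imu)
  f_tot_imu <- eval_vgrf_schedule(sch, subject, t_imu, "left") +
    eval_vgrf_schedule(sch, subject, t_imu, "right")
  z_pelvis <- pelvis_height_from_force(f_tot_imu, subject$mass, imu_rate,
                                       round(T_str * imu_rate), subject$height)
  phase <- (t_imu / T_str) %% 1
  pelvis_pos <- cbind(0.02 * sin(4 * pi * phase), 0.03 * sin(2 * pi * phase),
                      z_pelvis)
  pelvis_quat <- pelvis_orientation(subject, phase)

  angles <- joint_angle_trajectory(subject, speed, phase)
  angles$time <- t_imu
  fk <- forward_kinematics(subject, angles,
                           pelvis_pose = list(pos = pelvis_pos, quat = pelvis_quat))

  # impact displacement transients on the shank sensors (acceleration peak
  # a_pk at t_contact + t_passive)
  a_pk <- if (subject$strike_type == "rearfoot") 100 else 45
  sigma <- 0.008
  for (side in c("left", "right")) {
    key <- paste0("shank_", side)
    ev <- sch[sch$side == side, ]
    dip <- numeric(n)
    for (i in seq_len(nrow(ev))) {
      t_imp <- ev$t_contact[i] + ev$t_passive[i]
      idx <- which(abs(t_imu - t_imp) < 6 * sigma)
      if (length(idx) > 0L) {
        dip[idx] <- dip[idx] - a_pk * sigma^2 *
          exp(-0.5 * ((t_imu[idx] - t_imp) / sigma)^2)
      }
    }
    fk$pos[[key]][, 3L] <- fk$pos[[key]][, 3L] + dip
  }

  accels <- synthesize_accelerations(fk$pos, fk$quat, imu_rate,
                                     noise_scale = subject$noise_scales$accel,
                                     seed = seed)

  # orientation noise: right-compose each sensor quaternion with a small
  # random rotation; reference angles stay exact
  quats <- fk$quat
  if (subject$noise_scales$orientation_deg > 0) {
    quats <- with_local_seed(seed + 86028121L, {
      lapply(quats, function(q) {
        quat_normalize(quat_multiply(
          q, random_small_rotations(nrow(q), subject$noise_scales$orientation_deg)))
      })
    })
  } else {
    quats <- lapply(quats, quat_normalize)
  }

  sensor_cols <- function(pre, q, a) {
    out <- cbind(q, a)
    colnames(out) <- paste0(pre, c("qw", "qx", "qy", "qz", "ax", "ay", "az"))
    tibble::as_tibble(out)
  }
  imu <- dplyr::bind_cols(
    tibble::tibble(time = t_imu),
    sensor_cols("pelvis_", quats$pelvis, accels$pelvis),
    sensor_cols("shankL_", quats$shank_left, accels$shank_left),
    sensor_cols("shankR_", quats$shank_right, accels$shank_right)
  )

  ref_imu <- angles[, c("time", ANGLE_CHANNELS)]

  # optical-like reference: smooth per-subject offset (cubic polynomial of
  # stride phase, clipped to <= 5 deg amplitude) plus small noise
  u <- 2 * phase - 1
  cheb <- cbind(1, u, 2 * u^2 - 1, 4 * u^3 - 3 * u)
  off <- cheb %*% t(subject$optical_offset_coeffs)   # n x 6
  mx <- max(abs(off))
  if (mx > 5) off <- off * (5 / mx)
  opt_noise <- with_local_seed(seed + 67867967L,
                               matrix(rnorm(n * 6L, 0, 0.3), nrow = n))
  ref_opt <- ref_imu
  ref_opt[, ANGLE_CHANNELS] <- ref_imu[, ANGLE_CHANNELS] + off + opt_noise

  structure(list(
    subject = subject,
    speed = speed,
    duration = duration,
    seed = seed,
    imu_rate = imu_rate,
    force_rate = force_rate,
    imu = imu,
    force = tibble::tibble(time = grf$time, vgrf_left = grf$force_left,
                           vgrf_right = grf$force_right),
    ref_angles_imu = ref_imu,
    ref_angles_optical = ref_opt,
    events = sch
  ), class = "raw_trial")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial %s @ %g km/h, %gs (imu %g Hz, force %g Hz, seed %d)>\n",
              x$subject$subject_id, x$speed, x$duration, x$imu_rate,
              x$force_rate, x$seed))
  invisible(x)
}

#' Simulate a multi-subject, multi-speed study
#'
#' Generates the full study design the estimation method is evaluated on:
#' `n_subjects` synthetic runners, each running at every speed for
#' `duration` seconds.  Subject seeds are `subject_seed_base + 1 ...
#' subject_seed_base + n_subjects`, so the default reproduces subjects
#' seeded 1-8; over any such block the strike-type mix is 5 rearfoot /
#' 2 midfoot / 1 forefoot.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param speeds Belt speeds in km/h (default `c(10, 12, 14)`).
#' @param duration Per-trial length in s (default 180).
#' @param subject_seed_base Offset added to subject indices to form seeds.
#' @param trial_seed_base Offset mixed into per-trial noise seeds.
#' @return A tibble with columns `subject_id`, `speed`, `seed` and a
#'   list-column `trial` of `raw_trial` objects.
#' @export
simulate_study <- function(n_subjects = 8, speeds = c(10, 12, 14),
                           duration = 180, subject_seed_base = 0L,
                           trial_seed_base = 0L) {
  grid <- tidyr::expand_grid(idx = seq_len(n_subjects), speed = speeds)
  rows <- purrr::pmap(grid, function(idx, speed) {
    subject <- make_subject(subject_seed_base + idx)
    tseed <- trial_seed_base + 1009L * idx + round(7L * speed)
    trial <- simulate_trial(subject, speed, duration = duration, seed = tseed)
    tibble::tibble(subject_id = subject$subject_id, speed = speed,
                   seed = tseed, trial = list(trial))
  })
  dplyr::bind_rows(rows)
}
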