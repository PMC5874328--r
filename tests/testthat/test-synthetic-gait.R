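# The synthetic running simulator: subject sampling, angle templates,
# forward kinematics, force synthesis, accelerometers, and whole trials.

test_that("make_subject is deterministic, overridable, and population-plausible", {
  expect_identical(make_subject(1), make_subject(1))
  expect_equal(make_subject(1, overrides = list(mass = 70))$mass, 70)
  expect_error(make_subject(1, overrides = list(bogus = 1)),
               class = "imu2grf_bad_override")
  expect_error(make_subject(-1), class = "imu2grf_bad_seed")
  profs <- lapply(1:8, make_subject)
  masses <- vapply(profs, `[[`, numeric(1), "mass")
  expect_gt(mean(masses), 77.7 - 9.4)
  expect_lt(mean(masses), 77.7 + 9.4)
  strikes <- vapply(profs, `[[`, character(1), "strike_type")
  expect_setequal(unique(strikes), c("rearfoot", "midfoot", "forefoot"))
  for (p in profs) {
    expect_gt(p$duty_factor, 0); expect_lt(p$duty_factor, 0.5)
    expect_gte(p$peak_vgrf_multiple, 2.0); expect_lte(p$peak_vgrf_multiple, 3.5)
  }
})

test_that("joint-angle templates are periodic, speed-scaled, and shaped like gait", {
  s <- make_subject(3)
  eps <- 1e-9
  a0 <- joint_angle_trajectory(s, 12, 0)
  a1 <- joint_angle_trajectory(s, 12, 1 - eps)
  for (ch in imu2grf:::ANGLE_CHANNELS) {
    expect_equal(a0[[ch]], a1[[ch]], tolerance = 1e-5)
  }
  expect_error(joint_angle_trajectory(s, -1, 0.5), class = "imu2grf_bad_speed")

  grid <- seq(0, 0.999, length.out = 2000)
  for (seed in 1:8) {
    sub <- make_subject(seed)
    ang <- joint_angle_trajectory(sub, 12, grid)
    stance <- grid < sub$duty_factor
    stance_max <- max(ang$left_knee[stance])
    swing_max <- max(ang$left_knee[!stance])
    expect_gt(swing_max, stance_max)
    expect_true(all(ang$left_knee > -10 & ang$left_knee < 140))
  }
  # stance knee-flexion maximum grows from 10 to 14 km/h
  sub <- make_subject(3)
  st <- grid < sub$duty_factor
  m10 <- max(joint_angle_trajectory(sub, 10, grid)$left_knee[st])
  m14 <- max(joint_angle_trajectory(sub, 14, grid)$left_knee[st])
  expect_gt(m14, m10)
})

test_that("forward kinematics matches single-axis expectations for an ideal chain", {
  s <- make_subject(1, overrides = list(
    knee_axis_tilt_deg = 0, ankle_coupling = 0,
    mounts = list(pelvis = c(1, 0, 0, 0), shank_left = c(1, 0, 0, 0),
                  shank_right = c(1, 0, 0, 0))
  ))
  zero <- tibble::as_tibble(setNames(as.list(rep(0, 6)),
                                     imu2grf:::ANGLE_CHANNELS))
  fk <- forward_kinematics(s, zero)
  for (q in fk$quat) expect_equal(drop(q), c(1, 0, 0, 0), tolerance = 1e-12)
  # hip 0, knee 90 flexion -> shank rotated 90 deg about the mediolateral axis
  ang <- zero
  ang$left_knee <- 90
  fk <- forward_kinematics(s, ang)
  expect_equal(abs(drop(fk$quat$shank_left)),
               abs(quat_from_axis_angle(c(0, 1, 0), -90)), tolerance = 1e-12)
  expect_equal(drop(fk$quat$shank_right), c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("chain angles are recoverable from simulated quaternions", {
  s <- make_subject(7)
  # smooth random angle series through the physiologic range
  set.seed(7)
  tt <- seq(0, 1, length.out = 500)
  smooth <- function(lo, hi) {
    y <- rowSums(sapply(1:4, function(k) {
      rnorm(1, 0, 1 / k) * cos(2 * pi * k * tt) +
        rnorm(1, 0, 1 / k) * sin(2 * pi * k * tt)
    }))
    lo + (hi - lo) * (y - min(y)) / (max(y) - min(y))
  }
  ang <- tibble::tibble(
    left_hip = smooth(-15, 35), left_knee = smooth(0, 88),
    left_ankle = smooth(-25, 15), right_hip = smooth(-15, 35),
    right_knee = smooth(0, 88), right_ankle = smooth(-25, 15)
  )
  fk <- forward_kinematics(s, ang)
  for (side in c("left", "right")) {
    key <- paste0("shank_", side)
    q_rel <- relative_orientation(fk$quat$pelvis, fk$quat[[key]])
    q_seg <- quat_multiply(quat_multiply(s$mounts$pelvis, q_rel),
                           quat_conjugate(s$mounts[[key]]))
    ex <- extract_chain_angles(q_seg, s)
    truth <- as.matrix(ang[paste0(side, c("_hip", "_knee", "_ankle"))])
    expect_lt(max(abs(ex - truth)), 1e-6)
  }
})

test_that("synthesized vGRF is impulse-balanced with the configured peak", {
  s <- make_subject(3, overrides = list(stride_jitter_sd = 0))
  s$mass <- 70
  s$peak_vgrf_multiple <- 3.0
  s$duty_factor <- imu2grf:::derive_duty_factor(s, 12)
  grf <- synthesize_vgrf(s, 12, 60, fs = 1000, seed = 5, noise = FALSE)
  expect_equal(min(grf$force_left), 0)   # flight phases
  # per-stance maximum: 3.0 * 70 * 9.81 at 12 km/h (speed-anchored peak)
  expect_equal(max(grf$force_left), 2060.1, tolerance = 0.01)
  # impulse balance over an integer number of strides
  T_str <- stride_period(s, 12)
  sel <- grf$time < floor(60 / T_str) * T_str
  ratio <- mean(grf$force_left[sel] + grf$force_right[sel]) / (70 * 9.81)
  expect_gt(ratio, 0.98); expect_lt(ratio, 1.02)
  expect_error(synthesize_vgrf(s, 12, 60, fs = 100), class = "imu2grf_low_fs")
})

test_that("accelerometers read specific force in the sensor frame", {
  n <- 50
  static_pos <- list(s1 = matrix(0, n, 3))
  ident <- list(s1 = cbind(rep(1, n), 0, 0, 0))
  acc <- synthesize_accelerations(static_pos, ident, fs = 240)
  expect_equal(acc$s1[10, ], c(0, 0, 9.81), tolerance = 1e-9)
  # vertical oscillation A sin(2 pi f t): specific force g + z''
  fs <- 1000; A <- 0.01; f <- 5
  t <- seq(0, 1, by = 1 / fs)
  pos <- list(s1 = cbind(0, 0, A * sin(2 * pi * f * t)))
  q <- list(s1 = cbind(rep(1, length(t)), 0, 0, 0))
  acc <- synthesize_accelerations(pos, q, fs = fs)
  mid <- 100:900
  expected <- 9.81 - A * (2 * pi * f)^2 * sin(2 * pi * f * t[mid])
  expect_equal(acc$s1[mid, 3], expected, tolerance = 1e-3)
  # determinism with a fixed seed
  a1 <- synthesize_accelerations(pos, q, fs, noise_scale = 0.3, seed = 9)
  a2 <- synthesize_accelerations(pos, q, fs, noise_scale = 0.3, seed = 9)
  expect_identical(a1, a2)
  expect_error(
    synthesize_accelerations(list(s1 = matrix(0, 10, 3)),
                             list(s1 = cbind(rep(1, 9), 0, 0, 0)), 240),
    class = "imu2grf_stream_mismatch")
})

test_that("simulated trials are consistent, deterministic, and carry both references", {
  s <- make_subject(2)
  tr <- simulate_trial(s, 12, duration = 12, seed = 4)
  expect_equal(nrow(tr$force), 12 * 1000)
  expect_equal(nrow(tr$imu), 12 * 240)
  expect_true(all(tr$force$vgrf_left >= 0))
  qn <- sqrt(rowSums(as.matrix(
    tr$imu[paste0("pelvis_", c("qw", "qx", "qy", "qz"))])^2))
  expect_lt(max(abs(qn - 1)), 1e-9)
  expect_identical(simulate_trial(s, 12, duration = 12, seed = 4), tr)
  expect_error(simulate_trial(s, 12, duration = 5, seed = 1),
               class = "imu2grf_short_trial")
  # optical reference differs by a bounded smooth offset on the knee
  dknee <- tr$ref_angles_optical$left_knee - tr$ref_angles_imu$left_knee
  expect_gt(mean(abs(dknee)), 0)
  expect_lte(max(abs(dknee)), 5 + 4 * 0.3)   # offset bound plus noise tails
})

test_that("impact transients co-occur with the passive force peak for rearfoot runners", {
  for (seed in c(1, 2)) {
    s <- make_subject(seed)
    expect_equal(s$strike_type, "rearfoot")
    tr <- simulate_trial(s, 12, duration = 20, seed = 3)
    st <- preprocess_trial(tr)
    for (side in c("left", "right")) {
      pre <- if (side == "left") "shankL_" else "shankR_"
      acc <- global_vertical_acceleration(
        as.matrix(st$data[paste0(pre, c("qw", "qx", "qy", "qz"))]),
        as.matrix(st$data[paste0(pre, c("ax", "ay", "az"))]))
      ev <- tr$events[tr$events$side == side, ]
      ev <- ev[ev$t_contact > 0.5 & ev$t_contact + ev$stance_dur < 19.5, ]
      errs <- vapply(seq_len(nrow(ev)), function(i) {
        t_imp <- ev$t_contact[i] + ev$t_passive[i]
        win <- which(st$data$time >= ev$t_contact[i] &
                       st$data$time < ev$t_contact[i] + 0.5 * ev$stance_dur[i])
        abs(st$data$time[win[which.max(abs(acc[win]))]] - t_imp)
      }, numeric(1))
      expect_lte(max(errs), 0.010)
    }
  }
})

test_that("trials round-trip through the CSV/JSON export", {
  tr <- simulate_trial(make_subject(5), 12, duration = 12, seed = 6)
  stem <- file.path(withr::local_tempdir(), "trial")
  write_trial(tr, stem)
  back <- read_trial(stem)
  expect_equal(back$subject$mass, tr$subject$mass)
  expect_equal(back$subject$strike_type, tr$subject$strike_type)
  expect_equal(back$speed, tr$speed)
  expect_equal(as.data.frame(back$force), as.data.frame(tr$force),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$imu), as.data.frame(tr$imu),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$ref_angles_optical),
               as.data.frame(tr$ref_angles_optical), tolerance = 1e-12)
})
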