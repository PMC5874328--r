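# Synthetic runner profiles.  The simulator emulates a small cohort of
# healthy experienced treadmill runners (mass ~ 77.7 +/- 9.4 kg, height
# ~ 1.84 +/- 0.045 m) with subject-specific gait style: joint-angle
# templates, strike type, impact timing, sensor mounting offsets and a
# slightly oblique knee axis.

SUBJECT_POPULATION <- list(
  mass_mean = 77.7, mass_sd = 9.4,
  height_mean = 1.837, height_sd = 0.045,
  cadence_mean = 82, cadence_sd = 3
)

# strike-type mix over any 8 consecutive seeds: 5 rear / 2 mid / 1 fore
STRIKE_CYCLE <- c("rearfoot", "rearfoot", "midfoot", "rearfoot",
                  "forefoot", "rearfoot", "midfoot", "rearfoot")

# Evaluate a function on [0,1) with seeded RNG isolated from the caller.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Create a synthetic runner profile
#'
#' Draws anthropometry near the emulated population (mass 77.7 +/- 9.4 kg,
#' height 1.837 +/- 0.045 m) and a subject-specific gait style: joint-angle
#' template amplitudes, foot-strike type (5 rearfoot / 2 midfoot /
#' 1 forefoot over any 8 consecutive seeds), peak vGRF multiple, passive
#' impact timing, sensor-mounting misalignments and knee-axis obliquity.
#' The stance duty factor is derived from the peak vGRF multiple through
#' stride impulse balance, so every simulated trial supports a mean total
#' vGRF of one body weight.
#'
#' @param seed Non-negative integer; identical seeds give identical profiles.
#' @param overrides Optional named list of profile fields to set verbatim
#'   after generation (e.g. `list(mass = 70)`).  Unknown names are an error.
#' @return A `subject_profile` object (named list).
#' @examples
#' s <- make_subject(3)
#' s$mass
#' make_subject(3, overrides = list(mass = 70))$mass
#' @export
make_subject <- function(seed, overrides = NULL) {
  if (!is.numeric(seed) || length(seed) != 1L || seed < 0 || seed != round(seed)) {
    abort("`seed` must be a single non-negative integer.", class = "imu2grf_bad_seed")
  }
  seed <- as.integer(seed)
  pop <- SUBJECT_POPULATION
  prof <- with_local_seed(seed + 104729L, {
    strike <- STRIKE_CYCLE[((seed - 1L) %% 8L) + 1L]
    mass <- max(55, rnorm(1, pop$mass_mean, pop$mass_sd))
    height <- max(1.60, rnorm(1, pop$height_mean, pop$height_sd))
    peak <- min(3.4, max(2.2, runif(1, 2.75, 3.2)))
    passive_amp <- if (strike == "rearfoot") runif(1, 0.9, 1.3) else 0
    t_passive <- if (strike == "rearfoot") runif(1, 0.020, 0.030) else runif(1, 0.025, 0.035)
    templ <- draw_angle_templates(strike)
    list(
      subject_id = sprintf("S%02d", ((seed - 1L) %% 99L) + 1L),
      seed = seed,
      mass = mass,
      height = height,
      thigh_length = 0.245 * height,
      shank_length = 0.246 * height,
      cadence_base = rnorm(1, pop$cadence_mean, pop$cadence_sd),
      strike_type = strike,
      peak_vgrf_multiple = peak,
      passive_amplitude = passive_amp,
      t_passive = t_passive,
      duty_factor = NA_real_,  # filled below, derived from peak + strike
      angle_template_coeffs = templ,
      asymmetry = list(amp = 1 + rnorm(1, 0, 0.02), phase = rnorm(1, 0, 0.004)),
      knee_axis_tilt_deg = 10 + rnorm(1, 0, 2),
      ankle_coupling = 0.35,
      mounts = list(
        pelvis = drop(random_small_rotations(1L, 3)),
        shank_left = drop(random_small_rotations(1L, 4)),
        shank_right = drop(random_small_rotations(1L, 4))
      ),
      optical_offset_coeffs = matrix(rnorm(6L * 4L, 0, 1.1), nrow = 6L,
                                     dimnames = list(ANGLE_CHANNELS, NULL)),
      stride_jitter_sd = 0.02,
      pelvis_osc = list(pitch = runif(1, 2, 4), roll = runif(1, 1, 2.5),
                        phase = runif(1, 0, 2 * pi)),
      noise_scales = list(orientation_deg = 0.5, accel = 0.2, force_n = 5)
    )
  })
  prof$duty_factor <- derive_duty_factor(prof, speed = 12)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("`overrides` must be a fully named list.", class = "imu2grf_bad_override")
    }
    unknown <- setdiff(names(overrides), names(prof))
    if (length(unknown) > 0L) {
      abort(paste0("Unknown subject_profile field(s): ",
                   paste(unknown, collapse = ", ")),
            class = "imu2grf_bad_override")
    }
    prof[names(overrides)] <- overrides
  }
  structure(prof, class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s (seed %d)>\n", x$subject_id, x$seed))
  cat(sprintf("  mass %.1f kg, height %.2f m, %s strike\n",
              x$mass, x$height, x$strike_type))
  cat(sprintf("  cadence %.1f strides/min, duty factor %.3f, peak vGRF %.2f BW\n",
              x$cadence_base, x$duty_factor, x$peak_vgrf_multiple))
  invisible(x)
}

validate_subject <- function(subject) {
  stopifnot(inherits(subject, "subject_profile"))
  with(subject, {
    stopifnot(mass > 0, height > 0,
              duty_factor > 0, duty_factor < 0.5,
              peak_vgrf_multiple >= 2.0, peak_vgrf_multiple <= 3.5,
              noise_scales$orientation_deg >= 0,
              noise_scales$accel >= 0, noise_scales$force_n >= 0)
  })
  invisible(subject)
}

# Peak vGRF multiple at a given belt speed (km/h): modest increase with
# speed, anchored at 12 km/h.
peak_multiple_at_speed <- function(subject, speed) {
  subject$peak_vgrf_multiple * (1 + 0.024 * (speed - 12))
}

# Cadence (strides/min) and stride period (s) at a given speed.
cadence_at_speed <- function(subject, speed) {
  subject$cadence_base * (1 + 0.012 * (speed - 12))
}

#' Stride period of a subject at a given speed
#' @param subject A `subject_profile`.
#' @param speed Belt speed in km/h.
#' @return Stride period in seconds.
#' @export
stride_period <- function(subject, speed) {
  60 / cadence_at_speed(subject, speed)
}

# Stance fraction of the stride implied by impulse balance: per stride each
# foot must deliver an impulse of mass*g*T/2.  The stance profile is
# F(t) = mg * [ r * bump(t / t_p) + p * sin(pi * t / (d*T)) ] with the
# gamma-shaped impact bump of `passive_bump` (impulse r*mg*PASSIVE_BUMP_AREA*t_p)
# and the active half-sine (impulse p*mg*(2/pi)*d*T); solving
# r*PASSIVE_BUMP_AREA*t_p + p*(2/pi)*d*T = T/2 for d gives the duty factor.
derive_duty_factor <- function(subject, speed) {
  T_str <- stride_period(subject, speed)
  p <- peak_multiple_at_speed(subject, speed)
  r <- subject$passive_amplitude
  d <- pi * (T_str / 2 - PASSIVE_BUMP_AREA * r * subject$t_passive) /
    (2 * p * T_str)
  min(d, 0.45)
}
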