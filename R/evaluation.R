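# Evaluation drivers: the two training/evaluation scenarios
# (single-subject and leave-one-subject-out), the feature ablation for the
# force network, the speed-generalization study, and report rendering.

#' Simulate and preprocess a complete study dataset
#'
#' Convenience wrapper: [simulate_study()] followed by [preprocess_trial()]
#' on every trial.
#'
#' @inheritParams simulate_study
#' @param target_rate Common rate after resampling (Hz).
#' @return A tibble with `subject_id`, `speed`, `seed` and a `trial`
#'   list-column of `synced_trial` objects; simulator provenance in
#'   `attr(, "provenance")`.
#' @export
build_dataset <- function(n_subjects = 8, speeds = c(10, 12, 14),
                          duration = 180, subject_seed_base = 0L,
                          trial_seed_base = 0L, target_rate = 120) {
  raw <- simulate_study(n_subjects, speeds, duration, subject_seed_base,
                        trial_seed_base)
  raw$trial <- lapply(raw$trial, preprocess_trial, target_rate = target_rate)
  attr(raw, "provenance") <- list(
    n_subjects = n_subjects, speeds = speeds, duration = duration,
    subject_seed_base = subject_seed_base, trial_seed_base = trial_seed_base,
    target_rate = target_rate
  )
  raw
}

dataset_trial <- function(dataset, subject_id, speed) {
  hit <- dataset$subject_id == subject_id & dataset$speed == speed
  if (sum(hit) == 0L) {
    abort(sprintf("No trial for subject %s at %g km/h (available: %s).",
                  subject_id, speed,
                  paste(unique(dataset$speed[dataset$subject_id == subject_id]),
                        collapse = ", ")),
          class = "imu2grf_missing_trial")
  }
  dataset$trial[hit][[1L]]
}

#' Evaluate an estimator against a trial's references
#'
#' Runs the deployment path on one synchronized trial and scores it against
#' the chosen kinematic reference and the measured force: knee
#' flexion/extension agreement per stride (both sides), vGRF agreement per
#' stance in BW, and the discrete per-stance outcomes (maximal knee flexion
#' in stance, peak vGRF, loading rate from the acceleration-based
#' passive-peak time).
#'
#' @param estimator A `grf_estimator`.
#' @param trial A `synced_trial` with force channels.
#' @param scheme Reference variant to score the angles against (defaults to
#'   the estimator's training scheme).
#' @return A list with tibbles `agreement` (signal, side, rho_mean,
#'   rmse_mean, rmse_sd, n_segments) and `discrete` (measure, side, segment
#'   index, reference, estimate).
#' @export
evaluate_trial <- function(estimator, trial, scheme = estimator$scheme) {
  est <- estimate(estimator, trial)
  seg <- segment_trial(trial)
  ref_angles <- tibble::as_tibble(as.data.frame(ref_angle_matrix(trial, scheme)))
  mass <- trial$subject$mass
  bw <- mass * GRAVITY
  fs <- trial$rate

  agreement <- list()
  for (side in c("left", "right")) {
    strides <- seg$strides[seg$strides$side == side, ]
    if (nrow(strides) > 0L) {
      col <- paste0(side, "_knee")
      est_seg <- purrr::map2(strides$start, strides$end,
                             ~ est$angles[[col]][.x:(.y - 1L)])
      ref_seg <- purrr::map2(strides$start, strides$end,
                             ~ ref_angles[[col]][.x:(.y - 1L)])
      agreement[[paste0("knee_", side)]] <- dplyr::mutate(
        summarize_agreement(est_seg, ref_seg),
        signal = "knee_fe", side = side, .before = 1L)
    }
    if (!is.null(est$vgrf)) {
      stances <- seg$stances[seg$stances$side == side, ]
      if (nrow(stances) > 0L) {
        fcol <- paste0("vgrf_", side)
        est_seg <- purrr::map2(stances$start, stances$end,
                               ~ est$vgrf[[fcol]][.x:(.y - 1L)])
        ref_seg <- purrr::map2(stances$start, stances$end,
                               ~ trial$data[[fcol]][.x:(.y - 1L)] / bw)
        agreement[[paste0("vgrf_", side)]] <- dplyr::mutate(
          summarize_agreement(est_seg, ref_seg),
          signal = "vgrf", side = side, .before = 1L)
      }
    }
  }

  # discrete outcomes per stance
  discrete <- list()
  shank_acc <- list(
    left = global_vertical_acceleration(quat_block(trial$data, "shankL_"),
                                        accel_block(trial$data, "shankL_")),
    right = global_vertical_acceleration(quat_block(trial$data, "shankR_"),
                                         accel_block(trial$data, "shankR_"))
  )
  for (i in seq_len(nrow(seg$stances))) {
    st <- seg$stances[i, ]
    side <- st$side
    fcol <- paste0("vgrf_", side)
    ref_force_n <- trial$data[[fcol]]
    est_force_n <- if (is.null(est$vgrf)) NULL else est$vgrf[[fcol]] * bw
    rows <- list(tibble::tibble(
      measure = "max_knee_flexion_stance", side = side, segment = i,
      reference = max_knee_flexion_stance(ref_angles, st),
      estimate = max_knee_flexion_stance(est$angles, st)
    ))
    if (!is.null(est_force_n)) {
      t_pp <- passive_peak_time(shank_acc[[side]], st, fs)
      lr_ref <- tryCatch(loading_rate(ref_force_n, fs, st, t_pp, mass),
                         error = function(e) NA_real_)
      lr_est <- tryCatch(loading_rate(est_force_n, fs, st, t_pp, mass),
                         error = function(e) NA_real_)
      rows <- c(rows, list(
        tibble::tibble(measure = "peak_vgrf", side = side, segment = i,
                       reference = peak_vgrf_bw(ref_force_n, st, mass),
                       estimate = peak_vgrf_bw(est_force_n, st, mass)),
        tibble::tibble(measure = "t_passive_peak", side = side, segment = i,
                       reference = t_pp, estimate = t_pp),
        tibble::tibble(measure = "loading_rate", side = side, segment = i,
                       reference = lr_ref, estimate = lr_est)
      ))
    }
    discrete[[i]] <- dplyr::bind_rows(rows)
  }

  list(agreement = dplyr::bind_rows(agreement),
       discrete = dplyr::bind_rows(discrete))
}

summarize_discrete <- function(discrete) {
  discrete |>
    dplyr::filter(is.finite(.data$reference), is.finite(.data$estimate)) |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      ref_mean = mean(.data$reference), ref_sd = sd(.data$reference),
      est_mean = mean(.data$estimate), est_sd = sd(.data$estimate),
      n = dplyr::n(), .groups = "drop"
    )
}

discrete_ttests <- function(discrete, alpha = 0.05) {
  discrete |>
    dplyr::filter(.data$measure != "t_passive_peak",
                  is.finite(.data$reference), is.finite(.data$estimate)) |>
    dplyr::group_by(.data$measure) |>
    dplyr::reframe(paired_ttest(.data$estimate, .data$reference, alpha))
}

new_scenario_result <- function(scenario, scheme, feature_set, subject_id,
                                test_speed, ev, estimator = NULL) {
  structure(list(
    scenario = scenario, scheme = scheme, feature_set = feature_set,
    subject_id = subject_id, test_speed = test_speed,
    agreement = dplyr::mutate(ev$agreement, subject_id = subject_id, .before = 1L),
    discrete = dplyr::mutate(ev$discrete, subject_id = subject_id, .before = 1L),
    discrete_summary = summarize_discrete(ev$discrete),
    ttests = discrete_ttests(ev$discrete),
    estimator = estimator
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result %s subject %s @ %g km/h (%s scheme)>\n",
              x$scenario, x$subject_id, x$test_speed, x$scheme))
  print(x$agreement)
  invisible(x)
}

#' Single-subject training and evaluation
#'
#' Trains the concatenated estimator on one subject's trials at all speeds
#' other than `test_speed` and evaluates every outcome measure on the
#' held-out `test_speed` trial (speed interpolation when the test speed
#' lies between the training speeds, extrapolation otherwise).
#'
#' @param dataset A dataset tibble from [build_dataset()].
#' @param subject_id Subject to train and evaluate on.
#' @param test_speed Evaluation speed in km/h (default 12).
#' @param scheme Kinematic reference variant (`"imu"` or `"optical"`).
#' @param feature_set ANN 2 feature combination.
#' @param config A [train_config()].
#' @param keep_estimator Store the trained estimator in the result.
#' @param max_rows Cap on pooled training rows (deterministic thinning).
#' @return A `scenario_result`.
#' @export
scenario_single_subject <- function(dataset, subject_id, test_speed = 12,
                                    scheme = "imu", feature_set = "a_pl_theta",
                                    config = train_config(),
                                    keep_estimator = FALSE, max_rows = Inf) {
  rows <- dataset[dataset$subject_id == subject_id, ]
  if (nrow(rows) == 0L) {
    abort(sprintf("Unknown subject %s.", subject_id),
          class = "imu2grf_missing_trial")
  }
  train_rows <- rows[rows$speed != test_speed, ]
  if (nrow(train_rows) < 2L) {
    abort(sprintf("Subject %s needs >= 2 training speeds distinct from %g (has: %s).",
                  subject_id, test_speed,
                  paste(train_rows$speed, collapse = ", ")),
          class = "imu2grf_missing_trial")
  }
  est <- build_estimator(train_rows$trial, scheme = scheme,
                         feature_set = feature_set, config = config,
                         max_rows = max_rows)
  ev <- evaluate_trial(est, dataset_trial(dataset, subject_id, test_speed))
  new_scenario_result("single_subject_speed", scheme, feature_set,
                      subject_id, test_speed, ev,
                      if (keep_estimator) est else NULL)
}

#' Leave-one-subject-out training and evaluation
#'
#' Trains on all trials (all speeds) of every subject except `held_out`,
#' then evaluates on the held-out subject's trial at `test_speed`.
#'
#' @inheritParams scenario_single_subject
#' @param held_out Subject to hold out.
#' @param kinetics Also train/evaluate the force network (set `FALSE` for a
#'   kinematics-only run).
#' @param max_rows Cap on pooled training rows (deterministic thinning).
#' @return A `scenario_result`.
#' @export
scenario_loso <- function(dataset, held_out, test_speed = 12, scheme = "imu",
                          feature_set = "a_pl_theta", config = train_config(),
                          kinetics = TRUE, max_rows = Inf,
                          keep_estimator = FALSE) {
  if (length(unique(dataset$subject_id)) < 2L) {
    abort("Leave-one-subject-out requires at least 2 subjects.",
          class = "imu2grf_missing_trial")
  }
  train_rows <- dataset[dataset$subject_id != held_out, ]
  est <- build_estimator(train_rows$trial, scheme = scheme,
                         feature_set = feature_set, config = config,
                         train_ann2 = kinetics, max_rows = max_rows)
  ev <- evaluate_trial(est, dataset_trial(dataset, held_out, test_speed))
  new_scenario_result("leave_one_subject_out", scheme, feature_set,
                      held_out, test_speed, ev,
                      if (keep_estimator) est else NULL)
}

#' Feature ablation for the force network
#'
#' Evaluates every feature combination in [FEATURE_SETS] in the
#' single-subject scenario with shared seeds and a shared kinematic
#' network (ANN 1 does not depend on the feature set).
#'
#' @inheritParams scenario_single_subject
#' @return A tibble of per-feature-set vGRF agreement (one row per side),
#'   with columns `feature_set`, `side`, `rho_mean`, `rmse_mean`,
#'   `rmse_sd`, `n_segments`.
#' @export
feature_ablation <- function(dataset, subject_id, test_speed = 12,
                             scheme = "imu", config = train_config(),
                             max_rows = Inf) {
  out <- purrr::map(names(FEATURE_SETS), function(fs_tag) {
    res <- scenario_single_subject(dataset, subject_id, test_speed, scheme,
                                   feature_set = fs_tag, config = config,
                                   max_rows = max_rows)
    res$agreement |>
      dplyr::filter(.data$signal == "vgrf") |>
      dplyr::mutate(feature_set = fs_tag, .before = 1L) |>
      dplyr::select("feature_set", "side", "rho_mean", "rmse_mean",
                    "rmse_sd", "n_segments")
  })
  dplyr::bind_rows(out)
}

#' Speed generalization (leave one speed out)
#'
#' For each available speed of a subject, trains on the remaining speeds
#' and evaluates on it; interpolated (intermediate) speeds are expected to
#' be estimated more accurately than extrapolated ones.
#'
#' @inheritParams scenario_single_subject
#' @return A list with `agreement` (per evaluated speed) and `discrete`
#'   (per-speed discrete outcome summaries).
#' @export
speed_generalization <- function(dataset, subject_id, scheme = "imu",
                                 feature_set = "a_pl_theta",
                                 config = train_config(), max_rows = Inf) {
  speeds <- sort(unique(dataset$speed[dataset$subject_id == subject_id]))
  if (length(speeds) < 3L) {
    abort("Speed generalization needs >= 3 speeds.",
          class = "imu2grf_missing_trial")
  }
  res <- purrr::map(speeds, function(v) {
    r <- scenario_single_subject(dataset, subject_id, test_speed = v,
                                 scheme = scheme, feature_set = feature_set,
                                 config = config, max_rows = max_rows)
    list(agreement = dplyr::mutate(r$agreement, speed = v, .before = 1L),
         discrete = dplyr::mutate(r$discrete_summary, speed = v, .before = 1L))
  })
  list(agreement = dplyr::bind_rows(purrr::map(res, "agreement")),
       discrete = dplyr::bind_rows(purrr::map(res, "discrete")))
}

#' Cohort summary across scenario results
#'
#' Aggregates per-subject discrete-outcome means and tests estimate vs
#' reference across subjects with a paired t-test (two-sided, alpha 0.05,
#' no multiplicity correction).
#'
#' @param results List of `scenario_result` objects.
#' @return A list with `subject_means` and `cohort_tests` tibbles.
#' @export
cohort_summary <- function(results) {
  means <- purrr::map(results, function(r) {
    dplyr::mutate(r$discrete_summary, subject_id = r$subject_id, .before = 1L)
  }) |> dplyr::bind_rows()
  tests <- means |>
    dplyr::filter(.data$measure != "t_passive_peak") |>
    dplyr::group_by(.data$measure) |>
    dplyr::reframe(paired_ttest(.data$est_mean, .data$ref_mean))
  list(subject_means = means, cohort_tests = tests)
}

#' Render scenario results as text tables and a JSON-ready summary
#'
#' @param results A `scenario_result` or list of them.
#' @return A `run_report`: list with `agreement`, `discrete`, `ttests`
#'   tibbles pooled over results; its print method shows formatted tables,
#'   and [report_to_json()] / [report_from_json()] round-trip it.
#' @export
render_report <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  if (length(results) == 0L) abort("No results to report.", class = "imu2grf_empty")
  agreement <- purrr::map(results, function(r) {
    dplyr::mutate(r$agreement, scenario = r$scenario, scheme = r$scheme,
                  .before = 1L)
  }) |> dplyr::bind_rows()
  discrete <- purrr::map(results, function(r) {
    dplyr::mutate(r$discrete_summary, scenario = r$scenario,
                  subject_id = r$subject_id, .before = 1L)
  }) |> dplyr::bind_rows()
  ttests <- purrr::map(results, function(r) {
    dplyr::mutate(r$ttests, scenario = r$scenario, subject_id = r$subject_id,
                  .before = 1L)
  }) |> dplyr::bind_rows()
  structure(list(agreement = agreement, discrete = discrete, ttests = ttests),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Continuous agreement (per stride/stance) ==\n")
  df <- as.data.frame(x$agreement)
  df$rho_mean <- sprintf("%.3f", df$rho_mean)
  df$rmse <- sprintf("%.2f (%.2f)", x$agreement$rmse_mean, x$agreement$rmse_sd)
  print(df[, c("scenario", "scheme", "subject_id", "signal", "side",
               "rho_mean", "rmse")], row.names = FALSE)
  cat("\n== Discrete outcomes (mean (sd), reference vs estimate) ==\n")
  dd <- as.data.frame(x$discrete)
  dd$reference <- sprintf("%.2f (%.2f)", dd$ref_mean, dd$ref_sd)
  dd$estimate <- sprintf("%.2f (%.2f)", dd$est_mean, dd$est_sd)
  print(dd[, c("scenario", "subject_id", "measure", "reference", "estimate")],
        row.names = FALSE)
  invisible(x)
}

#' @rdname render_report
#' @param report A `run_report`.
#' @param path JSON output path.
#' @export
report_to_json <- function(report, path) {
  jsonlite::write_json(lapply(unclass(report), as.data.frame), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname render_report
#' @export
report_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(raw, tibble::as_tibble), class = "run_report")
}

#' Fingerprint feature rows (train/test leakage checks)
#'
#' @param X Numeric matrix.
#' @return Character vector of per-row fingerprints (values rounded to 12
#'   significant digits).
#' @export
row_fingerprints <- function(X) {
  apply(signif(as.matrix(X), 12L), 1L, paste, collapse = ",")
}
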