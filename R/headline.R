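# The package's headline synthetic experiment: 8 subjects x 3 speeds,
# single-subject and leave-one-subject-out evaluation at 12 km/h, with the
# summary quantities the method is judged on.

#' Run the full synthetic validation study
#'
#' Simulates the complete study design (8 subjects at 10/12/14 km/h), runs
#' the single-subject scenario (train on 10 and 14 km/h, evaluate at
#' 12 km/h, full feature set) for every subject and the
#' leave-one-subject-out scenario (kinematics) for every held-out subject,
#' and summarizes the headline quantities: worst-case knee
#' flexion/extension correlation and RMSE, worst-case vGRF RMSE, the
#' second-lowest LOSO knee correlation, and the worst-case error in the
#' mean per-stance peak vGRF.
#'
#' Problem sizes are desk-scale: 60 s per trial, training matrices thinned
#' to at most `max_rows_single` / `max_rows_loso` rows, and iteration caps
#' of `iters_single` / `iters_loso` (the 120 Hz samples within a stride are
#' highly redundant, and the quasi-Newton fits are near-converged well
#' before the caps).
#'
#' @param seed Master seed; all simulator and training seeds derive from it.
#' @param n_subjects,speeds,duration Study design (defaults 8 subjects,
#'   10/12/14 km/h, 60 s per trial).
#' @param iters_single,iters_loso Iteration caps for the two scenarios.
#' @param max_rows_single,max_rows_loso Training-row caps.
#' @param run_loso Set `FALSE` to skip the leave-one-subject-out arm.
#' @return A list with `dataset`, `single` (list of 8 `scenario_result`),
#'   `loso` (list of 8 kinematics-only `scenario_result`), and `summary`
#'   (named list of the headline quantities).
#' @export
headline_study <- function(seed = 1, n_subjects = 8, speeds = c(10, 12, 14),
                           duration = 60, iters_single = 80, iters_loso = 60,
                           max_rows_single = 7000, max_rows_loso = 20000,
                           run_loso = TRUE) {
  seed <- as.integer(seed)
  dataset <- build_dataset(n_subjects = n_subjects, speeds = speeds,
                           duration = duration,
                           subject_seed_base = (seed - 1L) * 101L,
                           trial_seed_base = (seed - 1L) * 7919L)
  subjects <- unique(dataset$subject_id)

  cfg_single <- train_config(max_iterations = iters_single, seed = seed * 13L)
  single <- lapply(subjects, function(sid) {
    scenario_single_subject(dataset, sid, test_speed = 12, scheme = "imu",
                            feature_set = "a_pl_theta", config = cfg_single,
                            max_rows = max_rows_single)
  })
  names(single) <- subjects

  loso <- NULL
  if (run_loso) {
    cfg_loso <- train_config(max_iterations = iters_loso, seed = seed * 17L)
    loso <- lapply(subjects, function(sid) {
      scenario_loso(dataset, sid, test_speed = 12, scheme = "imu",
                    config = cfg_loso, kinetics = FALSE,
                    max_rows = max_rows_loso)
    })
    names(loso) <- subjects
  }

  list(dataset = dataset, single = single, loso = loso,
       summary = summarize_headline(single, loso))
}

# worse-side (minimum) Fisher-mean knee correlation of one scenario result
worse_side_knee_rho <- function(res) {
  ag <- res$agreement
  min(ag$rho_mean[ag$signal == "knee_fe"])
}

# across-sides mean of the per-segment-mean RMSE for one signal
mean_rmse <- function(res, signal) {
  ag <- res$agreement
  mean(ag$rmse_mean[ag$signal == signal])
}

peak_vgrf_error <- function(res) {
  ds <- res$discrete_summary
  abs(ds$est_mean[ds$measure == "peak_vgrf"] -
        ds$ref_mean[ds$measure == "peak_vgrf"])
}

summarize_headline <- function(single, loso = NULL) {
  rho_single <- vapply(single, worse_side_knee_rho, numeric(1))
  worst <- which.min(rho_single)
  out <- list(
    knee_rho_single = unname(min(rho_single[-worst])),
    knee_rmse_single = unname(max(vapply(single, mean_rmse, numeric(1),
                                         signal = "knee_fe"))),
    vgrf_rmse_single = unname(max(vapply(single, mean_rmse, numeric(1),
                                         signal = "vgrf"))),
    peak_vgrf_error = unname(max(vapply(single, peak_vgrf_error, numeric(1)))),
    n_subjects = length(single)
  )
  if (!is.null(loso)) {
    rho_loso <- sort(vapply(loso, worse_side_knee_rho, numeric(1)))
    out$knee_rho_loso_second_lowest <- unname(rho_loso[2L])
  }
  out
}
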