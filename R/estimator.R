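# The concatenated estimator: ANN 1 (pelvis-relative shank quaternions ->
# six sagittal joint angles) feeding ANN 2 (angles + global vertical
# accelerations -> per-foot vGRF in body weights).  ANN 2 is trained on
# reference angles and evaluated on ANN 1's estimates (the deployment
# path), selectable via `ann2_training_angles`.

MODEL_FILE_VERSION <- "imu2grf-model-v1"

as_trial_list <- function(trials) {
  if (inherits(trials, "synced_trial")) return(list(trials))
  if (is.data.frame(trials) && "trial" %in% names(trials)) return(trials$trial)
  stopifnot(is.list(trials))
  trials
}

# deterministic regular row thinning to at most max_rows rows
thin_rows <- function(n, max_rows) {
  if (!is.finite(max_rows) || n <= max_rows) return(seq_len(n))
  seq(1L, n, by = ceiling(n / max_rows))
}

#' Train the concatenated angle + force estimator
#'
#' Trains ANN 1 on the pooled training trials (sign-continuous
#' pelvis-relative shank quaternions -> the chosen reference's six sagittal
#' angles), then ANN 2 (reference angles and/or vertical accelerations per
#' `feature_set` -> per-foot vGRF in body weights).
#'
#' @param train_trials A `synced_trial`, a list of them, or a dataset tibble
#'   with a `trial` list-column.
#' @param scheme Kinematic reference used for training and evaluation:
#'   `"imu"` (inertial-like) or `"optical"` (optical-like).
#' @param feature_set ANN 2 feature combination (see [FEATURE_SETS]).
#' @param config A [train_config()] used for both networks (ANN 2 gets a
#'   derived seed).
#' @param ann2_training_angles Train ANN 2 on `"reference"` angles (default)
#'   or on ANN 1's `"estimated"` angles.
#' @param max_rows Optional cap on pooled training rows (deterministic
#'   regular thinning; consecutive samples at 120 Hz are highly redundant).
#' @param train_ann2 Train the force network (requires force channels; set
#'   `FALSE` for a kinematics-only estimator).
#' @return A `grf_estimator` with elements `ann1`, `ann2` and metadata.
#' @export
build_estimator <- function(train_trials, scheme = c("imu", "optical"),
                            feature_set = "a_pl_theta",
                            config = train_config(),
                            ann2_training_angles = c("reference", "estimated"),
                            max_rows = Inf, train_ann2 = TRUE) {
  scheme <- match.arg(scheme)
  ann2_training_angles <- match.arg(ann2_training_angles)
  feature_set <- match_feature_set(feature_set)
  trials <- as_trial_list(train_trials)
  if (length(trials) == 0L) {
    abort("At least one training trial is required.", class = "imu2grf_no_trials")
  }
  io1 <- lapply(trials, build_ann1_io, reference = scheme)
  X1 <- do.call(rbind, lapply(io1, `[[`, "X"))
  Y1 <- do.call(rbind, lapply(io1, `[[`, "Y"))
  keep <- thin_rows(nrow(X1), max_rows)
  ann1 <- train_mlp(X1[keep, , drop = FALSE], Y1[keep, , drop = FALSE], config)

  ann2 <- NULL
  if (train_ann2 && !is.null(trials[[1L]]$data$vgrf_left)) {
    io2 <- lapply(seq_along(trials), function(i) {
      tr <- trials[[i]]
      angles <- if (ann2_training_angles == "reference") {
        ref_angle_matrix(tr, scheme)
      } else {
        predict(ann1, io1[[i]]$X)
      }
      build_ann2_io(angles, tr, feature_set)
    })
    X2 <- do.call(rbind, lapply(io2, `[[`, "X"))
    Y2 <- do.call(rbind, lapply(io2, `[[`, "Y"))
    keep2 <- thin_rows(nrow(X2), max_rows)
    cfg2 <- config
    cfg2$seed <- config$seed + 524287L
    ann2 <- train_mlp(X2[keep2, , drop = FALSE], Y2[keep2, , drop = FALSE], cfg2)
  }

  structure(list(
    ann1 = ann1,
    ann2 = ann2,
    scheme = scheme,
    feature_set = feature_set,
    ann2_training_angles = ann2_training_angles,
    subjects = unique(vapply(trials, function(t) t$subject$subject_id, character(1))),
    speeds = sort(unique(vapply(trials, function(t) t$speed, numeric(1))))
  ), class = "grf_estimator")
}

#' Estimate joint angles and vGRF for a trial
#'
#' The deployment path: ANN 1 predicts the six sagittal angles from the
#' trial's pelvis-relative shank orientations; those estimates (not the
#' reference) plus the vertical accelerations feed ANN 2, whose per-foot
#' vGRF output is clipped at 0 BW.  Force channels are not required.
#'
#' @param estimator A `grf_estimator`.
#' @param trial A `synced_trial` (force channels optional).
#' @return A list with `angles` (tibble: time + six estimated angles,
#'   degrees) and, if the estimator has a force network, `vgrf` (tibble:
#'   time, `vgrf_left`, `vgrf_right` in BW).
#' @export
estimate <- function(estimator, trial) {
  stopifnot(inherits(estimator, "grf_estimator"),
            inherits(trial, "synced_trial"))
  need <- paste0(rep(c("pelvis_", "shankL_", "shankR_"), each = 4L),
                 c("qw", "qx", "qy", "qz"))
  missing_cols <- setdiff(need, names(trial$data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Trial lacks IMU channels: ",
                 paste(missing_cols, collapse = ", ")),
          class = "imu2grf_missing_channels")
  }
  qp <- quat_block(trial$data, "pelvis_")
  relL <- enforce_sign_continuity(relative_orientation(qp, quat_block(trial$data, "shankL_")))
  relR <- enforce_sign_continuity(relative_orientation(qp, quat_block(trial$data, "shankR_")))
  X1 <- cbind(relL, relR)
  colnames(X1) <- estimator$ann1$input_columns
  angles_hat <- predict(estimator$ann1, X1)
  colnames(angles_hat) <- ANGLE_CHANNELS
  out <- list(
    angles = dplyr::bind_cols(tibble::tibble(time = trial$data$time),
                              tibble::as_tibble(angles_hat))
  )
  if (!is.null(estimator$ann2)) {
    feats <- build_ann2_features(angles_hat, trial, estimator$feature_set)
    vgrf_hat <- pmax(predict(estimator$ann2, feats), 0)
    out$vgrf <- tibble::tibble(time = trial$data$time,
                               vgrf_left = vgrf_hat[, 1L],
                               vgrf_right = vgrf_hat[, 2L])
  }
  out
}

# feature matrix only (no targets; works on force-free trials)
build_ann2_features <- function(angles, trial, feature_set) {
  cols <- FEATURE_SETS[[match_feature_set(feature_set)]]
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
    colnames(am) <- ANGLE_CHANNELS
    X <- if (is.null(X)) am else cbind(X, am)
  }
  X[, cols, drop = FALSE]
}

#' Save or load a concatenated estimator
#'
#' The file is a versioned archive (header string
#' `"imu2grf-model-v1"`) containing both networks' weights, scalers,
#' configurations and metadata; a load of a file with a different version
#' header fails explicitly.  Round-trips preserve predictions bit-exactly.
#'
#' @param estimator A `grf_estimator`.
#' @param path File path.
#' @return `save_estimator` invisibly returns `path`; `load_estimator`
#'   returns the estimator.
#' @export
save_estimator <- function(estimator, path) {
  stopifnot(inherits(estimator, "grf_estimator"))
  saveRDS(list(version = MODEL_FILE_VERSION, estimator = estimator), path)
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("Cannot read model file: ", conditionMessage(e)),
          class = "imu2grf_bad_model_file")
  })
  if (!is.list(payload) || !identical(payload$version, MODEL_FILE_VERSION)) {
    abort(sprintf("Model file version mismatch (expected \"%s\").",
                  MODEL_FILE_VERSION),
          class = "imu2grf_model_version")
  }
  payload$estimator
}

#' @export
print.grf_estimator <- function(x, ...) {
  cat(sprintf("<grf_estimator scheme=%s features=%s subjects=%s speeds=%s>\n",
              x$scheme, x$feature_set, paste(x$subjects, collapse = ","),
              paste(x$speeds, collapse = ",")))
  invisible(x)
}

#' Tidy both networks' training histories
#' @param x A `grf_estimator`.
#' @param ... Unused.
#' @return Tibble of per-iteration history with a `network` column.
#' @exportS3Method generics::tidy
tidy.grf_estimator <- function(x, ...) {
  h1 <- dplyr::mutate(tidy(x$ann1), network = "ann1", .before = 1L)
  if (is.null(x$ann2)) return(h1)
  dplyr::bind_rows(h1, dplyr::mutate(tidy(x$ann2), network = "ann2", .before = 1L))
}

#' One-row estimator summary
#' @param x A `grf_estimator`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.grf_estimator <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, feature_set = x$feature_set,
    n_subjects = length(x$subjects),
    ann1_iterations = x$ann1$iterations,
    ann1_final_loss = x$ann1$final_loss,
    ann2_iterations = if (is.null(x$ann2)) NA_integer_ else x$ann2$iterations,
    ann2_final_loss = if (is.null(x$ann2)) NA_real_ else x$ann2$final_loss
  )
}
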