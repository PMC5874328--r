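# ggplot2 helpers for trials, phase-normalized profiles, training
# histories and Bland-Altman plots.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a few seconds of a synchronized trial
#'
#' @param object A `synced_trial`.
#' @param window Time window in s plotted from the trial start (default 3).
#' @param ... Unused.
#' @return A ggplot with vGRF (BW) and knee flexion/extension traces.
#' @exportS3Method ggplot2::autoplot
autoplot.synced_trial <- function(object, window = 3, ...) {
  bw <- object$subject$mass * GRAVITY
  df <- object$data |>
    dplyr::filter(.data$time <= .data$time[1L] + window) |>
    dplyr::transmute(
      time = .data$time,
      `vGRF left [BW]` = .data$vgrf_left / bw,
      `vGRF right [BW]` = .data$vgrf_right / bw,
      `knee F/E left [deg]` = .data$left_knee_ref_imu,
      `knee F/E right [deg]` = .data$right_knee_ref_imu
    ) |>
    tidyr::pivot_longer(-"time")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~name, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = sprintf("%s @ %g km/h", object$subject$subject_id,
                                  object$speed)) +
    ggplot2::theme_minimal()
}

#' Phase-normalized mean profiles of estimate vs reference
#'
#' Normalizes each stride (knee angle) or stance (vGRF) to a 0-100% grid
#' and plots the across-segment mean with a +/- 1 SD band for both the
#' estimate and the reference.
#'
#' @param estimator A `grf_estimator`.
#' @param trial A `synced_trial` with force channels.
#' @param signal `"knee_fe"` (per stride) or `"vgrf"` (per stance).
#' @param side `"left"` or `"right"`.
#' @return A ggplot.
#' @export
plot_phase_profiles <- function(estimator, trial, signal = c("knee_fe", "vgrf"),
                                side = c("left", "right")) {
  signal <- match.arg(signal)
  side <- match.arg(side)
  est <- estimate(estimator, trial)
  seg <- segment_trial(trial)
  bw <- trial$subject$mass * GRAVITY
  if (signal == "knee_fe") {
    segs <- seg$strides[seg$strides$side == side, ]
    est_series <- est$angles[[paste0(side, "_knee")]]
    ref_series <- ref_angle_matrix(trial, estimator$scheme)[, paste0(side, "_knee")]
    ylab <- "knee F/E [deg]"
  } else {
    segs <- seg$stances[seg$stances$side == side, ]
    est_series <- est$vgrf[[paste0("vgrf_", side)]]
    ref_series <- trial$data[[paste0("vgrf_", side)]] / bw
    ylab <- "vGRF [BW]"
  }
  prof <- function(series, label) {
    m <- t(mapply(function(s, e) normalize_phase(series, s, e), segs$start, segs$end))
    tibble::tibble(phase = seq(0, 100, length.out = ncol(m)),
                   mean = colMeans(m), sd = apply(m, 2L, sd), source = label)
  }
  df <- dplyr::bind_rows(prof(est_series, "estimate"), prof(ref_series, "reference"))
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$mean, colour = .data$source,
                                   fill = .data$source)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("%% of %s", if (signal == "knee_fe") "stride" else "stance"),
                  y = ylab, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Training-history plot
#' @param object An `mlp_model`.
#' @param ... Unused.
#' @return A ggplot of loss and gradient norm per iteration (log scale).
#' @exportS3Method ggplot2::autoplot
autoplot.mlp_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history[, c("iteration", "loss", "grad_norm")],
                            -"iteration")
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#' @param object A `bland_altman` result.
#' @param ... Unused.
#' @return A ggplot of differences vs means with bias and limits of
#'   agreement.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$bias,
                                       object$loa_high),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::labs(x = "mean of estimate and reference",
                  y = "estimate - reference") +
    ggplot2::theme_minimal()
}
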