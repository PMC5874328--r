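# Outcome measures: continuous agreement (per-segment RMSE and Pearson
# correlation, Fisher-averaged) and discrete per-stance outcomes (maximal
# knee flexion in stance, peak vGRF in BW, passive-peak time from the
# lower-leg acceleration, 20-80% loading rate), plus Bland-Altman limits of
# agreement and the paired t-test.

#' Root mean squared error
#' @param est,ref Equal-length numeric sequences.
#' @return `sqrt(mean((est - ref)^2))` (unnormalized; same units as input).
#' @export
rmse <- function(est, ref) {
  if (length(est) != length(ref) || length(est) < 1L) {
    abort("`est` and `ref` must have equal, positive length.",
          class = "imu2grf_length_mismatch")
  }
  sqrt(mean((est - ref)^2))
}

#' Pearson correlation with explicit degenerate handling
#' @param est,ref Equal-length numeric sequences (length >= 3, both
#'   non-constant).
#' @return Sample correlation coefficient.
#' @export
pearson_rho <- function(est, ref) {
  if (length(est) != length(ref) || length(est) < 3L) {
    abort("`est` and `ref` must have equal length >= 3.",
          class = "imu2grf_length_mismatch")
  }
  if (sd(est) < .Machine$double.eps || sd(ref) < .Machine$double.eps) {
    abort("Correlation undefined for a constant sequence.",
          class = "imu2grf_constant_sequence")
  }
  stats::cor(est, ref)
}

#' Fisher-averaged correlation
#'
#' Averages correlations on the Fisher z scale:
#' `tanh(mean(atanh(rho)))`, with each coefficient clipped to
#' `+/-(1 - 1e-12)` so perfect fits stay finite.
#'
#' @param rhos Non-empty numeric vector of correlations.
#' @return The Fisher-mean correlation.
#' @export
fisher_mean_rho <- function(rhos) {
  if (length(rhos) == 0L) {
    abort("`rhos` must be non-empty.", class = "imu2grf_empty")
  }
  clipped <- pmin(pmax(rhos, -(1 - 1e-12)), 1 - 1e-12)
  tanh(mean(atanh(clipped)))
}

#' Maximal knee flexion during a stance phase
#' @param angles Joint-angle data frame with `left_knee`/`right_knee`
#'   columns aligned with the stance's sample indices.
#' @param stance One-row stance record (`side`, `start`, `end`).
#' @return Maximum ipsilateral knee flexion (degrees) over `[start, end)`.
#' @export
max_knee_flexion_stance <- function(angles, stance) {
  col <- paste0(stance$side, "_knee")
  if (!col %in% names(angles)) {
    abort(paste0("Angle series lacks column ", col), class = "imu2grf_schema")
  }
  if (stance$end - 1L > nrow(angles) || stance$start < 1L) {
    abort("Stance exceeds the angle series extent.", class = "imu2grf_bounds")
  }
  max(angles[[col]][stance$start:(stance$end - 1L)])
}

#' Peak vGRF of a stance in body weights
#' @param vgrf Force sequence (N).
#' @param stance One-row stance record.
#' @param mass Subject mass (kg).
#' @return `max(vgrf) / (mass * 9.81)` over the stance.
#' @export
peak_vgrf_bw <- function(vgrf, stance, mass) {
  stopifnot(mass > 0)
  if (stance$end <= stance$start) {
    abort("Empty stance.", class = "imu2grf_bounds")
  }
  max(vgrf[stance$start:(stance$end - 1L)]) / (mass * GRAVITY)
}

#' Passive-peak time from lower-leg acceleration
#'
#' The impact event is located as the maximum absolute ipsilateral shank
#' vertical acceleration within the first `search_fraction` of the stance
#' (the passive force peak is not defined for mid/forefoot strikers, so the
#' acceleration transient is used as the landmark).
#'
#' @param shank_vert_accel Global-frame vertical shank acceleration aligned
#'   with the force samples (m/s^2).
#' @param stance One-row stance record.
#' @param fs Sampling rate (Hz).
#' @param search_fraction Fraction of the stance searched (default 0.5).
#' @return Time of the peak relative to initial contact (s).
#' @export
passive_peak_time <- function(shank_vert_accel, stance, fs,
                              search_fraction = 0.5) {
  len <- stance$end - stance$start
  if (len < 3L) {
    abort("Stance shorter than 3 samples.", class = "imu2grf_bounds")
  }
  n_search <- max(2L, floor(len * search_fraction))
  idx <- stance$start:(stance$start + n_search - 1L)
  (which.max(abs(shank_vert_accel[idx])) - 1L) / fs
}

#' Loading rate of the vGRF rise
#'
#' Slope of the vGRF between 20% and 80% of the passive-peak time,
#' normalized to body weight:
#' `(F(0.8 t_pp) - F(0.2 t_pp)) / (0.6 t_pp) / (mass g)`, with `F`
#' linearly interpolated at off-grid times measured from initial contact.
#'
#' @param vgrf Force sequence (N).
#' @param fs Sampling rate (Hz).
#' @param stance One-row stance record.
#' @param t_pp Passive-peak time from contact (s), within the stance.
#' @param mass Subject mass (kg).
#' @return Loading rate in BW/s.
#' @export
loading_rate <- function(vgrf, fs, stance, t_pp, mass) {
  dur <- (stance$end - stance$start) / fs
  if (t_pp <= 0 || t_pp >= dur) {
    abort("`t_pp` must lie within the stance.", class = "imu2grf_bounds")
  }
  if (0.6 * t_pp < 1 / fs) {
    abort("`t_pp` too small to separate the 20% and 80% samples.",
          class = "imu2grf_bounds")
  }
  f_at <- function(t_rel) {
    pos <- stance$start + t_rel * fs   # fractional sample index
    i0 <- floor(pos)
    w <- pos - i0
    if (w < 1e-12) vgrf[i0] else (1 - w) * vgrf[i0] + w * vgrf[i0 + 1L]
  }
  slope <- (f_at(0.8 * t_pp) - f_at(0.2 * t_pp)) / (0.6 * t_pp)
  slope / (mass * GRAVITY)
}

#' Bland-Altman agreement analysis
#'
#' @param est_values,ref_values Paired numeric vectors (length >= 2).
#' @return A `bland_altman` list: `bias` (mean of est - ref), `loa_low`,
#'   `loa_high` (bias -/+ 1.96 sample SD of the differences) and a tibble
#'   `pairs` with per-pair means and differences.
#' @export
bland_altman <- function(est_values, ref_values) {
  if (length(est_values) != length(ref_values) || length(est_values) < 2L) {
    abort("Paired vectors of equal length >= 2 required.",
          class = "imu2grf_length_mismatch")
  }
  d <- est_values - ref_values
  bias <- mean(d)
  s <- sd(d)
  structure(list(
    bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    pairs = tibble::tibble(mean = (est_values + ref_values) / 2, diff = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman bias %.3g, LoA [%.3g, %.3g], n = %d>\n",
              x$bias, x$loa_low, x$loa_high, nrow(x$pairs)))
  invisible(x)
}

#' Paired t-test on discrete outcomes
#'
#' Two-sided paired t-test of `est - ref`; degenerate (zero-variance)
#' differences are reported explicitly instead of erroring.
#'
#' @param est_values,ref_values Paired numeric vectors (length >= 2).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `t`, `p`, `df`, `significant`, `degenerate`.
#' @export
paired_ttest <- function(est_values, ref_values, alpha = 0.05) {
  if (length(est_values) != length(ref_values) || length(est_values) < 2L) {
    abort("Paired vectors of equal length >= 2 required.",
          class = "imu2grf_length_mismatch")
  }
  d <- est_values - ref_values
  if (sd(d) < .Machine$double.eps) {
    return(tibble::tibble(t = NA_real_, p = NA_real_,
                          df = length(d) - 1L,
                          significant = FALSE, degenerate = TRUE))
  }
  tt <- t.test(est_values, ref_values, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value,
                 df = unname(tt$parameter),
                 significant = tt$p.value < alpha, degenerate = FALSE)
}

#' Summarize continuous agreement over segments
#'
#' Computes per-segment Pearson correlation and RMSE between estimated and
#' reference profiles, then aggregates: Fisher-mean correlation, mean and
#' stride-to-stride SD of the RMSE.
#'
#' @param est_segments,ref_segments Lists of equal count of aligned numeric
#'   vectors (one per stride/stance).
#' @return A one-row tibble: `rho_mean`, `rmse_mean`, `rmse_sd`,
#'   `n_segments`.
#' @export
summarize_agreement <- function(est_segments, ref_segments) {
  if (length(est_segments) != length(ref_segments)) {
    abort("Segment counts differ.", class = "imu2grf_length_mismatch")
  }
  if (length(est_segments) == 0L) {
    abort("No segments to summarize.", class = "imu2grf_empty")
  }
  rhos <- mapply(pearson_rho, est_segments, ref_segments)
  rmses <- mapply(rmse, est_segments, ref_segments)
  tibble::tibble(
    rho_mean = fisher_mean_rho(rhos),
    rmse_mean = mean(rmses),
    rmse_sd = if (length(rmses) > 1L) sd(rmses) else 0,
    n_segments = length(rmses)
  )
}
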