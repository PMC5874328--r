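# Gait-event segmentation: stance phases by the 20 N rule (with debounce),
# strides as ipsilateral contact-to-contact intervals, and phase
# normalization of per-segment signals.

#' Segment stance phases with a force threshold
#'
#' Finds maximal runs of samples with `vgrf >= threshold`.  Runs shorter
#' than `min_phase` are dropped and inter-run gaps shorter than `min_phase`
#' are merged (debounce against filter ripple near the threshold); runs
#' touching the first or last sample are discarded as incomplete contacts.
#'
#' @param vgrf Filtered force sequence (N).
#' @param fs Sampling rate in Hz.
#' @param threshold Contact threshold in N (default 20).
#' @param min_phase Minimum stance/flight duration in s (default 0.05).
#' @param side Optional label stored in the result.
#' @return A tibble of stance segments with columns `side`, `start`, `end`
#'   (half-open sample interval, 1-based) and `t_contact` (s, time of the
#'   start sample).  Empty tibble if no complete stance exists.
#' @examples
#' segment_stances(c(0, 5, 30, 500, 800, 400, 25, 10, 0), fs = 120,
#'                 min_phase = 0)
#' @export
segment_stances <- function(vgrf, fs, threshold = 20, min_phase = 0.05,
                            side = NA_character_) {
  stopifnot(fs > 0)
  empty <- tibble::tibble(side = character(), start = integer(),
                          end = integer(), t_contact = numeric())
  n <- length(vgrf)
  on <- vgrf >= threshold
  if (!any(on)) return(empty)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- tibble::tibble(start = starts[r$values], end = ends[r$values] + 1L)

  min_samp <- min_phase * fs
  # drop sub-min_phase runs first: filter pre-ring can push a short blip
  # above the threshold just ahead of true contact, and merging it into the
  # stance would bias the contact time
  if (min_samp > 0) {
    seg <- seg[(seg$end - seg$start) >= min_samp, , drop = FALSE]
  }
  # then merge runs separated by sub-min_phase gaps
  if (nrow(seg) > 1L && min_samp > 0) {
    merged <- seg[1L, ]
    for (i in 2:nrow(seg)) {
      gap <- seg$start[i] - merged$end[nrow(merged)]
      if (gap < min_samp) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
    seg <- merged
  }
  # drop short runs
  seg <- seg[(seg$end - seg$start) >= max(min_samp, 1), , drop = FALSE]
  # drop partial contacts at the sequence boundaries
  seg <- seg[seg$start > 1L & seg$end <= n, , drop = FALSE]
  if (nrow(seg) == 0L) return(empty)
  tibble::tibble(side = side, start = as.integer(seg$start),
                 end = as.integer(seg$end),
                 t_contact = (seg$start - 1L) / fs)
}

#' Build strides from ipsilateral stance sequences
#'
#' A stride runs from one foot contact to the next contact of the same
#' foot; each consecutive ipsilateral stance pair yields one stride headed
#' by the earlier stance.
#'
#' @param stances_left,stances_right Stance tibbles from
#'   [segment_stances()] (either may be empty).
#' @return A tibble with columns `side`, `start`, `end` (half-open sample
#'   interval from contact to next ipsilateral contact), `stance_start`,
#'   `stance_end`.
#' @export
segment_strides <- function(stances_left, stances_right) {
  one_side <- function(st, side) {
    if (is.null(st) || nrow(st) < 2L) {
      return(tibble::tibble(side = character(), start = integer(),
                            end = integer(), stance_start = integer(),
                            stance_end = integer()))
    }
    st <- st[order(st$start), ]
    k <- nrow(st)
    tibble::tibble(side = side,
                   start = st$start[-k],
                   end = st$start[-1L],
                   stance_start = st$start[-k],
                   stance_end = st$end[-k])
  }
  dplyr::arrange(
    dplyr::bind_rows(one_side(stances_left, "left"),
                     one_side(stances_right, "right")),
    .data$start
  )
}

#' Resample a segment of a signal onto a fixed phase grid
#'
#' Linearly interpolates `series[start:(end-1)]` onto `n_points` equally
#' spaced phase points covering the segment, endpoints preserved.  Used for
#' stride- (0-100% of the cycle) and stance-normalized profiles.
#'
#' @param series Numeric vector.
#' @param start,end Half-open sample interval `[start, end)`, 1-based.
#' @param n_points Output grid size (default 101).
#' @return Numeric vector of length `n_points`.
#' @export
normalize_phase <- function(series, start, end, n_points = 101) {
  if (end - start < 2) {
    abort("Segment must contain at least 2 samples.",
          class = "imu2grf_degenerate_segment")
  }
  idx <- seq(start, end - 1L)
  approx(seq_along(idx), series[idx], n = n_points)$y
}

#' Segment both feet of a synchronized trial
#'
#' @param trial A `synced_trial`.
#' @param threshold,min_phase Passed to [segment_stances()].
#' @return A list with `stances` (both sides, time-ordered) and `strides`.
#' @export
segment_trial <- function(trial, threshold = 20, min_phase = 0.05) {
  stopifnot(inherits(trial, "synced_trial"))
  sl <- segment_stances(trial$data$vgrf_left, trial$rate, threshold,
                        min_phase, side = "left")
  sr <- segment_stances(trial$data$vgrf_right, trial$rate, threshold,
                        min_phase, side = "right")
  list(stances = dplyr::arrange(dplyr::bind_rows(sl, sr), .data$start),
       strides = segment_strides(sl, sr))
}
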