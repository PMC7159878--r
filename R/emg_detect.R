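#' Detect supra-threshold EMG bursts in an RMS trace
#'
#' Marks EMG activity exceeding the baseline mean + `burst_k_sd` x baseline
#' SD, where the baseline is the fixation-to-Go window of the same trial.
#' Contiguous supra-threshold excursions inside the search window are
#' returned with their peak landmarks; the excursion with the largest peak
#' is flagged as the burst of the trial (all excursions are reported).
#'
#' A zero-variance baseline (possible on noiseless synthetic data) makes the
#' 8 SD rule degenerate; the threshold then falls back to the baseline mean
#' plus a small epsilon and the result is flagged.
#'
#' @param rms RMS trace from [emg_preprocess()].
#' @param fs sampling rate (Hz).
#' @param baseline_ms two-element window (ms, epoch time) used as baseline;
#'   normally `c(0, go_ms)`.
#' @param search_ms two-element window (ms) to search for bursts; defaults to
#'   Go to epoch end.
#' @param params a [detection_params()].
#' @param t0_ms epoch start time (ms); sample 1 sits at `t0_ms`.
#' @return list with `threshold`, `degenerate_baseline` flag and `bursts`, a
#'   data frame (possibly empty) of `start_ms, end_ms, peak_ms, peak_amp,
#'   is_main`.
#' @export
detect_burst <- function(rms, fs, baseline_ms, search_ms = NULL,
                         params = detection_params(), t0_ms = 0) {
  n <- length(rms)
  t_ms <- t0_ms + (seq_len(n) - 1) / fs * 1000
  bl <- rms[t_ms >= baseline_ms[1] & t_ms < baseline_ms[2]]
  if (!length(bl)) stop("baseline window contains no samples")
  m <- mean(bl); s <- sd(bl)
  degenerate <- !is.finite(s) || s == 0
  thr <- if (degenerate) m + 1e-9 else m + params$burst_k_sd * s
  if (is.null(search_ms)) search_ms <- c(baseline_ms[2], max(t_ms))
  in_win <- t_ms >= search_ms[1] & t_ms <= search_ms[2]
  above <- rms > thr & in_win
  runs <- rle_runs(above)
  if (!nrow(runs)) {
    bursts <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                         peak_ms = numeric(0), peak_amp = numeric(0),
                         is_main = logical(0))
  } else {
    bursts <- do.call(rbind, lapply(seq_len(nrow(runs)), function(k) {
      idx <- runs$start[k]:runs$end[k]
      pk <- idx[which.max(rms[idx])]
      data.frame(start_ms = t_ms[runs$start[k]], end_ms = t_ms[runs$end[k]],
                 peak_ms = t_ms[pk], peak_amp = rms[pk], is_main = FALSE)
    }))
    bursts$is_main[which.max(bursts$peak_amp)] <- TRUE
  }
  list(threshold = thr, degenerate_baseline = degenerate, bursts = bursts)
}

## start/end indices of TRUE runs in a logical vector
rle_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Backtrack from the burst peak to the EMG onset
#'
#' Starting at the peak and walking backwards, the onset is the latest
#' pre-peak time at which the RMS activity has stayed below
#' `onset_frac` x peak for `hold_ms` consecutive milliseconds. If the
#' criterion is never met the onset is pinned to the epoch start and
#' flagged.
#'
#' @param rms RMS trace.
#' @param fs sampling rate (Hz).
#' @param peak_idx sample index of the burst peak.
#' @param params a [detection_params()].
#' @return list with `onset_idx` and `flag_epoch_start`.
#' @export
find_onset <- function(rms, fs, peak_idx, params = detection_params()) {
  stopifnot(peak_idx >= 1, peak_idx <= length(rms))
  need <- ceiling(params$hold_ms * fs / 1000)
  crit <- params$onset_frac * rms[peak_idx]
  below <- rms[seq_len(peak_idx - 1)] < crit
  if (length(below) >= need) {
    ok <- which(run_ending_at(below) >= need)
    if (length(ok)) return(list(onset_idx = max(ok), flag_epoch_start = FALSE))
  }
  list(onset_idx = 1L, flag_epoch_start = TRUE)
}

#' Find the post-peak decline of an EMG burst
#'
#' The decline is the earliest time at or after the peak from which the RMS
#' trace decreases strictly for `hold_ms` consecutive milliseconds. Ties are
#' broken toward the earlier sample. Returns `NA` if no such run exists
#' before the epoch end (the trial is then excluded from CancelTime).
#'
#' @inheritParams find_onset
#' @return list with `decline_idx` (may be `NA`).
#' @export
find_decline <- function(rms, fs, peak_idx, params = detection_params()) {
  stopifnot(peak_idx >= 1, peak_idx <= length(rms))
  need <- ceiling(params$hold_ms * fs / 1000)
  d <- diff(rms)
  if (peak_idx > length(d) - need + 1) return(list(decline_idx = NA_integer_))
  dec <- d < 0
  run <- rev(run_ending_at(rev(dec)))  # run length of decreases starting at i
  ok <- which(run[peak_idx:length(run)] >= need)
  if (!length(ok)) return(list(decline_idx = NA_integer_))
  list(decline_idx = peak_idx + ok[1] - 1L)
}

#' Forward mirror of the onset rule: burst offset
#'
#' The offset landmark has no normative definition in the source method; as
#' a documented convention it mirrors the onset rule forward in time: the
#' earliest post-peak time at which activity has stayed below
#' `onset_frac` x peak for `hold_ms` consecutive ms.
#'
#' @inheritParams find_onset
#' @return list with `offset_idx` (may be `NA`).
#' @export
find_offset <- function(rms, fs, peak_idx, params = detection_params()) {
  need <- ceiling(params$hold_ms * fs / 1000)
  n <- length(rms)
  crit <- params$onset_frac * rms[peak_idx]
  if (peak_idx >= n) return(list(offset_idx = NA_integer_))
  below <- rms[(peak_idx + 1):n] < crit
  run <- run_ending_at(below)
  hit <- which(run >= need)
  if (length(hit))
    return(list(offset_idx = peak_idx + hit[1] - need + 1L))
  list(offset_idx = NA_integer_)
}

## length of the consecutive TRUE run ending at each position
run_ending_at <- function(b) {
  idx <- seq_along(b)
  last_false <- cummax(idx * (!b))
  ifelse(b, idx - last_false, 0L)
}
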