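#' Normalized average EMG profiles per trial type
#'
#' Before averaging across muscles, each muscle's RMS traces are divided by
#' that muscle's peak activity (over all its trials in the call, i.e. one
#' participant), so profiles are on a common [0, 1] scale. Traces are
#' re-aligned to `align_ms` (e.g. the Stop signal or the detected EMG onset)
#' and averaged within trial type.
#'
#' @param emg an `emg_set` (the active muscle of each trial is used).
#' @param trials the matching trial table.
#' @param align_ms per-trial alignment time (ms, epoch time); profiles are
#'   expressed relative to it. Trials with `NA` are dropped.
#' @param window_ms two-element window around the alignment point (ms).
#' @param params a [detection_params()].
#' @param rms_list optional precomputed RMS traces (one per trial) to avoid
#'   re-filtering.
#' @return list with `t_ms` (relative time axis) and `profiles`, a data frame
#'   `type, t_ms, mean, n`; means lie in [0, 1]. Trials whose muscle has zero
#'   peak are skipped and counted in attribute `n_skipped_zero_peak`.
#' @export
normalize_profiles <- function(emg, trials, align_ms,
                               window_ms = c(-200, 400),
                               params = detection_params(), rms_list = NULL) {
  stopifnot(length(emg) == nrow(trials), length(align_ms) == nrow(trials))
  fs <- emg[[1]]$fs
  if (is.null(rms_list))
    rms_list <- lapply(emg, function(tr)
      emg_preprocess(tr$muscles[[tr$active_muscle]], tr$fs, params, tr$trial))
  muscle <- vapply(emg, function(tr) tr$active_muscle, character(1))
  peaks <- tapply(vapply(rms_list, max, numeric(1)), muscle, max)
  n_rel <- round(diff(window_ms) * fs / 1000)
  t_rel <- window_ms[1] + (seq_len(n_rel) - 1) / fs * 1000
  skipped <- 0L
  rows <- list()
  for (i in seq_along(emg)) {
    if (is.na(align_ms[i])) next
    pk <- peaks[[muscle[i]]]
    if (!is.finite(pk) || pk <= 0) { skipped <- skipped + 1L; next }
    tr <- emg[[i]]
    idx0 <- (align_ms[i] - tr$t0_ms) / 1000 * fs + 1
    idx <- round(idx0 + (window_ms[1] / 1000) * fs) + seq_len(n_rel) - 1
    ok <- idx >= 1 & idx <= length(rms_list[[i]])
    prof <- rep(NA_real_, n_rel)
    prof[ok] <- rms_list[[i]][idx[ok]] / pk
    rows[[length(rows) + 1L]] <-
      data.frame(type = trials$outcome[i], t_ms = t_rel, value = prof)
  }
  if (!length(rows)) stop("no trials available for profile averaging")
  all <- do.call(rbind, rows)
  ag <- aggregate(value ~ type + t_ms, data = all, FUN = mean, na.rm = TRUE)
  cnt <- aggregate(value ~ type + t_ms, data = all,
                   FUN = function(v) sum(!is.na(v)))
  names(ag)[3] <- "mean"; ag$n <- cnt$value
  structure(list(t_ms = t_rel, profiles = ag),
            n_skipped_zero_peak = skipped)
}

#' Time at which two onset-aligned profiles diverge
#'
#' The divergence latency is the first time (relative to the common
#' alignment point) at which the absolute difference between the two mean
#' profiles exceeds `criterion` and stays above it for `hold_ms`.
#'
#' @param profile_a,profile_b numeric vectors on a common time axis.
#' @param t_ms the common time axis (ms).
#' @param criterion difference criterion, in normalized profile units.
#' @param hold_ms how long the criterion must hold (ms).
#' @return divergence time (ms) or `NA` if the profiles never diverge.
#' @export
profile_divergence <- function(profile_a, profile_b, t_ms,
                               criterion = 0.05, hold_ms = 5) {
  stopifnot(length(profile_a) == length(profile_b),
            length(profile_a) == length(t_ms))
  dt <- median(diff(t_ms))
  need <- max(1L, ceiling(hold_ms / dt))
  over <- abs(profile_a - profile_b) > criterion
  over[is.na(over)] <- FALSE
  run <- run_ending_at(over)
  hit <- which(run >= need)
  if (!length(hit)) return(NA_real_)
  t_ms[hit[1] - need + 1L]
}

#' Partial-burst amplitude as a function of SSD
#'
#' Groups partial-EMG trials into SSD bins (default 5, matching the number
#' of SSD levels analysed in the source studies) and reports the mean
#' normalized peak amplitude per bin. Empty bins are reported as `NA`, not
#' zero.
#'
#' @param annotations output of [annotate_emg()] restricted (internally) to
#'   partial-EMG trials.
#' @param trials the matching trial table.
#' @param n_bins number of SSD bins.
#' @param normalize divide peak amplitudes by their overall maximum.
#' @return data frame `bin, ssd_lo, ssd_hi, mean_amp, n`; bin edges logged in
#'   attribute `breaks`.
#' @export
amplitude_by_ssd <- function(annotations, trials, n_bins = 5, normalize = TRUE) {
  df <- merge(annotations, trials, by = "trial")
  df <- df[df$outcome == "SuccStop_PartialEMG" & df$burst_detected &
             !is.na(df$peak_amp_mv), , drop = FALSE]
  if (!nrow(df)) stop("no partial-EMG trials with detected bursts")
  amp <- df$peak_amp_mv
  if (normalize) amp <- amp / max(amp)
  breaks <- unique(quantile(df$ssd_ms, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2) breaks <- c(breaks, breaks + 1)
  bin <- cut(df$ssd_ms, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(bin = seq_len(length(breaks) - 1),
                    ssd_lo = head(breaks, -1), ssd_hi = tail(breaks, -1),
                    mean_amp = NA_real_, n = 0L)
  for (b in unique(bin)) {
    out$mean_amp[b] <- mean(amp[bin == b])
    out$n[b] <- sum(bin == b)
  }
  attr(out, "breaks") <- breaks
  out
}
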