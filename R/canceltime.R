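#' Annotate every trial of an EMG set with burst landmarks
#'
#' Runs the full single-trial chain on the direction-congruent muscle of
#' each trial: preprocessing to the RMS envelope, 8 SD burst detection
#' against the fixation-to-Go baseline, onset backtracking, decline and
#' offset landmarks. All landmark times are epoch times in ms (epoch starts
#' at fixation onset).
#'
#' @param emg an `emg_set` from [synthesize_emg()] (or a compatible list).
#' @param trials the matching trial table.
#' @param params a [detection_params()].
#' @return data frame: one row per trial with `trial, muscle, burst_detected,
#'   onset_ms, peak_ms, peak_amp_mv, decline_ms, offset_ms, threshold,
#'   flag_degenerate_baseline, flag_onset_at_epoch_start`.
#' @export
annotate_emg <- function(emg, trials, params = detection_params()) {
  stopifnot(length(emg) == nrow(trials))
  rows <- lapply(seq_along(emg), function(i) {
    tr <- emg[[i]]
    x <- tr$muscles[[tr$active_muscle]]
    rms <- emg_preprocess(x, tr$fs, params, trial = tr$trial)
    bl_start <- min(tr$t0_ms + params$baseline_trim_ms, tr$go_ms / 2)
    det <- detect_burst(rms, tr$fs, baseline_ms = c(bl_start, tr$go_ms),
                        params = params, t0_ms = tr$t0_ms)
    out <- data.frame(trial = tr$trial, muscle = tr$active_muscle,
                      burst_detected = FALSE, onset_ms = NA_real_,
                      peak_ms = NA_real_, peak_amp_mv = NA_real_,
                      decline_ms = NA_real_, offset_ms = NA_real_,
                      threshold = det$threshold,
                      flag_degenerate_baseline = det$degenerate_baseline,
                      flag_onset_at_epoch_start = FALSE)
    main <- det$bursts[det$bursts$is_main, ]
    if (nrow(main)) {
      peak_idx <- round((main$peak_ms - tr$t0_ms) * tr$fs / 1000) + 1L
      on <- find_onset(rms, tr$fs, peak_idx, params)
      de <- find_decline(rms, tr$fs, peak_idx, params)
      off <- find_offset(rms, tr$fs, peak_idx, params)
      to_ms <- function(idx) if (is.na(idx)) NA_real_ else
        tr$t0_ms + (idx - 1) / tr$fs * 1000
      out$burst_detected <- TRUE
      out$onset_ms <- to_ms(on$onset_idx)
      out$peak_ms <- main$peak_ms
      out$peak_amp_mv <- main$peak_amp
      out$decline_ms <- to_ms(de$decline_idx)
      out$offset_ms <- to_ms(off$offset_idx)
      out$flag_onset_at_epoch_start <- on$flag_epoch_start
    }
    out
  })
  do.call(rbind, rows)
}

#' Per-trial CancelTime with outlier rules
#'
#' CancelTime is the latency from the Stop signal to the detected EMG
#' decline on Successful Stop trials that carry a partial burst. Values
#' below `canceltime_floor_ms` are flagged, as are values above
#' Q3 + `iqr_k` x IQR of the CancelTime distribution (computed per call,
#' i.e. per participant). With fewer than 3 partial trials the IQR rule is
#' skipped (flagged): the quartiles are not meaningful.
#'
#' @param annotations output of [annotate_emg()].
#' @param trials the matching trial table (needs `ssd_ms`, `outcome`).
#' @param params a [detection_params()].
#' @param go_ms time of the Go cue within the epoch (ms).
#' @return data frame with `trial, canceltime_ms, outlier, outlier_reason`
#'   and attribute `iqr_rule_skipped`.
#' @export
compute_canceltimes <- function(annotations, trials,
                                params = detection_params(), go_ms = 500) {
  df <- merge(annotations, trials, by = "trial")
  df <- df[df$outcome == "SuccStop_PartialEMG" & df$burst_detected &
             !is.na(df$decline_ms), , drop = FALSE]
  ct <- df$decline_ms - (go_ms + df$ssd_ms)
  out <- data.frame(trial = df$trial, canceltime_ms = ct,
                    outlier = FALSE, outlier_reason = "", stringsAsFactors = FALSE)
  low <- ct < params$canceltime_floor_ms
  out$outlier[low] <- TRUE
  out$outlier_reason[low] <- "below_floor"
  skipped <- nrow(out) < 3
  if (!skipped) {
    q <- quantile(ct, c(0.25, 0.75), names = FALSE, type = 7)
    hi_cut <- q[2] + params$iqr_k * (q[2] - q[1])
    hi <- !low & ct > hi_cut
    out$outlier[hi] <- TRUE
    out$outlier_reason[hi] <- "above_iqr"
  }
  attr(out, "iqr_rule_skipped") <- skipped
  out
}

#' Two-sided IQR outlier rule for landmark distributions
#'
#' Generic landmark screening: values beyond `iqr_k` x IQR below Q1 or above
#' Q3 of their own distribution are flagged.
#'
#' @param x numeric vector.
#' @param iqr_k IQR multiplier.
#' @return logical vector of outlier flags (`NA` stays `NA`).
#' @export
iqr_outliers <- function(x, iqr_k = 1.5) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, na.rm = TRUE, type = 7)
  spread <- q[2] - q[1]
  x < q[1] - iqr_k * spread | x > q[2] + iqr_k * spread
}
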