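#' Quality-control filter for MEP trials
#'
#' Two rules: (i) the pre-TMS EMG amplitude (90 ms window) must be below
#' `pre_emg_max_mv`; (ii) the MEP amplitude must fall within the group mean
#' +/- `iqr_k` x IQR, where groups are time-point x trial-type cells. Cells
#' with fewer than `min_group` trials skip rule (ii) (flagged): the IQR is
#' not meaningful there.
#'
#' @param meps `mep_trials` data frame (see [synthesize_mep()]); needs
#'   `tms_label, trial_type, amplitude_mv, pre_tms_emg_mv`.
#' @param pre_emg_max_mv rule (i) cutoff (mV).
#' @param iqr_k rule (ii) IQR multiplier.
#' @param min_group minimum cell size for rule (ii).
#' @return the input with `qc_pass`, `qc_reason` and attribute
#'   `iqr_skipped_cells`.
#' @export
qc_filter <- function(meps, pre_emg_max_mv = 0.05, iqr_k = 1.5,
                      min_group = 4) {
  out <- meps
  out$qc_pass <- TRUE
  out$qc_reason <- ""
  bad_emg <- out$pre_tms_emg_mv >= pre_emg_max_mv
  out$qc_pass[bad_emg] <- FALSE
  out$qc_reason[bad_emg] <- "pre_tms_emg"
  skipped <- character(0)
  cells <- split(seq_len(nrow(out)),
                 paste(out$tms_label, out$trial_type, sep = ":"))
  for (nm in names(cells)) {
    idx <- cells[[nm]]
    if (length(idx) < min_group) {
      skipped <- c(skipped, nm)
      next
    }
    a <- out$amplitude_mv[idx]
    spread <- iqr_k * (quantile(a, 0.75, names = FALSE) -
                         quantile(a, 0.25, names = FALSE))
    bad <- a < mean(a) - spread | a > mean(a) + spread
    out$qc_pass[idx][bad & out$qc_pass[idx]] <- FALSE
    out$qc_reason[idx][bad] <- ifelse(out$qc_reason[idx][bad] == "",
                                      "amplitude_iqr", out$qc_reason[idx][bad])
  }
  attr(out, "iqr_skipped_cells") <- skipped
  out
}

#' Normalize MEP amplitudes to the inter-trial-interval baseline
#'
#' ITI amplitudes are collapsed across trial types and averaged; every
#' amplitude is then expressed as a percentage of that mean, so the ITI
#' group itself averages exactly 100%.
#'
#' @param meps QC-filtered `mep_trials` (rows failing QC are ignored for
#'   the baseline and receive `NA`).
#' @return the input with `amplitude_pct`; attribute `iti_mean_mv`.
#' @export
normalize_to_iti <- function(meps) {
  ok <- if ("qc_pass" %in% names(meps)) meps$qc_pass else rep(TRUE, nrow(meps))
  iti <- meps$amplitude_mv[ok & meps$tms_label == "ITI"]
  if (!length(iti)) stop("no passing ITI trials to define the baseline")
  base <- mean(iti)
  if (base <= 0) stop("ITI baseline mean is not positive")
  out <- meps
  out$amplitude_pct <- ifelse(ok, 100 * meps$amplitude_mv / base, NA_real_)
  attr(out, "iti_mean_mv") <- base
  out
}

#' Time-point means of normalized MEP amplitude per trial type
#'
#' @param meps output of [normalize_to_iti()].
#' @return data frame `trial_type, tms_label, tms_ms, mean_pct, n`.
#' @export
mep_timepoint_means <- function(meps) {
  ok <- meps$qc_pass & !is.na(meps$amplitude_pct)
  df <- meps[ok & meps$tms_label != "ITI", , drop = FALSE]
  ag <- aggregate(amplitude_pct ~ trial_type + tms_ms, df, mean)
  cnt <- aggregate(amplitude_pct ~ trial_type + tms_ms, df, length)
  names(ag)[3] <- "mean_pct"
  ag$n <- cnt$amplitude_pct
  ag$tms_label <- as.character(ag$tms_ms)
  ag[order(ag$trial_type, ag$tms_ms),
     c("trial_type", "tms_label", "tms_ms", "mean_pct", "n")]
}

#' Bin MEP amplitudes relative to the single-trial EMG decline
#'
#' For trials with a detected EMG burst, the TMS time is re-expressed
#' relative to the EMG decline (TMS time minus decline time: negative =
#' TMS before the muscle cancellation), binned into half-open `bin_ms`
#' windows labeled by their lower edge, and pooled across participants
#' after per-participant ITI normalization. Only bins holding at least
#' `min_trials` trials are reported.
#'
#' @param meps output of [normalize_to_iti()] (pooled; `amplitude_pct`).
#' @param decline_ms per-row EMG decline time on the same clock as
#'   `tms_ms` (ms post-Stop); `NA` drops the row.
#' @param bin_ms bin width (ms).
#' @param range_ms analysis range `[lo, hi)` (ms).
#' @param min_trials minimum trials per reported bin.
#' @return data frame `trial_type, bin_lo_ms, mean_pct, n` (only qualifying
#'   bins); empty (zero rows) with a message attribute if nothing qualifies.
#' @export
bin_relative_to_canceltime <- function(meps, decline_ms, bin_ms = 30,
                                       range_ms = c(-90, 60),
                                       min_trials = 50) {
  stopifnot(length(decline_ms) == nrow(meps))
  rel <- meps$tms_ms - decline_ms
  ok <- meps$qc_pass & !is.na(meps$amplitude_pct) & !is.na(rel) &
    rel >= range_ms[1] & rel < range_ms[2]
  if (!any(ok)) {
    out <- data.frame(trial_type = character(0), bin_lo_ms = numeric(0),
                      mean_pct = numeric(0), n = integer(0))
    attr(out, "message") <- "no qualifying trials"
    return(out)
  }
  lo <- bin_ms * floor(rel[ok] / bin_ms)
  df <- data.frame(trial_type = meps$trial_type[ok], bin_lo_ms = lo,
                   pct = meps$amplitude_pct[ok])
  ag <- aggregate(pct ~ trial_type + bin_lo_ms, df, mean)
  cnt <- aggregate(pct ~ trial_type + bin_lo_ms, df, length)
  names(ag)[3] <- "mean_pct"
  ag$n <- cnt$pct
  ag <- ag[ag$n >= min_trials, , drop = FALSE]
  ag[order(ag$trial_type, ag$bin_lo_ms), ]
}

#' Corticospinal conduction time from MEP waveforms
#'
#' Automated MEP-onset rule: the first post-stimulus point whose absolute
#' amplitude exceeds the pre-stimulus baseline mean + 3 SD and stays above
#' it for at least 1 ms. The conduction time is the earliest onset across
#' trials (a minimum statistic, as in the source protocol's
#' across-10-trials rule).
#'
#' @param waveforms list with `traces`, `t_ms` (0 = stimulus) and `fs`, as
#'   from [synthesize_mep_waveforms()].
#' @param k_sd baseline SD multiplier for the onset criterion.
#' @param hold_ms how long the excursion must persist (ms).
#' @return list with `conduction_ms` (`NA` if no MEP detected on any trial)
#'   and `onsets_ms` per trial.
#' @export
conduction_time <- function(waveforms, k_sd = 3, hold_ms = 1) {
  t_ms <- waveforms$t_ms
  fs <- waveforms$fs
  need <- max(1L, ceiling(hold_ms * fs / 1000))
  onsets <- vapply(waveforms$traces, function(x) {
    pre <- x[t_ms < 0]
    thr <- mean(abs(pre)) + k_sd * sd(abs(pre))
    post <- which(t_ms > 0)
    above <- abs(x[post]) > thr
    run <- run_ending_at(above)
    hit <- which(run >= need)
    if (!length(hit)) return(NA_real_)
    t_ms[post[hit[1] - need + 1L]]
  }, numeric(1))
  list(conduction_ms = if (all(is.na(onsets))) NA_real_
       else min(onsets, na.rm = TRUE),
       onsets_ms = onsets)
}
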