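#' Morlet wavelet time-frequency decomposition
#'
#' Complex Morlet convolution via the FFT, with the cycle rule used for the
#' frontal-IC selection step: 3 cycles at the lowest frequency, increasing
#' linearly by 0.5 per frequency step. Wavelets are normalized to unit gain
#' at their center frequency, so a sinusoid of amplitude `A` contributes the
#' same power to its own row at every analysis frequency; power is the
#' squared magnitude of the convolution.
#'
#' @param x signal samples.
#' @param fs sampling rate (Hz).
#' @param freqs analysis frequencies (Hz), default 4-30 in 1 Hz steps.
#' @param cycles wavelet cycles per frequency (default `3 + 0.5 * (k - 1)`).
#' @return list with `power` (frequency x time matrix), `freqs` and `fs`.
#' @export
morlet_tf <- function(x, fs, freqs = 4:30,
                      cycles = 3 + 0.5 * (seq_along(freqs) - 1)) {
  stopifnot(length(cycles) == length(freqs))
  n <- length(x)
  longest <- max(cycles / freqs)
  if (n / fs < longest)
    stop("epoch shorter than the longest wavelet (", round(longest, 2), " s)")
  X <- fft(x)
  pow <- matrix(0, length(freqs), n)
  tw <- (seq_len(n) - 1 - floor(n / 2)) / fs      # centered time axis
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sig_t <- cycles[k] / (2 * pi * f)
    w <- exp(-tw^2 / (2 * sig_t^2)) * exp(2i * pi * f * tw)
    w <- w / Mod(sum(w * exp(-2i * pi * f * tw))) # unit gain at center freq
    ## circularly shift so the wavelet is centered at sample 1
    w <- c(w[(floor(n / 2) + 1):n], w[seq_len(floor(n / 2))])
    conv <- fft(X * fft(w), inverse = TRUE) / n
    pow[k, ] <- Mod(conv)^2
  }
  list(power = pow, freqs = freqs, fs = fs)
}

#' Select the participant's peak beta frequency
#'
#' Applies the beta-power selection rule to a time-frequency map of
#' Successful Stop epochs: the component qualifies only if mean beta power
#' (13-30 Hz) in the Stop window (Stop signal to SSRT_Beh) exceeds mean
#' beta power in a pre-Go baseline window (-1000 to -500 ms relative to the
#' Stop signal); the returned peak frequency is the beta frequency with
#' maximal Stop-window power. A missing increase yields a rejection.
#'
#' @param tf output of [morlet_tf()] on Stop-aligned epochs (averaged map).
#' @param t_ms epoch time axis (ms relative to Stop).
#' @param ssrt_beh_ms the participant's behavioral SSRT (ms).
#' @param stop_window,base_window windows (ms); defaults per the rule.
#' @param beta_band beta limits (Hz).
#' @return list with `accepted`, `peak_beta_freq` (`NA` if rejected) and the
#'   two window powers.
#' @export
select_peak_beta <- function(tf, t_ms, ssrt_beh_ms,
                             stop_window = c(0, ssrt_beh_ms),
                             base_window = c(-1000, -500),
                             beta_band = c(13, 30)) {
  rows <- tf$freqs >= beta_band[1] & tf$freqs <= beta_band[2]
  in_w <- function(w) t_ms >= w[1] & t_ms <= w[2]
  stop_p <- mean(tf$power[rows, in_w(stop_window)])
  base_p <- mean(tf$power[rows, in_w(base_window)])
  if (!is.finite(stop_p) || !is.finite(base_p) || stop_p <= base_p)
    return(list(accepted = FALSE, peak_beta_freq = NA_real_,
                stop_power = stop_p, base_power = base_p))
  by_freq <- rowMeans(tf$power[rows, in_w(stop_window), drop = FALSE])
  list(accepted = TRUE,
       peak_beta_freq = tf$freqs[rows][which.max(by_freq)],
       stop_power = stop_p, base_power = base_p)
}

#' Standard EEG preprocessing pass-through
#'
#' Utility chain for continuous multichannel EEG ahead of spatial filtering:
#' downsample (simple decimation after an anti-alias low-pass), band-pass
#' 2-100 Hz, notch line noise, re-reference to the channel average. The 120
#' Hz harmonic is notched by default alongside 60 and 180 Hz (configurable).
#'
#' @param x channels x samples matrix (or a vector for one channel).
#' @param fs input sampling rate (Hz).
#' @param fs_out output rate (Hz); must divide `fs`.
#' @param band band-pass edges (Hz).
#' @param notch_freqs line-noise frequencies (Hz).
#' @param average_ref re-reference to the channel mean.
#' @return list with `x` (processed matrix) and `fs`.
#' @export
eeg_preprocess <- function(x, fs, fs_out = 512, band = c(2, 100),
                           notch_freqs = c(60, 120, 180),
                           average_ref = TRUE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (fs %% fs_out != 0) stop("fs_out must divide fs")
  dec <- fs / fs_out
  proc <- t(apply(x, 1, function(ch) {
    if (dec > 1) {
      aa <- signal::butter(4, 0.8 / dec, type = "low")
      ch <- signal::filtfilt(aa, ch)[seq(1, length(ch), by = dec)]
    }
    bp <- signal::butter(2, band / (fs_out / 2), type = "pass")
    ch <- signal::filtfilt(bp, ch)
    for (f0 in notch_freqs) {
      if (f0 + 2 >= fs_out / 2) next
      nt <- signal::butter(2, c(f0 - 2, f0 + 2) / (fs_out / 2), type = "stop")
      ch <- signal::filtfilt(nt, ch)
    }
    ch
  }))
  if (nrow(x) == 1) proc <- matrix(proc, nrow = 1)
  if (average_ref && nrow(proc) > 1)
    proc <- sweep(proc, 2, colMeans(proc))
  list(x = proc, fs = fs_out)
}

#' Project multichannel EEG through a spatial filter
#'
#' Collapses a channels x samples array to the single component time series
#' the burst pipeline consumes, given a spatial filter vector (e.g. an
#' externally computed independent-component unmixing row).
#'
#' @param x channels x samples matrix.
#' @param weights filter vector, one weight per channel.
#' @return numeric vector of length `ncol(x)`.
#' @export
apply_spatial_filter <- function(x, weights) {
  stopifnot(nrow(x) == length(weights))
  as.numeric(crossprod(weights, x))
}

#' Burst-detection parameters for the beta-band envelope
#'
#' @param filter_fwhm_hz full width at half maximum of the frequency-domain
#'   Gaussian filter (Hz).
#' @param thresh_k detection threshold: median + `thresh_k` x SD of the
#'   pooled envelope distribution.
#' @param width_k burst-width threshold: median + `width_k` x SD (< thresh_k).
#' @param thresh_window_ms window (ms, post-alignment) whose pooled envelope
#'   amplitudes define the thresholds.
#' @return list of class `burst_params`.
#' @export
burst_params <- function(filter_fwhm_hz = 5, thresh_k = 1.5, width_k = 1,
                         thresh_window_ms = c(500, 1000)) {
  stopifnot(width_k < thresh_k, filter_fwhm_hz > 0)
  structure(as.list(environment()), class = "burst_params")
}

## analytic signal after a frequency-domain Gaussian band filter:
## one FFT gives both the narrow-band filtering and the Hilbert envelope
narrowband_envelope <- function(x, fs, f0, fwhm_hz) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs            # signed frequency axis
  sig_f <- fwhm_hz / (2 * sqrt(2 * log(2)))
  gauss <- exp(-(f - f0)^2 / (2 * sig_f^2))
  h <- ifelse(f > 0, 2, ifelse(f == 0, 1, 0))    # analytic-signal weights
  Mod(fft(fft(x) * gauss * h, inverse = TRUE) / n)
}

#' Detect beta bursts from per-trial envelopes
#'
#' Filters every trial at the peak beta frequency with a frequency-domain
#' Gaussian window (FWHM `filter_fwhm_hz`), takes the Hilbert-envelope
#' amplitude, and pools amplitudes from the threshold window (500-1000 ms
#' after the alignment point) across all trials to fix the detection
#' threshold (median + 1.5 SD) and the burst-width threshold (median +
#' 1 SD). A burst is a contiguous supra-width-threshold run containing at
#' least one sample above the detection threshold; its BurstTime is the
#' envelope-peak time. The burst percentage time series is the fraction of
#' trials whose envelope is above the width threshold at each sample.
#'
#' @param eeg an `eeg_set` from [synthesize_eeg_beta()], or a list with
#'   `epochs` (each `samples`, `t_ms`) and `fs`.
#' @param peak_beta_freq filter center frequency (Hz).
#' @param params a [burst_params()].
#' @return list of class `beta_burst_set`: `bursts` (data frame `trial,
#'   burst_time_ms, onset_ms, offset_ms, peak_amp`), `burst_pct` (data frame
#'   `t_ms, pct` across all trials), `supra` (trial x time logical matrix),
#'   `thresholds`, `trials` (ids), `t_ms`.
#' @export
detect_bursts <- function(eeg, peak_beta_freq, params = burst_params()) {
  t_ms <- eeg$t_ms %||% eeg$epochs[[1]]$t_ms
  fs <- eeg$fs %||% eeg$epochs[[1]]$fs
  win <- params$thresh_window_ms
  if (win[1] < min(t_ms) || win[2] > max(t_ms))
    stop("threshold window lies outside the epoch")
  env <- t(vapply(eeg$epochs, function(ep)
    narrowband_envelope(ep$samples, fs, peak_beta_freq, params$filter_fwhm_hz),
    numeric(length(t_ms))))
  in_win <- t_ms >= win[1] & t_ms <= win[2]
  pool <- as.vector(env[, in_win])
  thr <- median(pool) + params$thresh_k * sd(pool)
  wthr <- median(pool) + params$width_k * sd(pool)
  supra <- env > wthr
  ids <- vapply(eeg$epochs, function(ep) ep$trial, numeric(1))
  bursts <- list()
  for (r in seq_len(nrow(env))) {
    runs <- rle_runs(supra[r, ])
    if (!nrow(runs)) next
    for (k in seq_len(nrow(runs))) {
      idx <- runs$start[k]:runs$end[k]
      if (!any(env[r, idx] > thr)) next
      pk <- idx[which.max(env[r, idx])]
      bursts[[length(bursts) + 1L]] <-
        data.frame(trial = ids[r], burst_time_ms = t_ms[pk],
                   onset_ms = t_ms[runs$start[k]], offset_ms = t_ms[runs$end[k]],
                   peak_amp = env[r, pk])
    }
  }
  bursts <- if (length(bursts)) do.call(rbind, bursts) else
    data.frame(trial = numeric(0), burst_time_ms = numeric(0),
               onset_ms = numeric(0), offset_ms = numeric(0),
               peak_amp = numeric(0))
  structure(list(
    bursts = bursts,
    burst_pct = data.frame(t_ms = t_ms, pct = colMeans(supra)),
    supra = supra, thresholds = c(detect = thr, width = wthr),
    trials = ids, t_ms = t_ms),
    class = "beta_burst_set")
}

#' Burst statistics per trial type and analysis window
#'
#' Computes the mean burst percentage for each trial type in the Stop
#' window (Stop signal to SSRT_Beh) and its baseline window (Go to Stop
#' signal on stop trials; Go to mean SSD on Correct Go trials, i.e.
#' `-ssd..0` in Stop-aligned time), plus the mean BurstTime of Successful
#' Stop bursts inside the Stop window. A burst counts toward a window if
#' its BurstTime falls inside it.
#'
#' @param burst_set a `beta_burst_set`.
#' @param trials trial table covering the epoched trials (`trial, outcome,
#'   ssd_ms`).
#' @param ssrt_beh_ms behavioral SSRT of the participant (ms).
#' @param mean_ssd_ms mean SSD (ms), for the go-trial baseline window.
#' @return list with `window_stats` (data frame `trial_type, window,
#'   mean_burst_pct`) and `mean_bursttime_ms` (`NA` if no Stop-window burst
#'   on Successful Stop trials).
#' @export
burst_window_stats <- function(burst_set, trials, ssrt_beh_ms, mean_ssd_ms) {
  t_ms <- burst_set$t_ms
  info <- trials[match(burst_set$trials, trials$trial), , drop = FALSE]
  ttype <- ifelse(info$outcome %in% c("SuccStop_PartialEMG", "SuccStop_NoEMG"),
                  "SuccStop",
                  ifelse(info$outcome == "FailedStop", "FailedStop",
                         ifelse(info$outcome == "CorrectGo", "CorrectGo", NA)))
  base_lo <- ifelse(ttype == "CorrectGo", -mean_ssd_ms, -info$ssd_ms)
  rows <- list()
  for (ty in c("SuccStop", "FailedStop", "CorrectGo")) {
    sel <- which(ttype == ty)
    if (!length(sel)) next
    for (w in c("StopWin", "BaseWin")) {
      pct <- vapply(sel, function(r) {
        lohi <- if (w == "StopWin") c(0, ssrt_beh_ms) else c(base_lo[r], 0)
        mean(burst_set$supra[r, t_ms >= lohi[1] & t_ms <= lohi[2]])
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(trial_type = ty, window = w,
                   mean_burst_pct = 100 * mean(pct, na.rm = TRUE))
    }
  }
  bt <- merge(burst_set$bursts, data.frame(trial = burst_set$trials,
                                           trial_type = ttype), by = "trial")
  bt <- bt[bt$trial_type == "SuccStop" & bt$burst_time_ms >= 0 &
             bt$burst_time_ms <= ssrt_beh_ms, , drop = FALSE]
  list(window_stats = do.call(rbind, rows),
       mean_bursttime_ms = if (nrow(bt)) mean(bt$burst_time_ms) else NA_real_)
}
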