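#' Detection parameters for the single-trial EMG pipeline
#'
#' All tunables of the burst-detection chain, with the values used
#' throughout: 4th-order Butterworth band-stop notches at 60/120/180 Hz,
#' full-wave rectification, 50 ms centered RMS; burst threshold at baseline
#' mean + 8 SD; onset where the activity stays below 20% of the peak for
#' 5 consecutive ms; decline at the first strictly decreasing 5 ms run after
#' the peak; CancelTime outlier floor 50 ms plus a Q3 + 1.5 IQR upper cutoff.
#'
#' @param notch_freqs line-noise frequencies to remove (Hz).
#' @param filter_order Butterworth order of each band-stop notch.
#' @param notch_halfwidth_hz half-width of each stop band (Hz).
#' @param baseline_trim_ms leading portion of the baseline window excluded
#'   from the threshold statistics (ms); guards against the edge transient
#'   of the zero-phase notch filters, which would otherwise inflate the
#'   baseline SD.
#' @param rms_window_ms centered RMS window (ms).
#' @param burst_k_sd burst threshold in baseline SDs above the baseline mean.
#' @param onset_frac onset criterion as a fraction of the burst peak.
#' @param hold_ms duration the onset/decline criteria must hold (ms).
#' @param canceltime_floor_ms lower CancelTime cutoff (ms).
#' @param iqr_k IQR multiplier for outlier cutoffs.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(notch_freqs = c(60, 120, 180), filter_order = 4,
                             notch_halfwidth_hz = 2,
                             baseline_trim_ms = 100,
                             rms_window_ms = 50, burst_k_sd = 8,
                             onset_frac = 0.20, hold_ms = 5,
                             canceltime_floor_ms = 50, iqr_k = 1.5) {
  p <- as.list(environment())
  stopifnot(all(unlist(p[-1]) > 0), onset_frac > 0, onset_frac < 1)
  structure(p, class = "detection_params")
}

#' Preprocess a raw EMG trace to its RMS envelope
#'
#' Applies the band-stop notches at 60 Hz and its harmonics (Butterworth,
#' zero-phase via forward-backward filtering), full-wave rectifies, and
#' computes the root-mean-square over a centered `rms_window_ms` window. At
#' the epoch edges the window shrinks to the available samples, so the
#' output has the same length as the input.
#'
#' @param x numeric vector of raw EMG samples (mV).
#' @param fs sampling rate (Hz).
#' @param params a [detection_params()].
#' @param trial optional trial id used in error messages.
#' @return non-negative RMS trace, same length as `x` (mV).
#' @export
emg_preprocess <- function(x, fs, params = detection_params(), trial = NULL) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite EMG samples", if (!is.null(trial)) paste0(" in trial ", trial))
  n <- length(x)
  w <- round(params$rms_window_ms * fs / 1000)
  if (n < w) stop("trace shorter than the RMS window")
  for (f0 in params$notch_freqs) {
    if (f0 + params$notch_halfwidth_hz >= fs / 2) next
    band <- c(f0 - params$notch_halfwidth_hz, f0 + params$notch_halfwidth_hz)
    bt <- signal::butter(params$filter_order / 2, band / (fs / 2), type = "stop")
    x <- signal::filtfilt(bt, x)
  }
  running_rms(abs(x), w)
}

## centered running RMS over exactly w samples (half-sample asymmetry for
## even w), with shrink-to-valid windows at the epoch edges
running_rms <- function(x, w) {
  n <- length(x)
  half_l <- floor(w / 2)
  half_r <- w - half_l - 1L
  cs <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_l)
  hi <- pmin(n, i + half_r)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}
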