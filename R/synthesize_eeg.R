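#' Surrogate single-channel EEG with injected beta bursts
#'
#' Produces one spatially-filtered-like EEG trace per trial, epoched -1.5 to
#' 1.5 s around the alignment point (the Stop signal on stop trials; Go +
#' mean SSD on Correct Go trials, mirroring how the recorded studies windowed
#' go trials). Background is 1/f ("pink") noise. On triggered Successful
#' Stop trials a beta burst - a Gaussian-windowed sinusoid at `beta_freq`,
#' about three cycles wide at half maximum - is injected with its envelope
#' peak at `muscle_cancel_ms - beta_lead_ms` after the Stop signal. Bursts
#' whose peak would fall before the Stop signal are clipped at 0 ms and
#' flagged.
#'
#' @param trials,truth as returned by [simulate_task()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list of class `eeg_set` with `epochs` (list per included trial:
#'   `trial`, `samples`, `fs`, `t_ms` from -1500 to 1500 around alignment),
#'   `injected` (data frame: trial, injected burst-peak time in ms post-Stop
#'   or `NA`, clipped flag) and `mean_ssd_ms`.
#' @export
synthesize_eeg_beta <- function(trials, truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(trials) == nrow(truth))
  with_seed(seed %||% config$seed, {
    fs <- config$fs_eeg
    half <- 1.5
    n_samp <- round(2 * half * fs)
    t_ms <- (seq_len(n_samp) - 1) / fs * 1000 - half * 1000
    mean_ssd <- mean(trials$ssd_ms, na.rm = TRUE)
    keep <- which(trials$type == "stop" | trials$outcome == "CorrectGo")
    epochs <- vector("list", length(keep))
    inj <- data.frame(trial = trials$trial[keep], burst_ms = NA_real_,
                      clipped = FALSE)
    fwhm_ms <- 3 / config$beta_freq * 1000          # ~3 cycles at half maximum
    sig_ms <- fwhm_ms / (2 * sqrt(2 * log(2)))
    for (j in seq_along(keep)) {
      i <- keep[j]
      x <- pink_noise(n_samp) * config$beta_noise_sd
      if (trials$type[i] == "stop" &&
          trials$outcome[i] %in% c("SuccStop_PartialEMG", "SuccStop_NoEMG") &&
          isTRUE(truth$triggered[i]) && is.finite(truth$muscle_cancel_ms[i])) {
        tc <- truth$muscle_cancel_ms[i] - config$beta_lead_ms
        if (tc < 0) {
          tc <- 0
          inj$clipped[j] <- TRUE
        }
        x <- x + config$beta_amp * exp(-(t_ms - tc)^2 / (2 * sig_ms^2)) *
          sin(2 * pi * config$beta_freq * (t_ms - tc) / 1000 + runif(1, 0, 2 * pi))
        inj$burst_ms[j] <- tc
      }
      epochs[[j]] <- list(trial = trials$trial[i], samples = x, fs = fs,
                          t_ms = t_ms,
                          outcome = trials$outcome[i], type = trials$type[i])
    }
    structure(list(epochs = epochs, injected = inj, mean_ssd_ms = mean_ssd,
                   fs = fs, t_ms = t_ms),
              class = "eeg_set")
  })
}

## 1/f-amplitude Gaussian noise, unit SD, generated in the frequency domain
pink_noise <- function(n) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- 1 / sqrt(f)
  phases <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]))
    if (nf > 1) full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(fft(full, inverse = TRUE))
  as.numeric(scale(x))
}

#' Synthesize MEP amplitudes for the TMS arm of the task
#'
#' Assigns a TMS time to every stop trial (drawn from ITI, 100, 120, 140,
#' 160, 180 ms post-Stop) and to half of the go trials (yoked to the previous
#' stop trial's time, as in the recorded protocol). Amplitudes are lognormal
#' around `mep_baseline_mv`; on Successful Stop trials with TMS at or after
#' `mep_suppression_onset_ms` the amplitude is scaled by
#' `mep_suppression_factor`. A fraction `mep_contam_rate` of trials gets
#' contaminated pre-TMS EMG (> 0.05 mV) for QC testing; the rest sit well
#' below that limit.
#'
#' @param trials,truth as returned by [simulate_task()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data frame of class `mep_trials`: `trial, trial_type, tms_label`
#'   ("ITI" or the post-Stop time), `tms_ms` (`NA` for ITI), `amplitude_mv`,
#'   `pre_tms_emg_mv`, `suppressed` (ground truth), `contaminated` (ground
#'   truth).
#' @export
synthesize_mep <- function(trials, truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed %||% config$seed, {
    times <- c(NA, 100, 120, 140, 160, 180)
    labels <- c("ITI", "100", "120", "140", "160", "180")
    trial_type <- ifelse(trials$outcome %in% c("SuccStop_PartialEMG",
                                               "SuccStop_NoEMG"), "SuccStop",
                  ifelse(trials$outcome == "FailedStop", "FailedStop",
                  ifelse(trials$outcome == "CorrectGo", "CorrectGo", NA)))
    idx_stop <- which(trials$type == "stop")
    idx_go <- which(trials$outcome == "CorrectGo")
    idx_go <- sort(sample(idx_go, floor(length(idx_go) / 2)))
    pick <- rep(NA_integer_, nrow(trials))
    pick[idx_stop] <- sample.int(6, length(idx_stop), replace = TRUE)
    last <- 1L
    for (i in seq_len(nrow(trials))) {       # yoke go-trial TMS to previous stop
      if (!is.na(pick[i]) && trials$type[i] == "stop") last <- pick[i]
      if (i %in% idx_go) pick[i] <- last
    }
    use <- which(!is.na(pick) & !is.na(trial_type))
    k <- pick[use]
    n <- length(use)
    amp <- rlnorm(n, meanlog = log(config$mep_baseline_mv),
                  sdlog = config$mep_sdlog)
    suppressed <- trial_type[use] == "SuccStop" & !is.na(times[k]) &
      times[k] >= config$mep_suppression_onset_ms
    amp[suppressed] <- amp[suppressed] * config$mep_suppression_factor
    contaminated <- runif(n) < config$mep_contam_rate
    pre <- abs(rnorm(n, 0.01, 0.005))
    pre[contaminated] <- runif(sum(contaminated), 0.06, 0.2)
    out <- data.frame(trial = trials$trial[use],
                      trial_type = trial_type[use],
                      tms_label = labels[k],
                      tms_ms = times[k],
                      amplitude_mv = amp,
                      pre_tms_emg_mv = pre,
                      suppressed = suppressed,
                      contaminated = contaminated,
                      stringsAsFactors = FALSE)
    class(out) <- c("mep_trials", class(out))
    out
  })
}

#' Synthetic MEP waveforms for conduction-time estimation
#'
#' Clean single-trial MEP traces: pre-stimulus baseline noise, then a damped
#' sinusoidal deflection starting `onset_ms + jitter` after the stimulus.
#' Used to exercise the automated MEP-onset / corticospinal conduction-time
#' estimator.
#'
#' @param n_trials number of traces.
#' @param onset_ms true earliest possible MEP onset (ms post-stimulus).
#' @param jitter_ms onset jitter: uniform on `[0, jitter_ms]` (>= 0).
#' @param fs sampling rate (Hz).
#' @param amp_mv MEP amplitude (mV).
#' @param noise_sd_mv baseline noise SD (mV).
#' @param pre_ms,post_ms trace extent around the stimulus (ms).
#' @param seed integer seed.
#' @return list with `traces` (list of sample vectors), `t_ms`, `fs` and
#'   `true_onsets_ms`.
#' @export
synthesize_mep_waveforms <- function(n_trials = 10, onset_ms = 23,
                                     jitter_ms = 2, fs = 2000, amp_mv = 1,
                                     noise_sd_mv = 0.01,
                                     pre_ms = 20, post_ms = 60, seed = NULL) {
  with_seed(seed, {
    t_ms <- seq(-pre_ms, post_ms, by = 1000 / fs)
    onsets <- onset_ms + runif(n_trials, 0, jitter_ms)
    traces <- lapply(seq_len(n_trials), function(i) {
      x <- rnorm(length(t_ms), 0, noise_sd_mv)
      u <- (t_ms - onsets[i]) / 1000
      mep <- ifelse(u > 0, amp_mv * sin(2 * pi * 120 * u) * exp(-u / 0.005), 0)
      x + mep
    })
    list(traces = traces, t_ms = t_ms, fs = fs, true_onsets_ms = onsets)
  })
}
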