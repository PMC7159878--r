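#' Race parameters for the stop-signal race model
#'
#' Ex-Gaussian parameters (in seconds) of the Go and Stop finish-time
#' distributions plus the trigger-failure probability `p_tf` (stop trials on
#' which the Stop process is never initiated). In the simulator the Go finish
#' is the time at which the EMG envelope would cross the press threshold (the
#' point of no return) and the Stop finish is the central stopping latency;
#' the Stop command reaches the muscle one corticospinal conduction time
#' later.
#'
#' Defaults are tuned to the pooled behavioral summary of the studies the
#' package emulates: Go keypress RT mean 483 ms / SD 94 ms once the 60 ms
#' ballistic + device delay is added back, stopping latency such that muscle
#' cancellation sits near 160 ms after the Stop signal, and ~4% trigger
#' failures.
#'
#' @param mu_go,sigma_go,tau_go Go process ex-Gaussian parameters (s).
#' @param mu_stop,sigma_stop,tau_stop Stop process ex-Gaussian parameters (s).
#' @param p_tf trigger-failure probability in `[0, 1]`.
#' @return A list of class `race_params`.
#' @export
race_params <- function(mu_go = 0.340, sigma_go = 0.050, tau_go = 0.083,
                        mu_stop = 0.100, sigma_stop = 0.030, tau_stop = 0.037,
                        p_tf = 0.04) {
  p <- list(mu_go = mu_go, sigma_go = sigma_go, tau_go = tau_go,
            mu_stop = mu_stop, sigma_stop = sigma_stop, tau_stop = tau_stop,
            p_tf = p_tf)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("race parameter '", nm, "' must be a single finite number")
  }
  if (p$sigma_go <= 0 || p$sigma_stop <= 0)
    stop("race parameter 'sigma_go'/'sigma_stop' must be > 0")
  if (p$tau_go < 0 || p$tau_stop < 0)
    stop("race parameter 'tau_go'/'tau_stop' must be >= 0")
  if (p$p_tf < 0 || p$p_tf > 1)
    stop("race parameter 'p_tf' must lie in [0, 1]")
  structure(p, class = "race_params")
}

#' Simulation configuration for the synthetic stop-signal study
#'
#' Bundles every constant of the emulated experiment: task schedule (25% stop
#' trials, +/-50 ms SSD staircase, 1 s response deadline, 2.5 s trials),
#' sampling rates, the race parameters, the timing cascade (ballistic stage,
#' electromechanical delay, corticospinal conduction), the EMG burst shape,
#' noise levels, the surrogate-EEG beta burst and the MEP suppression model.
#'
#' The EMG burst envelope rises as a gamma-like function
#' `r(u) = u^k exp(k (1 - u))` over `emg_rise_ms` to `emg_peak_mv`, then
#' decays exponentially with time constant `emg_decay_ms`. The press
#' threshold `press_threshold_mv` defines the point of no return; the lag
#' from EMG onset to the threshold crossing follows from the rise shape (see
#' [rise_lag_ms()]) and is what produces partial bursts. Once the envelope
#' crosses the threshold, the keypress follows after
#' `ballistic_ms + electromech_ms` regardless of any Stop command.
#'
#' @param n_trials total number of trials.
#' @param prop_stop fraction of stop trials (0 < prop_stop < 1).
#' @param ssd_start,ssd_step staircase start and step (ms).
#' @param ssd_fixed if non-`NULL`, disables the staircase and presents this
#'   SSD (ms) on every stop trial.
#' @param deadline response deadline from the Go cue (ms).
#' @param trial_length full trial duration (ms).
#' @param fs_emg,fs_eeg sampling rates (Hz).
#' @param fix_ms fixation-to-Go interval; the EMG epoch starts at fixation
#'   and the fixation window is the detection baseline (ms).
#' @param epoch_ms EMG epoch length from fixation onset (ms).
#' @param race a [race_params()] object.
#' @param ballistic_ms ballistic stage: point-of-no-return to the end of the
#'   un-cancellable mechanical response (ms).
#' @param electromech_ms device/contact delay completing the keypress (ms).
#' @param conduction_ms corticospinal conduction time added to the central
#'   Stop finish before it silences the muscle (ms).
#' @param emg_rise_ms envelope rise time from EMG onset to peak (ms).
#' @param emg_decay_ms envelope decay time constant after peak/cancellation
#'   (ms). The default satisfies the balance condition under which the
#'   centered-RMS maximum of a truncated burst sits at the truncation point
#'   (decay over half the RMS window matches the rise half a window before
#'   the median truncation lag), so detected declines track the injected
#'   muscle cancellation without systematic offset.
#' @param emg_peak_mv envelope peak of a full (keypress) burst (mV).
#' @param press_threshold_mv envelope level that triggers a keypress (mV);
#'   must be below `emg_peak_mv`.
#' @param emg_carrier_hz carrier frequency of the rendered burst (Hz); kept
#'   away from the line-noise notches.
#' @param noise_sd_mv baseline Gaussian EMG noise SD (mV).
#' @param line_amp_mv amplitude of the 60 Hz line component (mV).
#' @param beta_freq surrogate beta-burst frequency (Hz, 13-30).
#' @param beta_lead_ms beta-burst peak precedes muscle cancellation by this
#'   much (ms).
#' @param beta_amp,beta_noise_sd burst amplitude and 1/f background SD of the
#'   surrogate EEG (arbitrary units).
#' @param mep_suppression_onset_ms earliest post-Stop TMS time showing MEP
#'   suppression on Successful Stop trials (ms).
#' @param mep_suppression_factor multiplicative MEP suppression (1 = none).
#' @param mep_baseline_mv,mep_sdlog lognormal MEP amplitude model: median (mV)
#'   and log-SD.
#' @param mep_contam_rate fraction of trials with pre-TMS EMG contamination.
#' @param seed default seed used when none is passed to the generators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_trials = 600, prop_stop = 0.25,
                       ssd_start = 200, ssd_step = 50, ssd_fixed = NULL,
                       deadline = 1000, trial_length = 2500,
                       fs_emg = 2000, fs_eeg = 512,
                       fix_ms = 500, epoch_ms = 2000,
                       race = race_params(),
                       ballistic_ms = 35, electromech_ms = 25,
                       conduction_ms = 23,
                       emg_rise_ms = 100, emg_decay_ms = 19,
                       emg_peak_mv = 1.0, press_threshold_mv = 0.95,
                       emg_carrier_hz = 140,
                       noise_sd_mv = 0.01, line_amp_mv = 0.05,
                       beta_freq = 20, beta_lead_ms = 40,
                       beta_amp = 5, beta_noise_sd = 1,
                       mep_suppression_onset_ms = 140,
                       mep_suppression_factor = 0.6,
                       mep_baseline_mv = 0.4, mep_sdlog = 0.4,
                       mep_contam_rate = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (!inherits(race, "race_params")) cfg$race <- do.call(race_params, race)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  durs <- c("ssd_start", "deadline", "trial_length", "fix_ms", "epoch_ms",
            "ballistic_ms", "electromech_ms", "conduction_ms",
            "emg_rise_ms", "emg_decay_ms", "beta_lead_ms",
            "mep_suppression_onset_ms")
  for (nm in durs) {
    if (!num1(cfg[[nm]]) || cfg[[nm]] < 0)
      stop("config field '", nm, "' must be a finite duration >= 0")
  }
  if (!num1(cfg$prop_stop) || cfg$prop_stop <= 0 || cfg$prop_stop >= 1)
    stop("config field 'prop_stop' must lie strictly in (0, 1)")
  if (!num1(cfg$ssd_step) || cfg$ssd_step <= 0)
    stop("config field 'ssd_step' must be > 0")
  if (!num1(cfg$press_threshold_mv) || !num1(cfg$emg_peak_mv) ||
      cfg$press_threshold_mv >= cfg$emg_peak_mv || cfg$press_threshold_mv <= 0)
    stop("config field 'press_threshold_mv' must satisfy 0 < threshold < emg_peak_mv")
  if (!num1(cfg$beta_freq) || cfg$beta_freq < 13 || cfg$beta_freq > 30)
    stop("config field 'beta_freq' must lie in the beta band (13-30 Hz)")
  if (cfg$fs_emg <= 0 || cfg$fs_eeg <= 0)
    stop("config field 'fs_emg'/'fs_eeg' must be positive")
  invisible(cfg)
}

## gamma-like unit rise: 0 at u = 0, 1 at u = 1 (the peak), k fixes the shape
rise_shape <- function(u, k = 2) {
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- (u[pos]^k) * exp(k * (1 - u[pos]))
  out[u >= 1] <- 1
  out
}

## inverse of rise_shape on (0, 1): smallest u with r(u) = frac
rise_shape_inv <- function(frac, k = 2) {
  stopifnot(frac > 0, frac < 1)
  stats::uniroot(function(u) rise_shape(u, k) - frac,
                 interval = c(1e-9, 1), tol = 1e-10)$root
}

#' Lag from EMG onset to the press-threshold crossing
#'
#' Time the rendered EMG envelope needs to climb from onset to the press
#' threshold, given the configured rise shape. This lag is the width of the
#' window in which a Stop command truncates the burst without preventing the
#' keypress decision, i.e. it controls the proportion of partial-EMG trials.
#'
#' @param config a [sim_config()].
#' @return lag in ms.
#' @export
rise_lag_ms <- function(config) {
  config$emg_rise_ms *
    rise_shape_inv(config$press_threshold_mv / config$emg_peak_mv)
}

#' Noise-free EMG burst envelope
#'
#' The canonical envelope used by the generator: gamma-like rise over
#' `emg_rise_ms` to `emg_peak_mv`, exponential decay afterwards; if
#' `cancel_ms` (time from onset) is given the drive stops there and the
#' envelope decays from the attained level.
#'
#' @param t_ms times from EMG onset (ms); may be negative (returns 0).
#' @param config a [sim_config()].
#' @param cancel_ms optional truncation time from onset (ms).
#' @return envelope values (mV).
#' @export
burst_envelope <- function(t_ms, config, cancel_ms = NULL) {
  rise <- config$emg_rise_ms
  env <- config$emg_peak_mv * rise_shape(t_ms / rise)
  post <- t_ms > rise
  env[post] <- config$emg_peak_mv *
    exp(-(t_ms[post] - rise) / config$emg_decay_ms)
  if (!is.null(cancel_ms) && is.finite(cancel_ms)) {
    lvl <- burst_envelope(cancel_ms, config)
    cut <- t_ms > cancel_ms
    env[cut] <- lvl * exp(-(t_ms[cut] - cancel_ms) / config$emg_decay_ms)
  }
  env
}
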