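#' Render two-channel surface EMG for simulated trials
#'
#' Turns the abstract trial timeline of [simulate_task()] into sampled EMG
#' epochs (2 s from fixation onset at `fs_emg`). The direction-congruent
#' muscle (left -> FDI on the vertical pad, right -> ADM on the horizontal
#' pad) carries a movement burst rendered as envelope-modulated Gaussian
#' noise; the other muscle carries baseline activity only. On responded
#' trials the envelope runs its full course (rise to `emg_peak_mv`, then
#' exponential decay); on partial trials the drive is truncated at the
#' muscle cancellation time and decays from the attained level, so partial
#' amplitude grows with SSD. The burst carrier is a sinusoid at
#' `emg_carrier_hz` (random phase per trial): motor-unit interference
#' structure is deliberately not modelled, and a coherent carrier keeps the
#' rectified-RMS landmarks of the rendered burst well defined at the
#' single-trial level. Baseline Gaussian noise and a 60 Hz line component
#' (random phase per trial) are added everywhere.
#'
#' The pre-noise envelope of every muscle is stored alongside the samples so
#' that detection code can be validated against the generator's own truth.
#'
#' @param trials,truth as returned by [simulate_task()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list of class `emg_set`: one element per trial, each a list with
#'   `trial`, `fs`, `t0_ms` (epoch start = fixation onset, taken as 0),
#'   `go_ms` (Go cue within the epoch), `muscles` (named list of sample
#'   vectors, mV) and `envelope` (matching pre-noise envelopes).
#' @export
synthesize_emg <- function(trials, truth, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(trials) == nrow(truth))
  if (config$fs_emg * config$emg_rise_ms / 1000 < 4)
    stop("fs_emg too low: fewer than 4 samples over the burst rise")
  with_seed(seed %||% config$seed, {
    fs <- config$fs_emg
    n_samp <- round(config$epoch_ms * fs / 1000)
    t_ms <- (seq_len(n_samp) - 1) / fs * 1000
    go_ms <- config$fix_ms
    out <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      th <- truth[i, ]
      active <- if (tr$direction == "left") "FDI" else "ADM"
      other <- setdiff(c("FDI", "ADM"), active)
      env <- setNames(list(numeric(n_samp), numeric(n_samp)),
                      c(active, other))
      has_burst <- !is.na(th$emg_onset_ms) &&
        (tr$outcome %in% c("CorrectGo", "FailedStop", "SuccStop_PartialEMG"))
      if (has_burst) {
        ## snap onset to the sample grid so the rendered peak is exact
        onset_abs <- round((go_ms + th$emg_onset_ms) * fs / 1000) / fs * 1000
        cancel_rel <- if (tr$outcome == "SuccStop_PartialEMG")
          (go_ms + tr$ssd_ms + th$muscle_cancel_ms) - onset_abs else NULL
        env[[active]] <- burst_envelope(t_ms - onset_abs, config, cancel_rel)
      }
      mus <- lapply(env, function(e) {
        x <- e * sin(2 * pi * config$emg_carrier_hz * t_ms / 1000 +
                       runif(1, 0, 2 * pi))
        if (config$noise_sd_mv > 0) x <- x + rnorm(n_samp, 0, config$noise_sd_mv)
        if (config$line_amp_mv > 0)
          x <- x + config$line_amp_mv *
            sin(2 * pi * 60 * t_ms / 1000 + runif(1, 0, 2 * pi))
        x
      })
      out[[i]] <- list(trial = tr$trial, fs = fs, t0_ms = 0, go_ms = go_ms,
                       muscles = mus, envelope = env, active_muscle = active)
    }
    structure(out, class = "emg_set", fs = fs, go_ms = go_ms)
  })
}
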