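#' Race simulation with an explicit ballistic stage
#'
#' Simulates a full stop-signal session under the generative race (via
#' [simulate_task()]) with a configurable ballistic-stage duration and
#' returns both stopping-latency estimates: SSRT from keypresses
#' (integration method) and SSRT from EMG-onset-equivalent events (per-SSD
#' method). Because the keypress lands `ballistic + electromech` after the
#' race-deciding threshold crossing while the race itself is unaffected,
#' the predicted gap `ssrt_beh - ssrt_emg` grows one-for-one with the
#' post-crossing delay.
#'
#' @param race a [race_params()].
#' @param ballistic_ms ballistic-stage duration (ms).
#' @param n_trials total trials (25% stop); fewer than 200 stop trials is
#'   flagged as unstable.
#' @param electromech_ms additional device delay (ms); default 0 so the gap
#'   isolates the ballistic stage.
#' @param conduction_ms corticospinal conduction time (ms); default 0 for
#'   the abstract race (it shifts both estimates equally).
#' @param seed integer seed.
#' @return list: `ssrt_beh_ms`, `ssrt_emg_ms`, `gap_ms`,
#'   `mean_canceltime_ms` (ground-truth muscle cancellation on partial
#'   trials), `n_stop`, `flag_low_n`.
#' @export
simulate_ballistic <- function(race, ballistic_ms, n_trials = 40000,
                               electromech_ms = 0, conduction_ms = 0,
                               seed = 1L) {
  stopifnot(inherits(race, "race_params"), ballistic_ms >= 0)
  cfg <- sim_config(n_trials = n_trials, race = race,
                    ballistic_ms = ballistic_ms,
                    electromech_ms = electromech_ms,
                    conduction_ms = conduction_ms, seed = seed)
  sim <- simulate_task(cfg, seed)
  tr <- sim$trials
  n_stop <- sum(tr$type == "stop")
  ## at simulation scale, rarely-visited staircase-tail SSDs with a handful
  ## of trials produce wildly unstable per-SSD estimates; require 0.5% of
  ## the stop trials per level (>= 5, the participant-scale default)
  bs <- behavior_summary(tr, min_per_ssd = max(5, round(0.005 * n_stop)))
  ct <- sim$truth$muscle_cancel_ms[sim$truth$partial]
  list(ssrt_beh_ms = bs$ssrt_beh_ms,
       ssrt_emg_ms = bs$ssrt_emg_ms,
       gap_ms = bs$ssrt_beh_ms - bs$ssrt_emg_ms,
       mean_canceltime_ms = mean(ct),
       n_stop = n_stop,
       flag_low_n = n_stop < 200)
}

#' Sweep the ballistic-stage duration against an observed SSRT gap
#'
#' Runs [simulate_ballistic()] over a grid of ballistic durations and
#' reports the smallest duration whose predicted keypress-minus-EMG SSRT
#' gap reaches `target_gap_ms` - the minimum ballistic stage consistent
#' with an observed discrepancy between behavioral and EMG stopping-latency
#' estimates.
#'
#' @param race a [race_params()].
#' @param ballistic_grid_ms durations to test (ms).
#' @param target_gap_ms observed gap to reach (ms).
#' @param n_trials trials per grid point.
#' @param seed integer seed (each grid point gets a derived sub-seed).
#' @return list with `sweep` (data frame `ballistic_ms, gap_ms`),
#'   `min_consistent_ms` (smallest duration with gap >= target; `NA` if
#'   never reached) and `slope` (regression of gap on duration).
#' @export
sweep_ballistic <- function(race, ballistic_grid_ms = seq(0, 80, by = 5),
                            target_gap_ms = 50, n_trials = 40000,
                            seed = 1L) {
  gaps <- vapply(seq_along(ballistic_grid_ms), function(k)
    simulate_ballistic(race, ballistic_grid_ms[k], n_trials = n_trials,
                       seed = as.integer(seed) %% 100000L + 131L * k)$gap_ms,
    numeric(1))
  sweep <- data.frame(ballistic_ms = ballistic_grid_ms, gap_ms = gaps)
  hit <- which(gaps >= target_gap_ms)
  list(sweep = sweep,
       min_consistent_ms = if (length(hit)) ballistic_grid_ms[min(hit)]
                           else NA_real_,
       slope = unname(coef(stats::lm(gap_ms ~ ballistic_ms, sweep))[2]))
}
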