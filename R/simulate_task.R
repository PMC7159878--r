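#' Simulate a stop-signal session with full ground truth
#'
#' Runs the independent-race generative model trial by trial. On every trial
#' the Go process finishes (reaches the point of no return, i.e. the EMG
#' press-threshold crossing) at an ex-Gaussian time from the Go cue; on stop
#' trials a Stop process starts at the staircased SSD and, when triggered
#' (probability `1 - p_tf`), silences the muscle one conduction time after
#' its ex-Gaussian finish. A keypress occurs iff the crossing precedes both
#' the muscle cancellation and the deadline; the keypress itself lands
#' `ballistic_ms + electromech_ms` after the crossing. EMG drive starts one
#' rise-to-threshold lag before the crossing, so a Stop command arriving in
#' that window truncates a visible burst without a keypress (a partial-EMG
#' trial).
#'
#' Two independent +/-`ssd_step` staircases (left/right directions) track the
#' SSD: up after a Successful Stop, down after a Failed Stop.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list with `trials` (one row per trial: `trial, type, direction,
#'   ssd_ms, rt_ms, rt_emg_ms, outcome`) and `truth` (per-trial ground truth:
#'   go finish, stop finish, trigger flag, muscle cancellation time from the
#'   Stop signal, EMG onset from Go, partial flag, true keypress time).
#' @export
simulate_task <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed %||% config$seed, {
    n <- config$n_trials
    n_stop <- round(n * config$prop_stop)
    is_stop <- logical(n)
    is_stop[sample.int(n, n_stop)] <- TRUE
    direction <- sample(c("left", "right"), n, replace = TRUE)

    r <- config$race
    lag <- rise_lag_ms(config)
    g_ms <- 1000 * rexgauss(n, r$mu_go, r$sigma_go, r$tau_go)      # crossing
    s_ms <- 1000 * rexgauss(n, r$mu_stop, r$sigma_stop, r$tau_stop) # central stop
    triggered <- runif(n) >= r$p_tf

    ssd_now <- c(left = config$ssd_start, right = config$ssd_start)
    ssd <- rep(NA_real_, n)
    outcome <- character(n)
    rt <- rep(NA_real_, n)
    rt_emg <- rep(NA_real_, n)
    cancel <- rep(NA_real_, n)   # ms from Stop signal
    partial <- logical(n)

    press_delay <- config$ballistic_ms + config$electromech_ms
    for (i in seq_len(n)) {
      onset_i <- g_ms[i] - lag
      if (!is_stop[i]) {
        if (g_ms[i] <= config$deadline) {
          outcome[i] <- "CorrectGo"
          rt[i] <- g_ms[i] + press_delay
          rt_emg[i] <- onset_i
        } else {
          outcome[i] <- "GoOmission"
        }
        next
      }
      d <- if (is.null(config$ssd_fixed)) ssd_now[[direction[i]]] else config$ssd_fixed
      ssd[i] <- d
      cancel_abs <- if (triggered[i]) d + s_ms[i] + config$conduction_ms else Inf
      responded <- g_ms[i] < cancel_abs && g_ms[i] <= config$deadline
      if (responded) {
        outcome[i] <- "FailedStop"
        rt[i] <- g_ms[i] + press_delay
        rt_emg[i] <- onset_i
        ssd_now[[direction[i]]] <- max(0, d - config$ssd_step)
      } else {
        if (triggered[i]) cancel[i] <- cancel_abs - d
        partial[i] <- is.finite(cancel_abs) && onset_i < cancel_abs
        if (partial[i]) rt_emg[i] <- onset_i
        outcome[i] <- if (partial[i]) "SuccStop_PartialEMG" else "SuccStop_NoEMG"
        ssd_now[[direction[i]]] <-
          min(config$deadline - config$ssd_step, d + config$ssd_step)
      }
    }

    trials <- data.frame(
      trial = seq_len(n),
      type = ifelse(is_stop, "stop", "go"),
      direction = direction,
      ssd_ms = ssd,
      rt_ms = rt,
      rt_emg_ms = rt_emg,
      outcome = outcome,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      trial = seq_len(n),
      go_finish_ms = g_ms,
      stop_finish_ms = ifelse(is_stop, s_ms, NA_real_),
      triggered = ifelse(is_stop, triggered, NA),
      muscle_cancel_ms = cancel,
      emg_onset_ms = g_ms - lag,
      partial = partial,
      true_keypress_ms = rt,
      stringsAsFactors = FALSE
    )
    list(trials = trials, truth = truth, config = config)
  })
}

#' Outcome bookkeeping for a simulated (or classified) session
#'
#' @param trials a trial table as returned by [simulate_task()].
#' @return named vector of outcome counts plus `p_respond_stop`.
#' @export
outcome_summary <- function(trials) {
  n_stop <- sum(trials$type == "stop")
  counts <- table(factor(trials$outcome,
                         levels = c("CorrectGo", "GoOmission", "FailedStop",
                                    "SuccStop_PartialEMG", "SuccStop_NoEMG")))
  c(as.list(counts),
    list(p_respond_stop = if (n_stop) unname(counts["FailedStop"]) / n_stop
         else NA_real_))
}
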