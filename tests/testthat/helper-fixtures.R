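# Fixtures are built in code. The injected-partial harness constructs stop
# trials with known muscle-cancellation times and renders them through the
# same EMG generator the package ships, so detector output can be compared
# against injected ground truth.

make_injected_partials <- function(n, config = sim_config(),
                                   cancel_mean = 160, cancel_sd = 20,
                                   seed = 1) {
  set.seed(seed)
  cancel <- rnorm(n, cancel_mean, cancel_sd)
  ssd <- sample(seq(150, 350, 50), n, replace = TRUE)
  lag <- rise_lag_ms(config)
  delta <- runif(n, 5, lag)          # truncation lag within the partial window
  onset <- ssd + cancel - delta
  trials <- data.frame(trial = seq_len(n), type = "stop",
                       direction = sample(c("left", "right"), n, TRUE),
                       ssd_ms = ssd, rt_ms = NA_real_, rt_emg_ms = onset,
                       outcome = "SuccStop_PartialEMG",
                       stringsAsFactors = FALSE)
  truth <- data.frame(trial = seq_len(n), go_finish_ms = onset + lag,
                      stop_finish_ms = NA_real_, triggered = TRUE,
                      muscle_cancel_ms = cancel, emg_onset_ms = onset,
                      partial = TRUE, true_keypress_ms = NA_real_)
  list(trials = trials, truth = truth, cancel = cancel, delta = delta)
}

# independent brute-force race: respond iff the go finish beats both the
# (triggered) stop arrival at the muscle and the deadline
brute_force_p_inhibit <- function(params, ssd_s, n = 1e6,
                                  deadline_s = 1, conduction_s = 0) {
  g <- rexgauss(n, params$mu_go, params$sigma_go, params$tau_go)
  s <- rexgauss(n, params$mu_stop, params$sigma_stop, params$tau_stop)
  trig <- runif(n) >= params$p_tf
  cancel <- ifelse(trig, ssd_s + s + conduction_s, Inf)
  mean(!(g < cancel & g <= deadline_s))
}

quiet_classify <- function(sim, ann) {
  classify_trials(sim$trials[, c("trial", "type", "direction", "ssd_ms",
                                 "rt_ms")], ann)
}
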