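test_that("the noiseless envelope of a go burst peaks at exactly the configured amplitude", {
  cfg <- sim_config(n_trials = 4, prop_stop = 0.25, noise_sd_mv = 0,
                    line_amp_mv = 0)
  sim <- simulate_task(cfg, 2)
  go <- which(sim$trials$outcome == "CorrectGo")[1]  # seed 2: trial 2
  expect_false(is.na(go))
  emg <- synthesize_emg(sim$trials, sim$truth, cfg, 2)
  tr <- emg[[go]]
  expect_identical(max(tr$envelope[[tr$active_muscle]]), cfg$emg_peak_mv)
})

test_that("the pre-noise envelope of a partial burst declines at the injected cancellation", {
  cfg <- sim_config()
  inj <- make_injected_partials(6, cfg, cancel_mean = 160, cancel_sd = 0,
                                seed = 4)
  emg <- synthesize_emg(inj$trials, inj$truth, cfg, 4)
  for (i in seq_along(emg)) {
    tr <- emg[[i]]
    env <- tr$envelope[[tr$active_muscle]]
    peak_ms <- (which.max(env) - 1) / tr$fs * 1000
    cancel_abs <- tr$go_ms + inj$trials$ssd_ms[i] + 160
    expect_lt(abs(peak_ms - cancel_abs), 2)
  }
})

test_that("partial-burst amplitude is non-decreasing in SSD by construction", {
  cfg <- sim_config(n_trials = 20000)
  sim <- simulate_task(cfg, 9)
  part <- sim$truth$partial
  lvl <- burst_envelope(sim$trials$ssd_ms[part] + sim$truth$muscle_cancel_ms[part] -
                          sim$truth$emg_onset_ms[part], cfg)
  ssd <- sim$trials$ssd_ms[part]
  qs <- quantile(ssd, c(1/3, 2/3))
  m <- c(mean(lvl[ssd <= qs[1]]),
         mean(lvl[ssd > qs[1] & ssd <= qs[2]]),
         mean(lvl[ssd > qs[2]]))
  expect_true(all(diff(m) >= 0))
})

test_that("keypress trials cross the press threshold and partials stay below it", {
  cfg <- sim_config(n_trials = 300, noise_sd_mv = 0, line_amp_mv = 0)
  sim <- simulate_task(cfg, 12)
  emg <- synthesize_emg(sim$trials, sim$truth, cfg, 12)
  for (i in seq_along(emg)) {
    tr <- emg[[i]]
    pk <- max(tr$envelope[[tr$active_muscle]])
    out <- sim$trials$outcome[i]
    if (out %in% c("CorrectGo", "FailedStop"))
      expect_gte(pk, cfg$press_threshold_mv)
    if (out == "SuccStop_PartialEMG")  # 0.5 ms grid snap tolerance
      expect_lte(pk, cfg$press_threshold_mv + 0.002)
    if (out == "SuccStop_NoEMG")
      expect_equal(pk, 0)
  }
})

test_that("too low a sampling rate for the burst rise is rejected", {
  cfg <- sim_config(n_trials = 10)
  cfg$fs_emg <- 30
  sim <- simulate_task(cfg, 1)
  expect_error(synthesize_emg(sim$trials, sim$truth, cfg, 1), "fs_emg")
})

test_that("identical config and seed give bit-identical EMG", {
  cfg <- sim_config(n_trials = 12)
  sim <- simulate_task(cfg, 5)
  a <- synthesize_emg(sim$trials, sim$truth, cfg, 5)
  b <- synthesize_emg(sim$trials, sim$truth, cfg, 5)
  expect_identical(a, b)
})
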