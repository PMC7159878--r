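fs <- 512
t_ms <- (0:(3 * fs - 1)) / fs * 1000 - 1500

make_eeg <- function(epochs_samples, trials = seq_along(epochs_samples)) {
  list(epochs = lapply(seq_along(epochs_samples), function(i)
    list(trial = trials[i], samples = epochs_samples[[i]], fs = fs,
         t_ms = t_ms)), fs = fs, t_ms = t_ms)
}

test_that("Morlet power localizes pure and mixed tones", {
  x20 <- sin(2 * pi * 20 * t_ms / 1000)
  tf <- morlet_tf(x20, fs)
  ridge <- tf$freqs[apply(tf$power[, 300:1200], 2, which.max)]
  expect_true(all(abs(ridge - 20) <= 1))

  expect_true(all(morlet_tf(numeric(length(t_ms)), fs)$power == 0))

  two <- sin(2 * pi * 10 * t_ms / 1000) + 0.5 * sin(2 * pi * 25 * t_ms / 1000)
  tf2 <- morlet_tf(two, fs)
  mean_pow <- rowMeans(tf2$power[, 300:1200])
  pk10 <- mean_pow[tf2$freqs == 10]
  pk25 <- mean_pow[tf2$freqs == 25]
  expect_gt(pk10, max(mean_pow[abs(tf2$freqs - 10) > 2 &
                                 abs(tf2$freqs - 25) > 2]))
  expect_equal(pk25 / pk10, 0.25, tolerance = 0.03)

  expect_error(morlet_tf(numeric(40), fs), "epoch shorter")
})

test_that("peak-beta selection accepts only a stop-window beta increase", {
  burst <- exp(-(t_ms - 100)^2 / (2 * 60^2)) * sin(2 * pi * 18 * t_ms / 1000)
  tf <- morlet_tf(burst, fs)
  sel <- select_peak_beta(tf, t_ms, ssrt_beh_ms = 214)
  expect_true(sel$accepted)
  expect_equal(sel$peak_beta_freq, 18)

  flat <- sin(2 * pi * 18 * t_ms / 1000)
  sel2 <- select_peak_beta(morlet_tf(flat, fs), t_ms, 214)
  expect_false(sel2$accepted)
  expect_true(is.na(sel2$peak_beta_freq))
})

test_that("an injected burst is found at its time; constant envelopes give none", {
  set.seed(51)
  bg <- lapply(1:40, function(i) rnorm(length(t_ms), 0, 1))
  sig <- bg
  sig[[1]] <- sig[[1]] + 6 * exp(-(t_ms - 120)^2 / (2 * 40^2)) *
    sin(2 * pi * 20 * t_ms / 1000)
  bset <- detect_bursts(make_eeg(sig), 20)
  b1 <- bset$bursts[bset$bursts$trial == 1, ]
  expect_gte(nrow(b1), 1)
  expect_lt(min(abs(b1$burst_time_ms - 120)), 10)

  ## an envelope identically at its median (here: zero) yields no bursts
  silent <- make_eeg(lapply(1:5, function(i) numeric(length(t_ms))))
  expect_equal(nrow(detect_bursts(silent, 20)$bursts), 0)
  ## every reported burst respects its thresholds and landmark ordering
  expect_true(all(bset$bursts$peak_amp > bset$thresholds["detect"]))
  expect_true(all(bset$bursts$onset_ms <= bset$bursts$burst_time_ms &
                    bset$bursts$burst_time_ms <= bset$bursts$offset_ms))
})

test_that("burst percentage is bounded, gain invariant, and threshold-monotone", {
  set.seed(52)
  sig <- lapply(1:20, function(i) rnorm(length(t_ms)))
  eeg <- make_eeg(sig)
  b1 <- detect_bursts(eeg, 20)
  expect_true(all(b1$burst_pct$pct >= 0 & b1$burst_pct$pct <= 1))
  eeg2 <- make_eeg(lapply(sig, function(x) 10 * x))
  b2 <- detect_bursts(eeg2, 20)
  expect_equal(b1$burst_pct$pct, b2$burst_pct$pct)
  expect_equal(nrow(b1$bursts), nrow(b2$bursts))
  b3 <- detect_bursts(eeg, 20, burst_params(thresh_k = 2.5))
  expect_lte(nrow(b3$bursts), nrow(b1$bursts))
})

test_that("surrogate EEG injection-recovery meets recall and timing at default SNR", {
  cfg <- sim_config(n_trials = 500)
  sim <- simulate_task(cfg, 53)
  eeg <- synthesize_eeg_beta(sim$trials, sim$truth, cfg, 53)
  bset <- detect_bursts(eeg, cfg$beta_freq)
  inj <- eeg$injected[!is.na(eeg$injected$burst_ms), ]
  err <- vapply(seq_len(nrow(inj)), function(k) {
    b <- bset$bursts[bset$bursts$trial == inj$trial[k], ]
    if (!nrow(b)) return(NA_real_)
    min(abs(b$burst_time_ms - inj$burst_ms[k]))
  }, numeric(1))
  expect_gte(mean(!is.na(err) & err <= 10), 0.9)
  ws <- burst_window_stats(bset, sim$trials, ssrt_beh_ms = 214,
                          mean_ssd_ms = mean(sim$trials$ssd_ms, na.rm = TRUE))
  true_bt <- mean(inj$burst_ms)
  expect_lt(abs(ws$mean_bursttime_ms - true_bt), 15)
})

test_that("EEG pass-through downsamples, notches and re-references; spatial filter projects", {
  fs <- 1024
  t <- (0:(4 * fs - 1)) / fs
  ch1 <- sin(2 * pi * 20 * t) + sin(2 * pi * 60 * t)
  ch2 <- -sin(2 * pi * 20 * t) + sin(2 * pi * 60 * t)
  out <- eeg_preprocess(rbind(ch1, ch2), fs, fs_out = 512)
  expect_equal(out$fs, 512)
  expect_equal(ncol(out$x), 2 * fs)
  ## common-mode 60 Hz removed by both the notch and the average reference
  spec <- Mod(fft(out$x[1, 500:1500]))
  f_axis <- (seq_along(spec) - 1) * 512 / length(spec)
  p60 <- max(spec[abs(f_axis - 60) < 2])
  p20 <- max(spec[abs(f_axis - 20) < 2])
  expect_lt(p60 / p20, 0.02)

  w <- c(0.5, -0.5)
  proj <- apply_spatial_filter(out$x, w)
  expect_length(proj, ncol(out$x))
  td <- t[seq(1, length(t), by = 2)]            # decimated time axis
  expect_gt(cor(proj[500:1500], sin(2 * pi * 20 * td)[500:1500])^2, 0.9)
})

test_that("bursts leading the Stop signal are clipped and flagged", {
  cfg <- sim_config(n_trials = 600, beta_lead_ms = 400)
  sim <- simulate_task(cfg, 54)
  eeg <- synthesize_eeg_beta(sim$trials, sim$truth, cfg, 54)
  inj <- eeg$injected[!is.na(eeg$injected$burst_ms), ]
  expect_gt(sum(inj$clipped), 0)
  expect_true(all(inj$burst_ms[inj$clipped] == 0))
})
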