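fs <- 2000
ms <- function(idx) (idx - 1) / fs * 1000

test_that("burst detection finds an injected peak and ignores stationary noise", {
  set.seed(21)
  n <- 4000
  noise <- abs(rnorm(n, 0, 0.01))
  burst <- 0.2 * exp(-((seq_len(n) - 1) / fs * 1000 - 800)^2 / (2 * 30^2))
  det <- detect_burst(noise + burst, fs, baseline_ms = c(0, 500))
  main <- det$bursts[det$bursts$is_main, ]
  expect_equal(nrow(main), 1)
  expect_lt(abs(main$peak_ms - 800), 5)

  det0 <- detect_burst(noise, fs, baseline_ms = c(0, 500))
  expect_equal(nrow(det0$bursts), 0)
})

test_that("a zero-variance baseline falls back to a flagged epsilon threshold", {
  x <- c(rep(0.1, 1000), rep(0.5, 1000))
  det <- detect_burst(x, fs, baseline_ms = c(0, 500))
  expect_true(det$degenerate_baseline)
  expect_equal(nrow(det$bursts), 1)
})

test_that("onset on a triangular rise sits at the 20% crossing", {
  ## linear rise 0 -> 1 over 100 ms starting at 500 ms, preceded by zeros
  t <- ms(seq_len(2000))
  x <- pmax(pmin((t - 500) / 100, 1), 0)
  peak <- which.max(x)
  on <- find_onset(x, fs, peak)
  expect_false(on$flag_epoch_start)
  expect_lt(abs(ms(on$onset_idx) - 520), 1)   # 20 ms after the true start
})

test_that("onset on a step function lands at the step within one sample", {
  x <- c(numeric(1000), rep(1, 1000))
  on <- find_onset(x, fs, 1500)
  expect_lt(abs(ms(on$onset_idx) - ms(1000)), 1000 / fs + 1e-9)
})

test_that("onset is pinned to epoch start and flagged when never below criterion", {
  x <- rep(1, 500)
  on <- find_onset(x, fs, 400)
  expect_true(on$flag_epoch_start)
  expect_equal(on$onset_idx, 1L)
})

test_that("decline of a symmetric triangle is at its apex", {
  x <- c(seq(0, 1, length.out = 200), seq(1, 0, length.out = 200)[-1])
  peak <- which.max(x)
  de <- find_decline(x, fs, peak)
  expect_equal(de$decline_idx, peak)
})

test_that("a plateau delays the decline to the start of the decay", {
  x <- c(seq(0, 1, length.out = 200), rep(1, 100), seq(1, 0, length.out = 200))
  de <- find_decline(x, fs, 200)
  expect_equal(de$decline_idx, 301L)
  expect_true(is.na(find_decline(rep(1, 300), fs, 100)$decline_idx))
})

test_that("landmark ordering onset <= peak <= decline <= offset holds on synthetic trials", {
  cfg <- sim_config(n_trials = 60)
  sim <- simulate_task(cfg, 13)
  emg <- synthesize_emg(sim$trials, sim$truth, cfg, 13)
  ann <- annotate_emg(emg, sim$trials)
  ann <- ann[ann$burst_detected, ]
  expect_gt(nrow(ann), 0)
  expect_true(all(ann$onset_ms <= ann$peak_ms))
  ok <- !is.na(ann$decline_ms)
  expect_true(all(ann$peak_ms[ok] <= ann$decline_ms[ok]))
  ok2 <- ok & !is.na(ann$offset_ms)
  expect_true(all(ann$decline_ms[ok2] <= ann$offset_ms[ok2] + 1e-9))
})
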