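test_that("CancelTimes below the 50 ms floor are flagged as outliers", {
  ann <- data.frame(trial = 1:5, muscle = "FDI", burst_detected = TRUE,
                    onset_ms = 700, peak_ms = 750, peak_amp_mv = 0.5,
                    decline_ms = c(740, 860, 880, 900, 870), offset_ms = 950,
                    threshold = 0.02, flag_degenerate_baseline = FALSE,
                    flag_onset_at_epoch_start = FALSE)
  trials <- data.frame(trial = 1:5, type = "stop", ssd_ms = 200,
                       rt_ms = NA_real_, outcome = "SuccStop_PartialEMG")
  ct <- compute_canceltimes(ann, trials, go_ms = 500)
  ## decline 740 -> CancelTime 40 ms, below the floor
  expect_true(ct$outlier[ct$trial == 1])
  expect_equal(ct$outlier_reason[ct$trial == 1], "below_floor")
  expect_false(any(ct$outlier[ct$trial != 1]))
})

test_that("the upper IQR cutoff flags extreme CancelTimes, and is skipped below 3 trials", {
  set.seed(41)
  base <- data.frame(trial = 1:12, muscle = "FDI", burst_detected = TRUE,
                     onset_ms = 700, peak_ms = 750, peak_amp_mv = 0.5,
                     decline_ms = 500 + 200 + c(rnorm(11, 150, 8), 400),
                     offset_ms = 950, threshold = 0.02,
                     flag_degenerate_baseline = FALSE,
                     flag_onset_at_epoch_start = FALSE)
  trials <- data.frame(trial = 1:12, type = "stop", ssd_ms = 200,
                       rt_ms = NA_real_, outcome = "SuccStop_PartialEMG")
  ct <- compute_canceltimes(base, trials, go_ms = 500)
  expect_true(ct$outlier[12])
  expect_equal(ct$outlier_reason[12], "above_iqr")

  few <- compute_canceltimes(base[1:2, ], trials[1:2, ], go_ms = 500)
  expect_true(attr(few, "iqr_rule_skipped"))
})

test_that("recovered CancelTimes track injected cancellations without bias", {
  cfg <- sim_config()
  inj <- make_injected_partials(150, cfg, seed = 31)
  emg <- synthesize_emg(inj$trials, inj$truth, cfg, 32)
  ann <- annotate_emg(emg, inj$trials)
  ct <- compute_canceltimes(ann, inj$trials)
  err <- ct$canceltime_ms - inj$cancel[match(ct$trial, inj$trials$trial)]
  kept <- !ct$outlier
  expect_gt(nrow(ct), 120)
  expect_lte(median(abs(err[kept])), 10)
  expect_lte(abs(mean(err[kept])), 5)
  expect_lt(mean(ct$outlier), 0.05)
})

test_that("the generic two-sided IQR rule flags both tails", {
  set.seed(42)
  x <- c(rnorm(50, 100, 5), 20, 300)
  fl <- iqr_outliers(x)
  expect_true(fl[51] && fl[52])
  expect_lt(mean(fl[1:50]), 0.1)
})
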