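mk_meps <- function(n, seed = 1, contam = 0.05, factor = 0.6, onset = 140) {
  cfg <- sim_config(n_trials = n, mep_contam_rate = contam,
                    mep_suppression_factor = factor,
                    mep_suppression_onset_ms = onset)
  sim <- simulate_task(cfg, seed)
  list(mep = synthesize_mep(sim$trials, sim$truth, cfg, seed + 1), sim = sim,
       cfg = cfg)
}

test_that("QC excludes contaminated pre-TMS EMG and passes group-mean amplitudes", {
  set.seed(60)
  amps <- rlnorm(40, log(0.4), 0.3)
  m <- data.frame(trial = 1:42, trial_type = "CorrectGo", tms_label = "140",
                  tms_ms = 140, amplitude_mv = c(amps, mean(amps), 5),
                  pre_tms_emg_mv = c(0.10, rep(0.01, 41)))
  qc <- qc_filter(m)
  expect_false(qc$qc_pass[1])
  expect_equal(qc$qc_reason[1], "pre_tms_emg")
  expect_false(qc$qc_pass[42])         # amplitude far outside mean +/- 1.5 IQR
  expect_true(qc$qc_pass[41])          # a trial at the group mean always passes

  small <- qc_filter(m[1:3, ])
  expect_gt(length(attr(small, "iqr_skipped_cells")), 0)
})

test_that("QC exclusion tracks the injected contamination rate", {
  res <- mk_meps(4000, seed = 61)
  qc <- qc_filter(res$mep)
  rule1 <- qc$qc_reason == "pre_tms_emg"
  expect_lt(abs(mean(rule1) - 0.05), 0.012)
  expect_true(all(rule1[res$mep$contaminated]))
})

test_that("ITI normalization maps the baseline to 100% and is idempotent", {
  m <- data.frame(trial = 1:6, trial_type = "CorrectGo",
                  tms_label = c("ITI", "ITI", "100", "120", "140", "160"),
                  tms_ms = c(NA, NA, 100, 120, 140, 160),
                  amplitude_mv = c(0.5, 0.5, 0.25, 0.5, 1.0, 0.5),
                  pre_tms_emg_mv = 0.01)
  nm <- normalize_to_iti(qc_filter(m, min_group = 10))
  expect_equal(nm$amplitude_pct[3], 50)
  expect_equal(mean(nm$amplitude_pct[nm$tms_label == "ITI"]), 100)
  again <- nm
  again$amplitude_mv <- nm$amplitude_pct
  expect_equal(normalize_to_iti(again)$amplitude_pct, nm$amplitude_pct)
})

test_that("a null generator shows no suppression; the default shows it from onset", {
  null <- mk_meps(12000, seed = 62, factor = 1)
  nm0 <- normalize_to_iti(qc_filter(null$mep))
  tp0 <- mep_timepoint_means(nm0)
  expect_true(all(abs(tp0$mean_pct - 100) < 12))

  sup <- mk_meps(12000, seed = 63)
  nm1 <- normalize_to_iti(qc_filter(sup$mep))
  tp1 <- mep_timepoint_means(nm1)
  ss <- tp1[tp1$trial_type == "SuccStop", ]
  expect_true(all(abs(ss$mean_pct[ss$tms_ms < 140] - 100) < 12))
  expect_true(all(abs(ss$mean_pct[ss$tms_ms >= 140] - 60) < 12))
  other <- tp1[tp1$trial_type != "SuccStop", ]
  expect_true(all(abs(other$mean_pct - 100) < 12))
})

test_that("CancelTime-relative binning is half-open, conservative, and thresholded", {
  m <- data.frame(trial = 1:3, trial_type = "SuccStop", tms_label = "140",
                  tms_ms = 140, amplitude_mv = 0.4, pre_tms_emg_mv = 0.01,
                  qc_pass = TRUE, amplitude_pct = 100)
  decl <- c(160, 140, 111)     # relative: -20, 0, +29
  bins <- bin_relative_to_canceltime(m, decl, min_trials = 1)
  expect_equal(sort(bins$bin_lo_ms), c(-30, 0))
  expect_equal(bins$n[bins$bin_lo_ms == 0], 2)    # 0 and +29 share [0, 30)
  expect_equal(sum(bins$n), 3)

  none <- bin_relative_to_canceltime(m, decl, min_trials = 50)
  expect_equal(nrow(none), 0)
})

test_that("conduction time is the earliest automated MEP onset", {
  wf <- synthesize_mep_waveforms(10, onset_ms = 23, jitter_ms = 2, seed = 65)
  res <- conduction_time(wf)
  expect_lt(abs(res$conduction_ms - min(wf$true_onsets_ms)), 0.5)

  one <- synthesize_mep_waveforms(1, onset_ms = 20, jitter_ms = 0, seed = 66)
  expect_lte(abs(conduction_time(one)$conduction_ms - 20), 0.5)  # one sample

  inj <- synthesize_mep_waveforms(3, onset_ms = 23.1, jitter_ms = 0, seed = 67)
  inj$traces <- inj$traces[c(1, 2, 3)]
  expect_lt(abs(conduction_time(inj)$conduction_ms - 23.1), 0.5)

  set.seed(68)
  silent <- list(traces = list(rnorm(160, 0, 0.01)),
                 t_ms = seq(-20, 59.5, 0.5), fs = 2000)
  expect_true(is.na(conduction_time(silent)$conduction_ms))
})
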