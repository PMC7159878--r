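test_that("normalized profiles are scale invariant across muscles", {
  fs <- 2000
  shape <- exp(-((seq_len(2000) - 1000)^2) / (2 * 100^2))
  mk <- function(trial, dir, peak) {
    env <- setNames(list(numeric(2000), numeric(2000)),
                    if (dir == "left") c("FDI", "ADM") else c("ADM", "FDI"))
    active <- if (dir == "left") "FDI" else "ADM"
    env[[active]] <- peak * shape
    list(trial = trial, fs = fs, t0_ms = 0, go_ms = 500,
         muscles = env, envelope = env, active_muscle = active)
  }
  emg <- structure(list(mk(1, "left", 1), mk(2, "right", 0.1)),
                   class = "emg_set")
  trials <- data.frame(trial = 1:2, type = "go", direction = c("left", "right"),
                       ssd_ms = NA, rt_ms = 600,
                       outcome = c("CorrectGo", "CorrectGo"))
  ## identical shapes, 10x different gains: normalized profiles coincide
  prof <- normalize_profiles(emg, trials, align_ms = c(500, 500),
                             rms_list = list(shape, 0.1 * shape))
  dat <- prof$profiles
  a <- dat$mean[dat$type == "CorrectGo"]
  expect_true(all(a >= 0 & a <= 1))
  ## per-trial normalized values are equal, so the sd across trials is 0
  prof_each <- normalize_profiles(emg[1], trials[1, ], align_ms = 500,
                                  rms_list = list(shape))
  expect_equal(max(prof$profiles$mean), max(prof_each$profiles$mean),
               tolerance = 1e-10)
})

test_that("profile divergence is located where sustained separation begins", {
  t_ms <- seq(0, 200, by = 0.5)
  a <- rep(0.5, length(t_ms))
  b <- ifelse(t_ms < 50, 0.5, 0.7)
  expect_equal(profile_divergence(a, b, t_ms, criterion = 0.05), 50)
  expect_true(is.na(profile_divergence(a, a, t_ms)))
  ## a blip shorter than the hold window does not count
  c2 <- a; c2[t_ms >= 80 & t_ms < 82] <- 0.9
  expect_true(is.na(profile_divergence(a, c2, t_ms, criterion = 0.05,
                                       hold_ms = 5)))
})

test_that("partial amplitude grows with SSD in binned means; empty bins stay NA", {
  cfg <- sim_config(n_trials = 1200)
  sim <- simulate_task(cfg, 17)
  emg <- synthesize_emg(sim$trials, sim$truth, cfg, 17)
  ann <- annotate_emg(emg, sim$trials)
  out <- amplitude_by_ssd(ann, sim$trials, n_bins = 3)
  got <- out$mean_amp[!is.na(out$mean_amp)]
  expect_gt(length(got), 1)
  expect_gt(tail(got, 1), head(got, 1))

  one <- ann[sim$trials$outcome[match(ann$trial, sim$trials$trial)] ==
               "SuccStop_PartialEMG" & ann$burst_detected, ][1, ]
  res1 <- amplitude_by_ssd(one, sim$trials, n_bins = 5)
  expect_equal(sum(res1$n > 0), 1)
})
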