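test_that("integration-method SSRT matches hand-computed cases", {
  expect_equal(ssrt_integration(rep(400, 20), 0.5, 200), 200)
  ## ordered RTs {300,400,500,600}, n = ceil(0.5*4) = 2 -> 400; 400-150 = 250
  expect_equal(ssrt_integration(c(500, 300, 600, 400), 0.5, 150), 250)
  ## omissions are replaced by the maximum RT before ranking
  expect_equal(ssrt_integration(c(300, 400, NA, 500), 0.75, 100),
               ssrt_integration(c(300, 400, 500, 500), 0.75, 100))
  expect_warning(out <- ssrt_integration(c(300, 400), 1, 100))
  expect_true(is.na(out))
})

test_that("SSRT is translation equivariant", {
  set.seed(3)
  rts <- rnorm(200, 450, 60)
  s1 <- ssrt_integration(rts, 0.47, 230)
  s2 <- ssrt_integration(rts + 75, 0.47, 230 + 75)
  expect_equal(s1, s2)
})

test_that("per-SSD EMG SSRT reduces to the integration method at one SSD", {
  set.seed(4)
  onsets <- rnorm(120, 350, 50)
  trials <- data.frame(
    trial = 1:160, type = c(rep("go", 120), rep("stop", 40)),
    ssd_ms = c(rep(NA, 120), rep(200, 40)),
    rt_ms = NA_real_,
    rt_emg_ms = c(onsets, rep(NA, 40)),
    outcome = c(rep("CorrectGo", 120),
                rep(c("FailedStop", "SuccStop_NoEMG"), each = 20)))
  res <- ssrt_emg(trials)
  expect_equal(res$ssrt_emg_ms, ssrt_integration(onsets, 0.5, 200))
  expect_equal(sum(res$per_ssd$used), 1)
})

test_that("degenerate SSD levels are skipped and logged", {
  trials <- data.frame(
    trial = 1:30, type = c(rep("go", 10), rep("stop", 20)),
    ssd_ms = c(rep(NA, 10), rep(c(100, 300), each = 10)),
    rt_ms = NA_real_,
    rt_emg_ms = c(rnorm(10, 350, 40), rep(NA, 20)),
    outcome = c(rep("CorrectGo", 10), rep("SuccStop_NoEMG", 10),
                rep("FailedStop", 10)))
  res <- ssrt_emg(trials)
  expect_true(all(!res$per_ssd$used))
  expect_true(is.na(res$ssrt_emg_ms))
})

test_that("behavioral SSRT recovers the stopping latency of a simulated race", {
  ## zero ballistic/device delay and zero conduction: SSRT_Beh should sit at
  ## the mean central stop latency (137 ms for the default parameters)
  cfg <- sim_config(n_trials = 40000, ballistic_ms = 0, electromech_ms = 0,
                    conduction_ms = 0)
  sim <- simulate_task(cfg, 19)
  bs <- behavior_summary(sim$trials)
  true_s <- 1000 * (cfg$race$mu_stop + cfg$race$tau_stop)
  expect_lt(abs(bs$ssrt_beh_ms - true_s), 10)
  expect_lt(abs(bs$ssrt_beh_ms - bs$ssrt_emg_ms), 5)
})

test_that("trial classification conserves counts and flags anomalies", {
  trials <- data.frame(trial = 1:4, type = c("go", "go", "stop", "stop"),
                       ssd_ms = c(NA, NA, 200, 250),
                       rt_ms = c(450, NA, 400, NA))
  ann <- data.frame(trial = 1:4, burst_detected = c(TRUE, FALSE, FALSE, TRUE),
                    onset_ms = c(850, NA, NA, 880))
  cl <- classify_trials(trials, ann, go_ms = 500)
  expect_equal(cl$outcome,
               c("CorrectGo", "GoOmission", "FailedStop",
                 "SuccStop_PartialEMG"))
  expect_true(cl$anomaly[3])          # keypress without a detected burst
  expect_equal(cl$rt_emg_ms[4], 380)
})
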