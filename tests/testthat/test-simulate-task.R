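test_that("a degenerate instant stop wins every stop trial with no EMG", {
  cfg <- sim_config(n_trials = 400, ssd_fixed = 0, conduction_ms = 0,
                    race = race_params(mu_stop = 1e-9, sigma_stop = 1e-7,
                                       tau_stop = 1e-9, p_tf = 0))
  sim <- simulate_task(cfg, 1)
  st <- sim$trials[sim$trials$type == "stop", ]
  expect_true(all(st$outcome == "SuccStop_NoEMG"))
  expect_true(all(is.na(st$rt_ms)))
})

test_that("with certain trigger failure, stopping is independent of SSD", {
  p_at_ssd <- vapply(c(0, 300), function(d) {
    cfg <- sim_config(n_trials = 4000, ssd_fixed = d,
                      race = race_params(p_tf = 1))
    sim <- simulate_task(cfg, 2)
    unlist(outcome_summary(sim$trials)["p_respond_stop"])
  }, numeric(1))
  expected <- pexgauss(1, 0.340, 0.050, 0.083)   # P(go finish <= deadline)
  expect_equal(p_at_ssd[1], p_at_ssd[2], tolerance = 0.05)
  expect_equal(unname(p_at_ssd[1]), expected, tolerance = 0.03)
})

test_that("the SSD staircase settles at ~50% responding on stop trials", {
  cfg <- sim_config(n_trials = 20000)
  sim <- simulate_task(cfg, 3)
  p <- unlist(outcome_summary(sim$trials)["p_respond_stop"])
  expect_equal(unname(p), 0.5, tolerance = 0.02)
})

test_that("trial counts are conserved and outputs are reproducible", {
  cfg <- sim_config(n_trials = 500)
  a <- simulate_task(cfg, 7)
  b <- simulate_task(cfg, 7)
  expect_identical(a, b)
  cnt <- outcome_summary(a$trials)
  expect_equal(cnt$CorrectGo + cnt$GoOmission,
               sum(a$trials$type == "go"))
  expect_equal(cnt$FailedStop + cnt$SuccStop_PartialEMG + cnt$SuccStop_NoEMG,
               sum(a$trials$type == "stop"))
})

test_that("empirical stop-trial outcome matches the analytic race probability", {
  p <- race_params()
  cfg <- sim_config(n_trials = 60000, ssd_fixed = 250, conduction_ms = 0)
  sim <- simulate_task(cfg, 5)
  st <- sim$trials[sim$trials$type == "stop", ]
  emp <- mean(st$outcome != "FailedStop")
  ana <- p_inhibit(0.250, p, deadline_s = 1)
  se <- sqrt(ana * (1 - ana) / nrow(st))
  expect_lt(abs(emp - ana), 4 * se + 0.002)
})

test_that("non-finite race parameters are rejected with the field named", {
  expect_error(race_params(tau_stop = NaN), "tau_stop")
})
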