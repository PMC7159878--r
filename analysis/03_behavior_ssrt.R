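#!/usr/bin/env Rscript
# Behavioral analysis: trial classification against the detected EMG bursts,
# SSRT by the integration method (keypresses), per-SSD SSRT from EMG onsets,
# partial-EMG proportion, and a Weibull inhibition-function fit for both
# response definitions.

library(stopcascade)

files <- sort(list.files("results/trials", full.names = TRUE))
ann <- read.csv("results/emg_annotations.csv")

summ <- weib <- NULL
for (p in seq_along(files)) {
  trials <- read_trial_table(files[p])
  cl <- classify_trials(trials[, c("trial", "type", "direction", "ssd_ms",
                                   "rt_ms")],
                        ann[ann$participant == p, ])
  bs <- behavior_summary(cl)
  bs$participant <- p
  summ <- rbind(summ, bs)

  st <- cl[cl$type == "stop", ]
  tab <- aggregate(cbind(resp = outcome == "FailedStop",
                         resp_emg = outcome %in% c("FailedStop",
                                                   "SuccStop_PartialEMG")) ~
                     ssd_ms, st, mean)
  n_tab <- aggregate(trial ~ ssd_ms, st, length)
  if (nrow(tab) >= 4) {
    for (kind in c("resp", "resp_emg")) {
      fit <- fit_weibull(tab$ssd_ms, tab[[kind]], weights = n_tab$trial)
      if (fit$converged)
        weib <- rbind(weib, data.frame(participant = p, response = kind,
                                       alpha = fit$alpha, beta = fit$beta,
                                       gamma = fit$gamma, delta = fit$delta))
    }
  }
}

write.csv(summ, "results/behavior_summary.csv", row.names = FALSE)
if (!is.null(weib))
  write.csv(weib, "results/weibull_fits.csv", row.names = FALSE)

message(sprintf("mean SSRT_Beh %.0f ms, mean SSRT_EMG %.0f ms, gap %.0f ms",
                mean(summ$ssrt_beh_ms), mean(summ$ssrt_emg_ms),
                mean(summ$ssrt_beh_ms - summ$ssrt_emg_ms)))
message(sprintf("partial-EMG fraction of successful stops: %.0f%%",
                100 * mean(summ$p_partial)))
message("wrote results/behavior_summary.csv, results/weibull_fits.csv")
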