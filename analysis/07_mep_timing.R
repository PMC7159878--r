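#!/usr/bin/env Rscript
# MEP suppression chronometry: QC (pre-TMS EMG and amplitude-IQR rules),
# ITI normalization, per-time-point means by trial type, the trial-by-trial
# binning of MEP amplitude relative to the single-trial EMG decline, and the
# corticospinal conduction time from synthetic MEP waveforms.

library(stopcascade)

seed <- 20260907
cfg <- sim_config(n_trials = 600)
files <- sort(list.files("results/trials", full.names = TRUE))
truth <- read.csv("results/ground_truth.csv")
ann <- read.csv("results/emg_annotations.csv")

tp_all <- rel_all <- NULL
for (p in seq_along(files)) {
  trials <- read_trial_table(files[p])
  tru_p <- truth[truth$participant == p, ]
  mep <- synthesize_mep(trials, tru_p, cfg, seed + p)
  nm <- normalize_to_iti(qc_filter(mep))
  tp <- mep_timepoint_means(nm)
  tp$participant <- p
  tp_all <- rbind(tp_all, tp)

  ## TMS time relative to the detected EMG decline, per trial
  ann_p <- ann[ann$participant == p, ]
  decline <- ann_p$decline_ms[match(nm$trial, ann_p$trial)] - cfg$fix_ms -
    trials$ssd_ms[match(nm$trial, trials$trial)]   # ms post-Stop
  nm$participant <- p
  nm$decline_post_stop_ms <- decline
  rel_all <- rbind(rel_all, nm)
}

tp_mean <- aggregate(mean_pct ~ trial_type + tms_ms, tp_all, mean)
write.csv(tp_mean, "results/mep_timepoint_means.csv", row.names = FALSE)
message("MEP amplitude (% of ITI baseline) by time point:")
for (tt in unique(tp_mean$trial_type)) {
  r <- tp_mean[tp_mean$trial_type == tt, ]
  message(sprintf("  %-10s %s", tt,
                  paste(sprintf("%d:%.0f%%", r$tms_ms, r$mean_pct),
                        collapse = "  ")))
}

bins <- bin_relative_to_canceltime(rel_all, rel_all$decline_post_stop_ms,
                                   min_trials = 50)
write.csv(bins, "results/mep_canceltime_bins.csv", row.names = FALSE)
message("pooled MEP amplitude by time relative to the EMG decline:")
print(bins)

wf <- synthesize_mep_waveforms(10, onset_ms = 23, jitter_ms = 2, seed = seed)
ctm <- conduction_time(wf)
message(sprintf("corticospinal conduction time: %.1f ms", ctm$conduction_ms))
write.csv(data.frame(conduction_ms = ctm$conduction_ms,
                     onsets_ms = ctm$onsets_ms),
          "results/conduction_time.csv", row.names = FALSE)
message("wrote results/mep_timepoint_means.csv, results/mep_canceltime_bins.csv, results/conduction_time.csv")
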