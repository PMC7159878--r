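#!/usr/bin/env Rscript
# Does frontal beta-burst timing predict muscle cancellation across
# participants? Correlates mean BurstTime with mean CancelTime and tests the
# correlation against a window-limited null (BurstTimes uniform on
# (0, SSRT_Beh), 3000 iterations).

library(stopcascade)

ct <- read.csv("results/canceltimes.csv")
bt <- read.csv("results/beta_bursttimes.csv")
summ <- read.csv("results/behavior_summary.csv")

ct_mean <- aggregate(canceltime_ms ~ participant, ct[!ct$outlier, ], mean)
dat <- merge(merge(ct_mean, bt, by = "participant"),
             summ[, c("participant", "ssrt_beh_ms")], by = "participant")
dat <- dat[complete.cases(dat), ]
message(sprintf("%d participants with both measures", nrow(dat)))

r_pearson <- correlate(dat$canceltime_ms, dat$mean_bursttime_ms)
rho <- correlate(dat$canceltime_ms, dat$mean_bursttime_ms, "spearman")
message(sprintf("BurstTime vs CancelTime: r = %.2f, rho = %.2f",
                r_pearson, rho))
message(sprintf("mean BurstTime %.0f ms precedes mean CancelTime %.0f ms",
                mean(dat$mean_bursttime_ms), mean(dat$canceltime_ms)))

res <- permutation_corr_test(dat$canceltime_ms, dat$mean_bursttime_ms,
                             dat$ssrt_beh_ms,
                             burst_counts = pmax(dat$n_stopwin_bursts, 1),
                             n_iter = 3000, seed = 20260908)
message(sprintf("permutation test: r_obs = %.2f, p = %.4f (%d iterations)",
                res$r_obs, res$p, res$n_iter))

out <- data.frame(r_obs = res$r_obs, rho = rho, p_perm = res$p,
                  n_participants = nrow(dat), n_iter = res$n_iter)
write.csv(out, "results/bursttime_canceltime_test.csv", row.names = FALSE)
message("wrote results/bursttime_canceltime_test.csv")
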