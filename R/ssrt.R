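#' Classify trials from keypresses and EMG annotations
#'
#' Labels every trial from the behavioral record joined with the burst
#' annotations: Correct Go / Go omission on go trials, Failed Stop on stop
#' trials with a keypress, and Successful Stop split into Partial-EMG
#' (detected burst, no keypress) and No-EMG. Stop trials with a keypress but
#' no detected burst are labeled Failed Stop and flagged as anomalies
#' (possible detection miss). EMG onset times are carried over as `rt_emg_ms`
#' (relative to the Go cue).
#'
#' @param trials data frame with `trial, type, ssd_ms, rt_ms`.
#' @param annotations output of [annotate_emg()] (may cover a subset).
#' @param go_ms time of the Go cue within the EMG epoch (ms).
#' @return the trial table with `outcome`, `rt_emg_ms` and `anomaly` columns;
#'   trial counts are conserved.
#' @export
classify_trials <- function(trials, annotations, go_ms = 500) {
  ann <- annotations[match(trials$trial, annotations$trial), , drop = FALSE]
  burst <- !is.na(ann$burst_detected) & ann$burst_detected
  pressed <- !is.na(trials$rt_ms)
  out <- trials
  out$rt_emg_ms <- ifelse(burst, ann$onset_ms - go_ms, NA_real_)
  out$outcome <- ifelse(out$type == "go",
                        ifelse(pressed, "CorrectGo", "GoOmission"),
                        ifelse(pressed, "FailedStop",
                               ifelse(burst, "SuccStop_PartialEMG",
                                      "SuccStop_NoEMG")))
  out$anomaly <- out$type == "stop" & pressed & !burst
  out
}

#' SSRT by the integration method
#'
#' The stop-signal reaction time is the `p_respond` quantile of the go RT
#' distribution minus the mean SSD. The quantile is the nth ordered go RT
#' with `n = ceiling(p_respond * N)`; go omissions are replaced by the
#' maximum observed RT before ranking (consensus practice for the
#' integration method).
#'
#' @param go_rts go-trial RTs in ms; `NA` marks omissions.
#' @param p_respond probability of responding on stop trials, in (0, 1).
#' @param mean_ssd mean stop-signal delay (ms).
#' @return SSRT in ms, or `NA` (with a warning) if `p_respond` is degenerate.
#' @export
ssrt_integration <- function(go_rts, p_respond, mean_ssd) {
  if (!is.finite(p_respond) || p_respond <= 0 || p_respond >= 1) {
    warning("p_respond outside (0, 1); SSRT undefined")
    return(NA_real_)
  }
  if (!length(go_rts)) stop("no go RTs supplied")
  rts <- go_rts
  rts[is.na(rts)] <- max(rts, na.rm = TRUE)
  rts <- sort(rts)
  n <- ceiling(p_respond * length(rts))
  rts[n] - mean_ssd
}

#' EMG-based SSRT, estimated per SSD and averaged
#'
#' Recodes partial-EMG trials as responded and uses EMG onsets on Correct Go
#' trials as the finishing-time distribution. Because the EMG response
#' probability is typically well above 0.5, the integration method is
#' applied separately at every SSD with at least `min_per_ssd` stop trials
#' and a non-degenerate response probability, and the per-SSD estimates are
#' averaged without weighting.
#'
#' @param trials classified trial table (from [classify_trials()] or
#'   [simulate_task()]) with `rt_emg_ms` and `outcome`.
#' @param min_per_ssd minimum stop-trial count for an SSD level to be used.
#' @return list with `ssrt_emg_ms`, and `per_ssd`: data frame
#'   `ssd_ms, n, p_respond_emg, ssrt_ms, used` (skipped levels logged with
#'   `used = FALSE`).
#' @export
ssrt_emg <- function(trials, min_per_ssd = 5) {
  go_on <- trials$rt_emg_ms[trials$outcome == "CorrectGo" &
                              !is.na(trials$rt_emg_ms)]
  if (!length(go_on)) stop("no Correct Go trials with EMG onsets")
  st <- trials[trials$type == "stop", , drop = FALSE]
  emg_resp <- st$outcome %in% c("FailedStop", "SuccStop_PartialEMG")
  per <- aggregate(emg_resp, by = list(ssd_ms = st$ssd_ms),
                   FUN = function(v) c(n = length(v), p = mean(v)))
  per <- data.frame(ssd_ms = per$ssd_ms, n = per$x[, "n"], p = per$x[, "p"])
  per$used <- per$n >= min_per_ssd & per$p > 0 & per$p < 1
  per$ssrt_ms <- NA_real_
  for (k in which(per$used)) {
    srt <- sort(go_on)
    per$ssrt_ms[k] <- srt[ceiling(per$p[k] * length(srt))] - per$ssd_ms[k]
  }
  names(per)[names(per) == "p"] <- "p_respond_emg"
  list(ssrt_emg_ms = if (any(per$used)) mean(per$ssrt_ms[per$used]) else NA_real_,
       per_ssd = per)
}

#' Behavioral summary of one participant/session
#'
#' Convenience wrapper: P(respond|stop), mean SSD, SSRT by the integration
#' method (behavioral), per-SSD EMG SSRT, and partial-EMG fraction.
#'
#' @param trials classified trial table.
#' @param min_per_ssd minimum stop-trial count per SSD level, passed to
#'   [ssrt_emg()]; raise it for large simulated sessions.
#' @return one-row data frame.
#' @export
behavior_summary <- function(trials, min_per_ssd = 5) {
  st <- trials[trials$type == "stop", , drop = FALSE]
  p_resp <- mean(st$outcome == "FailedStop")
  go_rt <- ifelse(trials$outcome == "GoOmission", NA_real_, trials$rt_ms)
  go_rt <- go_rt[trials$type == "go"]
  ssrt_b <- ssrt_integration(go_rt, p_resp, mean(st$ssd_ms))
  se <- ssrt_emg(trials, min_per_ssd)
  n_succ <- sum(st$outcome %in% c("SuccStop_PartialEMG", "SuccStop_NoEMG"))
  data.frame(n_trials = nrow(trials),
             p_respond_stop = p_resp,
             mean_ssd_ms = mean(st$ssd_ms),
             go_rt_ms = mean(go_rt, na.rm = TRUE),
             ssrt_beh_ms = ssrt_b,
             ssrt_emg_ms = se$ssrt_emg_ms,
             p_partial = if (n_succ) sum(st$outcome == "SuccStop_PartialEMG") / n_succ
                         else NA_real_)
}
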