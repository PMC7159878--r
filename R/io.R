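#' Read and write the columnar trial table
#'
#' Plain-CSV persistence for trial tables and derived summaries; columns are
#' exactly those documented in [simulate_task()].
#'
#' @param trials trial table.
#' @param path file path.
#' @return `read_trial_table` returns the data frame; `write_trial_table`
#'   the path, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate a cohort of participants
#'
#' Repeats [simulate_task()] with participant-level variability: each
#' participant's race parameters are jittered around the configured group
#' values (multiplicative Gaussian jitter on the ex-Gaussian parameters,
#' additive on `p_tf`, truncated at the prior bounds).
#'
#' @param n_participants cohort size.
#' @param config base [sim_config()].
#' @param sd_frac relative between-participant SD on the race parameters.
#' @param sd_ptf absolute between-participant SD on `p_tf`.
#' @param seed integer seed.
#' @return list of per-participant [simulate_task()] results; each element
#'   also records the participant's true `race` parameters.
#' @export
simulate_cohort <- function(n_participants, config = sim_config(),
                            sd_frac = 0.08, sd_ptf = 0.02, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_participants), function(p) {
      r <- config$race
      jit <- function(x, lo = 1e-3, hi = Inf)
        min(max(x * exp(rnorm(1, 0, sd_frac)), lo), hi)
      rp <- race_params(
        mu_go = jit(r$mu_go, hi = 1.99), sigma_go = jit(r$sigma_go, hi = 0.49),
        tau_go = jit(r$tau_go, hi = 0.49),
        mu_stop = jit(r$mu_stop, hi = 1.99),
        sigma_stop = jit(r$sigma_stop, hi = 0.49),
        tau_stop = jit(r$tau_stop, hi = 0.49),
        p_tf = min(max(r$p_tf + rnorm(1, 0, sd_ptf), 0), 0.5))
      cfg <- config
      cfg$race <- rp
      sim <- simulate_task(cfg, seed = sample.int(1e6, 1))
      sim$race <- rp
      sim
    })
  })
}
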