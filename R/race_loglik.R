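#' Analytic probability of inhibiting at a given SSD
#'
#' Under the independent ex-Gaussian race with trigger failures, the
#' probability of no response on a stop trial at SSD `d` is
#' `p_tf * S_G(D) + (1 - p_tf) * (Int_0^D f_G(t) F_S(t - d) dt + S_G(D))`,
#' where `f_G`/`S_G` are the Go density and survivor, `F_S` the Stop CDF and
#' `D` the response deadline. The integral is evaluated by fixed
#' Gauss-Legendre quadrature (deterministic, accurate to ~1e-8 for these
#' smooth integrands).
#'
#' @param ssd_s SSD(s) in seconds (vectorized).
#' @param params a [race_params()].
#' @param deadline_s response deadline in seconds.
#' @param n_nodes quadrature nodes.
#' @return P(inhibit | SSD), same length as `ssd_s`.
#' @export
p_inhibit <- function(ssd_s, params, deadline_s = 1, n_nodes = 64) {
  gl <- pracma::gaussLegendre(n_nodes, 0, deadline_s)
  fg <- dexgauss(gl$x, params$mu_go, params$sigma_go, params$tau_go)
  surv_d <- 1 - pexgauss(deadline_s, params$mu_go, params$sigma_go, params$tau_go)
  vapply(ssd_s, function(d) {
    Fs <- pexgauss(gl$x - d, params$mu_stop, params$sigma_stop, params$tau_stop)
    I <- sum(gl$w * fg * Fs)
    params$p_tf * surv_d + (1 - params$p_tf) * (I + surv_d)
  }, numeric(1))
}

#' Log-likelihood of a stop-signal session under the race model
#'
#' Contributions per trial type: a Correct Go RT `t` contributes `f_G(t)`;
#' a go omission `S_G(D)`; a Failed Stop RT `t` at SSD `d` contributes
#' `f_G(t) * (p_tf + (1 - p_tf) * (1 - F_S(t - d)))` (the go finish either
#' beat a triggered stop or the stop never triggered); a Successful Stop at
#' `d` contributes [p_inhibit()]. Times are taken in ms at the interface and
#' converted to seconds internally, matching the prior scales.
#'
#' @param trials trial table with `type, outcome, ssd_ms, rt_ms` (classified
#'   outcomes; successful-stop rows need no RT).
#' @param params a [race_params()].
#' @param deadline_ms response deadline (ms).
#' @param n_nodes quadrature nodes for the inhibition integral.
#' @return scalar log-likelihood (finite on valid data; `-Inf` if the
#'   parameters give an impossible observation).
#' @export
race_loglik <- function(trials, params, deadline_ms = 1000, n_nodes = 64) {
  dat <- prep_race_data(trials, deadline_ms)
  subject_loglik(unlist(params[RACE_PAR_NAMES]), dat,
                 race_quadrature(deadline_ms / 1000, n_nodes))
}

RACE_PAR_NAMES <- c("mu_go", "sigma_go", "tau_go",
                    "mu_stop", "sigma_stop", "tau_stop", "p_tf")

race_quadrature <- function(deadline_s, n_nodes = 64) {
  gl <- pracma::gaussLegendre(n_nodes, 0, deadline_s)
  list(x = gl$x, w = gl$w, deadline_s = deadline_s)
}

## compact per-subject data for fast repeated likelihood evaluation
prep_race_data <- function(trials, deadline_ms = 1000) {
  if (any(!is.na(trials$rt_ms) & trials$rt_ms <= 0))
    stop("non-positive RT in trial table")
  succ <- trials$outcome %in% c("SuccStop_PartialEMG", "SuccStop_NoEMG",
                                "SuccStop")
  if (any(succ & !is.na(trials$rt_ms)))
    stop("RT present on a successful stop trial")
  go_rt <- trials$rt_ms[trials$outcome == "CorrectGo"] / 1000
  fs <- trials[trials$outcome == "FailedStop", , drop = FALSE]
  ss_tab <- table(trials$ssd_ms[succ])
  list(go_rt = go_rt,
       n_go_om = sum(trials$outcome == "GoOmission"),
       fs_rt = fs$rt_ms / 1000, fs_ssd = fs$ssd_ms / 1000,
       ss_ssd = as.numeric(names(ss_tab)) / 1000,
       ss_n = as.integer(ss_tab),
       deadline_s = deadline_ms / 1000)
}

## theta: numeric vector in RACE_PAR_NAMES order (seconds / probability)
subject_loglik <- function(theta, dat, gl) {
  mu_g <- theta[1]; sg <- theta[2]; tg <- theta[3]
  mu_s <- theta[4]; ss <- theta[5]; ts <- theta[6]; ptf <- theta[7]
  if (sg <= 0 || ss <= 0 || tg < 0 || ts < 0 || ptf < 0 || ptf > 1)
    return(-Inf)
  ll <- 0
  if (length(dat$go_rt))
    ll <- ll + sum(dexgauss(dat$go_rt, mu_g, sg, tg, log = TRUE))
  surv_d <- 1 - pexgauss(dat$deadline_s, mu_g, sg, tg)
  if (dat$n_go_om > 0)
    ll <- ll + dat$n_go_om * log(max(surv_d, 1e-300))
  if (length(dat$fs_rt)) {
    Fs <- pexgauss(dat$fs_rt - dat$fs_ssd, mu_s, ss, ts)
    ll <- ll + sum(dexgauss(dat$fs_rt, mu_g, sg, tg, log = TRUE) +
                     log(pmax(ptf + (1 - ptf) * (1 - Fs), 1e-300)))
  }
  if (length(dat$ss_ssd)) {
    fg <- dexgauss(gl$x, mu_g, sg, tg)
    pi_d <- vapply(dat$ss_ssd, function(d) {
      Fs <- pexgauss(gl$x - d, mu_s, ss, ts)
      ptf * surv_d + (1 - ptf) * (sum(gl$w * fg * Fs) + surv_d)
    }, numeric(1))
    ll <- ll + sum(dat$ss_n * log(pmax(pi_d, 1e-300)))
  }
  if (!is.finite(ll)) -Inf else ll
}
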