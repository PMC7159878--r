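#' Hierarchical Bayesian fit of the ex-Gaussian race model
#'
#' BEESTS-style estimation: each participant's seven race parameters
#' (`mu_go, sigma_go, tau_go, mu_stop, sigma_stop, tau_stop, p_tf`) are
#' drawn from truncated-normal group distributions whose bounds are the
#' prior bounds (`mu`: U(0,2); `sigma`, `tau`: U(0,0.5); `p_tf`: U(0,1), in
#' seconds / probability); group means have uniform hyperpriors over the
#' same bounds and group SDs uniform hyperpriors over (0, bound width).
#' Sampling is Metropolis-within-Gibbs with per-parameter Gaussian random
#' walks whose scales adapt toward ~20-50% acceptance during burn-in.
#' Convergence is assessed by the split-chain Gelman-Rubin statistic; chains
#' count as converged when every Rhat < 1.1.
#'
#' The summary SSRT is the posterior mean of the group-level
#' `mu_stop + tau_stop`, its SD the posterior mean of
#' `sqrt(sigma_stop^2 + tau_stop^2)`.
#'
#' With a single participant the group layer is dropped and the bounded
#' uniform priors act directly on that participant's parameters.
#'
#' @param trials_by_participant list of classified trial tables (one per
#'   participant), each with `type, outcome, ssd_ms, rt_ms`.
#' @param n_chains number of chains.
#' @param n_burn burn-in sweeps (adaptation happens here).
#' @param n_keep kept sweeps per chain after burn-in.
#' @param thin keep every `thin`-th sweep.
#' @param deadline_ms response deadline (ms).
#' @param n_nodes quadrature nodes for the inhibition integral.
#' @param seed integer seed.
#' @return object of class `race_posterior`: `draws` (array kept x chain x
#'   parameter, dimnames included), `rhat` per parameter, `converged`,
#'   `summary` (group posterior means, `ssrt_beests_ms`, `ssrt_sd_ms`,
#'   `p_tf`), and `subject_means` (per-participant posterior means).
#' @export
fit_hierarchical <- function(trials_by_participant,
                             n_chains = 3, n_burn = 400, n_keep = 1000,
                             thin = 1, deadline_ms = 1000, n_nodes = 48,
                             seed = 1L) {
  stopifnot(length(trials_by_participant) >= 1)
  S <- length(trials_by_participant)
  hierarchical <- S >= 2
  dats <- lapply(trials_by_participant, prep_race_data, deadline_ms = deadline_ms)
  gl <- race_quadrature(deadline_ms / 1000, n_nodes)

  lo <- c(0, 0, 0, 0, 0, 0, 0)
  hi <- c(2, 0.5, 0.5, 2, 0.5, 0.5, 1)
  P <- 7L
  par_lab <- RACE_PAR_NAMES

  init_subject <- function(dat) {
    rt <- c(dat$go_rt, dat$fs_rt)
    m <- if (length(rt)) mean(rt) else 0.5
    s <- if (length(rt) > 3) sd(rt) else 0.1
    th <- c(max(m - 0.6 * s, 0.05), max(0.5 * s, 0.02), max(0.6 * s, 0.02),
            0.15, 0.05, 0.05, 0.05)
    pmin(pmax(th, lo + 1e-4), hi - 1e-4)
  }

  ltn <- function(x, m, s, l, h) {     # truncated-normal log density on [l, h]
    dnorm(x, m, s, log = TRUE) -
      log(pmax(pnorm(h, m, s) - pnorm(l, m, s), 1e-300))
  }

  n_par_total <- S * P + if (hierarchical) 2 * P else 0
  par_names <- c(as.vector(outer(par_lab, seq_len(S),
                                 function(p, s) paste0(p, "[", s, "]"))),
                 if (hierarchical) c(paste0("group_mean_", par_lab),
                                     paste0("group_sd_", par_lab)))
  kept <- floor(n_keep / thin)
  draws <- array(NA_real_, dim = c(kept, n_chains, n_par_total),
                 dimnames = list(NULL, NULL, par_names))

  run_chain <- function(chain_seed) {
    with_seed(chain_seed, {
      theta <- vapply(dats, init_subject, numeric(P))       # P x S
      theta <- theta * matrix(runif(P * S, 0.95, 1.05), P, S)
      theta <- pmin(pmax(theta, lo + 1e-4), hi - 1e-4)
      m <- rowMeans(theta)
      s_grp <- pmax(apply(theta, 1, sd), (hi - lo) / 50)
      ll <- vapply(seq_len(S), function(i)
        subject_loglik(theta[, i], dats[[i]], gl), numeric(1))
      scale_th <- matrix(rep((hi - lo) / 50, S), P, S)
      scale_m <- (hi - lo) / 50
      scale_s <- (hi - lo) / 50
      acc_th <- matrix(0, P, S); try_th <- matrix(0, P, S)
      acc_m <- acc_s <- try_ms <- numeric(P)
      ## opposite-sign proposal pairs along the posterior's slow directions:
      ## mu/tau (mean trade-off) and sigma/tau (variance trade-off)
      ridge_pairs <- list(c(1L, 3L), c(4L, 6L), c(2L, 3L), c(5L, 6L))
      RP <- length(ridge_pairs)
      scale_ridge <- matrix(0.01, RP, S)
      acc_r <- try_r <- matrix(0, RP, S)
      scale_jr <- rep(0.005, RP)            # group-level joint ridge
      acc_jr <- try_jr <- numeric(RP)
      out <- matrix(NA_real_, kept, n_par_total)
      k <- 0L
      total <- n_burn + n_keep
      for (it in seq_len(total)) {
        for (i in seq_len(S)) {
          ## ridge moves along the mu/tau trade-off (mean-preserving), which
          ## single-parameter walks traverse very slowly
          for (pr in seq_len(RP)) {
            pair <- ridge_pairs[[pr]]
            dlt <- rnorm(1, 0, scale_ridge[pr, i])
            try_r[pr, i] <- try_r[pr, i] + 1
            prop <- theta[, i]
            prop[pair] <- prop[pair] + c(dlt, -dlt)
            if (all(prop[pair] > lo[pair]) && all(prop[pair] < hi[pair])) {
              ll_new <- subject_loglik(prop, dats[[i]], gl)
              dpr <- if (hierarchical)
                sum(ltn(prop[pair], m[pair], s_grp[pair], lo[pair], hi[pair])) -
                sum(ltn(theta[pair, i], m[pair], s_grp[pair], lo[pair], hi[pair]))
              else 0
              if (log(runif(1)) < ll_new - ll[i] + dpr) {
                theta[, i] <- prop
                ll[i] <- ll_new
                acc_r[pr, i] <- acc_r[pr, i] + 1
              }
            }
          }
          for (j in seq_len(P)) {
            prop <- theta[, i]
            prop[j] <- reflect_into(prop[j] + rnorm(1, 0, scale_th[j, i]),
                                    lo[j], hi[j])
            try_th[j, i] <- try_th[j, i] + 1
            if (prop[j] <= lo[j] || prop[j] >= hi[j]) next
            ll_new <- subject_loglik(prop, dats[[i]], gl)
            lprior_old <- if (hierarchical)
              ltn(theta[j, i], m[j], s_grp[j], lo[j], hi[j]) else 0
            lprior_new <- if (hierarchical)
              ltn(prop[j], m[j], s_grp[j], lo[j], hi[j]) else 0
            if (log(runif(1)) < ll_new - ll[i] + lprior_new - lprior_old) {
              theta[, i] <- prop
              ll[i] <- ll_new
              acc_th[j, i] <- acc_th[j, i] + 1
            }
          }
        }
        if (hierarchical) {
          ## joint group+subject ridge: moves the whole hierarchy along the
          ## mean-preserving mu/tau direction in one step
          for (pr in seq_len(RP)) {
            pair <- ridge_pairs[[pr]]
            dlt <- rnorm(1, 0, scale_jr[pr])
            try_jr[pr] <- try_jr[pr] + 1
            th_new <- theta
            th_new[pair, ] <- th_new[pair, ] + c(dlt, -dlt)
            m_new <- m
            m_new[pair] <- m_new[pair] + c(dlt, -dlt)
            if (all(th_new[pair, ] > lo[pair]) && all(th_new[pair, ] < hi[pair]) &&
                all(m_new[pair] > lo[pair]) && all(m_new[pair] < hi[pair])) {
              ll_new <- vapply(seq_len(S), function(i)
                subject_loglik(th_new[, i], dats[[i]], gl), numeric(1))
              dpr <- sum(ltn(th_new[pair, ], m_new[pair], s_grp[pair],
                             lo[pair], hi[pair])) -
                sum(ltn(theta[pair, ], m[pair], s_grp[pair], lo[pair], hi[pair]))
              if (log(runif(1)) < sum(ll_new) - sum(ll) + dpr) {
                theta <- th_new
                m <- m_new
                ll <- ll_new
                acc_jr[pr] <- acc_jr[pr] + 1
              }
            }
          }
          ## near-conjugate independence proposals: the conditional for the
          ## group mean/variance is Gaussian/inverse-gamma up to the
          ## truncation normalization, so proposing from it leaves only the
          ## normalization ratio in the acceptance probability
          lz <- function(mm, ss, j)
            log(pmax(pnorm(hi[j], mm, ss) - pnorm(lo[j], mm, ss), 1e-300))
          for (j in seq_len(P)) {
            th_bar <- mean(theta[j, ])
            mp <- rnorm(1, th_bar, s_grp[j] / sqrt(S))
            if (mp > lo[j] && mp < hi[j]) {
              a <- S * (lz(m[j], s_grp[j], j) - lz(mp, s_grp[j], j))
              if (log(runif(1)) < a) m[j] <- mp
            }
            ssq <- sum((theta[j, ] - m[j])^2)
            if (S >= 4) {
              vp <- 1 / rgamma(1, shape = (S - 1) / 2, rate = ssq / 2)
              sp <- sqrt(vp)
              if (sp > 1e-4 && sp < (hi[j] - lo[j])) {
                a <- S * (lz(m[j], s_grp[j], j) - lz(m[j], sp, j))
                if (log(runif(1)) < a) s_grp[j] <- sp
              }
            }
          }
          for (j in seq_len(P)) {
            try_ms[j] <- try_ms[j] + 1
            mp <- m[j] + rnorm(1, 0, scale_m[j])
            if (mp > lo[j] && mp < hi[j]) {
              a <- sum(ltn(theta[j, ], mp, s_grp[j], lo[j], hi[j])) -
                sum(ltn(theta[j, ], m[j], s_grp[j], lo[j], hi[j]))
              if (log(runif(1)) < a) { m[j] <- mp; acc_m[j] <- acc_m[j] + 1 }
            }
            sp <- s_grp[j] + rnorm(1, 0, scale_s[j])
            if (sp > 1e-4 && sp < (hi[j] - lo[j])) {
              a <- sum(ltn(theta[j, ], m[j], sp, lo[j], hi[j])) -
                sum(ltn(theta[j, ], m[j], s_grp[j], lo[j], hi[j]))
              if (log(runif(1)) < a) { s_grp[j] <- sp; acc_s[j] <- acc_s[j] + 1 }
            }
          }
        }
        if (it <= n_burn && it %% 25 == 0) {          # scale adaptation
          rate <- ifelse(try_th > 0, acc_th / try_th, 0.3)
          scale_th <- scale_th * exp(1.5 * (rate - 0.3))
          scale_th <- pmin(pmax(scale_th, 1e-5), (hi - lo) / 2)
          acc_th[] <- 0; try_th[] <- 0
          scale_ridge <- pmin(pmax(scale_ridge *
            exp(1.5 * (acc_r / pmax(try_r, 1) - 0.3)), 1e-5), 0.25)
          acc_r[] <- 0; try_r[] <- 0
          if (hierarchical) {
            scale_jr <- pmin(pmax(scale_jr *
              exp(1.5 * (acc_jr / pmax(try_jr, 1) - 0.3)), 1e-5), 0.25)
            acc_jr[] <- 0; try_jr[] <- 0
          }
          if (hierarchical) {
            scale_m <- pmin(pmax(scale_m * exp(1.5 * (acc_m / try_ms - 0.3)),
                                 1e-5), (hi - lo) / 2)
            scale_s <- pmin(pmax(scale_s * exp(1.5 * (acc_s / try_ms - 0.3)),
                                 1e-5), (hi - lo) / 2)
            acc_m[] <- 0; acc_s[] <- 0; try_ms[] <- 0
          }
        }
        if (it > n_burn && (it - n_burn) %% thin == 0) {
          k <- k + 1L
          if (k <= kept)
            out[k, ] <- c(as.vector(theta),
                          if (hierarchical) c(m, s_grp))
        }
      }
      out
    })
  }

  base_seed <- as.integer(seed) %% 100000L
  for (ch in seq_len(n_chains))
    draws[, ch, ] <- run_chain(base_seed + 1000L * ch)

  rhat <- apply(draws, 3, split_rhat)
  names(rhat) <- par_names
  post_mean <- apply(draws, 3, mean)
  names(post_mean) <- par_names

  grp <- function(p) {
    if (hierarchical) post_mean[paste0("group_mean_", p)]
    else post_mean[paste0(p, "[1]")]
  }
  ssrt_draws <- if (hierarchical)
    draws[, , "group_mean_mu_stop"] + draws[, , "group_mean_tau_stop"]
  else draws[, , "mu_stop[1]"] + draws[, , "tau_stop[1]"]
  sd_draws <- if (hierarchical)
    sqrt(draws[, , "group_mean_sigma_stop"]^2 + draws[, , "group_mean_tau_stop"]^2)
  else sqrt(draws[, , "sigma_stop[1]"]^2 + draws[, , "tau_stop[1]"]^2)

  subject_means <- t(vapply(seq_len(S), function(i)
    vapply(par_lab, function(p) post_mean[paste0(p, "[", i, "]")], numeric(1)),
    numeric(P)))
  rownames(subject_means) <- paste0("participant_", seq_len(S))
  colnames(subject_means) <- par_lab

  structure(list(
    draws = draws, rhat = rhat,
    converged = all(is.finite(rhat)) && all(rhat < 1.1),
    hierarchical = hierarchical,
    summary = list(
      group = setNames(vapply(par_lab, grp, numeric(1)), par_lab),
      ssrt_beests_ms = 1000 * mean(ssrt_draws),
      ssrt_sd_ms = 1000 * mean(sd_draws),
      p_tf = unname(grp("p_tf"))),
    subject_means = subject_means,
    n_chains = n_chains, n_burn = n_burn, n_keep = n_keep, thin = thin),
    class = "race_posterior")
}

## reflect a random-walk proposal back into (lo, hi); keeps the proposal
## symmetric so boundary parameters (e.g. p_tf near 0) still mix
reflect_into <- function(x, l, h) {
  for (k in 1:50) {
    if (x < l) x <- 2 * l - x
    else if (x > h) x <- 2 * h - x
    else break
  }
  x
}

## split-chain Gelman-Rubin statistic for a [iter x chain] matrix
split_rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  half <- floor(n / 2)
  seqs <- do.call(cbind, lapply(seq_len(ncol(x)), function(c)
    cbind(x[seq_len(half), c], x[(n - half + 1):n, c])))
  m <- ncol(seqs); len <- nrow(seqs)
  mu_j <- colMeans(seqs)
  var_j <- apply(seqs, 2, var)
  B <- len * var(mu_j)
  W <- mean(var_j)
  if (!is.finite(W) || W <= 0) return(Inf)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' @export
print.race_posterior <- function(x, ...) {
  cat("Hierarchical race-model posterior (", x$n_chains, " chains, ",
      x$n_keep, " kept sweeps)\n", sep = "")
  cat(sprintf("  SSRT (mu_stop + tau_stop): %.0f ms (SD %.0f ms)\n",
              x$summary$ssrt_beests_ms, x$summary$ssrt_sd_ms))
  cat(sprintf("  Trigger failures: %.1f%%\n", 100 * x$summary$p_tf))
  cat(sprintf("  max Rhat: %.3f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
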