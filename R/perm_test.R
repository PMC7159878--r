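#' Correlation with basic guards
#'
#' Pearson's r by default; Spearman's rho for bounded data. Constant input
#' yields `NA` with a warning rather than an error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient in [-1, 1], or `NA`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in correlation input")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = method)
}

#' Permutation test for the BurstTime-CancelTime correlation
#'
#' Tests whether the across-participant correlation between mean beta
#' BurstTime and mean EMG CancelTime exceeds what window-limited burst
#' timing alone would produce. Under the null, each participant's
#' BurstTimes are uniform on (0, SSRT_Beh) for that participant: every
#' iteration redraws one uniform BurstTime per observed burst (preserving
#' each participant's averaging noise), recomputes per-participant means
#' and the cross-participant correlation with the fixed CancelTimes. The
#' p-value is `(1 + #{r_perm >= r_obs}) / (1 + n_iter)` (add-one rule, so
#' p is never 0).
#'
#' An alternative `mode = "per_participant"` draws a single BurstTime per
#' participant per iteration.
#'
#' @param canceltimes per-participant mean CancelTimes (ms).
#' @param bursttimes observed per-participant mean BurstTimes (ms).
#' @param ssrt_beh per-participant behavioral SSRT (ms), all > 0.
#' @param burst_counts number of observed bursts per participant (>= 1).
#' @param n_iter permutation iterations.
#' @param method correlation statistic.
#' @param mode how many null BurstTimes to draw per participant.
#' @param seed integer seed.
#' @return list `r_obs, p, n_iter, r_perm` (the null sample).
#' @export
permutation_corr_test <- function(canceltimes, bursttimes, ssrt_beh,
                                  burst_counts = NULL, n_iter = 3000,
                                  method = c("pearson", "spearman"),
                                  mode = c("per_burst", "per_participant"),
                                  seed = 1L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  n <- length(canceltimes)
  stopifnot(length(bursttimes) == n, length(ssrt_beh) == n, n >= 4,
            n_iter >= 1)
  if (any(!is.finite(ssrt_beh)) || any(ssrt_beh <= 0))
    stop("ssrt_beh must be positive for every participant")
  if (is.null(burst_counts)) burst_counts <- rep(1L, n)
  stopifnot(length(burst_counts) == n, all(burst_counts >= 1))
  if (sd(canceltimes) == 0 || sd(bursttimes) == 0)
    stop("zero variance in canceltimes or bursttimes; test undefined")
  r_obs <- correlate(canceltimes, bursttimes, method)
  with_seed(seed, {
    perm_means <- matrix(NA_real_, n, n_iter)
    for (i in seq_len(n)) {
      k <- if (mode == "per_burst") burst_counts[i] else 1L
      draws <- matrix(runif(k * n_iter, 0, ssrt_beh[i]), k, n_iter)
      perm_means[i, ] <- colMeans(draws)
    }
    if (method == "spearman") {
      cx <- rank(canceltimes)
      pm <- apply(perm_means, 2, rank)
    } else {
      cx <- canceltimes
      pm <- perm_means
    }
    r_perm <- suppressWarnings(as.vector(cor(cx, pm)))
    p <- (1 + sum(r_perm >= r_obs, na.rm = TRUE)) / (1 + n_iter)
    list(r_obs = r_obs, p = p, n_iter = n_iter, r_perm = r_perm)
  })
}
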