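#' Fit a cumulative Weibull inhibition function
#'
#' Fits `w(t) = gamma - (gamma - delta) * exp(-(t / alpha)^beta)` to the
#' probability of responding as a function of SSD `t`: `alpha` is the SSD at
#' which the function has completed `1 - exp(-1)` (~64%) of its growth,
#' `beta` the slope, `delta` the lower and `gamma` the upper asymptote.
#' Weighted nonlinear least squares (weights = trial counts by default);
#' parameters are bounded (`gamma, delta` in [0, 1], `alpha, beta > 0`) and
#' start values are taken from the data range (`delta = min p`,
#' `gamma = max p`, `alpha` = SSD nearest the half-range crossing,
#' `beta = 2`).
#'
#' @param ssds SSD levels (ms), at least 4 distinct values.
#' @param p_respond response probabilities in [0, 1], one per SSD.
#' @param weights fit weights (default: equal; pass trial counts per SSD).
#' @return list of class `inhibition_fit` with `alpha, beta, gamma, delta`,
#'   `fitted`, `converged` and the optimizer object; `NULL` parameters with
#'   diagnostics if the fit does not converge.
#' @examples
#' w <- function(t) 1 - exp(-(t / 200)^2.5)
#' fit <- fit_weibull(seq(50, 450, 50), w(seq(50, 450, 50)))
#' @export
fit_weibull <- function(ssds, p_respond, weights = NULL) {
  stopifnot(length(ssds) == length(p_respond))
  if (length(unique(ssds)) < 4)
    stop("at least 4 distinct SSDs are required for the Weibull fit")
  if (any(p_respond < 0 | p_respond > 1)) stop("p_respond must lie in [0, 1]")
  if (is.null(weights)) weights <- rep(1, length(ssds))
  df <- data.frame(t = ssds, p = p_respond, w = weights)
  delta0 <- min(df$p); gamma0 <- max(df$p)
  half <- (delta0 + gamma0) / 2
  alpha0 <- df$t[which.min(abs(df$p - half))]
  if (alpha0 <= 0) alpha0 <- mean(df$t)
  fit <- try(minpack.lm::nlsLM(
    p ~ gamma - (gamma - delta) * exp(-(t / alpha)^beta),
    data = df, weights = df$w,
    start = list(alpha = alpha0, beta = 2, gamma = gamma0, delta = delta0),
    lower = c(alpha = 1e-6, beta = 1e-6, gamma = 0, delta = 0),
    upper = c(alpha = Inf, beta = Inf, gamma = 1, delta = 1),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
                          delta = NA_real_, converged = FALSE,
                          diagnostics = attr(fit, "condition")$message),
                     class = "inhibition_fit"))
  }
  cf <- coef(fit)
  structure(list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
                 gamma = unname(cf["gamma"]), delta = unname(cf["delta"]),
                 fitted = stats::fitted(fit), converged = TRUE, fit = fit),
            class = "inhibition_fit")
}

#' Evaluate a fitted (or parametric) inhibition function
#'
#' @param t SSDs (ms).
#' @param alpha,beta,gamma,delta Weibull parameters (see [fit_weibull()]).
#' @return predicted response probabilities.
#' @export
weibull_inhibition <- function(t, alpha, beta, gamma = 1, delta = 0) {
  gamma - (gamma - delta) * exp(-(t / alpha)^beta)
}
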