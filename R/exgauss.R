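#' Ex-Gaussian distribution
#'
#' Density, distribution function and random generation for the ex-Gaussian
#' distribution: the sum of a Gaussian component `N(mu, sigma^2)` and an
#' independent exponential component with mean `tau`. Finish times of the Go
#' and Stop processes in the race model are modelled as ex-Gaussian, so the
#' mean of a process is `mu + tau` and its variance `sigma^2 + tau^2`.
#'
#' For `tau` much smaller than `sigma` the distribution degenerates to the
#' Gaussian; the implementation switches to the Gaussian limit below
#' `tau < 1e-6 * sigma` to stay numerically stable.
#'
#' @param x,q vector of quantiles.
#' @param n number of draws.
#' @param mu,sigma,tau ex-Gaussian parameters; `sigma, tau > 0`.
#' @param log,log.p if `TRUE`, return log density / log probability.
#' @return `dexgauss` the density, `pexgauss` the CDF, `rexgauss` draws.
#' @examples
#' integrate(dexgauss, -Inf, Inf, mu = 0.4, sigma = 0.05, tau = 0.08)
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  stopifnot(sigma > 0, tau >= 0)
  if (tau < 1e-6 * sigma) {
    return(dnorm(x, mu, sigma, log = log))
  }
  z <- (x - mu) / sigma
  lf <- -log(tau) + (sigma / tau)^2 / 2 - (x - mu) / tau +
    pnorm(z - sigma / tau, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(q, mu, sigma, tau, log.p = FALSE) {
  stopifnot(sigma > 0, tau >= 0)
  if (tau < 1e-6 * sigma) {
    return(pnorm(q, mu, sigma, log.p = log.p))
  }
  z <- (q - mu) / sigma
  p <- pnorm(z) -
    exp((sigma / tau)^2 / 2 - (q - mu) / tau + pnorm(z - sigma / tau, log.p = TRUE))
  p <- pmin(pmax(p, 0), 1)
  if (log.p) log(p) else p
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(sigma > 0, tau >= 0)
  rnorm(n, mu, sigma) + if (tau > 0) rexp(n, 1 / tau) else 0
}
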