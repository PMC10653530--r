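# Benchmark unit distributions used in the model-comparison workflow.
# Each is given in its location/precision (or quantile) parametrization:
#   beta  mean mu, precision phi            (shape1 = mu*phi, shape2 = (1-mu)*phi)
#   kw    Kumaraswamy, q-th quantile mu, shape phi (q fixed at 0.5: median)
#   ug    unit gamma, mean mu, precision phi
#   ubs   unit Birnbaum-Saunders, shapes alpha, beta (Y = exp(-X), X ~ BS)
#   uw    unit Weibull, tau-th quantile mu, shape beta (tau fixed at 0.5)
#   cuw   complementary unit Weibull, median mu, shape beta

#' Competitor unit distributions
#'
#' Densities and distribution functions for six benchmark distributions on
#' (0, 1): the mean-precision beta (`dbetamu`), the quantile-parametrized
#' Kumaraswamy (`dkw`), the mean-parametrized unit gamma (`dug`), the unit
#' Birnbaum-Saunders (`dubs`), the quantile-parametrized unit Weibull
#' (`duw`) and the complementary unit Weibull (`dcuw`).  These are the
#' standard comparison set for unit-interval data and share the fitting
#' interface of the family members (see [fit_mle()]).
#'
#' Parametrizations: `mu` is the mean for the beta and unit gamma, and the
#' `q`/`tau`-th quantile (median at the 0.5 default) for the Kumaraswamy,
#' unit Weibull and complementary unit Weibull; `phi` is a precision
#' parameter; the unit Birnbaum-Saunders has two positive shapes `alpha`,
#' `beta` and no unit-interval location.
#'
#' @param x,q vector of values strictly inside (0, 1).
#' @param mu location parameter in (0, 1) (mean or quantile; see Details).
#' @param phi,beta positive precision/shape parameter.
#' @param alpha positive shape parameter (unit Birnbaum-Saunders only).
#' @param tau fixed quantile level for the unit Weibull and Kumaraswamy.
#' @param log logical; return the log density?
#' @return Numeric vector of densities or cumulative probabilities.
#' @examples
#' dbetamu(0.3, mu = 0.5, phi = 2)  # uniform case: density 1
#' pkw(0.3, mu = 0.3, phi = 1.4)    # = 0.5: mu is the median
#' @name competitors
NULL

#' @rdname competitors
#' @export
dbetamu <- function(x, mu, phi, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_prob(mu, "mu")
  .check_pos(phi, "phi")
  dbeta(x, mu * phi, (1 - mu) * phi, log = log)
}

#' @rdname competitors
#' @export
pbetamu <- function(q, mu, phi) {
  .check_unit_arg(q, "q")
  pbeta(q, mu * phi, (1 - mu) * phi)
}

#' @rdname competitors
#' @export
dkw <- function(x, mu, phi, tau = 0.5, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_prob(mu, "mu")
  .check_pos(phi, "phi")
  .check_prob(tau, "tau")
  b <- log1p(-tau) / log1p(-mu^phi)
  logf <- log(phi) + log(b) + (phi - 1) * log(x) + (b - 1) * log1p(-x^phi)
  if (log) logf else exp(logf)
}

#' @rdname competitors
#' @export
pkw <- function(q, mu, phi, tau = 0.5) {
  .check_unit_arg(q, "q")
  b <- log1p(-tau) / log1p(-mu^phi)
  -expm1(b * log1p(-q^phi))
}

#' @rdname competitors
#' @export
dug <- function(x, mu, phi, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_prob(mu, "mu")
  .check_pos(phi, "phi")
  d <- mu^(1 / phi) / (1 - mu^(1 / phi))
  logf <- phi * log(d) - lgamma(phi) + (d - 1) * log(x) +
    (phi - 1) * log(-log(x))
  if (log) logf else exp(logf)
}

#' @rdname competitors
#' @export
pug <- function(q, mu, phi) {
  .check_unit_arg(q, "q")
  d <- mu^(1 / phi) / (1 - mu^(1 / phi))
  # -log(Y) ~ Gamma(phi, rate = d)
  pgamma(-log(q), shape = phi, rate = d, lower.tail = FALSE)
}

#' @rdname competitors
#' @export
dubs <- function(x, alpha, beta, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_pos(alpha, "alpha")
  .check_pos(beta, "beta")
  t <- -log(x)
  z <- (sqrt(t / beta) - sqrt(beta / t)) / alpha
  logf <- dnorm(z, log = TRUE) + log(t + beta) - log(2 * alpha) -
    0.5 * log(beta) - 1.5 * log(t) - log(x)
  if (log) logf else exp(logf)
}

#' @rdname competitors
#' @export
pubs <- function(q, alpha, beta) {
  .check_unit_arg(q, "q")
  t <- -log(q)
  z <- (sqrt(t / beta) - sqrt(beta / t)) / alpha
  pnorm(z, lower.tail = FALSE)
}

#' @rdname competitors
#' @export
duw <- function(x, mu, beta, tau = 0.5, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_prob(mu, "mu")
  .check_pos(beta, "beta")
  .check_prob(tau, "tau")
  r <- log(x) / log(mu)
  logf <- log(beta) - log(x) + log(log(tau) / log(mu)) +
    (beta - 1) * log(r) + r^beta * log(tau)
  if (log) logf else exp(logf)
}

#' @rdname competitors
#' @export
puw <- function(q, mu, beta, tau = 0.5) {
  .check_unit_arg(q, "q")
  r <- log(q) / log(mu)
  exp(r^beta * log(tau))
}

#' @rdname competitors
#' @export
dcuw <- function(x, mu, beta, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_prob(mu, "mu")
  .check_pos(beta, "beta")
  s <- log1p(-x) / log1p(-mu)
  logf <- log(beta) + log(log(2)) - log1p(-x) -
    beta * log(-log1p(-mu)) + (beta - 1) * log(-log1p(-x)) -
    s^beta * log(2)
  if (log) logf else exp(logf)
}

#' @rdname competitors
#' @export
pcuw <- function(q, mu, beta) {
  .check_unit_arg(q, "q")
  s <- log1p(-q) / log1p(-mu)
  -expm1(-s^beta * log(2))
}
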