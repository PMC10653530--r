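# Closed forms for the five named family members, all in the quantile
# parametrization with fixed quantile level tau (default 0.5, the median).
# Throughout, x = y/(1-y) and m = mu/(1-mu) denote the ratio-transformed
# argument and location.
#
# Baselines:
#   URG    H(x) = exp(b x) - 1          (Gompertz, standard form)
#   URBXII H(x) = log(1 + x^b)          (Burr XII)
#   URL    H(x) = log(1 + x/b)          (Lomax)
#   URW    H(x) = x^b                   (Weibull)
#   URR    H(x) = x^2                   (Rayleigh; URW with b = 2)
#
# Every function is cross-validated against the generic engine in the test
# suite, and hazard rates are enforced to equal pdf / (1 - cdf).

.check_named_args <- function(mu, tau, beta = NULL) {
  .check_prob(mu, "mu")
  .check_prob(tau, "tau")
  if (!is.null(beta)) .check_pos(beta, "beta")
  invisible(NULL)
}

# --- unit ratio-Gompertz ---------------------------------------------------

#' The unit ratio-Gompertz distribution
#'
#' Density, cdf, quantile function, hazard rate and random generation for
#' the unit ratio-Gompertz (URG) distribution with quantile parameter `mu`
#' (the `tau`-th quantile), shape `beta` and fixed quantile level `tau`.
#' Obtained from the Gompertz baseline \eqn{H(x) = e^{\beta x} - 1} under
#' the ratio transformation.
#'
#' @param x,q vector of values strictly inside (0, 1).
#' @param p vector of probabilities strictly inside (0, 1).
#' @param n number of draws.
#' @param mu quantile parameter in (0, 1).
#' @param beta positive shape parameter.
#' @param tau fixed quantile level in (0, 1); default 0.5.
#' @param log logical; return the log density?
#' @return Numeric vector: density, cdf, quantiles, hazard, or draws.
#' @examples
#' purg(0.4, mu = 0.4, beta = 1)   # = 0.5: mu is the median when tau = 0.5
#' @export
durg <- function(x, mu, beta, tau = 0.5, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- x / (1 - x)
  lEm <- lexpm1(beta * m)
  logf <- log(beta) + log(-log1p(-tau)) + beta * xx - 2 * log1p(-x) - lEm +
    log1p(-tau) * exp(lexpm1(beta * xx) - lEm)
  if (log) logf else exp(logf)
}

#' @rdname durg
#' @export
purg <- function(q, mu, beta, tau = 0.5) {
  .check_unit_arg(q, "q")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- q / (1 - q)
  -expm1(log1p(-tau) * exp(lexpm1(beta * xx) - lexpm1(beta * m)))
}

#' @rdname durg
#' @export
qurg <- function(p, mu, beta, tau = 0.5) {
  .check_unit_arg(p, "p")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- log1p(expm1(beta * m) * log1p(-p) / log1p(-tau)) / beta
  .ratio_to_unit(xx)
}

#' @rdname durg
#' @export
hurg <- function(x, mu, beta, tau = 0.5) {
  .check_unit_arg(x, "x")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- x / (1 - x)
  exp(log(beta) + log(-log1p(-tau)) + beta * xx - 2 * log1p(-x) -
        lexpm1(beta * m))
}

#' @rdname durg
#' @export
rurg <- function(n, mu, beta, tau = 0.5) {
  qurg(runif(n), mu, beta, tau)
}

# --- unit ratio-Burr XII ---------------------------------------------------

#' The unit ratio-Burr XII distribution
#'
#' Density, cdf, quantile function, hazard rate and random generation for
#' the unit ratio-Burr XII (URBXII) distribution, from the Burr XII
#' baseline \eqn{H(x) = \log(1 + x^\beta)}.  With `beta = 1` it coincides
#' with the unit ratio-Lomax distribution with `beta = 1`.
#'
#' @inheritParams durg
#' @return Numeric vector: density, cdf, quantiles, hazard, or draws.
#' @examples
#' purbxii(0.3, mu = 0.3, beta = 2)  # = 0.5
#' @export
durbxii <- function(x, mu, beta, tau = 0.5, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- x / (1 - x)
  L <- log1p(m^beta)
  k <- log1p(-tau) / L
  logf <- log(-log1p(-tau)) + log(beta) + (beta - 1) * log(xx) -
    log1p(xx^beta) - 2 * log1p(-x) - log(L) + k * log1p(xx^beta)
  if (log) logf else exp(logf)
}

#' @rdname durbxii
#' @export
purbxii <- function(q, mu, beta, tau = 0.5) {
  .check_unit_arg(q, "q")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- q / (1 - q)
  -expm1(log1p(-tau) * log1p(xx^beta) / log1p(m^beta))
}

#' @rdname durbxii
#' @export
qurbxii <- function(p, mu, beta, tau = 0.5) {
  .check_unit_arg(p, "p")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- expm1(log1p(m^beta) * log1p(-p) / log1p(-tau))^(1 / beta)
  .ratio_to_unit(xx)
}

#' @rdname durbxii
#' @export
hurbxii <- function(x, mu, beta, tau = 0.5) {
  .check_unit_arg(x, "x")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- x / (1 - x)
  -log1p(-tau) * beta * xx^(beta - 1) /
    ((1 + xx^beta) * (1 - x)^2 * log1p(m^beta))
}

#' @rdname durbxii
#' @export
rurbxii <- function(n, mu, beta, tau = 0.5) {
  qurbxii(runif(n), mu, beta, tau)
}

# --- unit ratio-Lomax ------------------------------------------------------

#' The unit ratio-Lomax distribution
#'
#' Density, cdf, quantile function, hazard rate and random generation for
#' the unit ratio-Lomax (URL) distribution, from the Lomax baseline
#' \eqn{H(x) = \log(1 + x/\beta)}.
#'
#' @inheritParams durg
#' @return Numeric vector: density, cdf, quantiles, hazard, or draws.
#' @examples
#' purl(0.2, mu = 0.2, beta = 3)  # = 0.5
#' @export
durl <- function(x, mu, beta, tau = 0.5, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- x / (1 - x)
  Lm <- log1p(m / beta)
  k <- log1p(-tau) / Lm
  logf <- log(-log1p(-tau)) - log(beta + xx) - 2 * log1p(-x) - log(Lm) +
    k * log1p(xx / beta)
  if (log) logf else exp(logf)
}

#' @rdname durl
#' @export
purl <- function(q, mu, beta, tau = 0.5) {
  .check_unit_arg(q, "q")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- q / (1 - q)
  -expm1(log1p(-tau) * log1p(xx / beta) / log1p(m / beta))
}

#' @rdname durl
#' @export
qurl <- function(p, mu, beta, tau = 0.5) {
  .check_unit_arg(p, "p")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- beta * expm1(log1p(m / beta) * log1p(-p) / log1p(-tau))
  .ratio_to_unit(xx)
}

#' @rdname durl
#' @export
hurl <- function(x, mu, beta, tau = 0.5) {
  .check_unit_arg(x, "x")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- x / (1 - x)
  -log1p(-tau) / ((beta + xx) * (1 - x)^2 * log1p(m / beta))
}

#' @rdname durl
#' @export
rurl <- function(n, mu, beta, tau = 0.5) {
  qurl(runif(n), mu, beta, tau)
}

# --- unit ratio-Weibull ----------------------------------------------------

#' The unit ratio-Weibull and unit ratio-Rayleigh distributions
#'
#' Density, cdf, quantile function, hazard rate and random generation for
#' the unit ratio-Weibull (URW) distribution, from the Weibull baseline
#' \eqn{H(x) = x^\beta}, and for its one-parameter special case with
#' \eqn{\beta = 2}, the unit ratio-Rayleigh (URR) distribution.  The URR
#' has a unimodal density and a closed-form maximum-likelihood estimator
#' (see [closed_form_mu()]).
#'
#' @inheritParams durg
#' @return Numeric vector: density, cdf, quantiles, hazard, or draws.
#' @examples
#' all.equal(durr(0.3, mu = 0.2), durw(0.3, mu = 0.2, beta = 2))
#' @export
durw <- function(x, mu, beta, tau = 0.5, log = FALSE) {
  .check_unit_arg(x, "x")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- x / (1 - x)
  logf <- log(beta) + log(-log1p(-tau)) + (beta - 1) * log(xx) -
    beta * log(m) - 2 * log1p(-x) + log1p(-tau) * exp(beta * (log(xx) - log(m)))
  if (log) logf else exp(logf)
}

#' @rdname durw
#' @export
purw <- function(q, mu, beta, tau = 0.5) {
  .check_unit_arg(q, "q")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- q / (1 - q)
  -expm1(log1p(-tau) * exp(beta * (log(xx) - log(m))))
}

#' @rdname durw
#' @export
qurw <- function(p, mu, beta, tau = 0.5) {
  .check_unit_arg(p, "p")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- m * (log1p(-p) / log1p(-tau))^(1 / beta)
  .ratio_to_unit(xx)
}

#' @rdname durw
#' @export
hurw <- function(x, mu, beta, tau = 0.5) {
  .check_unit_arg(x, "x")
  .check_named_args(mu, tau, beta)
  m <- mu / (1 - mu)
  xx <- x / (1 - x)
  beta * (-log1p(-tau)) * xx^(beta - 1) / (m^beta * (1 - x)^2)
}

#' @rdname durw
#' @export
rurw <- function(n, mu, beta, tau = 0.5) {
  qurw(runif(n), mu, beta, tau)
}

# --- unit ratio-Rayleigh (URW with beta = 2) -------------------------------

#' @rdname durw
#' @export
durr <- function(x, mu, tau = 0.5, log = FALSE) {
  durw(x, mu, 2, tau, log)
}

#' @rdname durw
#' @export
purr <- function(q, mu, tau = 0.5) {
  purw(q, mu, 2, tau)
}

#' @rdname durw
#' @export
qurr <- function(p, mu, tau = 0.5) {
  qurw(p, mu, 2, tau)
}

#' @rdname durw
#' @export
hurr <- function(x, mu, tau = 0.5) {
  hurw(x, mu, 2, tau)
}

#' @rdname durw
#' @export
rurr <- function(n, mu, tau = 0.5) {
  qurr(runif(n), mu, tau)
}
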