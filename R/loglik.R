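# Log-likelihood, score and closed-form estimation machinery for the
# quantile-parametrized family.  With c = -log(1-tau), x_i = y_i/(1-y_i),
# m = mu/(1-mu):
#
#   l(mu, xi) = n log c - n log H(m) - 2 sum log(1-y_i)
#               + sum log h(x_i) - (c / H(m)) sum H(x_i)
#
#   U_mu = h(m) / [(1-mu)^2 H(m)] * [-n + (c / H(m)) sum H(x_i)]
#
# For fixed xi, U_mu = 0 has the unique root
#   mu_hat = g/(1+g),  g = Hinv[(c/n) sum H(x_i)]
# which is the estimator implemented by default.  A variant that skips the
# Hinv step (g = (c/n) sum H(x_i) directly) circulates in print; it does
# not solve the score equation and is badly biased -- it is kept behind
# `as_printed = TRUE` purely for auditability, with a test demonstrating
# the failure.

#' Log-likelihood and score of a quantile-parametrized family member
#'
#' `urew_loglik` evaluates the log-likelihood of a [urew()] distribution at
#' a sample; it is the analytic sum-of-terms form and agrees with
#' `sum(durew(y, dist, log = TRUE))`.  `urew_score_mu` is the analytic
#' partial derivative of the log-likelihood with respect to the quantile
#' parameter `mu`.
#'
#' @param dist a [urew()] object (quantile parametrization for
#'   `urew_score_mu`).
#' @param y observations: a numeric vector or [unit_sample()] strictly
#'   inside (0, 1).
#' @return A single number.
#' @examples
#' y <- rurr(50, mu = 0.3)
#' d <- urew("rayleigh", mu = 0.3)
#' urew_loglik(d, y)
#' @export
urew_loglik <- function(dist, y) {
  stopifnot(inherits(dist, "urew"))
  y <- .unit_values(y)
  n <- length(y)
  xx <- y / (1 - y)
  hx <- eval_h(dist$spec, xx, dist$xi)
  Hx <- eval_H(dist$spec, xx, dist$xi)
  bad <- which(!is.finite(log(hx)) | !is.finite(Hx))
  if (length(bad)) {
    stop("non-finite likelihood term at observation index ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  a <- .urew_alpha(dist)
  n * log(a) + sum(log(hx)) - 2 * sum(log1p(-y)) - a * sum(Hx)
}

#' @rdname urew_loglik
#' @export
urew_score_mu <- function(dist, y) {
  stopifnot(inherits(dist, "urew"))
  if (is.null(dist$mu)) {
    stop("the score in 'mu' requires the quantile parametrization",
         call. = FALSE)
  }
  y <- .unit_values(y)
  n <- length(y)
  cc <- -log1p(-dist$tau)
  m <- dist$mu / (1 - dist$mu)
  Hm <- eval_H(dist$spec, m, dist$xi)
  hm <- eval_h(dist$spec, m, dist$xi)
  sHx <- sum(eval_H(dist$spec, y / (1 - y), dist$xi))
  hm / ((1 - dist$mu)^2 * Hm) * (-n + cc * sHx / Hm)
}

#' Closed-form maximum-likelihood estimator of the quantile parameter
#'
#' For a family member whose shape vector \eqn{\xi} is fixed (in
#' particular the one-parameter members, \eqn{\xi = \emptyset}), the score
#' equation in `mu` has the unique root
#' \deqn{\hat\mu = g/(1+g), \quad
#'       g = H^{-1}\!\big[\tfrac{1}{n}\,(-\log(1-\tau))\textstyle\sum_i
#'       H(y_i/(1-y_i);\xi)\big],}
#' with no iteration required.  For the unit ratio-Rayleigh member
#' (\eqn{H(x)=x^2}) this reduces to
#' \eqn{g = \sqrt{-\log(1-\tau)\sum_i x_i^2 / n}}.
#'
#' `as_printed = TRUE` selects a variant that omits the \eqn{H^{-1}} step
#' (\eqn{g} set to the mean of \eqn{-\log(1-\tau) H(x_i)} itself).  That
#' variant does not solve the score equation and is severely biased; it is
#' provided only so the discrepancy can be audited, and the test suite
#' demonstrates that it fails to recover the truth in simulation.
#'
#' @param spec an [hspec()] or registered baseline name.
#' @param xi fixed shape-parameter vector.
#' @param y observations (numeric vector or [unit_sample()]).
#' @param tau fixed quantile level in (0, 1).
#' @param as_printed logical; use the audit variant (see Details).
#' @return The estimate \eqn{\hat\mu} in (0, 1).
#' @examples
#' set.seed(1)
#' y <- rurr(200, mu = 0.15)
#' closed_form_mu("rayleigh", y = y)
#' @export
closed_form_mu <- function(spec, xi = numeric(0), y, tau = 0.5,
                           as_printed = FALSE) {
  spec <- get_hspec(spec)
  xi <- .check_xi(spec, xi)
  y <- .unit_values(y)
  .check_prob(tau, "tau")
  cc <- -log1p(-tau)
  arg <- cc * mean(eval_H(spec, y / (1 - y), xi))
  g <- if (as_printed) arg else eval_Hinv(spec, arg, xi)
  g / (1 + g)
}

#' Observed information for the unit ratio-Rayleigh model
#'
#' Second derivative of the unit ratio-Rayleigh log-likelihood in `mu`:
#' \deqn{I(\mu) = \frac{2}{\mu^4}\Big[\frac{n\mu^2(1-2\mu)}{(1-\mu)^2}
#'   + (2\mu-3)(-\log(1-\tau))\sum_i \frac{y_i^2}{(1-y_i)^2}\Big].}
#' At the maximum-likelihood estimate it is strictly negative, and the
#' Wald variance is \eqn{-1/I(\hat\mu)}.
#'
#' @param mu evaluation point in (0, 1).
#' @param y observations (numeric vector or [unit_sample()]).
#' @param tau fixed quantile level in (0, 1).
#' @return The observed information (a single number).
#' @examples
#' set.seed(1)
#' y <- rurr(100, mu = 0.3)
#' urr_observed_info(closed_form_mu("rayleigh", y = y), y)  # < 0
#' @export
urr_observed_info <- function(mu, y, tau = 0.5) {
  .check_prob(mu, "mu")
  .check_prob(tau, "tau")
  y <- .unit_values(y)
  n <- length(y)
  cc <- -log1p(-tau)
  S <- sum((y / (1 - y))^2)
  2 / mu^4 * (n * mu^2 * (1 - 2 * mu) / (1 - mu)^2 + (2 * mu - 3) * cc * S)
}

#' Log-likelihood and score of the unit ratio-Gompertz model
#'
#' Analytic log-likelihood and score vector \eqn{(U_\beta, U_\mu)} for the
#' unit ratio-Gompertz distribution, written in overflow-safe form (all
#' \eqn{e^{\beta x} - 1} ratios are computed on the log scale).  The score
#' system has no closed-form root; [fit_mle()] maximizes by quasi-Newton
#' iteration.
#'
#' @param beta positive shape parameter.
#' @param mu quantile parameter in (0, 1).
#' @param y observations (numeric vector or [unit_sample()]).
#' @param tau fixed quantile level in (0, 1).
#' @return `urg_loglik` a single number; `urg_score` a length-2 numeric
#'   vector, ordered \eqn{(U_\beta, U_\mu)}.
#' @examples
#' set.seed(1)
#' y <- rurg(100, mu = 0.4, beta = 0.8)
#' urg_loglik(0.8, 0.4, y)
#' urg_score(0.8, 0.4, y)
#' @export
urg_loglik <- function(beta, mu, y, tau = 0.5) {
  .check_pos(beta, "beta")
  .check_prob(mu, "mu")
  .check_prob(tau, "tau")
  y <- .unit_values(y)
  n <- length(y)
  xx <- y / (1 - y)
  cc <- -log1p(-tau)
  m <- mu / (1 - mu)
  lEm <- lexpm1(beta * m)
  n * log(beta) + n * log(cc) + beta * sum(xx) - 2 * sum(log1p(-y)) -
    n * lEm - cc * sum(exp(lexpm1(beta * xx) - lEm))
}

#' @rdname urg_loglik
#' @export
urg_score <- function(beta, mu, y, tau = 0.5) {
  .check_pos(beta, "beta")
  .check_prob(mu, "mu")
  .check_prob(tau, "tau")
  y <- .unit_values(y)
  n <- length(y)
  xx <- y / (1 - y)
  cc <- -log1p(-tau)
  m <- mu / (1 - mu)
  lEm <- lexpm1(beta * m)
  r <- exp(lexpm1(beta * xx) - lEm)   # (e^{b x_i}-1) / (e^{b m}-1)
  s <- exp(beta * xx - lEm)           # e^{b x_i} / (e^{b m}-1)
  em <- 1 / (-expm1(-beta * m))       # e^{b m} / (e^{b m}-1)
  U_beta <- n / beta + sum(xx) - n * m * em +
    cc * m * em * sum(r) - cc * sum(xx * s)
  U_mu <- beta * em / (1 - mu)^2 * (-n + cc * sum(r))
  c(U_beta = U_beta, U_mu = U_mu)
}
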