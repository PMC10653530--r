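# Generic unit ratio-extended Weibull engine.
#
# Y = X/(1+X) for X extended-Weibull, so with x = y/(1-y):
#   F(y) = 1 - exp(-a H(x; xi)),          a > 0 (rate parametrization)
#   f(y) = a (1-y)^-2 h(x; xi) exp(-a H(x; xi))
# Under the quantile parametrization the rate is tied to the tau-th
# quantile mu through a = -log(1-tau) / H(mu/(1-mu); xi), so that
# F(mu) = tau exactly and mu is a directly interpretable location
# parameter (tau is fixed and known, default 0.5: the median).

#' Construct a unit ratio-extended Weibull distribution
#'
#' Builds a distribution object from a baseline generator and either the
#' quantile parametrization (`mu`, `tau`) or the native rate
#' parametrization (`alpha`).  Exactly one of `mu` and `alpha` must be
#' given.
#'
#' @param spec an [hspec()] or the name of a registered baseline
#'   (see [hspec_catalog()]).
#' @param xi shape-parameter vector for the baseline.
#' @param mu the tau-th quantile, in (0, 1) (quantile parametrization).
#' @param tau fixed, known quantile level in (0, 1); default 0.5.
#' @param alpha positive rate multiplier (rate parametrization).
#' @return An object of class \code{"urew"}.
#' @examples
#' d <- urew("rayleigh", mu = 0.5)      # median-parametrized
#' purew(0.5, d)                        # = 0.5 by construction
#' d2 <- urew("weibull", xi = 2, alpha = log(2))
#' @export
urew <- function(spec, xi = numeric(0), mu = NULL, tau = 0.5, alpha = NULL) {
  spec <- get_hspec(spec)
  xi <- .check_xi(spec, xi)
  if (is.null(mu) == is.null(alpha)) {
    stop("supply exactly one of 'mu' (quantile parametrization) or ",
         "'alpha' (rate parametrization)", call. = FALSE)
  }
  if (!is.null(mu)) {
    .check_prob(mu, "mu")
    .check_prob(tau, "tau")
    if (!is.null(spec$support_note) && spec$x_min(xi) > 0) {
      xmin <- spec$x_min(xi)
      if (mu / (1 - mu) <= xmin) {
        stop(sprintf(
          "'mu' = %g is below the support shift of baseline '%s' (%s)",
          mu, spec$name, spec$support_note), call. = FALSE)
      }
    }
  } else {
    .check_pos(alpha, "alpha")
  }
  structure(list(spec = spec, xi = xi, mu = mu, tau = tau, alpha = alpha),
            class = "urew")
}

#' @export
print.urew <- function(x, ...) {
  cat(sprintf("Unit ratio-extended Weibull distribution ('%s' baseline)\n",
              x$spec$name))
  if (!is.null(x$mu)) {
    cat(sprintf("  quantile parametrization: mu = %g at tau = %g\n",
                x$mu, x$tau))
  } else {
    cat(sprintf("  rate parametrization: alpha = %g\n", x$alpha))
  }
  if (length(x$xi)) {
    cat("  shape parameters:",
        paste(sprintf("%s = %g", x$spec$xi_names, x$xi), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Rate implied by the quantile parametrization
#'
#' Converts the quantile parametrization (`mu`, `tau`) to the native rate:
#' \deqn{\alpha = -\log(1-\tau) / H(\mu/(1-\mu); \xi).}
#' Plugging this rate into the cdf gives \eqn{F(\mu) = \tau} exactly.
#'
#' @param dist a [urew()] object in the quantile parametrization.
#' @return The positive rate \eqn{\alpha}.
#' @examples
#' alpha_from_quantile(urew("rayleigh", mu = 0.5))  # log(2)
#' @export
alpha_from_quantile <- function(dist) {
  stopifnot(inherits(dist, "urew"))
  if (is.null(dist$mu)) {
    stop("distribution is already in the rate parametrization", call. = FALSE)
  }
  m <- dist$mu / (1 - dist$mu)
  Hm <- eval_H(dist$spec, m, dist$xi)
  if (!is.finite(Hm) || Hm <= 0) {
    stop(sprintf(
      "degenerate parameters: H(mu/(1-mu)) = %g must be finite and positive",
      Hm), call. = FALSE)
  }
  -log1p(-dist$tau) / Hm
}

.urew_alpha <- function(dist) {
  if (!is.null(dist$alpha)) dist$alpha else alpha_from_quantile(dist)
}

#' The generic unit ratio-extended Weibull distribution
#'
#' Density, distribution function, quantile function, hazard rate and
#' random generation for an arbitrary family member defined by a [urew()]
#' object.  Arguments outside the open interval (0, 1) are a domain error;
#' the cdf endpoint limits are 0 and 1 by definition.
#'
#' @param x,q vector of values strictly inside (0, 1).
#' @param p vector of probabilities strictly inside (0, 1).
#' @param n number of draws.
#' @param dist a [urew()] object.
#' @param log logical; return the log density?
#' @return `durew` the density, `purew` the cdf, `qurew` the quantile
#'   function, `hurew` the hazard rate, `rurew` a vector of `n` draws
#'   generated by inversion of uniforms from R's random stream (use
#'   [set.seed()] for reproducibility).
#' @examples
#' d <- urew("rayleigh", mu = 0.5)
#' purew(0.5, d)
#' qurew(0.5, d)
#' integrate(durew, 0.001, 0.999, dist = d)$value  # ~ 1
#' @export
durew <- function(x, dist, log = FALSE) {
  stopifnot(inherits(dist, "urew"))
  .check_unit_arg(x, "x")
  a <- .urew_alpha(dist)
  xx <- x / (1 - x)
  Hx <- eval_H(dist$spec, xx, dist$xi)
  logf <- log(a) + log(eval_h(dist$spec, xx, dist$xi)) - 2 * log1p(-x) -
    a * Hx
  # far in the tail H (and hence h) may overflow; the density is then 0
  logf[is.nan(logf) & Hx == Inf] <- -Inf
  if (log) logf else exp(logf)
}

#' @rdname durew
#' @export
purew <- function(q, dist) {
  stopifnot(inherits(dist, "urew"))
  .check_unit_arg(q, "q")
  a <- .urew_alpha(dist)
  xx <- q / (1 - q)
  -expm1(-a * eval_H(dist$spec, xx, dist$xi))
}

#' @rdname durew
#' @export
qurew <- function(p, dist) {
  stopifnot(inherits(dist, "urew"))
  .check_unit_arg(p, "p")
  a <- .urew_alpha(dist)
  t <- -log1p(-p) / a
  xx <- eval_Hinv(dist$spec, t, dist$xi)
  .ratio_to_unit(xx)
}

#' @rdname durew
#' @export
hurew <- function(x, dist) {
  stopifnot(inherits(dist, "urew"))
  .check_unit_arg(x, "x")
  a <- .urew_alpha(dist)
  xx <- x / (1 - x)
  a * eval_h(dist$spec, xx, dist$xi) / (1 - x)^2
}

#' @rdname durew
#' @export
rurew <- function(n, dist) {
  stopifnot(inherits(dist, "urew"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  qurew(runif(n), dist)
}
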