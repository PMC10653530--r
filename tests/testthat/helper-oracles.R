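# Independent oracles shared across the test files: quadrature, finite
# differences, and admissible parameter points for every catalog baseline.

quad <- function(f, lower = 0, upper = 1, ...) {
  tryCatch(
    integrate(f, lower, upper, ..., rel.tol = 1e-10,
              subdivisions = 1000L)$value,
    error = function(e) {
      # endpoint singularities at very tight tolerances: relax slightly
      integrate(f, lower, upper, ..., rel.tol = 1e-8,
                subdivisions = 2000L)$value
    })
}

# Quadrature after the substitution t = -log(y): robust for densities with
# boundary-layer spikes near 0 or 1 (unit Birnbaum-Saunders, unit Weibull).
quad_log <- function(f, lower = 0, upper = 1) {
  g <- function(t) {
    y <- exp(-t)
    ok <- y > 0 & y < 1
    out <- numeric(length(t))
    out[ok] <- f(y[ok]) * y[ok]
    out
  }
  integrate(g, lower = if (upper >= 1) 0 else -log(upper),
            upper = if (lower <= 0) Inf else -log(lower),
            rel.tol = 1e-10, subdivisions = 1000L)$value
}

# As quad_log over the whole unit interval, split at a t-scale landmark
# (e.g. the parent distribution's center) so integrate() cannot step over
# a narrow interior peak on the way to infinity.
quad_log_split <- function(f, split) {
  g <- function(t) {
    y <- exp(-t)
    ok <- y > 0 & y < 1
    out <- numeric(length(t))
    out[ok] <- f(y[ok]) * y[ok]
    out
  }
  integrate(g, 0, split, rel.tol = 1e-9, subdivisions = 1000L)$value +
    integrate(g, split, Inf, rel.tol = 1e-9, subdivisions = 1000L)$value
}

# Quadrature after the ratio substitution x = y/(1-y): turns a unit-interval
# density back into its smooth positive-half-line parent.
quad_ratio <- function(f) {
  g <- function(x) f(x / (1 + x)) / (1 + x)^2
  tryCatch(
    integrate(g, 0, Inf, rel.tol = 1e-10, subdivisions = 1000L)$value,
    error = function(e) {
      # heavy power-law tails: split at 1 and accept a looser tolerance
      integrate(g, 0, 1, rel.tol = 1e-8, subdivisions = 1000L)$value +
        integrate(g, 1, Inf, rel.tol = 1e-8, subdivisions = 1000L)$value
    })
}

# Relative mismatch treating matching non-finite values and matching zeros
# as exact agreement (tail overflow makes hazards infinite in both forms).
max_rel_mismatch <- function(a, b) {
  if (length(a) != length(b)) return(Inf)
  same_special <- (is.na(a) & is.na(b)) |
    (!is.finite(a) & !is.finite(b) & sign(a) == sign(b)) |
    (abs(a) < 1e-290 & abs(b) < 1e-290)  # both underflowed
  ok <- is.finite(a) & is.finite(b) & !same_special
  if (!all(same_special | ok)) return(Inf)
  if (!any(ok)) return(0)
  max(abs(a[ok] - b[ok]) / pmax(abs(b[ok]), .Machine$double.eps))
}

central_diff <- function(f, x, h = 1e-6 * pmax(1, abs(x))) {
  (f(x + h) - f(x - h)) / (2 * h)
}

rel_err <- function(a, b) {
  abs(a - b) / pmax(abs(b), .Machine$double.eps)
}

# Admissible shape parameters for each registered baseline.
catalog_test_xi <- list(
  additive_weibull = c(1.3, 0.7, 1.5, 2),
  burr_xii = 1.7,
  chen = 0.8,
  exponential = numeric(0),
  exponential_power = c(1.2, 0.9),
  flexible_weibull = c(0.8, 0.5),
  gompertz = 1.4,
  gompertz_std = 1.4,
  linear_failure_rate = c(0.5, 1.2),
  log_logistic = 2.2,
  lomax = 1.8,
  modified_weibull = c(1.5, 0.7),
  pareto = 0.5,
  power_generalized_weibull = c(1.2, 1.5, 0.8),
  rayleigh = numeric(0),
  weibull = 2.5)

# Closed-form named models and their generic-engine baselines.
named_model_table <- function() {
  list(
    urg = list(d = durg, p = purg, q = qurg, h = hurg,
               spec = "gompertz_std", two_par = TRUE),
    urbxii = list(d = durbxii, p = purbxii, q = qurbxii, h = hurbxii,
                  spec = "burr_xii", two_par = TRUE),
    url = list(d = durl, p = purl, q = qurl, h = hurl,
               spec = "lomax", two_par = TRUE),
    urw = list(d = durw, p = purw, q = qurw, h = hurw,
               spec = "weibull", two_par = TRUE),
    urr = list(d = function(x, mu, beta, tau = 0.5, log = FALSE)
                 durr(x, mu, tau, log),
               p = function(q, mu, beta, tau = 0.5) purr(q, mu, tau),
               q = function(p, mu, beta, tau = 0.5) qurr(p, mu, tau),
               h = function(x, mu, beta, tau = 0.5) hurr(x, mu, tau),
               spec = "rayleigh", two_par = FALSE))
}

# Random admissible (mu, beta, tau) draws for property loops.
draw_named_params <- function(k = 5) {
  data.frame(mu = runif(k, 0.08, 0.92),
             beta = runif(k, 0.4, 3),
             tau = runif(k, 0.15, 0.85))
}
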