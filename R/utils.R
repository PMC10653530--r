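# Shared numerical and validation helpers (internal).

# Observations this close to 0 or 1 are rejected at validation time:
# likelihood terms involve y/(1-y) and log(1-y) and blow up at the edges.
.BOUNDARY_EPS <- 1e-10

# log(exp(z) - 1), stable for large z (z > 33 is exact to double precision).
lexpm1 <- function(z) {
  out <- z
  small <- is.finite(z) & z <= 33
  out[small] <- log(expm1(z[small]))
  out
}

.z_crit <- function(level) qnorm(1 - (1 - level) / 2)

# Map the positive half-line back to (0, 1).  For heavy-tailed members the
# extreme upper quantiles are closer to 1 than the double spacing allows;
# clamp to the largest representable value below 1 so quantile functions
# always return values strictly inside the open interval.
.ratio_to_unit <- function(xx) {
  pmin(pmax(xx / (1 + xx), 1e-300), 1 - .Machine$double.eps / 2)
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop(sprintf("'%s' must lie strictly inside (0, 1)", name), call. = FALSE)
  }
  invisible(x)
}

.check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be a positive finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Strict open-unit-interval check for function arguments (densities, cdfs).
.check_unit_arg <- function(x, name = "x") {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop(sprintf("'%s' must lie strictly inside the open interval (0, 1); ",
                 name),
         "cdf limits at the endpoints are 0 and 1 by definition, not by ",
         "evaluation", call. = FALSE)
  }
  invisible(x)
}

# Central finite-difference gradient.
.num_grad <- function(f, x, h = pmax(1e-6, 1e-6 * abs(x))) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x))
    e[j] <- h[j]
    g[j] <- (f(x + e) - f(x - e)) / (2 * h[j])
  }
  g
}

# Central finite-difference Hessian, step h_j = max(1e-5, 1e-5 |x_j|).
.num_hessian <- function(f, x, h = pmax(1e-5, 1e-5 * abs(x))) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k)
    ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < k) {
      for (j in seq(i + 1, k)) {
        ej <- numeric(k)
        ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Validated sample on the open unit interval
#'
#' Wraps a numeric vector of observations that must all lie strictly inside
#' (0, 1).  Values within 1e-10 of either endpoint are rejected with a named
#' validation error, because every likelihood in the package involves
#' \code{y/(1-y)} and \code{log(1-y)}.
#'
#' @param values numeric vector of observations in the open interval (0, 1).
#' @param label optional character label describing the sample.
#' @return An object of class \code{"unit_sample"}: a list with elements
#'   \code{values}, \code{label} and \code{n}.
#' @examples
#' s <- unit_sample(c(0.12, 0.2, 0.31), label = "toy")
#' s$n
#' @export
unit_sample <- function(values, label = NULL) {
  if (!is.numeric(values) || length(values) < 1) {
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("non-finite observation at index ",
         paste(which(!is.finite(values)), collapse = ", "), call. = FALSE)
  }
  bad <- values <= .BOUNDARY_EPS | values >= 1 - .BOUNDARY_EPS
  if (any(bad)) {
    stop("observations must lie strictly inside (0, 1) ",
         sprintf("(tolerance %g from the endpoints); offending index: %s",
                 .BOUNDARY_EPS, paste(which(bad), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(values = as.numeric(values), label = label,
                 n = length(values)),
            class = "unit_sample")
}

#' @export
print.unit_sample <- function(x, ...) {
  cat("Unit sample", if (!is.null(x$label)) sprintf("'%s'", x$label), "\n")
  cat(sprintf("  n = %d, range [%.4g, %.4g], mean %.4g\n",
              x$n, min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

# Accept either a unit_sample or a raw numeric vector.
.unit_values <- function(y) {
  if (inherits(y, "unit_sample")) return(y$values)
  unit_sample(y)$values
}
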