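# Baseline generator triples (H, h, Hinv) for the extended-Weibull class.
#
# An extended-Weibull variate X > 0 has survival exp(-a * H(x; xi)) for a
# nonnegative, monotonically increasing generator H with derivative h.
# Each triple plugged into the ratio transformation Y = X/(1+X) yields one
# member of the unit ratio-extended Weibull family.

#' Define an extended-Weibull baseline generator
#'
#' An \code{hspec} bundles a generator function \eqn{H(x;\xi)}, its
#' derivative \eqn{h(x;\xi)} and (optionally) its inverse
#' \eqn{H^{-1}(t;\xi)}, together with the names and positivity constraints of
#' the shape-parameter vector \eqn{\xi}.  \eqn{H} must be nonnegative and
#' strictly increasing on the support for admissible \eqn{\xi}.  When no
#' closed-form inverse exists, \code{Hinv} may be omitted and a safeguarded
#' bracketing root finder is used instead (bracket \code{[1e-12, 1e12]} with
#' geometric expansion, absolute x-tolerance 1e-12).
#'
#' If \code{h} is omitted it is replaced by a central finite difference of
#' \code{H}, with a warning: an analytic derivative should normally be
#' supplied since the density is proportional to \eqn{h}.
#'
#' @param name identifier for the baseline (lowercase, underscores).
#' @param xi_names character vector of shape-parameter names (may be empty).
#' @param H function \code{(x, xi) -> H(x; xi)}, vectorized in \code{x}.
#' @param h function \code{(x, xi) -> dH/dx}, or \code{NULL}.
#' @param Hinv function \code{(t, xi) -> x} with \code{H(x) = t}, or
#'   \code{NULL} to use numeric inversion.
#' @param xi_lower numeric vector of strict lower bounds for \code{xi}
#'   (default all 0, i.e. positive parameters).
#' @param x_min function \code{(xi) -> } lower support endpoint (default 0;
#'   e.g. the Pareto baseline needs \code{x > k}).
#' @param support_note optional text describing support restrictions.
#' @return An object of class \code{"hspec"}.
#' @seealso [hspec_catalog()], [register_hspec()], [eval_H()]
#' @examples
#' gom <- get_hspec("gompertz")
#' eval_H(gom, 2, xi = 1)
#' @export
hspec <- function(name, xi_names, H, h = NULL, Hinv = NULL,
                  xi_lower = rep(0, length(xi_names)),
                  x_min = function(xi) 0,
                  support_note = NULL) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(xi_names) || length(xi_names) == 0,
            is.function(H), is.null(h) || is.function(h),
            is.null(Hinv) || is.function(Hinv),
            length(xi_lower) == length(xi_names),
            is.function(x_min))
  structure(list(name = name, xi_names = as.character(xi_names),
                 H = H, h = h, Hinv = Hinv,
                 xi_lower = as.numeric(xi_lower), x_min = x_min,
                 support_note = support_note),
            class = "hspec")
}

#' @export
print.hspec <- function(x, ...) {
  cat(sprintf("Extended-Weibull baseline '%s'\n", x$name))
  cat("  shape parameters:",
      if (length(x$xi_names)) paste(x$xi_names, collapse = ", ") else "(none)",
      "\n")
  cat("  inverse:", if (is.null(x$Hinv)) "numeric (bracketing)" else
    "closed form", "\n")
  if (!is.null(x$support_note)) cat("  support:", x$support_note, "\n")
  invisible(x)
}

# Registry -----------------------------------------------------------------

.hspec_registry <- new.env(parent = emptyenv())

#' Baseline catalog access and registration
#'
#' `hspec_catalog()` lists the names of all registered baselines;
#' `get_hspec()` retrieves one; `register_hspec()` adds a user-defined
#' baseline under the [hspec()] contract.
#'
#' @param spec an \code{hspec} object (or, for `get_hspec`, a name or an
#'   already-constructed \code{hspec}, returned unchanged).
#' @param name baseline name.
#' @param overwrite logical; allow replacing an existing entry.
#' @return `hspec_catalog()` a character vector; `get_hspec()` an
#'   \code{hspec}; `register_hspec()` the registered \code{hspec},
#'   invisibly.
#' @examples
#' hspec_catalog()
#' @export
hspec_catalog <- function() {
  sort(ls(.hspec_registry))
}

#' @rdname hspec_catalog
#' @export
get_hspec <- function(name) {
  if (inherits(name, "hspec")) return(name)
  stopifnot(is.character(name), length(name) == 1)
  if (!exists(name, envir = .hspec_registry, inherits = FALSE)) {
    stop(sprintf("unknown baseline '%s'; see hspec_catalog()", name),
         call. = FALSE)
  }
  get(name, envir = .hspec_registry, inherits = FALSE)
}

#' @rdname hspec_catalog
#' @export
register_hspec <- function(spec, overwrite = FALSE) {
  stopifnot(inherits(spec, "hspec"))
  if (!overwrite &&
      exists(spec$name, envir = .hspec_registry, inherits = FALSE)) {
    stop(sprintf("baseline '%s' is already registered", spec$name),
         call. = FALSE)
  }
  assign(spec$name, spec, envir = .hspec_registry)
  invisible(spec)
}

# Validation ----------------------------------------------------------------

.check_xi <- function(spec, xi) {
  xi <- as.numeric(xi)
  if (length(xi) != length(spec$xi_names)) {
    stop(sprintf("baseline '%s' expects %d shape parameter(s) (%s), got %d",
                 spec$name, length(spec$xi_names),
                 paste(spec$xi_names, collapse = ", "), length(xi)),
         call. = FALSE)
  }
  if (length(xi)) {
    if (any(!is.finite(xi))) {
      stop(sprintf("non-finite shape parameter for baseline '%s'", spec$name),
           call. = FALSE)
    }
    bad <- xi <= spec$xi_lower
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("constraint violated for baseline '%s': '%s' must be > %g",
                   spec$name, spec$xi_names[i], spec$xi_lower[i]),
           call. = FALSE)
    }
  }
  xi
}

.check_x_support <- function(spec, x, xi) {
  xmin <- spec$x_min(xi)
  if (any(!is.finite(x)) || any(x <= xmin)) {
    stop(sprintf("'x' must be > %g for baseline '%s'", xmin, spec$name),
         call. = FALSE)
  }
  invisible(x)
}

# Evaluation ----------------------------------------------------------------

#' Evaluate a baseline generator, its derivative, or its inverse
#'
#' `eval_H` computes \eqn{H(x;\xi)}, `eval_h` its derivative
#' \eqn{h(x;\xi) = dH/dx}, and `eval_Hinv` the inverse \eqn{H^{-1}(t;\xi)}
#' (closed form when available, otherwise safeguarded bracketing
#' root-finding).  All three validate the shape parameters against the
#' baseline's constraints and the argument against its support.
#'
#' @param spec an [hspec()] or the name of a registered baseline.
#' @param x positive real(s) in the baseline support.
#' @param t nonnegative real(s) in the range of \eqn{H}.
#' @param xi shape-parameter vector (empty for e.g. the Rayleigh baseline).
#' @return Numeric vector of the same length as `x` (or `t`).
#' @examples
#' eval_H("weibull", 2, xi = 3)     # 2^3 = 8
#' eval_h("rayleigh", 3)            # 2x = 6
#' eval_Hinv("weibull", 8, xi = 3)  # 8^(1/3) = 2
#' @export
eval_H <- function(spec, x, xi = numeric(0)) {
  spec <- get_hspec(spec)
  xi <- .check_xi(spec, xi)
  .check_x_support(spec, x, xi)
  out <- spec$H(x, xi)
  if (any(!is.finite(out) & is.finite(x))) {
    # H may legitimately overflow to Inf far in the tail; NaN is an error
    if (any(is.nan(out))) {
      stop(sprintf("H for baseline '%s' returned NaN", spec$name),
           call. = FALSE)
    }
  }
  out
}

#' @rdname eval_H
#' @export
eval_h <- function(spec, x, xi = numeric(0)) {
  spec <- get_hspec(spec)
  xi <- .check_xi(spec, xi)
  .check_x_support(spec, x, xi)
  if (is.null(spec$h)) {
    warning(sprintf(
      "baseline '%s' has no analytic derivative; using central finite %s",
      spec$name, "differences of H"), call. = FALSE)
    eps <- pmax(1e-7, 1e-7 * abs(x))
    return((spec$H(x + eps, xi) - spec$H(x - eps, xi)) / (2 * eps))
  }
  spec$h(x, xi)
}

#' @rdname eval_H
#' @export
eval_Hinv <- function(spec, t, xi = numeric(0)) {
  spec <- get_hspec(spec)
  xi <- .check_xi(spec, xi)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("'t' must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(spec$Hinv)) {
    return(spec$Hinv(t, xi))
  }
  .invert_H(spec, t, xi)
}

# Safeguarded numeric inversion of H: geometric bracket expansion inside
# [1e-12, 1e12], then Brent root isolation to absolute tolerance 1e-12.
.invert_H <- function(spec, t, xi, xtol = 1e-12) {
  xmin <- spec$x_min(xi)
  vapply(t, function(ti) {
    if (ti == 0) return(xmin)
    lo <- if (xmin > 0) xmin * (1 + 1e-9) else 1e-12
    # shrink lo until H(lo) <= ti (H -> 0 near the lower support endpoint)
    k <- 0
    while (spec$H(lo, xi) > ti && k < 400) {
      lo <- if (xmin > 0) xmin + (lo - xmin) / 10 else lo / 10
      k <- k + 1
    }
    hi <- max(1, 2 * lo)
    k <- 0
    while (spec$H(hi, xi) < ti && k < 60) {
      hi <- hi * 10
      k <- k + 1
    }
    if (spec$H(hi, xi) < ti || spec$H(lo, xi) > ti) {
      stop(sprintf(
        "baseline '%s': t = %g is not invertible within the bracket [%g, %g]",
        spec$name, ti, lo, hi), call. = FALSE)
    }
    r <- uniroot(function(x) spec$H(x, xi) - ti, lower = lo, upper = hi,
                 tol = xtol)$root
    # Newton polish: the absolute x-tolerance above is loose relative to
    # roots many orders of magnitude below 1
    if (!is.null(spec$h)) {
      for (k in 1:4) {
        step <- (spec$H(r, xi) - ti) / spec$h(r, xi)
        if (!is.finite(step)) break
        rn <- r - step
        if (rn <= lo || rn >= hi) break
        r <- rn
      }
    }
    r
  }, numeric(1))
}
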