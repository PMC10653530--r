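# Maximum-likelihood fitting with a single interface for the five family
# members and the six competitor distributions.
#
# Two-parameter models are maximized by quasi-Newton (BFGS) iteration on an
# unconstrained scale (logit for unit-interval parameters, log for positive
# ones); standard errors come from the central finite-difference observed
# information of the log-likelihood at the optimum on the NATURAL scale
# (step max(1e-5, 1e-5|theta_j|)), matching direct-scale Wald intervals.
# The unit ratio-Rayleigh member uses the closed-form estimator and its
# analytic observed information: no iteration at all.

.unit_model_ids <- c("urg", "urbxii", "url", "urw", "urr",
                     "beta", "kw", "ug", "ubs", "uw", "cuw")

#' Model identifiers understood by the fitting interface
#'
#' @return Character vector of model ids: the five family members
#'   (`urg`, `urbxii`, `url`, `urw`, `urr`) followed by the six
#'   competitors (`beta`, `kw`, `ug`, `ubs`, `uw`, `cuw`).
#' @examples
#' unit_models()
#' @export
unit_models <- function() .unit_model_ids

# Sum of log densities for a model at natural-scale parameters.
.logdens_sum <- function(model, par, y, tau) {
  switch(model,
    urg    = urg_loglik(par[2], par[1], y, tau),
    urbxii = sum(durbxii(y, par[1], par[2], tau, log = TRUE)),
    url    = sum(durl(y, par[1], par[2], tau, log = TRUE)),
    urw    = sum(durw(y, par[1], par[2], tau, log = TRUE)),
    urr    = sum(durr(y, par[1], tau, log = TRUE)),
    beta   = sum(dbetamu(y, par[1], par[2], log = TRUE)),
    kw     = sum(dkw(y, par[1], par[2], tau, log = TRUE)),
    ug     = sum(dug(y, par[1], par[2], log = TRUE)),
    ubs    = sum(dubs(y, par[1], par[2], log = TRUE)),
    uw     = sum(duw(y, par[1], par[2], tau, log = TRUE)),
    cuw    = sum(dcuw(y, par[1], par[2], log = TRUE)),
    stop("unknown model '", model, "'", call. = FALSE))
}

# Fitted cdf factory, used by the goodness-of-fit ranking.
.model_cdf <- function(model, par, tau = 0.5) {
  force(par); force(tau)
  switch(model,
    urg    = function(y) purg(y, par[1], par[2], tau),
    urbxii = function(y) purbxii(y, par[1], par[2], tau),
    url    = function(y) purl(y, par[1], par[2], tau),
    urw    = function(y) purw(y, par[1], par[2], tau),
    urr    = function(y) purr(y, par[1], tau),
    beta   = function(y) pbetamu(y, par[1], par[2]),
    kw     = function(y) pkw(y, par[1], par[2], tau),
    ug     = function(y) pug(y, par[1], par[2]),
    ubs    = function(y) pubs(y, par[1], par[2]),
    uw     = function(y) puw(y, par[1], par[2], tau),
    cuw    = function(y) pcuw(y, par[1], par[2]),
    stop("unknown model '", model, "'", call. = FALSE))
}

# Parameter metadata: names, which are unit-interval, starting values.
# Starts follow the standard recipe: 1 for the shape/precision parameter,
# the sample mean for mean-indexed models, the sample tau-quantile for
# quantile-parametrized ones.
.model_pars <- function(model, y, tau) {
  qy <- unname(quantile(y, tau))
  switch(model,
    urg    = ,
    urbxii = ,
    url    = ,
    urw    = list(names = c("mu", "beta"), unit = c(TRUE, FALSE),
                  start = c(qy, 1)),
    urr    = list(names = "mu", unit = TRUE, start = qy),
    beta   = list(names = c("mu", "phi"), unit = c(TRUE, FALSE),
                  start = c(mean(y), 1)),
    ug     = list(names = c("mu", "phi"), unit = c(TRUE, FALSE),
                  start = c(mean(y), 1)),
    kw     = list(names = c("mu", "phi"), unit = c(TRUE, FALSE),
                  start = c(qy, 1)),
    ubs    = list(names = c("alpha", "beta"), unit = c(FALSE, FALSE),
                  start = c(1, 1)),
    uw     = ,
    cuw    = list(names = c("mu", "beta"), unit = c(TRUE, FALSE),
                  start = c(qy, 1)),
    stop("unknown model '", model, "'", call. = FALSE))
}

.to_trans <- function(par, unit) {
  ifelse(unit, qlogis(par), log(par))
}

.to_natural <- function(pt, unit) {
  out <- ifelse(unit, plogis(pt), exp(pt))
  # keep strictly inside the admissible region during line searches
  out[unit] <- pmin(pmax(out[unit], 1e-12), 1 - 1e-12)
  out[!unit] <- pmin(pmax(out[!unit], 1e-300), 1e300)
  out
}

# Natural-scale observed information by central finite differences, with
# steps shrunk so unit-interval parameters stay inside (0, 1).
.observed_info <- function(f, est, unit) {
  h <- pmax(1e-5, 1e-5 * abs(est))
  h[unit] <- pmin(h[unit], est[unit] / 3, (1 - est[unit]) / 3)
  -.num_hessian(f, est, h)
}

# Fast dedicated unit ratio-Gompertz fitter (used by the Monte Carlo
# harness, where it is called tens of thousands of times).
.fit_urg_fast <- function(y, tau = 0.5, level = 0.95, se = TRUE,
                          init = NULL) {
  n <- length(y)
  xx <- y / (1 - y)
  c0 <- -log1p(-tau)
  sx <- sum(xx)
  sly <- sum(log1p(-y))
  nll <- function(pt) {
    mu <- plogis(pt[1])
    b <- exp(pt[2])
    if (mu <= 0 || mu >= 1 || !is.finite(b) || b <= 0) return(1e10)
    m <- mu / (1 - mu)
    lEm <- lexpm1(b * m)
    v <- -(n * log(b) + n * log(c0) + b * sx - 2 * sly - n * lEm -
             c0 * sum(exp(lexpm1(b * xx) - lEm)))
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(pt) {
    mu <- plogis(pt[1])
    b <- exp(pt[2])
    m <- mu / (1 - mu)
    lEm <- lexpm1(b * m)
    r <- exp(lexpm1(b * xx) - lEm)
    s <- exp(b * xx - lEm)
    em <- 1 / (-expm1(-b * m))
    U_b <- n / b + sx - n * m * em + c0 * m * em * sum(r) - c0 * sum(xx * s)
    U_m <- b * em / (1 - mu)^2 * (-n + c0 * sum(r))
    g <- -c(U_m * mu * (1 - mu), U_b * b)
    if (any(!is.finite(g))) g[] <- 0
    g
  }
  start <- if (is.null(init)) c(unname(quantile(y, tau)), 1) else init
  pt0 <- c(qlogis(start[1]), log(start[2]))
  opt <- tryCatch(
    optim(pt0, nll, gr, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    return(list(est = c(NA_real_, NA_real_), se = c(NA_real_, NA_real_),
                ll = NA_real_, converged = FALSE, vcov = NULL,
                optim = opt))
  }
  est <- c(plogis(opt$par[1]), exp(opt$par[2]))
  conv <- opt$convergence == 0
  se_v <- c(NA_real_, NA_real_)
  vcov <- NULL
  if (se) {
    f_nat <- function(th) {
      v <- tryCatch(urg_loglik(th[2], th[1], y, tau),
                    error = function(e) NaN)
      if (is.finite(v)) v else NaN
    }
    J <- tryCatch(.observed_info(f_nat, est, unit = c(TRUE, FALSE)),
                  error = function(e) NULL)
    vcov <- if (!is.null(J)) tryCatch(solve(J), error = function(e) NULL)
    if (!is.null(vcov) && all(is.finite(diag(vcov))) &&
        all(diag(vcov) > 0)) {
      se_v <- sqrt(diag(vcov))
    } else {
      conv <- FALSE  # non-positive-definite observed information
    }
  }
  list(est = setNames(est, c("mu", "beta")),
       se = setNames(se_v, c("mu", "beta")),
       ll = -opt$value, converged = conv, vcov = vcov,
       optim = opt[c("convergence", "counts")])
}

#' Fit a unit distribution by maximum likelihood
#'
#' Fits any model in [unit_models()] to a sample on (0, 1).  Two-parameter
#' models are maximized by the quasi-Newton BFGS algorithm with starting
#' values 1 for the shape (or precision) parameter and the sample
#' mean/quantile for the location; the unit ratio-Rayleigh member uses the
#' closed-form estimator ([closed_form_mu()]) and its analytic observed
#' information ([urr_observed_info()]) with no iteration.  Standard errors
#' and level-`level` Wald intervals come from the inverse of the numeric
#' observed-information matrix at the optimum, on the natural parameter
#' scale.
#'
#' @param model a model id from [unit_models()].
#' @param y observations: numeric vector or [unit_sample()] strictly in
#'   (0, 1).
#' @param tau fixed quantile level for quantile-parametrized models.
#' @param init optional natural-scale starting values (location, shape).
#' @param level confidence level for the Wald intervals.
#' @return An object of class \code{"urew_fit"}: a list with elements
#'   `model`, `estimates`, `se`, `ci`, `loglik`, `converged`, `n`, `tau`,
#'   `level`, `vcov` and `optim` (optimizer diagnostics).
#' @examples
#' set.seed(7)
#' y <- rurr(200, mu = 0.17)
#' fit_mle("urr", y)
#' @export
fit_mle <- function(model, y, tau = 0.5, init = NULL, level = 0.95) {
  model <- match.arg(model, .unit_model_ids)
  y <- .unit_values(y)
  n <- length(y)
  n_min <- if (model == "urr") 2L else 3L
  if (n < n_min) {
    stop(sprintf("model '%s' needs at least %d observations", model, n_min),
         call. = FALSE)
  }
  if (var(y) == 0) {
    stop("degenerate sample: all observations identical; the likelihood ",
         "has no interior maximum", call. = FALSE)
  }
  z <- .z_crit(level)

  if (model == "urr") {
    mu_hat <- closed_form_mu("rayleigh", y = y, tau = tau)
    info <- urr_observed_info(mu_hat, y, tau)
    se <- sqrt(-1 / info)
    est <- c(mu = mu_hat)
    ses <- c(mu = se)
    ci <- cbind(lower = est - z * ses, upper = est + z * ses)
    out <- list(model = model, estimates = est, se = ses, ci = ci,
                loglik = sum(durr(y, mu_hat, tau, log = TRUE)),
                converged = TRUE, n = n, tau = tau, level = level,
                vcov = matrix(-1 / info, 1, 1,
                              dimnames = list("mu", "mu")),
                optim = list(method = "closed-form"))
    class(out) <- "urew_fit"
    return(out)
  }

  if (model == "urg") {
    ft <- .fit_urg_fast(y, tau, level, se = TRUE, init = init)
    ci <- cbind(lower = ft$est - z * ft$se, upper = ft$est + z * ft$se)
    out <- list(model = model, estimates = ft$est, se = ft$se, ci = ci,
                loglik = ft$ll, converged = ft$converged, n = n, tau = tau,
                level = level, vcov = ft$vcov, optim = ft$optim)
    class(out) <- "urew_fit"
    return(out)
  }

  meta <- .model_pars(model, y, tau)
  start <- if (is.null(init)) meta$start else init
  nll <- function(pt) {
    par <- .to_natural(pt, meta$unit)
    v <- tryCatch(.logdens_sum(model, par, y, tau),
                  error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  pt0 <- .to_trans(start, meta$unit)
  # non-finite likelihood at the start: retry from perturbed starts
  tries <- 0
  while (nll(pt0) >= 1e10 && tries < 5) {
    tries <- tries + 1
    message(sprintf(
      "model '%s': non-finite log-likelihood at the starting values; %s",
      model, sprintf("retrying from a perturbed start (%d)", tries)))
    pt0 <- pt0 + stats::rnorm(length(pt0), sd = 0.25)
  }
  opt <- tryCatch(
    optim(pt0, nll, method = "BFGS",
          control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    out <- list(model = model,
                estimates = setNames(rep(NA_real_, length(meta$names)),
                                     meta$names),
                se = setNames(rep(NA_real_, length(meta$names)), meta$names),
                ci = NULL, loglik = NA_real_, converged = FALSE, n = n,
                tau = tau, level = level, vcov = NULL,
                optim = list(convergence = NA_integer_,
                             note = "optimizer failure"))
    class(out) <- "urew_fit"
    return(out)
  }
  est <- setNames(.to_natural(opt$par, meta$unit), meta$names)
  conv <- opt$convergence == 0
  f_nat <- function(th) {
    v <- tryCatch(.logdens_sum(model, th, y, tau), error = function(e) NaN)
    if (is.finite(v)) v else NaN
  }
  J <- tryCatch(.observed_info(f_nat, unname(est), meta$unit),
                error = function(e) NULL)
  vcov <- if (!is.null(J)) tryCatch(solve(J), error = function(e) NULL)
  ses <- setNames(rep(NA_real_, length(est)), meta$names)
  if (!is.null(vcov) && all(is.finite(diag(vcov))) && all(diag(vcov) > 0)) {
    ses <- setNames(sqrt(diag(vcov)), meta$names)
    dimnames(vcov) <- list(meta$names, meta$names)
  } else {
    vcov <- NULL
    warning(sprintf(
      "model '%s': singular or non-positive-definite observed information; %s",
      model, "standard errors undefined"), call. = FALSE)
  }
  ci <- cbind(lower = est - z * ses, upper = est + z * ses)
  out <- list(model = model, estimates = est, se = ses, ci = ci,
              loglik = -opt$value, converged = conv && !is.null(vcov),
              n = n, tau = tau, level = level, vcov = vcov,
              optim = c(opt[c("convergence", "counts")],
                        list(restarts = tries)))
  class(out) <- "urew_fit"
  out
}

#' @export
print.urew_fit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit: %s  (n = %d, tau = %g)\n",
              x$model, x$n, x$tau))
  tab <- cbind(estimate = x$estimates, `std.error` = x$se)
  if (!is.null(x$ci)) tab <- cbind(tab, x$ci)
  print(round(tab, 4))
  cat(sprintf("logLik = %.4f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
as.list.urew_fit <- function(x, ...) {
  list(model = x$model, estimates = as.list(x$estimates),
       std_errors = as.list(x$se),
       ci = if (!is.null(x$ci)) {
         setNames(lapply(seq_len(nrow(x$ci)), function(i) unname(x$ci[i, ])),
                  rownames(x$ci))
       },
       loglik = x$loglik, converged = x$converged, n = x$n, tau = x$tau,
       level = x$level)
}
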