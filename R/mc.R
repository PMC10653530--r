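# Monte Carlo harness for the sampling behavior of the estimators.
#
# Column conventions: two bias/error conventions are computed side by side.
#   rb100        = 100 * (mean - truth)        (absolute bias x 100)
#   mse          = variance + (mean - truth)^2
#   rel_bias_pct = 100 * (mean - truth)/truth  (textbook relative bias)
#   rmse         = sqrt(mse)                   (textbook root-MSE)
# The first pair is the convention used in the simulation tables this
# harness reproduces; the second is the textbook reading of the same
# column names.  `cp` is the fraction of level-`ci_level` Wald intervals
# covering the truth; failed fits are dropped and counted.

#' Run one Monte Carlo scenario
#'
#' Simulates `reps` samples of size `n` from a unit ratio-Rayleigh
#' (`model = "urr"`) or unit ratio-Gompertz (`model = "urg"`) law by
#' inversion, fits each sample with the model's estimator (closed form for
#' the former, quasi-Newton with starting values sample-quantile/1 for the
#' latter) and aggregates per-parameter summaries: mean, variance, both
#' bias conventions, both error conventions, and empirical Wald-interval
#' coverage.
#'
#' @param model `"urr"` or `"urg"`.
#' @param mu true quantile parameter in (0, 1).
#' @param beta true shape parameter (`"urg"` only).
#' @param n sample size per replication (>= 2).
#' @param reps number of Monte Carlo replications.
#' @param tau fixed quantile level.
#' @param ci_level confidence level of the Wald intervals.
#' @param seed integer seed; the whole scenario is reproducible from it.
#' @return A data.frame with one row per parameter and columns `model`,
#'   `mu_true`, `beta_true`, `n`, `reps`, `parameter`, `truth`, `mean`,
#'   `variance`, `rb100`, `mse`, `rel_bias_pct`, `rmse`, `cp`,
#'   `n_failed`, `flagged` (`TRUE` when more than 1\% of fits failed).
#' @examples
#' run_scenario("urr", mu = 0.4, n = 50, reps = 200, seed = 1)
#' @export
run_scenario <- function(model = c("urr", "urg"), mu, beta = NULL, n,
                         reps = 10000, tau = 0.5, ci_level = 0.95,
                         seed = 1L) {
  model <- match.arg(model)
  .check_prob(mu, "mu")
  .check_prob(tau, "tau")
  stopifnot(n >= 2, reps >= 1)
  if (model == "urg") .check_pos(beta, "beta")
  z <- .z_crit(ci_level)
  set.seed(as.integer(seed))

  if (model == "urr") {
    cc <- -log1p(-tau)
    m <- mu / (1 - mu)
    u <- matrix(runif(reps * n), reps, n)
    yy <- matrix(qurr(c(u), mu, tau), reps, n)
    S <- rowSums((yy / (1 - yy))^2)
    g <- sqrt(cc * S / n)
    muh <- g / (1 + g)
    info <- 2 / muh^4 *
      (n * muh^2 * (1 - 2 * muh) / (1 - muh)^2 + (2 * muh - 3) * cc * S)
    se <- sqrt(-1 / info)
    cover <- (muh - z * se <= mu) & (mu <= muh + z * se)
    est <- matrix(muh, ncol = 1, dimnames = list(NULL, "mu"))
    covm <- matrix(cover, ncol = 1, dimnames = list(NULL, "mu"))
    truth <- c(mu = mu)
    failed <- 0L
  } else {
    est <- matrix(NA_real_, reps, 2, dimnames = list(NULL, c("mu", "beta")))
    covm <- matrix(NA, reps, 2, dimnames = list(NULL, c("mu", "beta")))
    truth <- c(mu = mu, beta = beta)
    for (r in seq_len(reps)) {
      yy <- qurg(runif(n), mu, beta, tau)
      ft <- .fit_urg_fast(yy, tau, ci_level, se = TRUE)
      if (isTRUE(ft$converged)) {
        est[r, ] <- ft$est
        covm[r, ] <- (ft$est - z * ft$se <= truth) &
          (truth <= ft$est + z * ft$se)
      }
    }
    keep <- !is.na(est[, 1])
    failed <- sum(!keep)
    est <- est[keep, , drop = FALSE]
    covm <- covm[keep, , drop = FALSE]
  }

  rows <- lapply(colnames(est), function(p) {
    e <- est[, p]
    mn <- mean(e)
    vr <- var(e)
    bias <- mn - truth[[p]]
    data.frame(model = model, mu_true = mu,
               beta_true = if (model == "urg") beta else NA_real_,
               n = n, reps = reps, parameter = p, truth = truth[[p]],
               mean = mn, variance = vr,
               rb100 = 100 * bias, mse = vr + bias^2,
               rel_bias_pct = 100 * bias / truth[[p]],
               rmse = sqrt(vr + bias^2),
               cp = mean(covm[, p]),
               n_failed = failed,
               flagged = failed > 0.01 * reps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run a batch of Monte Carlo scenarios
#'
#' Applies [run_scenario()] to every row of a scenario table and stacks
#' the results in long format, keyed by (scenario, parameter, n).  Also
#' computes, per scenario and sample size, the totals used in the summary
#' curves: the sum of `|rb100|` and of `mse` across parameters.
#'
#' @param scenarios a data.frame with columns `model`, `mu`, `n`, and
#'   optionally `beta` (required for `"urg"` rows) and `scenario` labels.
#' @param reps replications per scenario.
#' @param tau fixed quantile level.
#' @param ci_level Wald confidence level.
#' @param seed base integer seed; scenario i uses `seed + i` so each row
#'   is independently reproducible.
#' @return A list with elements `cells` (long results) and `totals`
#'   (per scenario x n: `total_abs_rb100`, `total_mse`).
#' @examples
#' sc <- data.frame(model = "urr", mu = c(0.25, 0.4), n = 50)
#' run_table(sc, reps = 200, seed = 1)$totals
#' @export
run_table <- function(scenarios, reps = 10000, tau = 0.5, ci_level = 0.95,
                      seed = 1L) {
  stopifnot(is.data.frame(scenarios), nrow(scenarios) >= 1,
            all(c("model", "mu", "n") %in% names(scenarios)))
  if (is.null(scenarios$beta)) scenarios$beta <- NA_real_
  if (is.null(scenarios$scenario)) {
    key <- paste(scenarios$model, scenarios$mu, scenarios$beta)
    scenarios$scenario <- as.integer(factor(key, levels = unique(key)))
  }
  cells <- do.call(rbind, lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    out <- run_scenario(sc$model, mu = sc$mu,
                        beta = if (is.na(sc$beta)) NULL else sc$beta,
                        n = sc$n, reps = reps, tau = tau,
                        ci_level = ci_level, seed = as.integer(seed) + i)
    out$scenario <- sc$scenario
    out
  }))
  totals <- do.call(rbind, lapply(
    split(cells, list(cells$scenario, cells$n), drop = TRUE),
    function(d) {
      data.frame(scenario = d$scenario[1], n = d$n[1],
                 total_abs_rb100 = sum(abs(d$rb100)),
                 total_mse = sum(d$mse))
    }))
  totals <- totals[order(totals$scenario, totals$n), ]
  rownames(totals) <- NULL
  list(cells = cells, totals = totals)
}
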