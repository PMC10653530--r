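# Corrected Cramer-von Mises goodness of fit.

#' Corrected Cramér–von Mises statistic
#'
#' Computes the small-sample-corrected Cramér–von Mises statistic
#' \eqn{W^* = W^2 (1 + 0.5/n)} on probability-integral-transformed data,
#' where, with \eqn{u_{(i)}} the sorted fitted-cdf values,
#' \deqn{W^2 = \frac{1}{12n} + \sum_{i=1}^n
#'   \Big[u_{(i)} - \frac{2i-1}{2n}\Big]^2.}
#' Smaller values indicate better fit; the attainable minimum is
#' \eqn{(1/(12n))(1 + 0.5/n)}, reached when the \eqn{u_{(i)}} sit exactly
#' at the plotting positions.  The statistic is evaluated at the fitted
#' (maximum-likelihood) parameters; no p-value is attached.
#'
#' @param y observations (numeric vector or [unit_sample()]); ignored when
#'   `u` is supplied directly.
#' @param cdf fitted cdf: a function mapping (0,1) values to probabilities.
#' @param u optionally, the probability-integral transforms themselves.
#' @return The statistic \eqn{W^*} (a single nonnegative number).
#' @examples
#' cvm_star(u = c(0.25, 0.5, 0.75))       # 7/144
#' set.seed(1)
#' y <- rurr(100, mu = 0.3)
#' f <- fit_mle("urr", y)
#' cvm_star(y, cdf = function(z) purr(z, f$estimates["mu"]))
#' @export
cvm_star <- function(y = NULL, cdf = NULL, u = NULL) {
  if (is.null(u)) {
    if (is.null(y) || is.null(cdf)) {
      stop("supply either 'u' or both 'y' and 'cdf'", call. = FALSE)
    }
    y <- .unit_values(y)
    u <- cdf(y)
  }
  n <- length(u)
  if (n < 1) stop("empty sample", call. = FALSE)
  bad <- which(!is.finite(u) | u <= 0 | u >= 1)
  if (length(bad)) {
    stop("fitted cdf outside (0, 1) at observation index ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  us <- sort(u)
  i <- seq_len(n)
  W2 <- 1 / (12 * n) + sum((us - (2 * i - 1) / (2 * n))^2)
  W2 * (1 + 0.5 / n)
}

#' Rank fitted models by goodness of fit
#'
#' Orders a set of goodness-of-fit reports on the same sample by ascending
#' \eqn{W^*} (smaller is better) and assigns ranks 1..K.  Ties are broken
#' by lexicographic model id, which is recorded so rankings are
#' reproducible.
#'
#' @param reports a data.frame with columns `model`, `w_star` and `n`
#'   (one row per fitted model, all on the same sample).
#' @return The data.frame sorted by `w_star` with a `rank` column added.
#' @examples
#' rank_models(data.frame(model = c("a", "b", "c"),
#'                        w_star = c(0.3, 0.1, 0.2), n = 50))
#' @export
rank_models <- function(reports) {
  if (!is.data.frame(reports) ||
      !all(c("model", "w_star", "n") %in% names(reports))) {
    stop("'reports' must be a data.frame with columns model, w_star, n",
         call. = FALSE)
  }
  if (nrow(reports) < 2) {
    stop("need at least two models to rank", call. = FALSE)
  }
  if (length(unique(reports$n)) != 1) {
    stop("all reports must refer to the same sample size", call. = FALSE)
  }
  ord <- order(reports$w_star, reports$model)
  out <- reports[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
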