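# Built-in extended-Weibull baseline catalog.
#
# Each entry is the generator triple (H, h, Hinv) of a classical lifetime
# model.  Notes on two deliberate corrections of commonly mistyped forms:
#   * burr_xii / log_logistic: H(x) = log(1 + x^b) with inverse
#     [exp(t) - 1]^(1/b) (a negative sign inside the log would make H
#     undefined for x > 0 and is inconsistent with the unit ratio-Burr XII
#     cdf this baseline must induce).
#   * The Frechet generator x^(-y) is decreasing with negative derivative,
#     so it is not an admissible H and is not registered.
#
# Two Gompertz forms are provided: "gompertz" with H = [exp(bx) - 1]/b and
# "gompertz_std" with H = exp(bx) - 1.  They induce the same two-parameter
# family (the 1/b factor is absorbed by the rate a); the unit ratio-Gompertz
# closed forms use the standard (unscaled) one.

.builtin_hspecs <- function() {
  list(
    hspec("exponential", character(0),
          H = function(x, xi) x,
          h = function(x, xi) rep(1, length(x)),
          Hinv = function(t, xi) t),
    hspec("rayleigh", character(0),
          H = function(x, xi) x^2,
          h = function(x, xi) 2 * x,
          Hinv = function(t, xi) sqrt(t)),
    hspec("weibull", "y",
          H = function(x, xi) x^xi[1],
          h = function(x, xi) xi[1] * x^(xi[1] - 1),
          Hinv = function(t, xi) t^(1 / xi[1])),
    hspec("gompertz", "beta",
          H = function(x, xi) expm1(xi[1] * x) / xi[1],
          h = function(x, xi) exp(xi[1] * x),
          Hinv = function(t, xi) log1p(xi[1] * t) / xi[1]),
    hspec("gompertz_std", "beta",
          H = function(x, xi) expm1(xi[1] * x),
          h = function(x, xi) xi[1] * exp(xi[1] * x),
          Hinv = function(t, xi) log1p(t) / xi[1]),
    hspec("burr_xii", "beta",
          H = function(x, xi) log1p(x^xi[1]),
          h = function(x, xi) xi[1] * x^(xi[1] - 1) / (1 + x^xi[1]),
          Hinv = function(t, xi) expm1(t)^(1 / xi[1])),
    hspec("log_logistic", "c",
          H = function(x, xi) log1p(x^xi[1]),
          h = function(x, xi) xi[1] * x^(xi[1] - 1) / (1 + x^xi[1]),
          Hinv = function(t, xi) expm1(t)^(1 / xi[1])),
    hspec("lomax", "beta",
          H = function(x, xi) log1p(x / xi[1]),
          h = function(x, xi) 1 / (xi[1] + x),
          Hinv = function(t, xi) xi[1] * expm1(t)),
    hspec("chen", "b",
          H = function(x, xi) expm1(x^xi[1]),
          h = function(x, xi) xi[1] * x^(xi[1] - 1) * exp(x^xi[1]),
          Hinv = function(t, xi) log1p(t)^(1 / xi[1])),
    hspec("exponential_power", c("lambda", "beta"),
          H = function(x, xi) expm1((xi[1] * x)^xi[2]),
          h = function(x, xi) {
            xi[2] * xi[1] * (xi[1] * x)^(xi[2] - 1) * exp((xi[1] * x)^xi[2])
          },
          Hinv = function(t, xi) log1p(t)^(1 / xi[2]) / xi[1]),
    hspec("flexible_weibull", c("lambda", "beta"),
          H = function(x, xi) exp(xi[1] * x - xi[2] / x),
          h = function(x, xi) {
            exp(xi[1] * x - xi[2] / x) * (xi[1] + xi[2] / x^2)
          },
          Hinv = NULL),  # no closed form; numeric bracketing
    hspec("linear_failure_rate", c("a", "b"),
          H = function(x, xi) xi[1] * x + xi[2] * x^2 / 2,
          h = function(x, xi) xi[1] + xi[2] * x,
          Hinv = NULL),
    hspec("additive_weibull", c("alpha1", "alpha2", "beta1", "beta2"),
          H = function(x, xi) (x / xi[3])^xi[1] + (x / xi[4])^xi[2],
          h = function(x, xi) {
            (xi[1] / xi[3]) * (x / xi[3])^(xi[1] - 1) +
              (xi[2] / xi[4]) * (x / xi[4])^(xi[2] - 1)
          },
          Hinv = NULL),
    hspec("modified_weibull", c("y", "lambda"),
          H = function(x, xi) x^xi[1] * exp(xi[2] * x),
          h = function(x, xi) {
            x^(xi[1] - 1) * exp(xi[2] * x) * (xi[1] + xi[2] * x)
          },
          Hinv = NULL),
    hspec("power_generalized_weibull", c("alpha1", "beta", "theta"),
          H = function(x, xi) (1 + (x / xi[2])^xi[1])^xi[3] - 1,
          h = function(x, xi) {
            (xi[3] * xi[1] / xi[2]) * (1 + (x / xi[2])^xi[1])^(xi[3] - 1) *
              (x / xi[2])^(xi[1] - 1)
          },
          Hinv = function(t, xi) {
            xi[2] * ((t + 1)^(1 / xi[3]) - 1)^(1 / xi[1])
          }),
    hspec("pareto", "k",
          H = function(x, xi) log(x / xi[1]),
          h = function(x, xi) 1 / x,
          Hinv = function(t, xi) xi[1] * exp(t),
          x_min = function(xi) xi[1],
          support_note = paste(
            "requires x > k; the induced unit variable is supported on",
            "(k/(1+k), 1)"))
  )
}

.register_builtins <- function() {
  for (sp in .builtin_hspecs()) {
    register_hspec(sp, overwrite = TRUE)
  }
}

.onLoad <- function(libname, pkgname) {
  .register_builtins()
}
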