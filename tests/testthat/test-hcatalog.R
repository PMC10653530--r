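# Baseline generator catalog: derivative consistency, inversion
# round-trips, monotonicity, and the registration contract.

test_that("catalog derivative h matches finite differences of H", {
  for (nm in hspec_catalog()) {
    xi <- catalog_test_xi[[nm]]
    sp <- get_hspec(nm)
    xmin <- sp$x_min(xi)
    grid <- xmin + 10^seq(-2, 1, length.out = 25)
    fd <- central_diff(function(x) eval_H(sp, x, xi), grid,
                       h = 1e-6 * pmax(1, abs(grid)))
    expect_lt(max(rel_err(eval_h(sp, grid, xi), fd)), 1e-5,
              label = sprintf("'%s' h vs finite differences", nm))
  }
})

test_that("H(Hinv(t)) = t round-trips for every catalog entry", {
  ts <- c(1e-6, 1e-3, 0.1, 1, 10, 50)
  for (nm in hspec_catalog()) {
    xi <- catalog_test_xi[[nm]]
    x <- eval_Hinv(nm, ts, xi)
    expect_lt(max(rel_err(eval_H(nm, x, xi), ts)), 1e-8,
              label = sprintf("'%s' inversion round-trip", nm))
  }
})

test_that("H is strictly increasing and h positive on the support", {
  for (nm in hspec_catalog()) {
    xi <- catalog_test_xi[[nm]]
    sp <- get_hspec(nm)
    grid <- sp$x_min(xi) + 10^seq(-3, 1.5, length.out = 40)
    Hv <- eval_H(sp, grid, xi)
    expect_true(all(diff(Hv) > 0), label = sprintf("'%s' monotone", nm))
    expect_true(all(eval_h(sp, grid, xi) > 0),
                label = sprintf("'%s' h positive", nm))
  }
})

test_that("catalog entries evaluate to their textbook values", {
  expect_equal(eval_H("weibull", 2, xi = 3), 8)
  expect_equal(eval_H("rayleigh", 1), 1)
  expect_equal(eval_h("rayleigh", 3), 6)
  expect_equal(eval_h("weibull", 1, xi = 5), 5)
  # Lomax H = log(1 + x/beta) inverts the exponential at x = beta (e - 1)
  expect_equal(eval_H("lomax", 2 * (exp(1) - 1), xi = 2), 1)
  expect_equal(eval_Hinv("weibull", 8, xi = 3), 2)
  # Gompertz table form: Hinv(t = (e-1)/beta) at beta = 1 is 1
  expect_equal(eval_Hinv("gompertz", exp(1) - 1, xi = 1), 1)
})

test_that("decreasing-generator baselines are not in the catalog", {
  expect_false("frechet" %in% hspec_catalog())
  expect_error(get_hspec("frechet"), "unknown baseline")
})

test_that("the two Gompertz forms induce the same quantile-parametrized law", {
  # the 1/beta scale factor is absorbed by the rate, so the quantile
  # parametrization makes them identical
  y <- seq(0.05, 0.95, by = 0.05)
  for (b in c(0.5, 1.7)) {
    d1 <- urew("gompertz", xi = b, mu = 0.3)
    d2 <- urew("gompertz_std", xi = b, mu = 0.3)
    expect_equal(purew(y, d1), purew(y, d2), tolerance = 1e-12)
    expect_equal(durew(y, d1), durew(y, d2), tolerance = 1e-12)
  }
})

test_that("domain violations are rejected with named constraints", {
  expect_error(eval_H("weibull", -1, xi = 2), "must be > 0")
  expect_error(eval_H("weibull", 1, xi = -2), "'y' must be > 0")
  expect_error(eval_H("weibull", 1, xi = c(1, 2)), "expects 1 shape")
  expect_error(eval_Hinv("weibull", -0.5, xi = 2), ">= 0")
  # Pareto support shift: x must exceed k
  expect_error(eval_H("pareto", 0.3, xi = 0.5), "must be > 0.5")
})

test_that("user baselines register through the hspec contract", {
  cubic <- hspec("test_cubic", character(0),
                 H = function(x, xi) x^3,
                 h = function(x, xi) 3 * x^2,
                 Hinv = function(t, xi) t^(1 / 3))
  register_hspec(cubic)
  expect_true("test_cubic" %in% hspec_catalog())
  expect_equal(eval_H("test_cubic", 2), 8)
  expect_error(register_hspec(cubic), "already registered")
  # the generic engine accepts the new baseline
  d <- urew("test_cubic", mu = 0.4)
  expect_equal(purew(0.4, d), 0.5)
  rm("test_cubic", envir = urew:::.hspec_registry)
})

test_that("missing derivative falls back to finite differences with warning", {
  noh <- hspec("test_noh", character(0), H = function(x, xi) x^2)
  expect_warning(v <- eval_h(noh, 3), "finite")
  expect_equal(v, 6, tolerance = 1e-6)
})

test_that("numeric inversion is used for no-closed-form entries", {
  for (nm in c("additive_weibull", "linear_failure_rate",
               "flexible_weibull", "modified_weibull")) {
    expect_null(get_hspec(nm)$Hinv)
    xi <- catalog_test_xi[[nm]]
    t <- c(0.02, 1.7, 23)
    expect_equal(eval_H(nm, eval_Hinv(nm, t, xi), xi), t,
                 tolerance = 1e-8)
  }
})
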