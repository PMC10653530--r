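# Generic engine: parametrization equivalence, normalization, quantile
# anchoring, inversion sampling.

test_that("alpha_from_quantile reproduces hand-computed rates", {
  expect_equal(alpha_from_quantile(urew("rayleigh", mu = 0.5)), log(2))
  # Weibull shape 1 is the exponential baseline
  expect_equal(alpha_from_quantile(urew("weibull", xi = 1, mu = 0.5)),
               log(2))
  # plugging the implied rate back in anchors the cdf at (mu, tau)
  set.seed(41)
  for (i in 1:5) {
    mu <- runif(1, 0.1, 0.9)
    tau <- runif(1, 0.2, 0.8)
    dq <- urew("burr_xii", xi = 1.5, mu = mu, tau = tau)
    da <- urew("burr_xii", xi = 1.5, alpha = alpha_from_quantile(dq))
    expect_equal(purew(mu, da), tau, tolerance = 1e-12)
  }
})

test_that("rate and quantile parametrizations agree everywhere", {
  y <- seq(0.02, 0.98, by = 0.02)
  set.seed(42)
  for (nm in c("rayleigh", "gompertz_std", "burr_xii", "lomax", "weibull")) {
    xi <- if (nm == "rayleigh") numeric(0) else runif(1, 0.5, 2.5)
    dq <- urew(nm, xi = xi, mu = runif(1, 0.1, 0.9))
    da <- urew(nm, xi = xi, alpha = alpha_from_quantile(dq))
    expect_lt(max(abs(purew(y, dq) - purew(y, da))), 1e-12)
  }
})

test_that("densities integrate to one and differentiate the cdf", {
  set.seed(43)
  for (nm in c("rayleigh", "gompertz_std", "burr_xii", "lomax", "weibull")) {
    for (i in 1:5) {
      xi <- if (nm == "rayleigh") numeric(0) else runif(1, 0.5, 2.5)
      d <- urew(nm, xi = xi, mu = runif(1, 0.15, 0.85),
                tau = runif(1, 0.2, 0.8))
      expect_equal(quad_ratio(function(y) durew(y, d)), 1, tolerance = 1e-6)
      # cdf equals the integral of the density
      yy <- runif(1, 0.2, 0.8)
      expect_equal(quad(function(y) durew(y, d), upper = yy),
                   purew(yy, d), tolerance = 1e-8)
      # density equals the cdf derivative
      expect_equal(durew(yy, d),
                   central_diff(function(y) purew(y, d), yy, h = 1e-6),
                   tolerance = 1e-5)
    }
  }
})

test_that("quantile function inverts the cdf, anchored at (tau, mu)", {
  u <- seq(0.01, 0.99, by = 0.01)
  set.seed(44)
  for (nm in c("rayleigh", "gompertz_std", "burr_xii", "lomax", "weibull",
               "additive_weibull")) {
    xi <- catalog_test_xi[[nm]]
    mu <- runif(1, 0.15, 0.85)
    tau <- runif(1, 0.25, 0.75)
    d <- urew(nm, xi = xi, mu = mu, tau = tau)
    expect_lt(max(abs(purew(qurew(u, d), d) - u)), 1e-9)
    expect_equal(qurew(tau, d), mu, tolerance = 1e-9)
  }
})

test_that("hazard rate equals density over survival", {
  y <- seq(0.05, 0.95, by = 0.05)
  d <- urew("gompertz_std", xi = 1.2, mu = 0.35)
  # compare where the survival has not underflowed (the 1 - cdf oracle
  # cancels catastrophically once the cdf is within ~1e-8 of one)
  sel <- purew(y, d) < 1 - 1e-8
  expect_equal(hurew(y[sel], d),
               durew(y[sel], d) / (1 - purew(y[sel], d)),
               tolerance = 1e-6)
  expect_true(all(hurew(y, d) >= 0))
})

test_that("cdf is pointwise nonincreasing in mu (stochastic ordering)", {
  y <- seq(0.05, 0.95, by = 0.05)
  mus <- seq(0.1, 0.9, by = 0.1)
  for (nm in c("rayleigh", "burr_xii")) {
    xi <- catalog_test_xi[[nm]]
    cdfs <- sapply(mus, function(m) purew(y, urew(nm, xi = xi, mu = m)))
    expect_true(all(apply(cdfs, 1, function(r) all(diff(r) <= 1e-14))))
  }
})

test_that("evaluation at the endpoints is a domain error", {
  d <- urew("rayleigh", mu = 0.4)
  expect_error(durew(0, d), "strictly inside")
  expect_error(purew(1, d), "strictly inside")
  expect_error(qurew(0, d), "strictly inside")
  # cdf limits approach 0 and 1
  expect_lt(purew(1e-8, d), 1e-6)
  expect_gt(purew(1 - 1e-9, d), 1 - 1e-6)
})

test_that("inversion sampling matches the law and is reproducible", {
  d <- urew("weibull", xi = 1.6, mu = 0.3)
  set.seed(101)
  y <- rurew(10000, d)
  expect_true(all(y > 0 & y < 1))
  ks <- suppressWarnings(stats::ks.test(y, function(q) purew(q, d)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(10000))  # 1% critical value
  # empirical tau-quantile near mu
  set.seed(102)
  y2 <- rurew(100000, d)
  expect_lt(abs(unname(quantile(y2, 0.5)) - 0.3), 0.01)
  # determinism under a fixed seed
  set.seed(103)
  a <- rurew(50, d)
  set.seed(103)
  expect_identical(a, rurew(50, d))
})

test_that("degenerate and invalid constructions are rejected", {
  expect_error(urew("rayleigh"), "exactly one of")
  expect_error(urew("rayleigh", mu = 0.5, alpha = 1), "exactly one of")
  expect_error(urew("rayleigh", mu = 1.2), "strictly inside")
  expect_error(urew("rayleigh", alpha = -1), "positive")
  # Pareto support shift: mu below k/(1+k) has H(mu/(1-mu)) undefined
  expect_error(urew("pareto", xi = 1, mu = 0.3), "support shift")
})
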