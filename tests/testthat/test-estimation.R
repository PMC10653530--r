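# Likelihood machinery: analytic forms against summation/finite-difference
# oracles, closed-form estimators against numeric optimization, observed
# information, and the fitting interface.

test_that("family log-likelihood equals the sum of log densities", {
  set.seed(71)
  for (nm in c("rayleigh", "gompertz_std", "lomax")) {
    xi <- catalog_test_xi[[nm]]
    d <- urew(nm, xi = xi, mu = 0.35, tau = 0.4)
    y <- rurew(200, d)
    expect_equal(urew_loglik(d, y), sum(durew(y, d, log = TRUE)),
                 tolerance = 1e-10)
  }
  # single observation at the quantile parameter
  d1 <- urew("rayleigh", mu = 0.3)
  expect_equal(urew_loglik(d1, 0.3), durr(0.3, 0.3, log = TRUE))
  # additivity: duplicating the sample doubles the log-likelihood
  d <- urew("rayleigh", mu = 0.35)
  y <- c(0.1, 0.22, 0.4)
  expect_equal(urew_loglik(d, c(y, y)), 2 * urew_loglik(d, y),
               tolerance = 1e-12)
})

test_that("analytic score in mu matches the numeric gradient", {
  set.seed(72)
  y <- rurr(150, mu = 0.3)
  for (mu in c(0.15, 0.3, 0.6)) {
    d <- urew("rayleigh", mu = mu)
    fd <- central_diff(function(m) {
      urew_loglik(urew("rayleigh", mu = m), y)
    }, mu, h = 1e-6)
    expect_lt(rel_err(urew_score_mu(d, y), fd), 1e-6)
  }
})

test_that("the score vanishes exactly at the closed-form estimate", {
  set.seed(73)
  for (nm in c("rayleigh", "gompertz_std", "burr_xii")) {
    xi <- catalog_test_xi[[nm]]
    d0 <- urew(nm, xi = xi, mu = 0.25)
    y <- rurew(100, d0)
    muh <- closed_form_mu(nm, xi = xi, y = y)
    expect_lt(abs(urew_score_mu(urew(nm, xi = xi, mu = muh), y)), 1e-7)
    # sign change across the root
    expect_gt(urew_score_mu(urew(nm, xi = xi, mu = muh * 0.9), y), 0)
    expect_lt(urew_score_mu(urew(nm, xi = xi, mu = muh * 1.05), y), 0)
  }
})

test_that("closed-form estimate equals the 1-D numeric argmax", {
  set.seed(74)
  for (i in 1:5) {
    y <- rurr(80, mu = runif(1, 0.15, 0.8))
    muh <- closed_form_mu("rayleigh", y = y)
    opt <- optimize(function(m) sum(durr(y, m, log = TRUE)),
                    c(0.01, 0.99), maximum = TRUE, tol = 1e-12)
    expect_lt(abs(muh - opt$maximum), 1e-8)
  }
})

test_that("a sample concentrated at the quantile pins the estimate", {
  # observations with y/(1-y) = (log 2)^(-1/2) force g = 1, mu_hat = 1/2
  x <- 1 / sqrt(log(2))
  y <- rep(x / (1 + x), 10)
  expect_equal(closed_form_mu("rayleigh", y = y), 0.5, tolerance = 1e-14)
})

test_that("the as-printed estimator variant disagrees with the score root", {
  set.seed(75)
  y <- rurr(200, mu = 0.15)
  mu_corr <- closed_form_mu("rayleigh", y = y)
  mu_prnt <- closed_form_mu("rayleigh", y = y, as_printed = TRUE)
  expect_false(isTRUE(all.equal(mu_corr, mu_prnt, tolerance = 1e-3)))
  # the printed variant does not annihilate the score
  expect_gt(abs(urew_score_mu(urew("rayleigh", mu = mu_prnt), y)), 1)
})

test_that("observed information matches the numeric Hessian and is negative", {
  set.seed(76)
  for (i in 1:5) {
    y <- rurr(60, mu = runif(1, 0.2, 0.8))
    muh <- closed_form_mu("rayleigh", y = y)
    I_an <- urr_observed_info(muh, y)
    h <- 1e-4
    ll <- function(m) sum(durr(y, m, log = TRUE))
    I_fd <- (ll(muh + h) - 2 * ll(muh) + ll(muh - h)) / h^2
    expect_lt(rel_err(I_an, I_fd), 1e-4)
    expect_lt(I_an, 0)
    expect_gt(-1 / I_an, 0)  # positive Wald variance
  }
})

test_that("Gompertz-member log-likelihood and score are consistent", {
  set.seed(77)
  y <- rurg(150, 0.4, 0.8)
  for (i in 1:4) {
    b <- runif(1, 0.3, 3)
    mu <- runif(1, 0.2, 0.8)
    expect_equal(urg_loglik(b, mu, y),
                 sum(durg(y, mu, b, log = TRUE)), tolerance = 1e-8)
    num <- c(central_diff(function(t) urg_loglik(t, mu, y), b, h = 1e-6),
             central_diff(function(t) urg_loglik(b, t, y), mu, h = 1e-6))
    expect_lt(max(rel_err(unname(urg_score(b, mu, y)), num)), 1e-5)
  }
  # first-order condition at the optimizer's solution
  ft <- fit_mle("urg", y)
  sc <- urg_score(ft$estimates[["beta"]], ft$estimates[["mu"]], y)
  expect_lt(max(abs(sc)), 0.02 * length(y))
})

test_that("fitting interface: closed-form dispatch and Wald intervals", {
  set.seed(78)
  y <- rurr(300, mu = 0.17)
  ft <- fit_mle("urr", y)
  expect_identical(ft$estimates[["mu"]], closed_form_mu("rayleigh", y = y))
  expect_true(ft$converged)
  # interval half-width uses the 0.975 normal quantile 1.959964
  hw <- unname(ft$ci[1, "upper"] - ft$estimates[["mu"]])
  expect_equal(hw / ft$se[["mu"]], 1.959964, tolerance = 1e-6)
  # estimation is invariant to sample order
  ft2 <- fit_mle("urr", rev(y))
  expect_identical(ft$estimates, ft2$estimates)
  ftg <- fit_mle("urg", y)
  ftg2 <- fit_mle("urg", sample(y))
  expect_equal(ftg$estimates, ftg2$estimates, tolerance = 1e-8)
})

test_that("two-parameter fits recover simulated truth at large n", {
  set.seed(79)
  y <- rurg(10000, 0.5, 1.5)
  ft <- fit_mle("urg", y)
  expect_true(ft$converged)
  expect_lt(abs(ft$estimates[["mu"]] - 0.5), 0.02)
  expect_lt(abs(ft$estimates[["beta"]] - 1.5), 0.1)
})

test_that("bias shrinks with the sample size (consistency)", {
  set.seed(80)
  bias <- sapply(c(10, 100), function(n) {
    muh <- replicate(500, closed_form_mu("rayleigh", y = rurr(n, 0.4)))
    abs(mean(muh) - 0.4)
  })
  expect_lt(bias[2], bias[1])
})
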