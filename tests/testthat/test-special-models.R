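# Named closed-form models against the generic plug-in engine, plus the
# model identities (URW with shape 2 = URR; URBXII and URL coincide at
# shape 1) and shape properties.

test_that("closed forms agree with the generic engine to 1e-12", {
  y <- seq(0.001, 0.999, length.out = 1000)
  set.seed(51)
  pars <- draw_named_params(5)
  for (nm in names(named_model_table())) {
    mt <- named_model_table()[[nm]]
    for (i in seq_len(nrow(pars))) {
      mu <- pars$mu[i]; b <- pars$beta[i]; tau <- pars$tau[i]
      xi <- if (mt$two_par) b else numeric(0)
      gen <- urew(mt$spec, xi = xi, mu = mu, tau = tau)
      expect_lt(max_rel_mismatch(mt$d(y, mu, b, tau), durew(y, gen)),
                1e-12, label = sprintf("%s density vs engine", nm))
      expect_lt(max_rel_mismatch(mt$p(y, mu, b, tau), purew(y, gen)),
                1e-12, label = sprintf("%s cdf vs engine", nm))
      expect_lt(max_rel_mismatch(mt$h(y, mu, b, tau), hurew(y, gen)),
                1e-12, label = sprintf("%s hazard vs engine", nm))
    }
  }
})

test_that("quantile anchoring and round-trips hold for every named model", {
  u <- seq(0.01, 0.99, by = 0.01)
  set.seed(52)
  pars <- draw_named_params(5)
  for (nm in names(named_model_table())) {
    mt <- named_model_table()[[nm]]
    for (i in seq_len(nrow(pars))) {
      mu <- pars$mu[i]; b <- pars$beta[i]; tau <- pars$tau[i]
      expect_equal(mt$p(mu, mu, b, tau), tau, tolerance = 1e-12)
      expect_equal(mt$q(tau, mu, b, tau), mu, tolerance = 1e-12)
      yq <- mt$q(u, mu, b, tau)
      expect_true(all(yq > 0 & yq < 1) && all(diff(yq) >= 0))
      # heavy tails: the extreme upper quantiles can sit closer to 1 than
      # double spacing; the inversion identity is checked off that region
      sel <- yq < 1 - 1e-6
      expect_true(all(diff(yq[sel]) > 0))
      expect_lt(max(abs(mt$p(yq[sel], mu, b, tau) - u[sel])), 1e-9)
    }
  }
})

test_that("URW with shape 2 is the URR model", {
  y <- seq(0.01, 0.99, by = 0.01)
  for (mu in c(0.15, 0.5, 0.85)) {
    expect_identical(durr(y, mu), durw(y, mu, 2))
    expect_identical(purr(y, mu), purw(y, mu, 2))
    expect_identical(qurr(y, mu), qurw(y, mu, 2))
    expect_identical(hurr(y, mu), hurw(y, mu, 2))
  }
})

test_that("URBXII and URL coincide at shape 1", {
  y <- seq(0.01, 0.99, by = 0.01)
  for (mu in c(0.2, 0.6)) {
    expect_equal(durbxii(y, mu, 1), durl(y, mu, 1), tolerance = 1e-13)
    expect_equal(purbxii(y, mu, 1), purl(y, mu, 1), tolerance = 1e-13)
  }
})

test_that("hand-reduced closed forms evaluate correctly", {
  # URW at mu = 0.5, tau = 0.5, beta = 1: F(y) = 1 - 2^(-y/(1-y))
  y <- seq(0.05, 0.95, by = 0.05)
  expect_equal(purw(y, 0.5, 1), 1 - 2^(-y / (1 - y)), tolerance = 1e-14)
  # exponential-baseline member at y = mu = tau = 0.5: pdf = 2 log 2
  expect_equal(durw(0.5, 0.5, 1), 2 * log(2), tolerance = 1e-14)
})

test_that("named-model hazards satisfy the hazard identity", {
  y <- seq(0.05, 0.95, by = 0.05)
  set.seed(53)
  pars <- draw_named_params(3)
  for (nm in names(named_model_table())) {
    mt <- named_model_table()[[nm]]
    for (i in seq_len(nrow(pars))) {
      mu <- pars$mu[i]; b <- pars$beta[i]; tau <- pars$tau[i]
      # the 1 - cdf oracle cancels once the cdf is numerically ~ 1
      sel <- mt$p(y, mu, b, tau) < 1 - 1e-8
      expect_equal(mt$h(y[sel], mu, b, tau),
                   mt$d(y[sel], mu, b, tau) /
                     (1 - mt$p(y[sel], mu, b, tau)),
                   tolerance = 1e-6,
                   label = sprintf("%s hazard identity", nm))
    }
  }
})

test_that("the URR density is unimodal", {
  y <- seq(0.002, 0.998, length.out = 3000)
  for (mu in c(0.15, 0.4, 0.7)) {
    for (tau in c(0.3, 0.5, 0.7)) {
      f <- durr(y, mu, tau)
      s <- sign(diff(f))
      s <- s[s != 0]  # drop ties from the underflowed far tail
      sign_changes <- sum(diff(s) != 0)
      expect_lte(sign_changes, 1,
                 label = sprintf("URR unimodal at mu=%g tau=%g", mu, tau))
    }
  }
})

test_that("named-model samplers are deterministic and on-support", {
  set.seed(54)
  y <- rurg(500, 0.4, 0.8)
  expect_true(all(y > 0 & y < 1))
  set.seed(54)
  expect_identical(y, rurg(500, 0.4, 0.8))
  ks <- suppressWarnings(
    stats::ks.test(y, function(q) purg(q, 0.4, 0.8)))
  expect_gt(ks$p.value, 0.001)
})
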