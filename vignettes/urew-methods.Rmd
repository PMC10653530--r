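---
title: "Unit ratio-extended Weibull models for rates and proportions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unit ratio-extended Weibull models for rates and proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urew)
set.seed(1)
```

## The model

Many outcomes of scientific interest are double-bounded: dropout rates of
undergraduate courses, literacy rates, vote shares, humidity, proportions
of chemical components.  The classical tools for such data are the beta
and Kumaraswamy distributions, but both struggle with heavy right tails
and with N- or U-shaped densities.

This package builds unit-interval distributions from *lifetime* models.
A positive random variable $X$ belongs to the extended-Weibull class when
its survival function is

$$\Pr(X > x) = \exp\{-\alpha\, H(x; \xi)\}, \qquad x > 0,\ \alpha > 0,$$

for a nonnegative, monotonically increasing generator $H(\cdot;\xi)$ with
derivative $h(\cdot;\xi)$.  Each choice of $H$ gives a familiar lifetime
law: $H(x) = x$ the exponential, $x^2$ the Rayleigh, $x^\beta$ the
Weibull, $e^{\beta x}-1$ the Gompertz, $\log(1+x^\beta)$ the Burr XII,
$\log(1+x/\beta)$ the Lomax, and so on.  The package carries a catalog of
sixteen such generator triples $(H, h, H^{-1})$ (see `hspec_catalog()`)
and accepts user-defined ones through the `hspec()` contract.

The **ratio transformation** $Y = X/(1+X)$ maps $X$ onto $(0,1)$, with
inverse $x = y/(1-y)$.  The resulting family has cdf

$$F(y) = 1 - \exp\Big\{-\alpha H\Big(\tfrac{y}{1-y}; \xi\Big)\Big\},
  \qquad 0 < y < 1 .$$

Because $H \circ$ ratio is an increasing bijection, quantiles are closed
form, sampling by inversion is exact, and the family inherits the shape
flexibility of its parents: members can be unimodal, N-shaped or
U-shaped, and can carry much heavier right tails than the beta law.

### Quantile parametrization

The rate $\alpha$ has no direct interpretation on the unit interval.  The
package therefore re-expresses it through the $\tau$-th quantile
$\mu = Q(\tau)$:

$$\alpha = \frac{-\log(1-\tau)}{H\!\big(\mu/(1-\mu); \xi\big)}
  \quad\Longrightarrow\quad
  F(y) = 1 - (1-\tau)^{H(y/(1-y);\,\xi) / H(\mu/(1-\mu);\,\xi)} .$$

$F(\mu) = \tau$ then holds *exactly*, by construction.  $\tau$ is a
fixed, known constant — never estimated — defaulting to $0.5$, so that
$\mu$ is the median: an outlier-resistant location parameter that a
practitioner can read directly ("the median dropout rate is 16%").
Both parametrizations are available in `urew()`; `alpha_from_quantile()`
converts, and the two induce identical distributions.

### The named members

Five members get dedicated closed-form `d/p/q/r/h` functions, vectorized
and written on the log scale:

| model | baseline $H(x)$        | parameters        |
|-------|------------------------|-------------------|
| URG   | $e^{\beta x}-1$        | $\mu, \beta$      |
| URBXII| $\log(1+x^\beta)$      | $\mu, \beta$      |
| URL   | $\log(1+x/\beta)$      | $\mu, \beta$      |
| URW   | $x^\beta$              | $\mu, \beta$      |
| URR   | $x^2$                  | $\mu$             |

Two structural identities tie the set together and are enforced by tests:
URW with $\beta = 2$ *is* URR, and URBXII with $\beta = 1$ coincides with
URL with $\beta = 1$ (both reduce to the $\log(1+x)$ baseline).  A note
on two baseline conventions: the catalog's `gompertz` entry uses the
scaled generator $[e^{\beta x}-1]/\beta$ while the URG closed forms use
$e^{\beta x}-1$; under the quantile parametrization the scale factor is
absorbed by $\alpha$, so both induce the same family (unit-tested).  The
URL baseline is the Lomax $\log(1+x/\beta)$ — the unique choice under
which its cdf, density, quantile function and hazard are mutually
consistent.  A decreasing generator such as $x^{-\gamma}$ is *not*
admissible (it violates the monotonicity requirement of the class) and is
deliberately absent from the catalog.

```{r shapes, fig.width = 6, fig.height = 4}
y <- seq(0.005, 0.995, length.out = 400)
plot(y, durbxii(y, mu = 0.3, beta = 0.7), type = "l", ylim = c(0, 3),
     ylab = "density", main = "Shape flexibility on (0,1)")
lines(y, durr(y, mu = 0.3), lty = 2)
lines(y, durg(y, mu = 0.3, beta = 2), lty = 3)
legend("topright", c("URBXII (U/N-shaped)", "URR (unimodal)", "URG"),
       lty = 1:3, bty = "n")
```

## Maximum likelihood

With $c = -\log(1-\tau)$, $x_i = y_i/(1-y_i)$ and $m = \mu/(1-\mu)$, the
log-likelihood of a sample $y_1,\dots,y_n$ is

$$\ell(\mu, \xi) = n\log c - n\log H(m) - 2\sum_i \log(1-y_i)
  + \sum_i \log h(x_i) - \frac{c}{H(m)} \sum_i H(x_i).$$

`urew_loglik()` evaluates this analytically; the test suite pins it to
`sum(durew(y, d, log = TRUE))`.

**Closed-form estimator.**  For fixed $\xi$ the score in $\mu$
(`urew_score_mu()`) has the unique root

$$\hat\mu = \frac{g}{1+g}, \qquad
  g = H^{-1}\!\Big[\frac{c}{n}\sum_i H(x_i)\Big],$$

implemented in `closed_form_mu()`.  For the URR member this is
$g = \sqrt{c\sum_i x_i^2 / n}$ — no iteration, no starting values.  An
algebraically simplified variant that skips the $H^{-1}$ step circulates
in print; it does **not** solve the score equation and is severely biased
(for a true median of 0.15 it converges to about 0.03).  It is kept
behind `as_printed = TRUE` purely so the discrepancy can be audited, and
the test suite demonstrates its failure.  The score-consistent form is
consistent: under the URR law, $c\,x_i^2$ is exponential with mean $m^2$,
so $g \to m$ and $\hat\mu \to \mu$.

**Observed information.**  For URR, `urr_observed_info()` implements

$$I(\mu) = \frac{2}{\mu^4}\Big[\frac{n\mu^2(1-2\mu)}{(1-\mu)^2}
  + (2\mu-3)\, c \sum_i \frac{y_i^2}{(1-y_i)^2}\Big],$$

which is strictly negative at $\hat\mu$ (equal to $-4n(1+g)^4/g^2$
there), giving the Wald variance $-1/I(\hat\mu)$.

**Two-parameter members.**  `fit_mle()` maximizes by quasi-Newton (BFGS)
iteration.  Design choices that matter:

* *Starting values*: 1 for the shape/precision parameter; the sample
  $\tau$-quantile for quantile-parametrized locations; the sample mean
  for mean-parametrized ones (beta, unit gamma).
* *Optimization scale*: logit for unit-interval parameters, log for
  positive ones, so the search is unconstrained; convergence uses a
  relative tolerance of 1e-12 with at most 500 iterations.  The URG
  member additionally supplies its analytic score (`urg_score()`,
  validated against numeric gradients at 1e-5), which makes a fit at
  $n = 100$ cost about a millisecond.
* *Standard errors*: central finite-difference Hessian of the
  log-likelihood at $\hat\theta$ **on the natural scale**, step
  $\max(10^{-5}, 10^{-5}|\hat\theta_j|)$ (shrunk near the boundary for
  unit parameters), inverted to give Wald intervals
  $\hat\theta \pm z_{\eta/2}\,\widehat{se}$.  No delta-method
  back-transformation: intervals are reported on the scale the parameters
  live on.  A singular or non-positive-definite information matrix is
  reported as `converged = FALSE` with standard errors `NA` rather than
  silently dropped.
* *Degenerate inputs*: zero-variance samples are rejected (the likelihood
  has no interior maximum); observations within $10^{-10}$ of 0 or 1 are
  rejected at validation, since every likelihood term involves
  $y/(1-y)$ and $\log(1-y)$.

A caveat the package's own simulations quantify: the observed-information
Wald interval for the URR median *undercovers* in very small samples
(true coverage of the nominal 95% interval is about 0.93 at $n = 10$ for
small $\mu$, recovering to 0.945–0.95 by $n = 50$).  This is a property
of the interval, not of the estimator, whose bias is negligible even at
$n = 10$.

## Competitor models and ranking

The comparison battery (`beta`, `kw`, `ug`, `ubs`, `uw`, `cuw`) covers
the standard unit-interval alternatives, each in its common
location/precision or median parametrization and each behind the same
`fit_mle()` interface.  Where a printed density form is typographically
ambiguous (the Kumaraswamy and unit-gamma forms are frequent victims),
the implementation is derived from the defining construction — e.g. the
Kumaraswamy cdf $1-(1-y^\phi)^b$ with $b$ pinned by the median condition
$F(\mu) = 1/2$ — and validated by normalization and location-semantics
quadrature oracles rather than by the printed string.  The unit
Birnbaum–Saunders is implemented by the exact transformation
$Y = e^{-X}$ of a Birnbaum–Saunders variate.

Model comparison uses the corrected Cramér–von Mises statistic on
probability-integral-transformed data,

$$W^{*} = \Big[\frac{1}{12n} + \sum_{i=1}^n
  \Big(u_{(i)} - \frac{2i-1}{2n}\Big)^2\Big]\Big(1 + \frac{0.5}{n}\Big),$$

evaluated at the fitted parameters (`cvm_star()`).  Smaller is better;
`rank_models()` and `fit_and_rank()` order ascending, breaking ties
lexicographically by model id so rankings are reproducible.  No p-values
are attached: the statistic is used as a relative ranking criterion.

## Monte Carlo harness

`run_scenario()` simulates by inversion, fits with the model's estimator,
and aggregates.  Two column conventions are reported side by side,
because both appear in applied work under the same names:

* `rb100` $= 100(\bar{\hat\theta} - \theta)$ and
  `mse` $=$ variance $+$ bias$^2$ — the convention of the simulation
  tables this harness reproduces;
* `rel_bias_pct` $= 100(\bar{\hat\theta} - \theta)/\theta$ and
  `rmse` $= \sqrt{\text{mse}}$ — the textbook reading.

Coverage (`cp`) is the fraction of replications whose Wald interval
contains the truth; replications whose fit fails to converge or yields a
non-positive-definite information matrix are dropped and counted
(`n_failed`, flagged above 1%).  Every scenario is reproducible from one
integer seed; `run_table()` batches scenarios (row $i$ seeded
`seed + i`) and also emits per-$n$ totals of $|$`rb100`$|$ and `mse`
across parameters.

Problem sizes used by the package's own checks: 10,000 replications per
scenario at $n \le 100$ (the URR scenarios run vectorized in seconds;
a URG scenario takes roughly ten seconds), and 50 independent fixtures
of $n = 5{,}000$ for the ranking self-consistency check.

## The synthetic fixture generator

`generate_fixture()` emulates course-level first-year dropout rates:
right-skewed unit samples with mean around 0.13–0.18, median below the
mean, and mass concentrated left — the signature of dropout data, where
most courses lose fewer than a fifth of their freshmen.  The four presets
(`civil-like`, `economics-like`, `computer-like`, `control-like`) draw
from unit ratio-Weibull laws whose $(\mu, \beta)$ and sample sizes match
published course-level fits (e.g. $n = 658$, $\mu \approx 0.16$,
$\beta \approx 1.18$ for civil-engineering-like data); they are synthetic
stand-ins, clearly labelled as such in their manifests.

What the generator deliberately does *not* emulate: the discreteness of
observed rates (ratios of small integer counts), exact zeros and ones
(removed upstream by the unit-interval filter), institutional
heterogeneity and within-institution correlation.  Tests passing on
fixtures therefore validate the *estimation and ranking machinery*, not
the claim that any particular course type follows a given law.

The ingestion side (`dropout_rate()`, `apply_course_filters()`) applies
the course-selection rules — presential modality, more than 29 new
students, rate strictly inside $(0,1)$ — and reports per-rule exclusion
counts, so a reanalysis of real census microdata can slot in by providing
a `dropped`/`enrolled`/`modality` table.

## Numerical choices

* All $(1-\tau)^A$ powers are computed as $\exp\{A \log(1-\tau)\}$ with
  `log1p`; $x = y/(1-y)$ is formed once; $\log(e^z - 1)$ uses a guarded
  `lexpm1` ($z$ for $z > 33$), so URG likelihoods survive $\beta x$ far
  beyond overflow.
* Numeric generator inversion (baselines marked "no closed form":
  additive Weibull, linear failure rate, flexible and modified Weibull)
  brackets in $[10^{-12}, 10^{12}]$ with geometric expansion, isolates
  the root by Brent's method at absolute tolerance $10^{-12}$, then
  applies up to four Newton polish steps — necessary because roots can
  sit many orders of magnitude below 1, where an absolute tolerance is
  loose in relative terms.
* Quantile functions clamp into
  $[10^{-300},\, 1 - \varepsilon/2]$: for heavy-tailed members with
  extreme $(\mu, \tau)$, upper quantiles can be closer to 1 than the
  spacing of double-precision numbers, so the exact value is not
  representable.  Round-trip identities are verified off that saturated
  zone.
* The hazard identity $h_Y = f/(1-F)$ holds analytically everywhere, but
  the right-hand side loses all precision once $F$ is within $\sim
  10^{-16}$ of 1; tests compare where the survival is at least $10^{-8}$.
* If a user-registered baseline omits the derivative $h$, it is replaced
  by central finite differences *with a warning* — the density is
  proportional to $h$, so an analytic derivative should be supplied.

## Limitations

* No moment expressions: means and variances of family members are
  obtained by quadrature when needed.
* No censoring, covariate regression, or zero/one inflation; data on the
  boundary must be handled upstream.
* Wald intervals only (no profile or bootstrap), with the small-sample
  undercoverage noted above.
* The catalog's Pareto baseline induces support on $(k/(1+k), 1)$; the
  constructor flags quantile parameters below the shift, but fitting
  machinery does not estimate $k$.
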