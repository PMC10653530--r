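Package: urew
Title: Unit Ratio-Extended Weibull Distributions for Rates and Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Density, distribution, quantile and random generation for the
    unit ratio-extended Weibull (UREW) family of distributions on (0,1),
    obtained by applying the ratio transformation Y = X/(1+X) to
    extended-Weibull variates with survival exp(-a*H(x)).  Ships a pluggable
    catalog of baseline generator triples (H, h, H^-1), a generic engine
    under both the rate and the quantile parametrization, and closed forms
    for five named members: the unit ratio-Gompertz, -Burr XII, -Lomax,
    -Weibull and -Rayleigh distributions.  Maximum-likelihood fitting with
    Wald intervals (closed-form estimator for the unit ratio-Rayleigh),
    six competitor unit distributions (beta, Kumaraswamy, unit gamma, unit
    Birnbaum-Saunders, unit Weibull, complementary unit Weibull), corrected
    Cramer-von Mises goodness-of-fit ranking, a Monte Carlo harness for
    bias, mean-squared-error and coverage studies, and a pipeline for
    modeling first-year dropout rates of undergraduate courses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
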