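Package: spathrr
Title: Bayesian Spatiotemporal Hierarchical Related Regression for Small-Area Early Mortality
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for Bayesian spatiotemporal multilevel analysis of 30-day
    mortality after systemic anticancer therapy, built around the hierarchical
    related regression (HRR) framework: a joint individual-level Bernoulli and
    area-level Binomial/Poisson likelihood that marginalizes the individual
    logistic model over the within-area joint covariate distribution, with
    Besag intrinsic conditional autoregressive (ICAR) structured spatial
    effects, exchangeable unstructured effects, and linear plus quadratic
    temporal trends. Includes a synthetic registry generator with Queen
    contiguity lattices, a native Metropolis-within-Gibbs sampler with
    conjugate precision updates, convergence diagnostics (Brooks-Gelman-Rubin
    statistic, batch-means Monte Carlo error), DIC-based forward model
    selection, and reporting of crude rates with Wilson intervals, adjusted
    odds ratio tables, standardized relative risk surfaces, and choropleth
    GeoJSON export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
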