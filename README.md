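# spathrr

Bayesian spatiotemporal hierarchical related regression (HRR) for
small-area analysis of early mortality — death within 30 days of starting
systemic anticancer therapy (SACT) — in a cancer registry observed over
local government areas and calendar periods. The package is aimed at
biostatisticians and cancer epidemiologists who want a self-contained,
tested implementation of the joint individual/aggregate modelling approach:
synthetic registry generation, Queen-contiguity spatial structure, the HRR
likelihood, a native Metropolis-within-Gibbs sampler, convergence and DIC
diagnostics, and standardized-relative-risk reporting.

## The model

Individual outcomes are Bernoulli with a multilevel logistic model,

```
y_ijt ~ Bernoulli(p_ijt)
logit(p_ijt) = mu + beta' x_ijt + gamma' z_j + u_j + v_j
               + delta1 c(t) + delta2 c(t)^2
```

where `x_ijt` are individual covariates (age group, multidisciplinary
meeting presentation, supportive-care screening, clinical stage,
comorbidity, ECOG status), `z_j` are area covariates (socioeconomic
quartile, remoteness class), `u_j` is a Besag intrinsic CAR (ICAR)
structured spatial effect over the Queen-1 adjacency with binary weights,
`v_j` an exchangeable normal effect, and `c(t)` the centered period index.

Aggregate counts for area `j` and period `t` follow

```
y_jt ~ Binomial(N_jt, p_jt)        (or Poisson(N_jt * p_jt))
p_jt = sum_k f_jtk * p_jtk
```

with `f_jtk` the joint within-area distribution of the individual
covariates over the `K = 2*2*2*4*2*3 = 192` strata and `p_jtk` the
stratum-level risk from the individual model. Marginalizing the individual
model over `f_jtk` is the hierarchical related regression device that
removes ecological bias from the aggregate level. The full likelihood is
the product of the individual and aggregate likelihoods.

Priors: N(0, precision 0.725) on all non-intercept coefficients — the
precision implied by a 95% prior belief that an odds ratio lies in
(0.1, 10) — an improper flat prior on `mu`, the ICAR prior on `u`,
i.i.d. normals on `v`, and Gamma(0.5, 0.0005) hyperpriors on the two
random-effect precisions. Estimation is by Metropolis-within-Gibbs:
adaptive scalar random-walk updates for the coefficients, single-site
updates for `u_j` and `v_j`, conjugate draws for the precisions, and exact
auxiliary kernels (reference-translation and hierarchical-centering
exchanges, and a blocked eigenbasis update of the `u`/`v` variance
partition) that remove the slow mixing directions of this model class.

## Worked example

Simulate a registry at desk scale (20 areas, 4000 patients, three
periods), fit the joint HRR model with two chains, and report adjusted
odds ratios, diagnostics and the standardized relative risk surface:

```r
library(spathrr)

cfg      <- sim_config(n_areas = 20, lattice_dims = c(4, 5),
                       n_patients = 4000, seed = 42)
registry <- simulate_registry(cfg)
registry
#> Synthetic registry: 4000 patients, 20 areas x 3 periods, 182 deaths (4.55%)

data <- hrr_data_from_registry(registry, protocol = "joint")
fit  <- run_mcmc(data, sampler_config(10000, 5000, n_chains = 2, seed = 43))

aors <- aor_table(fit)
subset(aors, parameter %in% c("mdm_yes", "scs_yes", "stage_IV", "ecog_poor"))
#>   parameter  aor lower upper significant
#> 2   mdm_yes 0.64  0.46  0.86        TRUE
#> 3   scs_yes 0.51  0.36  0.69        TRUE
#> 6  stage_IV 3.80  1.42  8.73        TRUE
#> 8 ecog_poor 2.39  1.45  3.62        TRUE

diagnostics_report(fit, pars = c("mu", "stage_IV", "ecog_poor", "scs_yes"))
#>   parameter    bgr    mc_se mc_ratio bgr_ok mc_ok
#> 1        mu 0.9999 0.010384  0.01900   TRUE  TRUE
#> 2  stage_IV 0.9999 0.010100  0.02162   TRUE  TRUE
#> 3 ecog_poor 0.9999 0.005670  0.02420   TRUE  TRUE
#> 4   scs_yes 1.0001 0.004145  0.02483   TRUE  TRUE
#> DIC = 1583.71 (Dbar = 1557.43, pD = 26.28)

surface <- srr_surface(fit)
head(surface[surface$period == 3, ], 4)
#>    area_id period  n srr_mean srr_lower srr_upper exceedance
#> 3        1      3 60    0.184    0.0567     0.395     0.0000
#> 6        2      3 61    0.415    0.2190     0.666     0.0005
#> 9        3      3 69    0.869    0.5263     1.317     0.2395
#> 12       4      3 83    1.260    0.8797     1.713     0.8880
```

The odds ratios are the exponentiated posterior summaries of the
individual-level coefficients (here recovering the generator's true effect
sizes, e.g. supportive-care screening halves the odds of early death);
`srr_mean` is each area-period's covariate-standardized risk relative to
the pooled standardized risk, with `exceedance = P(SRR > 1)` flagging
elevated-risk cells. `choropleth_export()` writes the surface as per-period
GeoJSON choropleths.

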