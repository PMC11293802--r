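# bgwr: Bayesian geographically weighted regression with coefficient clustering

Areal health and social data rarely obey a single global regression: the
association between a covariate and an outcome can strengthen, vanish, or
reverse from one region to the next. `bgwr` is an R package for
epidemiologists and spatial statisticians who want to (i) estimate
region-specific regression coefficients with honest uncertainty, (ii) ask
*which* covariates matter *where*, and (iii) group regions whose covariate
effects behave alike.

## The model

For a focal region *s*, every observation *i* is down-weighted by its
distance from *s* through a kernel *w\_i(s) = f(d\_i(s) | b)* (exponential
*e^{−d/b}*, Gaussian *e^{−(d/b)²}*, or bi-square), where *b* is the
bandwidth. The local likelihood is a product of univariate Gaussians in
which the weight multiplies the precision,

  y\_i | β(s), σ²(s) ~ N(x\_iᵀβ(s), σ²(s)/w\_i(s)),

with conjugate priors β\_j(s) ~ N(0, σ\_β²), σ²(s) ~ IG(α₁, α₂),
σ\_β² ~ IG(a\_β, b\_β) and b ~ Uniform(0, D). A Metropolis-within-Gibbs
sampler (RcppArmadillo core) draws all parameters; per-location
reversible-jump moves add or delete coefficients through binary indicators
γ\_j(s) ~ Bernoulli(ψ\_j), giving a posterior inclusion probability for
every (region, covariate) pair.

Posterior coefficient surfaces are then clustered: a Gaussian mixture
(EM, BIC-selected K) or a truncated stick-breaking Dirichlet-process
mixture is fitted to sampled posterior iterations, consensus partitions
are formed by Dahl's least-squares coassignment method or the per-region
mode, and accuracy against a known truth is scored by the Rand index.

## Worked example

```r
library(bgwr)

# a 64-region study with constant true coefficients (2, 0, 0, 4, 8)
st  <- louisiana_like(seed = 1)
fit <- run_bgwr(st$table, st$map, kernel_spec("exponential", D = 100),
                settings = mcmc_settings(iterations = 3000, burn_in = 1000,
                                         seed = 1))
round(apply(fit$beta, 3, mean), 3)
#>     X1     X2     X3     X4     X5
#>  1.963 -0.092  0.080  3.929  7.980
```

The posterior means sit on the generating values (2, 0, 0, 4, 8): the two
null covariates are correctly near zero. With variable selection the nulls
are actively excluded:

```r
sel <- run_bgwr_select(st$table, st$map, kernel_spec("exponential", D = 100),
                       settings = mcmc_settings(iterations = 20000,
                                                burn_in = 2000, seed = 11),
                       always_include = character(0))
round(colMeans(inclusion_probabilities(sel)$probability), 3)
#>    X1    X2    X3    X4    X5
#> 1.000 0.001 0.000 1.000 1.000
```

Regions keep X1, X4, X5 with probability ~1 and drop the null X2, X3
almost always. For spatially varying coefficients, cluster the surfaces:

```r
ga  <- georgia_like(setting = 3, seed = 1)   # 3 true clusters: 51/49/59
b   <- gwr_cv_bandwidth(ga$table, ga$map)    # leave-one-out CV bandwidth
fit <- run_bgwr(ga$table, ga$map, kernel_spec("exponential", bandwidth = b),
                settings = mcmc_settings(iterations = 2000, burn_in = 500,
                                         seed = 21))
cfg <- two_stage_configuration(fit, n_samples = 50, clusterer = "dpmm",
                               config_method = "mode", seed = 31)
rand_index(cfg$assignment, ga$true_clusters)
#> [1] 0.86
```

A Rand index of 0.86 means 86% of all region pairs are classified
(together/apart) exactly as in the generating partition.

A command-line wrapper over the same functions lives at
`inst/scripts/bgwr-cli.R` (subcommands `simulate`, `fit`, `select`,
`cluster`, `assess`, `run`).

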