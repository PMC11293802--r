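---
title: "Methods behind bgwr: model, sampler, clustering, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind bgwr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

Geographically weighted regression treats every region *s* as the centre of
its own regression problem: observation *i* enters region *s*'s likelihood
with a kernel weight $w_i(s) = f(d_i(s)\mid b)$ that decays with the
distance between the observation's region and the focal region. `bgwr`
implements the Bayesian form with a vectorized weighted-Gaussian
likelihood,

$$y_i \mid \beta(s), \sigma^2(s) \sim
  N\!\big(x_i^\top \beta(s),\; \sigma^2(s) / w_i(s)\big),$$

so a weight multiplies the *precision*: nearby observations count more.
The hierarchy uses conjugate priors — $\beta_j(s) \sim N(0, \sigma_\beta^2)$
with a single $\sigma_\beta^2 \sim \mathrm{IG}(a_\beta, b_\beta)$ shared by
all regions and covariates, $\sigma^2(s) \sim \mathrm{IG}(\alpha_1,
\alpha_2)$ per region, and $b \sim \mathrm{Uniform}(0, D)$.

Assumptions worth keeping in mind: Gaussian errors; one shared bandwidth
for the whole map (no adaptive per-region bandwidths); weights depend only
on region-to-region distances, so all observations in a region are
exchangeable with respect to the weighting. The weighted likelihood reuses
every observation in all $S$ focal models — it is a *pseudo*-likelihood,
which matters for how the bandwidth is updated (below).

## Sampler

One sweep per iteration, in an RcppArmadillo core driven by R's RNG (so
`set.seed` gives bit-identical chains):

1. $\beta(s)$ for each region from its multivariate-normal full
   conditional with precision $X^\top W(s) X/\sigma^2(s) + I/\sigma_\beta^2$,
   restricted to the region's active covariates (masked coefficients stay
   exactly zero);
2. $\sigma^2(s) \sim \mathrm{IG}(\alpha_1 + n/2,\; \alpha_2 +
   \tfrac12\sum_i w_i(s) r_i^2(s))$;
3. $\sigma_\beta^2$ from its conjugate update over all active coefficients;
4. a reflected random-walk Metropolis move on $b$ (skipped when the
   bandwidth is fixed).

**Bandwidth target.** The natural conditional for $b$ — the product of all
$S$ weighted region likelihoods — counts every datum $S$ times, and in our
measurements it makes the bandwidth posterior far more concentrated than a
single data set can justify. The default move therefore tempers the joint
pseudo-log-likelihood by $1/S$, the standard composite-likelihood
correction that restores each datum's information to its nominal weight;
`bandwidth_target = "joint"` retains the untempered product. Zero weights
from bounded-support kernels are floored at $10^{-12}$ so the likelihood
stays finite (a singular weight matrix is a known hazard of hard-threshold
kernels).

**Initialization.** The pseudo-posterior over $b$ is bimodal when the data
are spatially heterogeneous: a near-global basin (large $b$, misfit
absorbed by inflated $\sigma^2(s)$) and a localized basin (small $b$,
small local variances). A one-dimensional random-walk chain does not cross
between them, because $\sigma^2(s)$ re-adapts within each basin and
flattens the conditional seen by the move. The chain therefore starts at
the classical GWR leave-one-out cross-validation bandwidth
(`gwr_cv_bandwidth`, default), which places it in the basin the data
prefer; `"midpoint"` ($D/2$) is available for comparison. Local
coefficients initialize implicitly through their first Gibbs draw at the
starting bandwidth; $\sigma^2(s) = 1$.

For analyses whose goal is *clustering* the coefficient surfaces we go one
step further and fix the bandwidth at the CV optimum rather than sampling
it. Under the precision-weighting convention the $\sigma^2(s)$ update uses
shape $\alpha_1 + n/2$ while the weighted rate involves only
$\sum_i w_i(s) \ll n$ effective observations; at small bandwidths this
over-tightens the local variances, and the bandwidth chain then drifts
back toward semi-global values, washing out the very spatial structure the
clustering is meant to find. Conditioning on a CV-chosen bandwidth — the
standard frequentist GWR practice — sidesteps this and is what the
package's own spatially-varying-study checks use. Bandwidth estimation
remains the default for homogeneous-coefficient analyses, where it
reproduces the expected near-prior behaviour of $b$ under a
deliberately large $D$.

**Defaults.** $\alpha_1 = \alpha_2 = a_\beta = b_\beta = 0.01$ (weakly
informative; the data dominate at $n$ in the tens); bandwidth step $D/20$
(reflected at $0$ and $D$; the fit warns when the acceptance rate leaves
$[0.1, 0.6]$); chains of 10 000 iterations with 2 000 burn-in and no
thinning unless overridden.

## Per-location variable selection

Binary indicators $\gamma_j(s) \sim \mathrm{Bernoulli}(\psi_j)$ multiply
the coefficients elementwise in the linear predictor. Each sweep proposes,
for every selectable (region, covariate) pair, a birth (draw a fresh
$\beta_j(s)$ from its $N(0, \sigma_\beta^2)$ prior) or a death (remove
it). With the prior as proposal the trans-dimensional proposal and
Jacobian terms cancel exactly, leaving the weighted-likelihood ratio times
the $\psi_j$ odds — a move equivalent in stationary distribution to
indicator-embedding samplers of the Kuo–Mallick type. $\psi_j$ is shared
across regions per covariate (its update is the conjugate
$\mathrm{Beta}(1 + \sum_s \gamma_j(s),\, 1 + S - \sum_s \gamma_j(s))$);
the intercept is exempt by default. Excluded coefficients are stored as 0,
and summaries report both the marginal ($\gamma \cdot \beta$) and the
conditional ($\beta \mid \gamma = 1$) posterior means — a never-included
pair reports a missing conditional mean, not zero.

## Clustering the coefficient surfaces

Stage 1 samples posterior iterations (without replacement); each sampled
$S \times p$ coefficient matrix is clustered — the full matrix by default,
or a single covariate surface via the `covariate` argument:

* **GMM route**: full-covariance EM with restarts (best final
  log-likelihood wins), $K$ chosen by BIC with
  $q = K - 1 + Kp + Kp(p+1)/2$ parameters, ties toward smaller $K$;
  maximum-responsibility labels.
* **DPMM route**: a truncated stick-breaking Dirichlet-process mixture via
  blocked Gibbs ($z \mid C, \theta$; $V_k \sim \mathrm{Beta}(1 + n_k,
  \alpha + \sum_{l>k} n_l)$; conjugate per-dimension Normal–Inverse-Gamma
  base), condensed within-sample by Dahl's method or the mode method.

Stage 2 canonically relabels each sample's partition (labels in order of
first region appearance; an optional greedy best-overlap alignment to the
first sample is provided), stacks them, and takes the per-region mode
ignoring missing entries. Canonical relabeling is a heuristic answer to
label switching across samples; it is exact whenever two samples induce
the same partition, which is the case the mode aggregation relies on.

Numerical choices: EM tolerance $10^{-6}$ (relative log-likelihood),
maximum 500 iterations, 10 restarts (3 inside the two-stage loop, where
hundreds of fits run); covariance diagonals floored at $10^{-6}$ and
eigenvalues clipped to keep matrices positive-definite; EM solutions in
which a component retains fewer than $p + 1$ effective members are
rejected as spike degeneracies. DPMM defaults: truncation $H = 20$,
$\alpha = 1$, 1 000 iterations with 200 burn-in per sample; base measure
$m_0$ = pooled mean, $\kappa_0 = 0.1$, $a_0 = 2$, $b_0$ set so the prior
mean of each component variance equals the pooled variance. The sampler
warns when all $H$ components are ever occupied. All tie-breaks — mode
ties, BIC ties, Dahl arg-min ties — go to the smallest index for
determinism.

Dahl's method picks the sampled partition whose coassignment matrix
$B^{(c)}(i,j) = \mathbf 1(z_i^{(c)} = z_j^{(c)})$ is closest in squared
distance to the posterior mean coassignment $\bar B$; the Rand index
scores agreement of two partitions over all unordered region pairs.

## Model assessment

WAIC and DIC use each observation's *own-region* predictive density at
self-weight 1, $N(x_i^\top \beta(s_i), \sigma^2(s_i))$ — the only choice
under which every observation has a single well-defined predictive density
in a model where each datum otherwise appears in all $S$ local
likelihoods. WAIC $= -2(\mathrm{lppd} - p_\mathrm{WAIC})$ with the
pointwise-variance penalty (population variance over draws, so duplicating
draws leaves it exactly unchanged); DIC $= D(\bar\theta) + 2 p_D$ with
$p_D$ = mean deviance minus deviance at the posterior means. A negative
$p_D$ is flagged as a mixing warning, not an error. Absolute magnitudes
are strongly design-dependent; only model rankings should be compared.

## What the synthetic generators emulate — and what they do not

`louisiana_like()` reproduces a 64-region design with three observations
per region, i.i.d. standard-normal covariates, constant coefficients
$(2, 0, 0, 4, 8)$ and unit noise, on a lattice rescaled so the maximum
pairwise distance is 10 (so a $\mathrm{Uniform}(0, 100)$ bandwidth prior
is deliberately near-non-informative: even at the maximum distance the
relative weight is $e^{-10/100} \approx 0.9$).

`georgia_like()` reproduces a 159-region design: a jittered lattice split
into three contiguous blocks of 51/49/59 regions (sorted first by the
horizontal, then the vertical coordinate), six spatially correlated
covariates from a Gaussian process with covariance $\exp(-(d/\phi)^2)$,
cluster-constant coefficient vectors per signal-strength setting
(setting 3 is the strongest, e.g. cluster 1 uses $(9, 0, -4, 0, 2, 5)$),
$\beta_0 = 0$, one observation per region, unit noise. The covariate
range defaults to $\phi = 1$ lattice unit: at $\phi$ much larger than the
lattice spacing the covariate fields are locally near-constant and the
seven local coefficients become unidentifiable from one observation per
region — no method could then recover the clusters, while clearly positive
spatial autocorrelation (Moran's I) is retained at $\phi = 1$. An optional
smooth within-cluster coefficient perturbation exists but is off by
default: the partition *is* the truth being recovered.

Neither generator reproduces real administrative geographies, irregular
polygon adjacency, heteroscedastic or non-Gaussian noise, or missing-data
patterns; passing recovery checks on them demonstrates correctness of the
machinery under the stated designs, not performance on real areal data.
`impute_by_neighbors()` (mean of contiguous neighbours for continuous
variables, neighbourhood majority for categories, islands dropped with a
warning) and `one_hot()` with per-region active-covariate masks are the
utilities provided for real-data preprocessing.

## Problem sizes used by the package's own checks

The test suite and `scripts/acceptance.R` use reduced but representative
sizes, chosen as the smallest runs whose Monte-Carlo error is well below
the tolerances they check: 10 replicates of 3 000 iterations (1 000
burn-in) for constant-coefficient recovery; 3 replicates of 20 000
iterations for selection; one 2 000-iteration fit with 50 posterior
samples (DPMM: 1 000 Gibbs iterations per sample) for the clustering
accuracy. Every run is seeded and reproducible.

## Known limitations

* The weighted pseudo-likelihood is not a generative joint model; the
  bandwidth's "posterior" is target-dependent (hence the tempered default
  and the fixed-CV-bandwidth recommendation for clustering analyses).
* A single shared bandwidth and a single shared $\sigma_\beta^2$; no
  adaptive bandwidths, no GLM responses, no shrinkage priors.
* DPMM cluster counts are known to be posterior-inconsistent for the
  number of components; treat them as descriptive, and prefer the Rand
  index against external structure when one exists.
* Canonical relabeling across samples is heuristic; strongly multimodal
  posteriors over partitions can defeat the cross-sample mode.
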