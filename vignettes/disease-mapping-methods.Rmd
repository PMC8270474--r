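---
title: "Bayesian small-area disease mapping with dismap: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian small-area disease mapping with dismap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dismap)
```

## The problem

Registry counts of a rare cancer over small administrative districts are too
noisy to map directly: a district with three cases instead of one looks like
a tripled risk. `dismap` implements the standard hierarchical remedy for
area-level incidence data — indirect age-sex standardization followed by a
Bayesian log-linear Poisson model whose spatial random effects borrow
strength between neighboring districts — together with the diagnostics that
justify it (a non-spatial Poisson screen and Moran's I with a permutation
null) and a synthetic registry generator with known ground truth so that the
whole chain can be validated without access to restricted registry
microdata.

## Counts and expected counts

Cases arrive as a line list (district, sex, one of 12 age bands from <35 to
85+, diagnosis year, ICD-O-3 stomach topography code). Observed counts are
\[ Y_i = \sum_{j}\sum_{k} y_{ijk}, \]
summing over sexes $j$ and age bands $k$, optionally within sub-site
(cardia C160 vs non-cardia C161–C168, with C169 site-unspecified) and
five-year period strata. Expected counts use *internal* indirect
standardization: pooled reference rates $y_{jk}/n_{jk}$ from the analysed
data itself, applied to each district's stratum populations,
\[ E_i = \sum_{j}\sum_{k} \frac{y_{jk}}{n_{jk}} n_{ijk}. \]
This forces $\sum_i E_i = \sum_i Y_i$ (a conservation identity the test
suite checks to 1e-9) and makes $Y_i/E_i$ an age-sex standardized incidence
ratio. Strata with no population and no cases contribute zero (0/0 → 0);
a stratum with cases but no population is a data error and stops the run.
Districts with $E_i = 0$ cannot be fit (their Poisson mean is identically
zero) and are dropped with a warning before modelling.

For period-stratified tables the reference rates are recomputed within each
period, so conservation holds per period. A consequence worth knowing:
period-wise internal standardization absorbs any global temporal trend into
$E_{it}$ by construction, which is appropriate when the question is the
*spatial* pattern within each period. Parameter-recovery experiments for the
temporal effects therefore use the generator's design-based expected counts
(`counts_from_truth()`), which do not re-absorb the trend.

## The contiguity graph

Both the spatial prior and Moran's I use first-order binary contiguity:
$w_{ij} = 1$ exactly when districts share a boundary, with no row
standardization, and aggregate weight $S_0 = \sum_i\sum_j w_{ij}$ (twice the
edge count). Graphs are built from edge-list CSVs or legacy GAL files and
validated for symmetry and absence of self-loops. Isolated districts
("islands") are allowed but flagged: their conditional spatial distribution
is undefined, so the model pins their structured effect to zero and lets the
unstructured term carry their variation; the intrinsic CAR rank used in the
precision update is $n - c$ with $c$ the number of connected components,
which accounts for islands automatically.

## Spatial dependency screen

Before any spatial model is fit, a multivariable Poisson GLM
$\log \mu_i = \log E_i + a + b'x_i$ (fit by an in-package IRLS routine,
cross-checked in the tests against `stats::glm` and a direct likelihood
maximization) absorbs the covariates; the residual ratios $Y_i/\hat\mu_i$
are the "unexplained variation" surface. Moran's I,
\[ I = \frac{n}{S_0}\,
   \frac{\sum_i\sum_j w_{ij}(y_i-\bar y)(y_j - \bar y)}
        {\sum_i (y_i - \bar y)^2}, \]
is then computed on those ratios. Because ~100 districts are too few to
lean on asymptotic null moments, the test permutes the value-to-district
assignment uniformly (default 999 permutations, fixed seed) and reports the
one-sided upper $p = (1 + \#\{I_{perm} \ge I_{obs}\})/(1 + n_{perm})$; the
+1 correction keeps the test exact under exchangeability and $p > 0$. The
upper tail is the alternative of interest since disease clustering means
positive autocorrelation.

## The hierarchical models

The spatial model is the convolution (BYM-type) Poisson regression
\[ Y_i \sim \text{Poisson}(\lambda_i E_i), \qquad
   \log \lambda_i = \alpha + \beta' x_i + u_i + \eta_i, \]
with iid heterogeneity $u_i \sim N(0, \sigma_u^2)$ and an intrinsic CAR
prior on the structured effect,
\[ \eta_i \mid \eta_{-i} \sim
   N\!\Big(\tfrac{1}{|N(i)|}\textstyle\sum_{j\sim i}\eta_j,\;
   \tfrac{\sigma_\eta^2}{|N(i)|}\Big). \]
The spatio-temporal extension adds additive period terms
$\gamma_t \sim N(0, \sigma^2_\gamma)$ (exchangeable) and a first-order
random walk $\phi_t$ whose full conditionals are the three-case step
function (endpoints $N(\phi_{t\pm1}, \sigma^2_\phi)$, interior
$N((\phi_{t-1}+\phi_{t+1})/2, \sigma^2_\phi/2)$). No space-time interaction
is included — the model is deliberately additive.

Priors: a flat improper prior on $\alpha$ (propriety is restored by the
data; the fitter refuses all-zero count tables), $\beta \sim N(0, 1000)$ on
each slope, and Gamma(0.1, 0.01) on each precision
$\tau = 1/\sigma^2$. The $N(0, 1000)$ is read as a *variance*; the common
precision-0.001 convention is numerically the same prior, and the value is
configurable (`prior_beta_var`). IRRs per covariate unit are reported as
the posterior median and 2.5/97.5 percentiles of $e^\beta$; quantiles are
taken on the log scale and exponentiated, which makes the summary exactly
equivariant under sign flips of $\beta$.

## The sampler

Inference is by Metropolis-within-Gibbs MCMC, implemented in C++:
single-site random-walk Metropolis updates for $\alpha$, each $\beta$, each
$u_i$, $\eta_i$, $\gamma_t$ and $\phi_t$, and exact conjugate Gamma draws
for the precisions, $\tau \mid \cdot \sim \text{Gamma}(a + r/2, b + q/2)$
with $q$ the structure's quadratic form and rank $r$ equal to $n$ (iid),
$n - c$ (intrinsic CAR) or $T - 1$ (RW(1)). Because only the sum
$\gamma_t + \phi_t$ enters the likelihood, the temporal sweep also makes a
swap proposal $(\phi_t + d, \gamma_t - d)$ accepted on the prior ratio
alone — a likelihood-invariant move that mixes the structured/unstructured
split far faster than the single-site updates can.

Numerical choices that matter:

* **Proposal scales.** Latent-field proposals are expressed relative to the
  current conditional-prior standard deviation (e.g. $s_u/\sqrt{\tau_u}$
  for $u_i$), so mixing survives the large precision swings a Gamma(0.1,
  0.01) hyperprior produces. The dimensionless multipliers adapt toward a
  0.44 acceptance rate in windows of 100 sweeps during burn-in only and are
  frozen afterwards, preserving detailed balance for the retained draws.
* **Identifiability.** The intrinsic CAR and RW(1) priors are invariant to
  level shifts, so $\eta$ and $\phi$ are recentred to sum to zero after
  each sweep, with the deducted means absorbed into the flat-prior
  intercept. Because the intercept's prior is flat and both field priors are
  shift-invariant, this recentring is an exactly measure-preserving move
  (the likelihood is untouched), not an approximation — the reason the
  means go into $\alpha$ rather than into $\gamma$, whose proper prior
  would be perturbed. On graphs with islands the $\eta$ recentring is
  projection-only over the non-island districts.
* **Chains and seeds.** Default budget: 4 chains × 30,000 iterations,
  10,000 burn-in, thinning 10, overdispersed starts around the crude rate
  $\log(\sum Y/\sum E)$. Per-chain seeds derive deterministically from one
  master seed, so runs are exactly reproducible; split-chain Gelman–Rubin
  $\hat R$ is computed for every model parameter and $\hat R > 1.1$ is a
  recorded warning, never a silent pass.

With the likelihood switched off (`likelihood = FALSE`) the same sampler
explores the prior; the test suite uses this to confirm the implemented
priors really are $N(0, 1000)$ and Gamma(0.1, 0.01).

## The synthetic registry

`simulation_scenario()` + `simulate_registry()` generate the model's own
data: a rook lattice (default 8 × 12 = 96 districts, mirroring a province
partitioned into ~100 health districts), stratum populations (two sexes ×
12 age bands; log-normal district sizes around 12,000; an age-incidence
profile that rises steeply and peaks at 75–79), a spatially smooth SES
index and patchy percentage covariates, and counts drawn from
$y_{ijkt} \sim \text{Poisson}(n_{ijk}\, r_{jkt}\, \lambda_{it})$ with
$\lambda$ built exactly from the fitted model's equation. Default truth
values are of the magnitude registry analyses report: IRR 0.92 per SES
unit, 1.003 and 1.01 per percentage point, $\sigma^2_u = 0.05$,
$\sigma^2_\eta = 0.1$, about 3,200 cases over a 25-year window, and a
cardia / non-cardia / unspecified topography mix of 31/49/20 percent.
Sub-site labels are assigned independently of district by default.

Structured fields are drawn *exactly* on the sum-to-zero subspace via
eigendecomposition of the graph Laplacian (coefficients
$N(0, \sigma^2/\lambda_k)$ on the positive-eigenvalue eigenvectors). The
generator therefore shares no code with the fitter's Gibbs machinery — a
genuine cross-check, verified by the expectation identity
$E[\eta'Q\eta] = \sigma^2 (n - c)$ and by positive empirical Moran's I.

What the generator does *not* emulate: postal-code geocoding error, census
undercount, population drift between periods (populations are held
constant, matching the single-census convention for a demographically
stable province), registry reporting delay, or spatially confounded
sub-site mixes. Passing recovery tests on this generator demonstrates the
estimator is correct for its own model class, not that real registry data
satisfy those assumptions.

## Validation strategy and problem sizes

The acceptance-style tests pin the implementation to independent oracles
and known truth, at sizes chosen to keep the full suite in the minutes
range: Moran's I against a literal $O(n^2)$ double loop on 100 random
graphs; permutation-test size on 200 null datasets (expected rejection
0.05, accepted band 0.02–0.09); the sampler's $\alpha$ posterior against
deterministic grid integration on a 3-district path with fixed precisions
(agreement to 0.03); 95% interval coverage of a known covariate effect in
88–99 of 100 synthetic registries at a reduced budget of 2 chains × 6,000
iterations; monotone recovery of a planted temporal trend in ≥ 95% of 20
replicates; Kolmogorov–Smirnov agreement of the precision draws with their
closed-form Gamma conditionals (10^5 draws); and prior recovery with the
likelihood disabled on a 2 × 2 lattice, where the small field makes the
heavy-tailed precision marginal mix fast enough to estimate its mean to
5%.

## Design decisions that were genuinely open

* **Estimation by MCMC.** The model class is usually fit by INLA; the
  package implements the identical model and priors by MCMC instead, since
  the model, priors and posterior summaries — not the estimator — define
  the analysis. Nothing in the interface depends on the estimator.
* **SES index.** The socio-economic score is a single-factor analysis of
  income, employment and education: z-standardized indicators, iterated
  principal-factor extraction from the correlation matrix (communality
  tolerance 1e-8, max 500 iterations), scores as the loading-weighted sum
  of standardized indicators, sign fixed so income loads positively.
  Loading-weighted scores (rather than regression-method scores) are used
  because they remain defined when indicators are perfectly collinear, a
  case the tests exercise. The index is invariant to affine rescaling of
  any indicator; an optional affine map to a fixed range is off by default.
* **Overall analyses keep C169.** Site-unspecified cases are retained in
  "overall" strata and excluded from sub-site strata; both behaviors are
  explicit filters.
* **Covariates enter on their raw scales** (IRRs per SES unit and per
  percentage point); mean-centering is available as a flag and changes only
  the intercept's interpretation.
* **Risk maps.** District risk is summarized as the posterior median of
  $\exp(u_i + \eta_i)$ (times $\exp(\gamma_t + \phi_t)$ per period), with
  "elevated" defined by the 95% interval lying above 1, and legend
  categories defaulting to quintiles with fixed user breaks supported; tied
  values take the lower category.

## Known limitations

The permutation test assumes exchangeability of the residual ratios, which
heteroscedastic $E_i$ can strain; the additive spatio-temporal model cannot
express district-specific trends (no interaction term); single-site
Metropolis mixes slowly for very large graphs (the 96-district scale it
targets is comfortable); and the high-risk flag depends on the exceedance
rule stated above — different rules give different district counts.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_registry(simulation_scenario(seed = 1))
counts <- expected_counts(sim$cases, sim$populations, region_ids(sim$graph))
glm_fit <- fit_poisson_glm(counts$Y[, 1], counts$E[, 1],
                           as.matrix(sim$covariates[, -1]))
moran <- morans_i_permutation_test(
  residual_risk_ratio(counts$Y[, 1], counts$E[, 1], glm_fit)$ratio,
  sim$graph, seed = 1)
fit <- fit_spatial(counts, sim$covariates, sim$graph, model_spec(seed = 1))
irr_summary(fit)
head(smoothed_region_risk(fit))
```

The README shows this example with the numbers it prints.
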