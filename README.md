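# dismap

Bayesian spatial and spatio-temporal disease mapping for area-level cancer
registry data.

Cancer registries report counts of a rare disease over ~100 small health
districts; raw rates at that scale are dominated by Poisson noise. `dismap`
is for epidemiologists and biostatisticians who need the standard
small-area workflow as reusable, tested R functions:

1. **Cohort preparation** — line-list cases (district, sex, 12 age bands,
   year, ICD-O-3 stomach topography code) plus stratum populations become
   observed counts *Y<sub>i</sub>* and internally standardized expected
   counts *E<sub>i</sub>* = Σ<sub>jk</sub> (y<sub>jk</sub>/n<sub>jk</sub>)
   n<sub>ijk</sub> (indirect age-sex standardization; Σ E = Σ Y by
   construction), with sub-site (cardia C160 / non-cardia C161–C168 /
   unspecified C169), sex, and five-year-period stratification.
2. **Spatial-dependency diagnostics** — a non-spatial Poisson GLM
   (log μ = log E + a + b′x) screens out covariates; Moran's I with binary
   contiguity weights,
   I = (n/S₀) · Σᵢⱼ wᵢⱼ(yᵢ−ȳ)(yⱼ−ȳ) / Σᵢ(yᵢ−ȳ)²,
   is tested against a permutation null on the residual risk ratios.
3. **Hierarchical models** — the convolution (BYM-type) Poisson regression
   Yᵢ ~ Poisson(λᵢEᵢ), log λᵢ = α + β′xᵢ + uᵢ + ηᵢ, with iid u and an
   intrinsic CAR (neighbor-averaging) prior on η; optionally extended with
   exchangeable γₜ and random-walk RW(1) φₜ temporal effects. Priors: flat
   α, β ~ N(0, 1000), Gamma(0.1, 0.01) on each precision. Fit by adaptive
   Metropolis-within-Gibbs MCMC (C++ core), with split-chain R̂
   diagnostics.
4. **Reportables** — covariate incidence-risk-ratio (IRR) tables with 95%
   credible intervals, smoothed district risk surfaces exp(uᵢ+ηᵢ)
   (× exp(γₜ+φₜ) per period), exceedance flags, and choropleth-ready risk
   categories.
5. **A synthetic registry generator** with known ground truth (ICAR fields
   drawn exactly by Laplacian eigendecomposition), so the entire chain is
   validated end-to-end without restricted registry microdata.

See `vignettes/disease-mapping-methods.Rmd` for the models, priors,
numerical choices and their rationale.

## Worked example

```r
library(dismap)

sim    <- simulate_registry(simulation_scenario(seed = 1))  # 96 districts
counts <- expected_counts(sim$cases, sim$populations, region_ids(sim$graph))
print(counts)
#> count_table: 96 regions
#>   total Y = 2950  total E = 2950

glm_fit <- fit_poisson_glm(counts$Y[, 1], counts$E[, 1],
                           as.matrix(as.data.frame(sim$covariates)[, -1]))
moran <- morans_i_permutation_test(
  residual_risk_ratio(counts$Y[, 1], counts$E[, 1], glm_fit)$ratio,
  sim$graph, seed = 1)
print(moran)
#> Moran's I = 0.1412  (n = 96, 999 permutations)
#>   one-sided p = 0.028

fit <- fit_spatial(counts, sim$covariates, sim$graph, model_spec(seed = 1))
print(fit)
#> posterior_draws: 4 chains x 2000 retained draws, 198 parameters
#>   model: spatial | 96 regions
#>   max R-hat: 1.031 (converged)

irr_summary(fit)
#>        covariate       IRR   lower95   upper95 significant
#> 1           sesi 0.9161932 0.8601635 0.9723324        TRUE
#> 2  pct_immigrant 1.0009009 0.9953543 1.0065474       FALSE
#> 3 pct_indigenous 1.0115822 1.0064799 1.0166591        TRUE

risk <- smoothed_region_risk(fit)
head(risk, 4)
#>   region_id risk_median   lower95  upper95 elevated
#> 1      R001   0.7542627 0.4972225 1.109689    FALSE
#> 2      R002   0.9682571 0.6799406 1.360590    FALSE
#> 3      R003   1.0860360 0.7502175 1.544577    FALSE
#> 4      R004   1.2728841 0.8592028 1.862382    FALSE
categorize_risk(risk$risk_median)$counts
#> cat1 cat2 cat3 cat4 cat5
#>   20   19   19   19   19
```

Reading the output: the simulated ~2,950 cases were generated with a true
SES effect of IRR 0.92 per index unit and a true Indigenous-share effect of
1.01 per percentage point; the fitted intervals recover both (0.916 and
1.012, each excluding 1), while the immigrant share is correctly found
null. Moran's I on the GLM residuals (0.141, p = 0.028) confirms the
residual spatial clustering the hierarchical model then absorbs; the risk
table gives each district's smoothed relative risk with its credible
interval, and the category counts feed map legends.

The same analysis runs from the shell against CSV inputs:

```sh
inst/exec/dismap simulate --out data --seed 1
inst/exec/dismap run --config analysis.yaml --seed 1 --out results
```

with a YAML config naming the input files, the strata (overall / male /
female / cardia / non_cardia), the period switch, and the MCMC budget.

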