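# rmnchlca

Multilevel latent class analysis of reproductive, maternal, newborn and
child health (RMNCH) service utilization, with a companion suite of
health-inequality indices.

## The problem

Household surveys across many countries record, for each woman with a
recent birth, whether she received each of 12 RMNCH services along the
continuum of care — antenatal visits, tetanus protection, facility
delivery, skilled birth attendance, postnatal checks for mother and
newborn, four childhood immunizations, age-appropriate breastfeeding, and
modern family planning. Coverage patterns are heterogeneous at two nested
levels: women differ within countries, and countries differ in their
overall service environment. `rmnchlca` is for epidemiologists and health
systems researchers who want to (i) classify women into data-driven
utilization profiles while respecting the country nesting, (ii) relate
class membership to individual and country covariates, and (iii) quantify
how unequally good utilization is distributed across wealth, education,
residence and occupation groups.

## The model

For woman *i* in country *j* with indicator vector
**y**<sub>ij</sub> = (y<sub>ij1</sub>, …, y<sub>ijH</sub>), the two-level
latent class model places a discrete class W<sub>j</sub> ∈ {1, …, M} on
each country and C<sub>ij</sub> ∈ {1, …, K} on each woman:

P(**y**<sub>j</sub>) = Σ<sub>m</sub> π<sub>m</sub> Π<sub>i∈j</sub>
[ Σ<sub>k</sub> τ<sub>k|m</sub> Π<sub>h</sub>
ρ<sub>hk</sub><sup>y<sub>ijh</sub></sup> (1 −
ρ<sub>hk</sub>)<sup>1−y<sub>ijh</sub></sup> ]<sup>w<sub>ij</sub></sup>

with country-class shares π, conditional woman-class shares τ, and
item-response probabilities ρ. Estimation is two-step: the measurement
model (π, τ, ρ) is maximized first by multi-start EM entirely in log
space; structural multinomial-logit regressions for class membership at
both levels are then estimated with ρ held fixed. Class numbers are chosen
sequentially by AIC/BIC (individual-level BIC for K, country-level BIC and
its entropy-adjusted ICL variant for M), with normalized entropy reporting
classification quality. Country-level clustering of any binary outcome is
summarized via a random-intercept logistic model through the latent-scale
intraclass correlation ICC = σ²/(σ² + π²/3) and the median odds ratio
MOR = exp(√(2σ²)·Φ⁻¹(0.75)). Inequality in the posterior probability of
the optimal-utilizer class is measured by group difference/ratio, absolute
and relative concentration indices, slope and relative indices of
inequality, and population attributable risk/fraction, all with
country-clustered bootstrap confidence intervals.

## Worked example

```r
library(rmnchlca)

sim <- simulate_rmnch(rmnch_config(J = 30, n_per_group = 200, seed = 7))
fit <- fit_mlca(sim$data, K = 2, M = 2, n_starts = 10, seed = 11)
fit
#> Two-level latent class model: K = 2, M = 2
#> N = 6000 records in J = 30 groups, 12 indicators
#> loglik = -37772.1150 after 14 EM iterations (best of 10 starts)
#>
#> Country-class shares (pi):
#> high_coverage  low_coverage
#>         0.533         0.467
#>
#> Individual-class shares given country class (tau):
#>               optimal suboptimal
#> high_coverage   0.825      0.175
#> low_coverage    0.481      0.519
```

The generator plants a two-class structure (82.7% vs 46.5% optimal
utilizers in high- vs low-coverage countries); the fitted τ rows recover
it to within sampling error, and the estimated item profile puts facility
delivery at 0.97 and skilled attendance at 0.98 in the optimal class.
`summarize_classes(fit$posteriors)$lower` reports the overall class split
(here 66.5% optimal), `glance(fit)` the information criteria and entropy
(E_low 0.94, E_high 1.00 — countries are classified with certainty), and
`autoplot(fit)` the class-conditional probability profile.

Clustering and equity summaries use the same grammar:

```r
mor_icc(1.10)
#>   sigma2   ICC   MOR
#> 1    1.1 0.251  2.72

d <- dplyr::mutate(sim$data, optimal = fit$posteriors$indiv_post[, 1])
s <- stratified_outcome(d, "optimal", "urban", order = c("0", "1"))
cluster_bootstrap_ci(s, "difference", B = 500, seed = 1,
                     advantaged = "1", disadvantaged = "0")
#>   measure    estimate  CI_low CI_high type     n_countries   B
#> 1 difference  0.00334 -0.0184  0.0275 absolute          30 500
```

A variance of 1.10 on the logit scale corresponds to an ICC of 25.1% and a
median odds ratio of 2.72: a quarter of the latent variation sits between
countries, and two otherwise-identical women from two random countries
typically face almost threefold odds differences. The urban–rural
difference above is null by construction (the default generator carries no
covariate effects), and its bootstrap CI duly straddles zero.

The full pipeline — simulation or CSV input, harmonization, optional
chained-equations imputation, class-number selection, measurement and
structural fits, equity table — runs from one configuration via
`run_pipeline()`, or from a shell through
`inst/scripts/rmnchlca --config config.yaml --out results/`.

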