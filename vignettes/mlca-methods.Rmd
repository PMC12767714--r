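---
title: "Two-level latent class analysis of RMNCH service utilization: models, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level latent class analysis of RMNCH service utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmnchlca)
```

## The model and its assumptions

`rmnchlca` analyzes binary service-receipt indicators for women nested in
countries with a discrete latent class at each level. Country $j$ carries a
class $W_j \in \{1,\dots,M\}$ drawn with probabilities $\pi_m$; woman $i$
in that country carries a class $C_{ij} \in \{1,\dots,K\}$ drawn with
probabilities $\tau_{k|m}$ that depend on the country class; and her $H$
indicators are conditionally independent Bernoulli draws with item
probabilities $\rho_{hk}$ that depend only on her own class. The marginal
likelihood of a country's data integrates over both latent variables:

$$
P(\mathbf{y}_j) \;=\; \sum_{m=1}^{M} \pi_m \prod_{i \in j}
\Bigl[\; \sum_{k=1}^{K} \tau_{k|m} \prod_{h=1}^{H}
\rho_{hk}^{\,y_{ijh}} (1-\rho_{hk})^{1-y_{ijh}} \Bigr]^{w_{ij}} .
$$

The key assumptions are (i) *local independence*: indicators are
independent given the woman's class, so all cross-indicator association is
carried by the classes; (ii) *nonparametric country effects*: between-country
heterogeneity enters through a discrete class rather than a continuous
random effect; and (iii) *missing at random under the model*: a missing
indicator cell simply contributes no Bernoulli factor. Survey weights
$w_{ij}$ enter as frequency weights on the log scale; whether design
weights belong in a latent class likelihood is genuinely debatable, so
unweighted fits are available by dropping the weight column.

## Estimation

`fit_mlca()` maximizes the weighted log-likelihood by EM. All products run
in log space with log-sum-exp over $k$ (per record) and $m$ (per country),
so likelihoods remain finite at survey scale. The E-step computes country
posteriors $P_{jm} \propto \pi_m f(\mathbf{y}_j \mid m)$ and joint record
posteriors $q_{imk} = P_{j(i)m}\,P(C_i = k \mid m, y_i)$; the M-step
updates $\pi$, $\tau$, $\rho$ as posterior- and weight-weighted means. The
likelihood is multimodal, so the fit runs from `n_starts = 20` random
initializations — $\rho$ from overall item means perturbed by $\pm 0.25$
uniform noise, $\tau$ and $\pi$ from flat Dirichlet draws — and keeps the
best. Convergence is declared when the relative log-likelihood change
falls below `tol = 1e-8` (default cap 1000 iterations). Item probabilities
are clamped to $[10^{-6}, 1-10^{-6}]$ to prevent degenerate log-likelihoods
at the boundary.

Latent class labels are arbitrary, so every fit is canonicalized: women's
classes are ordered by descending mean item probability (the first class
is the "optimal utilizer" profile, ties broken on the first indicator),
and country classes by descending share of that optimal class (the first
is "high coverage"). MAP assignments break posterior ties toward the lower
class index. These rules make restarts, refits and simulation recoveries
directly comparable.

The two-step structural stage (`fit_two_step()`) holds $\rho$ fixed and
re-maximizes the same likelihood over multinomial-logit membership models:
country class on country covariates, and woman class on individual
covariates separately within each country class (the stratified reporting
layout). Its EM M-step solves posterior-weighted multinomial logistic
problems by Newton–Raphson with a $10^{-6}$ ridge and step-halving;
coefficients beyond $\pm 15$ on the logit scale are flagged as separation.
The reference category at each level is the canonical low/suboptimal
class, so positive coefficients mean higher odds of optimal utilization.
Wald covariances come from the information of the converged weighted
logistic problems — the complete-data information. This ignores both
step-1 uncertainty (the usual two-step trade-off) and the gap between
complete-data and observed information, which closes as classification
entropy approaches 1; the null-effect simulation below checks the
resulting calibration empirically (94% coverage at nominal 95% over 200
replicates of 25 × 60 records). A country-level nonparametric bootstrap is
the recommended alternative when classes separate weakly.

## Class enumeration and classification quality

`select_structure()` enumerates class counts sequentially: sweep $K$ with
$M = 1$, fix the winner, sweep $M$, then re-check $K$ at the chosen $M$.
The individual-level criterion is BIC with $n = $ records
(`BIC_low`); the country-level criterion is BIC with $n = J$ countries
(`BIC_high`), or its entropy-adjusted variant
`ICL_BIC_high` $=$ `BIC_high` $+ 2\,EN_{high}$ with
$EN_{high} = -\sum_j\sum_m P_{jm}\ln P_{jm}$ — the two coincide exactly
when countries are classified with certainty. Normalized entropy
$E = 1 - \frac{-\sum_i \sum_k P_{ik}\ln P_{ik}}{n \ln K}$ is reported at
both levels. At the country level the sum runs over the $J$ groups with
denominator $J \ln M$: this is the scale on which a perfectly classified
country level reads exactly 1.00, which is what strongly separated
two-level fits produce; `per_individual_higher = TRUE` restores the
per-record variant for users who prefer record-weighted certainty.
Logarithms are natural throughout; the normalization cancels the base.

## Random-intercept summaries

For a binary outcome clustered by country,
`fit_random_intercept_logistic()` wraps a logistic mixed model estimated
by adaptive Gauss–Hermite quadrature (15 nodes by default; the unit tests
verify that doubling the nodes moves the log-likelihood by under
$10^{-4}$). The latent-scale intraclass correlation is
$\sigma^2/(\sigma^2 + \pi^2/3)$ and the median odds ratio
$\exp(\sqrt{2\sigma^2}\,\Phi^{-1}(0.75))$. A variance of 1.10 gives
ICC $= 25.06\%$ and MOR $= 2.72$. Note that an MOR quoted alongside a
*rounded* variance need not match the closed form applied to that rounded
value — e.g. variances anywhere in $(1.13, 1.16)$ round to 1.1 yet give
MOR $\approx 2.76$ — so `mor_icc()` always reports the closed form of the
variance it is given. The variance CI is a profile interval on the
random-effect standard deviation, squared.

## Inequality measures

All equity measures operate on a `stratified_outcome`: weighted subgroup
shares $p_g$, subgroup means $y_g$ of a bounded outcome, and midpoint
cumulative ranks $x_g$. The outcome is, by convention, the *posterior
probability* of the optimal class rather than the hard MAP indicator —
it preserves classification uncertainty and changes smoothly under
refitting; pass the MAP column instead to compare. The families are:

* difference $y_{adv} - y_{dis}$ and ratio $y_{adv}/y_{dis}$ for any
  two subgroups (the only measures used for binary dimensions such as
  residence and occupation);
* absolute/relative concentration indices
  $RCI = \tfrac{2}{\mu}\sum_g p_g y_g x_g - 1$, $ACI = \mu \cdot RCI$ for
  ordered dimensions (wealth poorest→richest, education none→higher);
* slope/relative indices of inequality from a $p_g$-weighted regression
  of $y_g$ on $x_g$, by default on the logit link because the outcome is
  bounded (the identity link is available; with two subgroups the logit
  fit is exact and closed-form);
* population attributable risk $\max(y_{ref}-\mu, 0)$ and fraction
  $100\,PAR/\mu$, with the best-performing subgroup as the default
  reference — the counterfactual of levelling everyone up — and negative
  values floored at zero.

$ACI = \mu \cdot RCI$ and $PAF = 100\,PAR/\mu$ hold exactly by
construction and are asserted on arbitrary inputs in the test suite, as
are the null fixed points (0 for absolute, 1 for ratio-type measures on
constant outcomes). Inference resamples *countries* with replacement
(default $B = 1000$, percentile intervals), reflecting the national-level
clustering of the design.

## The synthetic-data generator

`rmnch_config()` encodes the study conditions the package validates
against: two country classes with shares $(0.656, 0.344)$, optimal-utilizer
shares $0.827$ and $0.465$ within them, and the eleven class-conditional
item probability pairs of the fitted two-class profile (facility delivery
$0.97/0.20$, skilled attendance $0.98/0.25$, postnatal care $0.73/0.10$
and $0.76/0.09$, BCG $0.97/0.60$, DPT $0.87/0.39$, polio $0.77/0.38$,
measles $0.86/0.44$, antenatal care $0.25/0.12$, family planning
$0.41/0.15$, breastfeeding $0.66/0.63$). The tetanus-toxoid pair is not
part of that profile; the default $(0.55, 0.30)$ is a free choice of this
package (roughly the observed marginal split around the two-dose
threshold) and must not be read as an estimated value. Covariate effects
default to zero; multinomial-logit effects can be planted at either level,
with intercepts derived from $\pi$ and $\tau$ so zero effects reproduce
the marginal shares exactly. Group sizes may be fixed, explicit, or
log-normal around a requested mean (country sample sizes in multi-country
surveys are right-skewed data, not parameters); weights default to 1 with
an optional mean-one gamma spec mimicking survey weights. One integer seed
drives sizes, covariates, classes, indicators and weights through a fixed
stream-splitting rule, so output is bit-identical across runs.

What the generator deliberately does *not* emulate: two-stage cluster
sampling geometry (strata/PSUs), spatial structure, local dependence
between indicators, and informative missingness beyond a
logistic-on-a-covariate MAR rule. Passing recovery tests on this generator
therefore shows the estimator is correct *under the model*, not that real
survey data satisfy local independence or MAR.

## Data preparation choices

Indicator harmonization follows the guideline-based thresholds: the
antenatal-care indicator requires ≥ 4 visits for surveys before 2017 and
≥ 8 from 2017 on; tetanus protection ≥ 2 doses; DPT and polio 3 doses
each. Age-appropriate breastfeeding is accepted as a pre-coded binary
because no operational formula is part of the indicator set's definition
here. Records with unusable survey years are retained with the
year-dependent indicator set to missing and listed in a `problems`
attribute.

Two routes handle missing indicators, *not* to be combined: likelihood
factor omission inside the EM (the default), or chained-equations multiple
imputation (`chained_impute()`: logistic regression per incomplete binary
variable, coefficients drawn from their asymptotic normal, 10 cycles,
$m = 5$, visit order by increasing missingness). When the pipeline
imputes, the measurement model is fitted to every completed dataset and
class-proportion tables averaged; structural coefficients are the natural
target for Rubin pooling, which applies unchanged to the per-dataset fits.
Continuous country covariates should be z-standardized before structural
fits; coefficients are then per-SD effects.

## Numerical choices and degenerate inputs

Probability clamping at $10^{-6}$; mixture weights floored at $10^{-300}$
inside logs only; EM monotonicity asserted in tests to a $10^{-7}$
relative slack for float roundoff. Requesting more classes than
distinguishable response patterns (or $M > J$) warns and flags the fit as
boundary rather than failing. A grid-search oracle validates the EM on
instances of ≤ 8 records: an exhaustive 0.05 lattice over $(\tau, \rho)$
refined to 0.01 and then 0.001 around its optimum; the EM log-likelihood
must not fall below the lattice maximum and agrees with the refined
maximum within $10^{-4}$. Bootstrap replicates that lose a subgroup
entirely return `NA` and are dropped with a warning; `B = 1` is allowed
but warned as degenerate.

## Validation scale

The test suite exercises recovery at the survey-like scale of 30 countries
× 500 women ($N = 15{,}000$): item-probability RMSE under 0.02 with the
optimal-class facility-delivery and skilled-attendance probabilities
recovered within $\pm 0.01$, MAP agreement with truth above 95% at both
levels, planted structural effects ($\gamma = \ln 2$) recovered within
their 95% CI, and null-effect coverage of 95% ± 4pp over 200 replicates of
25 × 60 records. Class-number selection and subset-sensitivity checks run
at 25 × 100. The maternal-care indicator block (7 strongly separating
items) reproduces the full-model classification with adjusted Rand index
above 0.8; the child-care block cannot — its items separate the classes
only weakly (e.g. breastfeeding 0.66 vs 0.63), which is itself the
substantive point of a sensitivity split and is asserted as
far-above-chance agreement rather than near-identity.

## Known limitations

No local-dependence modeling; no continuous random-effect variant of the
country level; no one-step joint estimation or three-step bias-adjusted
(BCH/ML) corrections — naive two-step standard errors are anti-conservative
when entropy is low; no design-based (strata/PSU) variance estimation
beyond per-record weights; concentration indices are uncorrected
(no Wagstaff/Erreygers bounds adjustment for binary outcomes).
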