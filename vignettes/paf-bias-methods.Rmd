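---
title: "Attributable fractions under confounding and selection bias: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable fractions under confounding and selection bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafbias)
```

## The estimand and the two formulas

The population attributable fraction (PAF) is the proportion of deaths in a
closed cohort that would not have occurred had the exposure been removed.
Two classical estimators dominate applied work. Writing `RR` for the
mortality risk ratio of the exposed against the never-exposed reference
group, the *prevalence-of-deceased* form uses `pd`, the share of the
deceased who were exposed:

$$\mathrm{PAF}_{pd} = \frac{pd\,(RR - 1)}{RR},$$

and the *prevalence-of-exposed* form uses `pe`, the share of the whole
cohort that was exposed:

$$\mathrm{PAF}_{pe} = \frac{pe\,(RR - 1)}{1 + pe\,(RR - 1)}.$$

In a single internally consistent closed cohort the two are algebraically
identical, because $pd = pe\,RR / (1 + pe\,(RR-1))$. The package
property-tests this identity on randomized count tables to $10^{-12}$; it
is the reason `paf_pd()` and `paf_pe()` always agree when both are fed
quantities computed from the same stratum.

They stop agreeing the moment their inputs come from different places —
an adjusted RR from a model combined with a crude `pd` or `pe` from a
biased sample — and that divergence is precisely what this package is
built to expose.

### Confounder strata and the weighted sum

With an observed confounder, the package computes the PAF within each
confounder stratum $i$ and standardizes by $W_i$, the share of all deaths
occurring in stratum $i$:

$$\mathrm{PAF} = \sum_i W_i \, \mathrm{PAF}_i.$$

Death-share weights (not population-share weights) are the definition used
throughout; a population-share variant would be a different estimand and is
deliberately not offered as a default anywhere. The weighted sum with
pd-based stratum PAFs is algebraically identical to the counterfactual PAF
below; the package asserts this identity exactly on randomized cohorts.

### The counterfactual ground truth

For simulated or hypothetical cohorts the true PAF is computable directly:
apply each stratum's reference-level death probability to the entire
stratum, sum the counterfactual deaths $D_{cf}$, and form
$(D - D_{cf})/D$. `counterfactual_paf()` returns this value together with
the per-stratum counterfactual count table, so every worked scenario can be
checked against its own ground truth.

### Multi-level exposures

With several non-reference exposure levels (e.g. former and current
smokers), the pd form sums per-level terms and the pe form pools the
per-level excess risks:

$$\mathrm{PAF}_{pd} = \sum_k \frac{pd_k (RR_k - 1)}{RR_k}, \qquad
  \mathrm{PAF}_{pe} = \frac{\sum_k pe_k (RR_k - 1)}
                           {1 + \sum_k pe_k (RR_k - 1)}.$$

Both reduce exactly to the two-level formulas with one non-reference level,
which is tested as an identity.

## Why the two formulas react differently to bias

*Observed confounding* distorts the crude RR (and hence both crude PAFs),
but stratum-specific PAFs combined with the weighted sum recover the truth
with **either** formula — the package's first worked example
(`run_exercise1()`) walks through exactly this: a crude PAF of 0.233
against a true (counterfactual and weighted-sum) PAF of 0.222.

*Endogenous selection* (collider bias) is different. When study inclusion
depends on latent health more strongly for the exposed than for the
unexposed, deaths among the sampled exposed are under-counted. This biases
three ingredients at once: the sample RRs, the sample `pd`, and the
death-share weights $W_i$. Supplying externally adjusted RRs repairs only
the first. The pe-based stratum PAFs are then unbiased (exposure prevalence
is not distorted in the scenario), leaving only the $W_i$ bias, while the
pd-based PAFs remain biased through `pd` itself. `run_exercise2()`
quantifies this: with corrected RRs the pe route lands within a fraction of
a percent of the true 0.301, while the pd route sits near 0.263, roughly
13% too low. This asymmetry, not any one number, is the methodological
point of the package.

## Standardized risk ratios

`standardized_rr()` offers Mantel–Haenszel (default) and death-share-
weighted averaging of stratum RRs. Mantel–Haenszel is the default because
it is the field-standard stratified risk ratio with well-understood
behaviour in sparse strata. On the confounding scenario the two give 2.213
and 2.252; summaries of stratified RRs depend on the standard chosen, and
no single "adjusted RR" should be treated as canonical — which is why the
PAF machinery works from stratum-level quantities rather than from one
pooled RR.

## Replication mode

Published hand calculations are often carried out on intermediates rounded
to three decimals, and some printed totals are only reachable that way
(e.g. $0.290 \cdot 0.273 + 0.306 \cdot 0.727 = 0.302$, where full
precision gives 0.301). `weighted_sum_paf(..., mode = "replication")`
rounds stratum PAFs and weights half-up to 3 decimals before summing and
stamps the result's provenance accordingly. Full precision is always the
default; replication mode exists solely to reproduce rounded-intermediate
arithmetic, never to improve agreement with anything. Display rounding
throughout the package is half-up (`round_half_up()`), 3 decimals for PAFs
and proportions, 2–3 for RRs, matching the conventions of the applied
literature; internal computation is always full precision.

## The synthetic-cohort generator

`population_spec()` describes a multi-stratum closed cohort by stratum
size, per-level exposure prevalence, and per-level death probability.
Two selection mechanisms turn a population into an observed sample:

* **`direct_risk`** asserts the sample's death probabilities directly.
  This is the device of the bundled hypothetical scenario: the sample
  equals the population except that smokers' mortality is lower in the
  sample (0.429/0.375 instead of 0.500), the visible footprint of health
  selection. It reproduces printed tables exactly and is the default
  device for the worked examples because it is deterministic.
* **`latent_health`** is a mechanistic collider model. Each individual
  carries latent health $U \sim N(0,1)$; inclusion has log-odds
  $a_0 + a_1 U$ (slope $a_{1,\text{exposed}}$, offset $a_2$ for the
  exposed) and death probability is the cell's base $q_x$ shifted on the
  log-odds scale by $b_1 U$. The defaults ($a_1 = 1$, $b_1 = -1$,
  $a_2 = 0$) are deliberately simple: inclusion rises with health,
  mortality falls with it. Collider bias appears exactly when selection on
  $U$ differs by exposure ($a_{1,\text{exposed}} \ne a_1$ or
  $a_2 \ne 0$); the qualitative description this model makes testable
  never came with published parameter values, so these defaults are the
  package's own choice and are documented as such.

Expected mode computes all cell counts as exact integrals over $U$
(61-point Gauss–Hermite), so the collider *direction* — sample RR below
population RR in every stratum — is asserted on expectations, not on noisy
draws; the integrals are cross-checked in the tests against adaptive
quadrature. Stochastic mode draws individuals with a caller-supplied seed
(recorded in the result, no global RNG state left behind) and converges to
the expected counts, which is also tested.

What the generator does **not** emulate: survey weighting and frame
mechanics, institutionalization, time-varying exposure status, or any
calibration to a real survey's inclusion probabilities. Passing tests
therefore demonstrate the estimators' algebraic and statistical behaviour
under the stated mechanisms, not fidelity to any particular survey's
selection process.

## Discrete-time survival machinery

Person-period data (one row per subject per half-open age interval at
risk, death assigned to the interval in which it occurs — the standard
discrete-time likelihood construction) are modelled with the
complementary log-log link, $q = 1 - \exp(-\exp(\eta))$, whose
exponentiated coefficients are discrete-time hazard ratios.

`fit_cloglog()` maximizes the Bernoulli likelihood by Newton–Raphson with
step-halving; an accepted step never decreases the log-likelihood, and
convergence requires a relative log-likelihood change below $10^{-10}$
(at most 100 iterations; non-convergence is flagged, never silent).
Rank-deficient designs are rejected up front with the offending columns
named. Frequency weights let aggregated covariate-pattern rows stand in
for expanded microdata. The fitter is validated three ways: saturated
models must reproduce empirical proportions exactly (a binomial MLE
identity), coefficients must agree with an independent generic GLM
implementation to $10^{-6}$, and the reported log-likelihood must be
reproducible from the stored coefficients and data to $10^{-8}$.

`fit_cloglog_re()` adds a group-level (entry-cohort) normal random
intercept and maximizes the marginal likelihood with a fixed-grid
Gauss–Hermite rule (default 20 points; fixed rather than adaptive so
results are deterministic; fewer than 3 points is refused). The SD is
log-parameterized inside the optimizer; estimates below $10^{-3}$ are
flagged as boundary fits, and the SD-zero limit must reproduce the
fixed-effects log-likelihood, which is tested.

Because the exponentiated-coefficient "RR" of a clog-log model is a hazard
ratio, the package also provides `risk_ratios()`: model-predicted period
death probabilities averaged over the observed covariate distribution,
with the exposure set to each level in turn. Both outputs are labelled
explicitly; on a saturated baseline model of the bundled survey table the
standardized risk ratios equal the count-based RRs (1.489 and 1.524),
while the hazard ratios would not.

### The selection demonstration

`simulate_person_periods(..., entry = "staggered")` reproduces the
age-at-entry selection of long-running survey panels: later-entering
groups are observed only if they survived the pre-entry periods. With a
shared group frailty, observed late entrants over-represent low-mortality
groups — and exposed survivors especially — so a pooled fit attenuates
the exposure coefficient while the random-intercept (group-conditional)
fit does not. The tests assert the direction (conditional exceeds
marginal) on a simulated panel of 6,000–8,000 subjects over six periods
with 24 entry groups; parameter recovery of the fixed effects is verified
over 200 replicates of 5,000 subjects, sizes at which the Monte-Carlo
error of the checks is comfortably below the asserted margins.

## Adjusted RRs from outside the package

Confounder- or bias-adjusted RRs estimated elsewhere (e.g. from shared
frailty survival models fitted to restricted microdata) enter through
`paf_from_adjusted_rrs()` / `rr_table_to_paf()`: the user supplies a
stratum-by-level RR table, the observed cohort supplies `pe`/`pd` and the
weights, and the result records which formula and weights produced each
number. `run_exercise3()` accepts either such an RR table or an
already-assembled pd/pe PAF pair, for which it reports the proportionate
difference $(\mathrm{PAF}_{pd} - \mathrm{PAF}_{pe})/\mathrm{PAF}_{pe}$ —
the summary statistic of how much the pd route understates the burden
under selection.

## Degenerate inputs and numerical choices

* Zero reference-level deaths make the RR undefined; zero total deaths
  make `pd` undefined. Both are hard errors by default. An explicit
  `continuity = TRUE` applies a 0.5 correction to every cell of the
  affected stratum; it is opt-in because silent corrections change
  reported values.
* Counts are validated as nonnegative but may be non-integer, so
  expected-count cohorts flow through the same types as data files.
* Protective exposures (RR < 1) yield negative PAFs with a warning rather
  than an error; the estimand is well-defined, merely unusual in this
  literature.
* The Levin denominator $1 + pe(RR-1)$ and its multi-level analogue must
  be positive; violations are domain errors, not NaNs.
* `paf_pe` is evaluated directly rather than via `pd`, so the two
  formulas' agreement in consistent cohorts is an emergent (and tested)
  property, not a shortcut.

## Known limitations

* No variance or confidence-interval estimation for PAFs; the package's
  scope is point estimation and bias anatomy.
* Closed cohorts only: no censoring-aware person-time denominators. The
  discrete-time module handles staggered entry, but the count-table side
  assumes everyone is followed over one interval.
* The latent-health selection model is one smooth mechanism among many;
  it demonstrates direction and magnitude under its own assumptions, not
  the selection process of any particular survey.
* Reproducing published *model-based* adjusted RRs requires the microdata
  those models were fitted to; the package reproduces the assembly
  arithmetic from supplied RRs or PAFs instead.
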