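---
title: "Population-level HLA-disease profiles: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-level HLA-disease profiles: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaprofiler)
```

## The model

The package estimates ecological (population-level) associations between
HLA allele frequencies and disease prevalence. The working model is that
prevalence varies exponentially with allele frequency, so that on the log
scale

$$\ln P_c = \alpha + \sum_a \beta_a f_{a,c} + \varepsilon_c,$$

where $P_c$ is percent prevalence in country $c$, $f_{a,c}$ is the
population frequency of allele $a$ there, and $\varepsilon_c$ collects
country-level influences not mediated by HLA. The estimand per allele is
the marginal Pearson correlation $r_a = \mathrm{cor}(f_{a,c}, \ln P_c)$
across countries, Fisher z-transformed to $r'_a = \mathrm{atanh}(r_a)$ to
normalize its distribution for the profile-level analyses. A negative
$r'$ is read as population-level protection, a positive one as
susceptibility, and $|r'|$ as strength.

Two caveats are inherent to the design and worth stating up front. First,
these are ecological correlations: they describe countries, not
individuals, and do not by themselves establish individual-level risk.
Second, because every allele's correlation shares the same per-country
prevalence vector, the 127 values of a profile are not independent draws;
this matters for the calibration of profile-level tests (see
*Validation*, below).

## Parameters that matter

* `min_countries` (default **9**): an allele enters the profile only if
  its frequency is reported in at least this many of the countries that
  also have a prevalence value. The default is a conservative coverage
  threshold for a 14-country panel; below 3 the correlation itself is
  undefined, and the package refuses thresholds under 3. Per-allele N
  still varies (9–14 in the reference profile) because each correlation
  uses exactly the countries reporting that allele — the only
  intersection rule consistent with the reference profile's N column.
* Prevalence transform: prevalence is computed as
  $100\,\times$ cases/population and correlated as $\ln(\text{percent})$.
  The correlation is invariant to the 100× scaling; the choice affects
  reporting only.
* `clamp` in `hla_profile()` / `fisher_z()`: $|r| = 1$ (attainable on
  tiny or noiseless inputs) maps to $\pm\infty$ under atanh and would
  poison every downstream ANOVA, so it is a domain error by default;
  `clamp = TRUE` pulls such correlations to $1 - 10^{-12}$ and is used in
  simulation harnesses where perfect collinearity arises by construction.

## The inference battery

`profile_stats()` (also `summary()` on a profile) runs, in deterministic
order:

* **Sign splits and proportion tests.** Counts of negative and positive
  $r'$ (overall, per class) with `prop_z_test()`, the one-sample normal
  approximation $z = (k - np_0)/\sqrt{np_0(1-p_0)}$ with **no continuity
  correction** and two-sided $p = 2(1-\Phi(|z|))$. This exact form is
  what profile reports print; the exact binomial test
  (`binom_exact_test()`, via `stats::binom.test`) is shipped as a
  clearly-labelled alternative and agrees with the approximation to
  within 0.005 by $n = 1000$. A Wald unpooled two-proportion z-test
  (`wald_two_proportion()`) is provided for comparisons of independent
  groups, e.g. the protective fraction of class I vs class II entries;
  it is not valid for complementary proportions of a single sample,
  where the one-sample test is the right tool.
* **Sample-size bias check.** One-way ANOVA of $r'$ with N as the
  grouping factor (for a single factor the F statistic is the same
  whether the factor is called fixed or random), plus all pairwise
  group-mean comparisons. The pairwise method after ANOVA is a design
  choice the data do not dictate; the default is Bonferroni-adjusted
  pooled-variance t-tests (conservative), configurable through
  `pairwise_group_means()`.
* **Class/gene decomposition.** A nested ANOVA with class (I vs II) and
  gene within class (6 loci: df 1, 4, and residual). The error term for
  the class effect is genuinely ambiguous in a nested layout: testing
  over the residual mean square treats genes as fixed; testing over the
  gene-within-class mean square treats them as a random sample of loci.
  Both are exposed (`class_error = "residual"` (default) or `"gene"`).
* **Strength comparison.** Pooled-variance independent-samples t-tests of
  $|r'|$ between negative and positive entries, per class and per gene
  (Welch available via `var_equal = FALSE`); cells with fewer than two
  entries of either sign are skipped with a warning rather than tested.

A failing component is recorded as an error entry in the report without
aborting the others.

## The synthetic-data generator

`hla_sim_config()` describes a study: number of countries, alleles per
locus, a concentration parameter for between-country frequency spread,
per-allele slopes $\beta_a$, baseline $\alpha$, noise $\sigma$, a
missingness rate, and the population used to back-convert prevalence to
integer case counts. The defaults are fixed study conditions chosen to
mirror the reference profile's setting, not tuning knobs:

* 14 countries and the reference allele counts per locus
  (20/36/13/15/14/29, 127 alleles);
* `concentration = 50`, giving between-country frequency spread of the
  order seen across Western European populations;
* `alpha = log(0.35)`: a baseline prevalence of 0.35%, mid-range for
  European T1D;
* `noise_sd = 0.1` on the ln-prevalence scale (non-HLA country effects);
* `missing_rate = 0.2`: expected coverage $14 \times 0.8 = 11.2$
  countries, matching the reference profile's N range of 9–14;
* `population = 1e7`, so integer case-count rounding perturbs ln
  prevalence by under $10^{-5}$.

Frequencies are drawn per locus as Dirichlet compositions: one mean
composition per locus over its alleles **plus an unlisted remainder
category** (so listed alleles sum to less than 1, as real per-locus
reports do), then one composition per country around that mean with
spread $\propto 1/\text{concentration}$. Effects are additive on the
ln-prevalence scale with no interactions, matching the model above.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure between loci, demographic or geographic structure
among the countries, reporting biases of real frequency databases, and
prevalence misclassification. Passing tests on synthetic data therefore
show that the estimator recovers the model it assumes — not that real
data satisfy that model.

## Validation and a calibration subtlety

`recovery_experiment()` repeatedly simulates, fits, and measures
sign-recovery of effect alleles, the mean $r'$ of null alleles, and the
rejection rate of the overall sign-split test. Three properties anchor
the test suite:

1. **Noiseless limit.** With $\sigma = 0$ and a single effect allele, that
   allele's frequency is the only source of prevalence variation, so its
   fitted sign matches the generating slope in every replicate
   (sign-recovery rate exactly 1.0). With several effect alleles the
   *marginal* correlation of one allele also absorbs the others'
   contributions, so sign recovery per allele is only guaranteed when the
   frequency columns are orthogonal — the unit tests construct exactly
   that case.
2. **Null calibration.** Under an all-null configuration the sign-split
   test should reject at its nominal level. This is exactly true only
   when allele frequencies are independent across alleles: conditional on
   the shared country noise, the allele correlations are then i.i.d. and
   the sign count is Binomial(n, ½). The generator's
   `composition = "independent"` mode provides that regime (every
   frequency an independent Beta(2, 30) draw), and the acceptance check
   runs there (500 replicates, fixed seed, rejection within ±0.02 of
   0.05). Under the default compositional mode, the within-locus sum
   constraint makes allele signs negatively dependent, under-dispersing
   the sign proportion relative to the binomial — the test errs on the
   conservative side there, a real feature of compositional ecological
   profiles rather than a defect of the test.
3. **Noise degradation.** Sign recovery decays monotonically as $\sigma$
   grows (checked over a small $\sigma$ grid).

## Numerical choices and degenerate inputs

* Internal computation is full double precision; 3 decimals is a display
  convention only (the packaged reference profile carries 3-decimal
  $r'$, which is why its ANOVA F is compared at tolerance 0.01).
* Ordering of profiles is canonical and total — locus order A, B, C,
  DPB1, DQB1, DRB1, then numeric allele fields — so fitted profiles are
  invariant to input row order and ranking ties break deterministically.
* Degenerate inputs fail loudly: unknown loci, frequencies outside
  [0, 1], duplicate (allele, country) keys, non-positive populations and
  duplicate countries are errors at ingestion; zero-variance or
  under-covered alleles are reported in the profile's `unanalyzable`
  attribute rather than silently dropped; all-equal $r'$ makes the
  ANOVAs error rather than return F = 0/0.
* Country keys are case-insensitive opaque strings with a small alias
  map for common plot-label abbreviations, so the two input tables join
  regardless of formatting.

## Problem sizes used in the checks

The packaged reference profile (127 alleles) drives all fixture-based
checks and runs in well under a second. Simulation-based checks use the
default 127-allele, 14-country configuration: 500 replicates for the null
calibration, 5–30 replicates elsewhere; the full suite completes in
about two minutes on a single core.

## Known limitations

* Ecological associations do not transfer to individual risk without
  validation; confounding by unmodelled country-level factors (diet,
  pathogen exposure, diagnostic practice) is possible in real data.
* The profile is two-field; finer resolution is truncated, and
  haplotypes are out of scope.
* Per-allele p-values are offered only as an optional reporting column
  (`cor_pvalues = TRUE`); the package deliberately performs no per-allele
  multiple-testing correction, as profile-level inference is the object.
* The afnd-style reader is best-effort for a web export whose column
  layout is not pinned; the simple CSV dialect is the stable interface.
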