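---
title: "Detecting sex-specific smoking effects by significance-rank differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-specific smoking effects by significance-rank differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

Tobacco smoking leaves broad marks on the blood transcriptome and methylome,
and epidemiological evidence suggests that some smoking-related disease risks
(cardiovascular disease in particular) differ between the sexes. Testing
whether molecular smoking responses are sex-specific by comparing *effect
sizes* between sex strata is fragile: effect sizes depend strongly on
exposure intensity and duration, which are rarely measured well enough to
adjust for, and the strata usually differ in size and hence in power.

`sexspec` implements a rank-based alternative. The idea is that unequal
exposure between the sexes would scale effect sizes but should not reorder
features *within* a sex stratum, so the position of a feature in the
stratum's significance ranking is a more robust signature of response than
its coefficient. The procedure is:

1. **Mixed-sex differential analysis.** For each feature (log2 expression
   intensity, or the M value `log2(beta / (1 - beta))` for methylation), fit
   a linear model of current-vs-never smoking adjusted for sex, age, BMI,
   cohort, future disease, case-control status, processing batch and (for
   methylation) leukocyte composition. Former smokers are excluded from the
   contrast. Candidates are the features passing an FDR threshold
   (Benjamini–Hochberg; defaults 0.10 for expression, 0.05 for methylation;
   Bonferroni is available as a switch because both conventions are in use
   for methylation candidate lists).
2. **Sex-stratified re-analysis.** Fit the same model (without the sex
   covariate) separately in males and females over the *full* feature
   universe, and rank every feature by ascending p-value. Ranks are integers
   `1..N`; ties are broken lexicographically by feature id so the ranking is
   a deterministic bijection.
3. **Rank differences.** For each candidate, `d = rank_male - rank_female`.
   Positive `d` means the feature is more significant in females.
4. **Survival-function calls.** A Gaussian null is fitted to the candidate
   set's own differences (mean, and maximum-likelihood SD). For `d >= mu`
   the complementary CDF (survival function) of the fitted Gaussian gives
   the tail probability and the candidate's direction is *female-specific*;
   for `d < mu` the lower tail is used and the direction is
   *male-specific*. Candidates with tail probability below `alpha = 0.05`
   are flagged. A histogram of all candidate tail probabilities (bin width
   0.05) is attached as a diagnostic: an excess in the lowest bin signals a
   genuine sex-specific subgroup.
5. **Balance check.** Because the female stratum is typically larger,
   the analysis is repeated on balanced subpopulations: every male plus an
   equal number of females sampled at random, preserving the female
   population's cohort-by-smoking-status proportions, and the overlap of
   each round's flagged list with the full-population list is reported
   (per-round, mean, SD, and the cumulative curve over progressive unions).

```{r}
library(sexspec)
cfg <- study_config(seed = 1)
res <- run_sex_specific_pipeline(cfg, "methylation_beta",
                                 resample = subsample_spec(rounds = 10, seed = 1))
head(res$calls[res$calls$flagged, ])
res$overlap
```

## Why a null fitted on the candidates themselves

The null hypothesis is "rankings are not sex-related", under which candidate
rank differences scatter around zero in a steep unimodal distribution. The
null is fitted on the candidate differences rather than the whole universe
because the candidates are the population of interest: their ranks are
compressed toward the top of both strata by construction (they were selected
as smoking-responsive overall), so a universe-wide null would be badly
miscalibrated for them. The cost is contamination: genuinely sex-specific
candidates inflate the fitted SD and make the test conservative. A
median/MAD variant (`fit_gaussian_null(robust = TRUE)`) resists this
contamination; it is provided behind a flag and is not the default, which
keeps the default estimator the plain moment/ML fit.

## Calibration of the one-sided per-direction test

The tail is evaluated one-sided per direction with `alpha` applied per
feature. This has a known consequence: if candidate differences were exactly
Gaussian, the flagged fraction under the null would be `2 * alpha` (each
tail contributes `alpha`), not `alpha`. In practice rank differences have
bounded support and lighter-than-Gaussian tails, and the package's own
calibration analysis (all-null cohorts of 2,000 features, candidate list
fixed at the 500 smallest mixed-analysis p-values — an FDR rule correctly
selects almost nothing under a global null, so the candidate-list size must
be fixed for this analysis) measures a flagged fraction between `alpha` and
`2 * alpha`, around 8% at `alpha = 0.05`. Users who need a null flagging
rate of `alpha` exactly should halve `alpha`; the default follows the
per-feature `p < 0.05` convention of the procedure as published. The
direction split is exactly calibrated: under the null, false flags divide
evenly between female- and male-specific.

## The synthetic cohort

No raw data accompany the study design this package emulates, so a
generator stands in for it. Its defaults reproduce the published design
margins exactly: 236 males / 413 females across NSHDS and EPIC-Italy;
43/102/91 male and 100/93/220 female current/former/never smokers; the
cohort-by-sex-by-smoking cross-classification (which the design reports
only as margins) is completed by largest-remainder proportional allocation.
Age and BMI are truncated normals matching the published means and ranges
(SDs chosen so the printed ranges are plausible extremes). Case-control
status (the subject's role in the nested matched design) and future disease
(their own later diagnosis: breast cancer only in females, B-cell lymphoma
in either sex) are related but deliberately not collinear. Six leukocyte
fractions are Dirichlet-distributed around typical adult whole-blood
proportions and sum to one; the differential model consumes them directly
(dropping one to avoid the sum-to-one collinearity) rather than estimating
them from methylation.

Feature matrices are built on the analysis scale — log2 for expression, M
values for methylation, mapped back to beta so stored methylation values lie
strictly in (0, 1). Methylation baselines are drawn from a bimodal M-scale
mixture (hypo- and hyper-methylated compartments). Each feature carries one
truth class: `null`, `both_sex`, `female_specific` or `male_specific`;
smoking adds the configured magnitude to current smokers of the responding
sex(es) only. Defaults: 2,000 features per modality, 480 both-sex responders
and 20 female-specific, methylation effects of 1.0 M units, expression
effects of -0.32 log2 units (an expression ratio of 0.80, the published
median), residual SD 0.5, ten additive batches of SD 0.3, and small random
per-feature covariate effects. Former smokers are generated (the design
includes them, and the balance check can preserve their proportions) but
carry no smoking term, matching their exclusion from the contrast.

What the generator does **not** emulate: probe-level microarray artifacts,
normalisation residue, dye bias, correlated feature blocks (co-methylated
regions, co-expression modules), within-subject correlation between the two
assays, and exposure-intensity gradients. Passing recovery tests on this
generator therefore shows that the statistic behaves as designed under its
own assumptions — independent features, additive effects, Gaussian noise —
not that it would attain the same power on real arrays.

One scale caveat: the synthetic universe is 2,000 features with ~500
candidates (25%), whereas a genome-wide study has hundreds of thousands of
features with <1% candidates. The compressed geometry caps the attainable
rank difference for truly sex-specific features (a null feature's male rank
can be at most 2,000), so measured recovery (~80% of injected
female-specific features at 1.0 M units) understates what the same effect
sizes would yield at genome-wide scale, where a sex-specific feature's rank
difference can be orders of magnitude larger than the null spread.

## Numerical and design choices

* **Batch as fixed effects.** Processing dates are modelled as fixed
  indicator covariates rather than variance components: with many small
  batches the OLS fit is deterministic, dependency-light, and equivalent
  for ranking purposes. The per-feature fits go through `limma::lmFit` with
  ordinary (non-moderated) t-statistics, so each feature's result is exactly
  the single-feature `lm` fit.
* **Ties and determinism.** All rankings break p-value ties
  lexicographically by feature id; every stochastic step takes its stream
  from a configuration seed and restores the caller's RNG state, so equal
  seeds give bit-identical outputs end to end.
* **M-value formula** is fixed as `log2(beta / (1 - beta))`; effects are
  injected on the M scale so the generator's effect parameter and the
  model's coefficient are commensurable.
* **Degenerate inputs** fail loudly: rank-deficient designs name the
  collinear column, null fits require at least three non-identical
  differences, matrix parsing reports the offending line, and infeasible
  balanced subsamples (more males than females) are errors.
* **Largest-remainder female allocation.** The balance check preserves the
  female population's stratum proportions by largest-remainder rounding of
  the proportional quotas (the published description states that
  proportions were maintained but not the rounding rule).
* **Median convention for table summaries.** Published summary medians are
  reproduced with: odd count, the middle order statistic; even count, the
  mean of the two central order statistics truncated toward zero at the
  printed precision. This is the unique simple convention that reproduces
  all four even-count medians of the curated tables simultaneously.
* **Curated fixtures.** The shipped result tables resolve the source's
  numeral dialect (female-rank cells printed with a period plus three
  digits are thousands-separated integers — validated by reproducing the
  printed female median rank of 432), correct one gene-symbol typo, and
  store the final methylation column as the absolute value its definition
  requires. Printed delta-beta columns are authoritative; recomputation
  from the rounded beta means is checked only within ±0.02. The printed
  per-row rank-difference p-values are carried but not recomputed: they
  depend on the full candidate rank vectors, which were never published.

## Problem sizes

The test suite and the acceptance script run the statistical analyses at
2,000 features and the full 649-subject design: type-I error pooled over
three all-null cohorts, calibration over ten all-null cohorts (5,000
candidate calls), and recovery over 200 simulated cohorts (50 in the
acceptance script). These sizes give Monte-Carlo standard errors of under
one percentage point on the reported rates.

## Known limitations

* The survival-function test is calibrated per tail, not per feature (see
  above); its null flagging rate lies between `alpha` and `2 * alpha`.
* The Gaussian form of the null is an assumption; heavy contamination by
  true positives inflates the default fit (use `robust_null = TRUE` in
  `run_sex_specific_pipeline()` when the candidate list is expected to be
  dominated by sex-specific features).
* Rank differences are not comparable across universes of different sizes;
  the statistic orders features within one analysis, it does not estimate a
  transferable effect quantity.
* The balance check subsamples females only; it rules out female-excess
  group-size bias, not other asymmetries.
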