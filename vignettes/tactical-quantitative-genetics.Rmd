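---
title: "Selection gradients and intertactical heritability in tactic-structured pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection gradients and intertactical heritability in tactic-structured pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactqg)
```

## The scientific problem

In species with alternative reproductive tactics (ARTs), the same trait can
sit under different selection regimes in different classes of individuals.
Coho salmon are the motivating case: females, large fighting "hooknose"
males, and small sneaking "jack" males all express length at maturity, and
length affects fitness differently in each class.  Intralocus conflict —
sexual or tactical — arises when (1) selection on the shared trait is
antagonistic between classes and (2) the trait is genetically correlated
across classes, so that no class can respond to its own selection without
dragging the others along.

`tactqg` implements both halves of that diagnosis for a two-generation
wild pedigree:

1. **Tactic-specific selection gradients** on length at maturity
   (`selection_table()`, `interaction_scan()`), and
2. **intra- and intertactical heritabilities** from single
   parent–offspring regressions (`heritability_grid()`), with an
   unequal-variance correction and dual null-hypothesis tests.

Because suitable public pedigrees are scarce and never ship with latent
genetic values, the package also contains a forward simulator
(`simulate_pedigree()`) whose generative model makes every estimator's
expected value known in closed form.  All calibration claims in the test
suite are statements about this simulator, not about any particular field
dataset.

## Data model and filtering

A pedigree is one row per individual: `id`, `sex`, `tactic`
(`female`/`hooknose`/`jack`), return `year`, `length_mm` (fork length at
maturity), `rs` (reproductive success: offspring surviving to return as
adults), `dam_id`/`sire_id` (NA when unknown), and `generation`
(`parent`/`offspring`).  Validation (`as_pedigree()`) enforces the
structural invariants — tactic = female exactly for females, positive
lengths, integer non-negative `rs`, parent links resolving to the correct
sex, no self-ancestry, and parent-generation years strictly preceding
offspring-generation years — and names the offending rows on failure.

Tactic labels present in the input are retained untouched;
`classify_male_tactic()` (jack strictly below 500 mm, hooknose at or
above, reflecting the bimodal male length distribution) is applied only
when the tactic column is absent.  Study-inclusion filtering
(`filter_pedigree()`) is an explicit logged pass — length present, `rs`
present, optionally both parents known and wild origin — never a silent
drop.

Subset semantics (`subset_pedigree()`): `NULL` means "no filter on this
field", while a zero-length set is a vacuous filter that returns an empty
pedigree; composing two subsets equals one subset with intersected
filters.

## Selection analysis

Within every analysed subset, length is standardized to that subset's mean
in units of its sample SD (n − 1 denominator, the convention that matches
the OLS standard errors), and relative fitness is `rs` divided by the
subset mean `rs`.  Pooled analyses standardize on the pooled subset — the
pooled mean is never an average of per-subset means.  Individuals with
`rs = 0` are included: zeros are real fitness outcomes, not missing data.

The linear gradient β is the OLS slope of relative fitness on standardized
length; the quadratic gradient γ is **twice** the quadratic coefficient of
the joint model `w ~ x + x²` (its SE also doubled).  The doubling is the
standard convention that makes γ the curvature of the selection surface;
the associated caveat that some software reports unsure-doubled values is
handled here by doubling exactly once, in one place.  `selection_table()`
reports both the linear-only β and the jointly estimated linear slope
(`beta_joint`), because the two differ whenever the length distribution is
skewed and published tables rarely say which was used.

Significance comes from Poisson log-link GLMs of *absolute* reproductive
success via analysis of deviance: drop-one likelihood-ratio chi-square
tests, not Wald tests.  `interaction_scan()` reproduces a backward
sequence over the full model with tactic, year, and all length
interactions: both three-way terms tested against the full model, the
quadratic three-way dropped, the linear three-way retested, then each
two-way length interaction tested by drop-one from the no-three-way
model.  The output order is fixed and documented; deviance tests are
invariant to the reference level chosen for the categorical codings
(asserted in the tests).

Degenerate subsets (fewer than 5 records, zero length SD, zero mean `rs`)
become NA rows with the reason retained, mirroring how published tables
leave cells blank when a tactic did not return in a year.

## Heritability analysis

The parent–offspring regression for a (parent tactic, offspring tactic)
cell regresses the **per-parent mean** length of that parent's offspring
of the given tactic on the parent's own length, one point per parent,
unweighted by family size.  Per-parent means match both the wording of the
source models ("mean offspring length") and the error degrees of freedom
of published single-regression tables; each offspring contributes to both
its dam-side and its sire-side cell, which is what makes the 3×3 grid
asymmetric.  The offspring-level interaction model
(`offspring_interaction_model()`) is the exception: it is fitted on
individual offspring (its published error df implies per-offspring units)
and serves as the omnibus test of whether resemblance differs by offspring
tactic before the grid is read cell by cell.

Under the additive model a parent transmits half its breeding value, so
`h² = 2·b_op` when the parent and offspring classes have equal phenotypic
variances.  When they do not, the Falconer correction applies:
`h² = 2·b_op·(σ_p/σ_o)`, the 95% CI is `3.92·se·(σ_p/σ_o)` (z = 1.96, the
convention that reproduces published CI widths), and the slope expected
under `h² = 1` becomes `0.5/(σ_p/σ_o)`.  Two tests are reported per cell:
a t test of slope = 0 (`h² = 0`) and an F test of slope = null
(`h² = 1`), with `F = t²` when the nulls coincide.

Three choices here were genuinely open and are fixed as follows:

* **Which SDs enter the ratio.**  σ_p is the sample SD of length of all
  *parent-generation* individuals of the parent tactic and σ_o that of all
  *offspring-generation* individuals of the offspring tactic.  Published
  analyses do not say which generation's SDs they used; tying each SD to
  the generation actually contributing that margin of the regression is
  the internally consistent reading, and the choice is configurable in
  spirit by computing the grid from any subset.
* **When to correct.**  The correction triggers exactly when the two-sided
  variance-ratio F test between those two groups rejects at `alpha_var`
  (default 0.05).  Diagonal cells compare two generations of the same
  tactic, so they almost never trigger and the occasional false trigger
  multiplies by a ratio near 1.
* **Maternal effects** are not modelled: in salmonids maternal influence
  on length dissipates before maturity, and the single-regression design
  cannot separate it anyway.  Dam-line heritabilities should be read with
  that in mind.

## The simulator and what "calibrated" means

Each individual carries a 4-component breeding-value vector: three
tactic-specific expressions of length (`a_f`, `a_h`, `a_j`, unit variance,
correlation matrix `r_G`) plus an independent liability component `a_L`.
Phenotype is `μ_t + √h²_t·σ_t·a_t + e` with environmental variance
`(1 − h²_t)σ²_t`, so the phenotypic SD per tactic is exactly the
configured σ_t.  Males are jacks when
`√h²_L·a_L + √(1 − h²_L)·ε` exceeds the normal quantile implied by the
configured jack fraction — a liability-threshold maturation rule with
heritability `tactic_liability_h2` (default 0.9, consistent with reported
maturation-threshold heritabilities).  The liability component is kept
uncorrelated with the length components: using a length expression itself
as the liability would truncate the expressed-length distribution within
male tactics and break the variance bookkeeping that the recovery results
below rely on.

Offspring draw a dam and a sire with probability proportional to parental
reproductive success, receive the parental mean breeding value plus a
Mendelian-segregation deviate with covariance `Σ/2`, and the **emitted**
parental `rs` is the realized offspring count, matching the
"offspring that returned" semantics of the fitness measure.  Reproductive
success is Poisson with `log mean = b0_t + b1_t·x + b2_t·x²` on
within-tactic standardized length.  Everything is driven by one
Mersenne-Twister stream seeded once at the top of `simulate_pedigree()`
(inversion normals), so a config plus seed is byte-reproducible.

Under this model the estimators have closed-form expectations:

* diagonal grid cells estimate the generative `h²_t`;
* the off-diagonal (o, p) cell estimates `r_G(o,p)·h_o·h_p`, the
  intertactical heritability.

The default configuration emulates the motivating cohort: 301 dams + 322
sires (jack fraction 0.18) in 2002–2003, 775 offspring in 2004–2006;
tactic means 733/735/423 mm; the female SD anchored at 48 mm (consistent
with a female SE of 1.84 at n ≈ 680) and the hooknose and jack SDs set by
the observed variance ratios (hooknose:female = 1/0.415, hooknose:jack =
2.77); per-tactic h² of 0.36/0.87/0.47 mirroring the published diagonal
estimates; `r_G` identity (the published result was *no* intertactical
heritability); and fitness coefficients matching the pooled per-tactic
gradients and mean reproductive successes (2.61/2.80/1.21).

For the estimator-calibration experiments in the acceptance tests
(parameter recovery and the intertactical expectation), the fitness regime
is set flat (`uniform_selection()`: common `b0 = log 2.5`, `b1 = b2 = 0`)
at 1000 dams, 1000 sires and 4000 offspring over 100 seeds.  A flat regime
isolates the estimator: family membership is then unselected with respect
to length, and every cell — including the jack cells, which are small at
the realistic jack fraction — accumulates enough families for the bias of
the mean over seeds to be meaningful.  These sizes keep the whole
calibration suite under a minute of CPU while leaving Monte-Carlo error
well inside the tolerances being asserted.

What the simulator does **not** emulate: overlapping generations,
year-structured recruitment (offspring years are assigned uniformly, so
year × tactic selection heterogeneity is absent by construction unless
configured), environmental determination of tactic beyond the liability
residual, mutation, inbreeding (mates are drawn with replacement from
unrelated founders), and origin effects (hatchery vs wild).  Passing
calibration therefore shows the estimators are correct *under the additive
trivariate model*, not that any field dataset satisfies that model.

## Numerical conventions and degenerate inputs

* Sample SDs everywhere (n − 1); standardization tolerances asserted at
  1e-10.
* Poisson GLM convergence epsilon 1e-10, 100-iteration cap; a
  non-converged fit is flagged, a separated fit (|coefficient| diverging)
  is an error, never a silent result.
* Negative-binomial fits use the mean/size parameterization with log link
  and ML-estimated size; its log-likelihood weakly dominates the Poisson's
  on the same data, an asserted invariant.
* Ties and boundaries: the jack rule is *strictly* below threshold; a
  500 mm male is a hooknose.
* Zero-length subset filters return empty pedigrees rather than erroring;
  degenerate analysis subsets return NA rows with reasons rather than
  aborting a whole table.
* All-equal lengths or zero mean `rs` in a subset raise explicit errors
  (`standardize()`), because both invalidate the standardization that the
  gradients are defined on.

## Known limitations

* Heritabilities come from single parent–offspring regressions, not an
  animal model; with few families per cell (jack cells especially) the
  estimates are noisy and occasionally fall outside [0, 1], which is
  expected behaviour of the estimator, not a bug.
* The variance-correction trigger is itself a hypothesis test, so the
  correction indicator is subject to type-I/II error at small n; the
  grid exposes `corrected`, `sigma_p`, `sigma_o` so users can recompute
  under a different rule.
* Fitness is measured as offspring surviving to return, which folds
  offspring survival into parental fitness; gradients inherit that
  interpretation.
* Age is deliberately absent from all models: in the motivating system age
  and tactic are completely confounded (all jacks mature a year earlier),
  so age effects are not identifiable alongside tactic.
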