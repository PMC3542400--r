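---
title: "Modeling corn masa flour fortification and usual folic acid intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling corn masa flour fortification and usual folic acid intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masafort)
```

## The scientific question

In the United States, enriched cereal grain products are fortified with
folic acid, but corn masa flour — the basis of tortillas, tamales, and
other staples consumed disproportionately by Mexican-American households —
historically was not. Extending fortification to corn masa flour would
raise folate intake in a population with elevated neural-tube-defect risk,
but any fortification proposal must also quantify the safety side: what
fraction of the population would end up with a *usual* daily total folic
acid intake above the tolerable upper intake level (UL, 1,000 µg/day for
adults, lower for children)?

`masafort` implements that analysis end to end on survey data shaped like a
national 24-hour-recall survey: a fortification scenario engine, 30-day
supplement averaging, an analytic exclusion cascade, a measurement-error
model that converts one or two recalls per person into a usual-intake
distribution, and delete-one-group jackknife inference. Because real
microdata cannot ship with the package, a seeded synthetic generator with
known ground truth stands in for the survey; every estimator is validated
against that truth.

## The fortification scenario

A scenario is a fortification level (µg folic acid per 100 g of corn masa
flour) plus the set of food codes treated as corn-masa foods. The mass of
corn masa flour in a food is proxied by its non-wholegrain corn grams, so a
recall row contributes

`added µg = nonwholegrain_g × level / 100`.

The worked example used throughout: 32 g of non-wholegrain corn at
140 µg/100 g adds `32 × 140 / 100 = 44.8` µg.

```{r}
added_folic_acid(32, 140)
```

Total daily intake per person-day is food folic acid + scenario addition +
a 30-day average of supplemental folic acid (`dose × servings × days / 30`).
The *current* scenario is the same computation at level 0, so modeled
totals dominate current totals row by row, by construction.

## The usual-intake measurement-error model

A single 24-hour recall confounds between-person differences with
day-to-day fluctuation; tail fractions computed from raw recall days are
badly biased outward. `fit_usual_intake()` separates the two variance
components in the style of the classical usual-intake estimators built on
repeated recalls:

1. **Transformation.** A shifted power-family transform (log included) is
   selected over the grid λ ∈ {−1, −0.95, …, 1} to minimize the absolute
   survey-weighted skewness of the transformed day intakes. If the data are
   degenerate (essentially constant), λ = 1 is used and all adjustment
   steps are skipped.
2. **Covariate adjustment.** Transformed intakes are regressed (weighted
   least squares) on day-of-week — weekday / Friday / weekend by default, a
   full 7-level scheme optionally — and interview mode (in-person /
   telephone), and estimated effects are removed relative to the
   weekday/in-person reference, standardizing all days to a common
   reference recall.
3. **Variance components.** The within-person variance σ²w is the weighted
   mean of half the squared difference between the two adjusted recalls of
   two-day persons; survey cycles with only one recall per person can
   borrow an external σ²w. The between-person variance is
   σ²b = weighted var of person means − σ²w · mean(1/dᵢ), floored at zero.
4. **Person-level representation.** The best predictor of a person's usual
   transformed intake shrinks their mean toward the weighted grand mean by
   Fᵢ = σ²b / (σ²b + σ²w/dᵢ). For the *population distribution*, however,
   full shrinkage under-disperses: the shrunken values have variance
   Fᵢ·σ²b < σ²b, which systematically understates tail fractions (measured
   at about −3 percentage points on the adult UL in simulation). The
   distribution representation therefore scales deviations by √Fᵢ, which
   reproduces σ²b exactly — the classical "adjusted daily intake"
   construction. Both representations are stored.
5. **Back-transformation.** Usual intake on the µg scale targets the
   long-run *mean*, not the median day, so the inverse transform carries
   the second-order adjustment h(y) + h″(y)·σ²w/2 (for the log,
   exp(y + σ²w/2)).

`percent_above()` then evaluates the weighted fraction of usual intakes
above a cut-point. When more than 0 but fewer than 12 persons lie beyond
the cut-point the estimate is flagged **NE** (not estimable): sample-tail
estimates at that effective size are dominated by a handful of
observations and are not reportable.

## Scenario comparison is coupled, not refit

`scenario_exceedance()` fits the model once, on current intake, and pushes
the fortified person-day totals through that same fit
(`project_usual_intake()`): the same λ and shift, the same covariate
effects, the same variance components and per-person shrinkage weights.
The rationale is that the fortification addition is a deterministic
function of the foods already reported — it does not alter the
recall-error structure — so re-estimating nuisance parameters from shifted
data adds only noise. The practical consequence is structural
monotonicity: since modeled totals dominate current totals person-day by
person-day, every projected usual intake, and hence every exceedance cell
at every cut-point, satisfies modeled ≥ current — in the full sample and
in every jackknife replicate. With independent refits this can fail in
small strata purely through re-estimated covariate coefficients.

## Inference

Variances come from delete-one-group jackknife replicate weights: persons
are randomly partitioned into R groups; replicate r zeroes group r and
rescales the rest to preserve the weight total; then
SE = sqrt(((R−1)/R) · Σ (θr − θ̂)²). Replicate refits hold λ fixed at its
full-sample value — λ selection on a grid is discontinuous, and letting it
jump between replicates injects spurious variance. The current-vs-modeled
difference uses a *paired* t-test: the jackknife SE of the per-replicate
differences, with R−1 degrees of freedom, exploiting the near-perfect
correlation between scenarios evaluated on the same sample. A replicate
that deletes an entire small domain carries no information about that
domain's variability; its estimate is set to the full-sample value (zero
contribution).

## The synthetic generator and its truth

`generate_survey()` draws, per person: demographics with analytic weights
that differ by race/ethnicity stratum (so weighting matters), a lognormal
usual food folic-acid intake (between-person SD 0.5 on the log scale),
day-level intakes around it (within-person SD 0.6, a +10% weekend bump,
day-2 recalls mostly by telephone), corn-masa consumption with
race-specific probabilities and a person-constant lognormal non-wholegrain
amount, and a 30-day supplement inventory (34.2% users; doses 200–1,000
µg; days taken 30/15/7; 15% of users a second product). A quarter of
persons contribute only one recall. Exclusion triggers (pregnancy, recall
quality, missing supplement data, implausible supplemental intake ≥ 93,000
µg/day) are planted at realistic rates.

The generator also emits its own truth: each person's true usual food
intake is the day-of-week-standardized long-run mean exp(µᵢ + σ²w/2), plus
the constant supplement average, plus `nwg × level / 100` under the
scenario. The truth table reports, per age bracket and UL cut-point, the
weighted fraction above the UL with and without fortification — the target
the estimators are tested against. What the generator does *not* emulate:
multi-stage cluster sampling (weights are independent of the outcome
within stratum), seasonal effects, correlated supplement and food intake,
or food-composition measurement error.

## Numerical choices

- λ grid −1..1 step 0.05; ties broken toward the first minimizing value;
  non-finite skewness criteria treated as +∞.
- σ²b floored at zero; when σ²b + σ²w/dᵢ = 0 the shrinkage weight is 1.
- Back-transform domain violations (λy + 1 ≤ 0) raise an error rather than
  silently clipping; usual intakes are floored at 0 µg after the bias
  adjustment.
- Confidence intervals are Wald, clipped to [0, 100].
- Strata smaller than `min_stratum_n` (default 25) are omitted with a
  warning rather than reported.

## Problem sizes

The defaults target desk scale: 2,000–5,000 synthetic persons, ≤ 122
replicates, ~100 food codes. A full pipeline run (all axes, all
populations, all supplement groups, 32 replicates, 2,000 persons) takes on
the order of a minute; the test suite, including 20-seed parameter
recovery at n = 5,000, runs in well under five minutes.

## A small end-to-end example

```{r, eval = FALSE}
bundle <- run_pipeline(list(
  generator = list(n_persons = 1000, n_replicates = 16),
  scenario = list(level_ug_per_100g = 140),
  seed = 7, axes = c("total", "sex"),
  populations = "all", supplement_groups = "all"
))
bundle$adult_table[, c("stratum", "current_pct", "modeled_pct", "diff_p")]
render_tables(bundle, "tables_out")
```

## Limitations

Estimates are only as good as the non-wholegrain gram proxy for corn masa
flour mass; supplement intake is treated as a constant daily average, not
an episodic process; the jackknife assumes the replicate groups mimic the
sampling design, which the synthetic generator satisfies by construction
but real surveys only approximate; and NE cells are suppressed rather than
smoothed — no model-based tail extrapolation is attempted.
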