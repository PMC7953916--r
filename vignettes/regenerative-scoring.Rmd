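---
title: "Scoring regenerative farm systems and validating the score against outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring regenerative farm systems and validating the score against outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(regenscore)
```

## The model

Regenerative agriculture is defined by two principles — reduce uniform
disturbance (tillage, synthetic agrichemicals) and increase diversity
(biological, and of enterprises) — but certifying an operation needs a
number, not a philosophy. The approach implemented here distills an
operation to a short practice questionnaire and an unweighted composite:

* **Cropland** (row crops and orchards): nine binary items. Eliminating
  synthetic fertilizers, herbicides, fungicides, insecticides and tillage
  each earn a 1; including cover crops (or deliberately fostered resident
  vegetation), diversified field margins/hedgerows, organic amendments and
  grazing livestock each earn a 1. The composite is the sum, out of 9.
  Cornfield surveys asked only six of the nine questions (no fungicide,
  field-margin or organic-amendment item), so corn composites are out of 6
  and the three unasked items are never imputed. A normalized score
  (composite / maximum) is reported for cross-system display only.
* **Rangeland**: four ordinal items scored 0–2 — ivermectin use (none 2,
  single annual dose outside the grazing period 1, multiple doses or any
  dose during grazing 0), stocking density (<5 AU/ha 0, 5–10 AU/ha 1,
  >10 AU/ha 2), rotation frequency (≥30 d 0, 10–<30 d 1, <10 d 2) and
  post-grazing rest (none 0, 1–30 d 1, >30 d 2). High stocking density with
  fast rotation and long rest is the adaptive multi-paddock end of the
  scale. The composite is out of 8.

Scores in surveyed populations are strikingly bimodal: operations bundle
practices, so composites pile up near the bottom and the top of the range.
The classifier exploits this instead of imposing a model: the **dividing
score** is the midpoint (rounded half up) of the widest gap between
consecutive distinct observed scores. On the packaged tables this
reproduces the published split — cropland divides at 5 (gap between 3 and
6, midpoint 4.5) and rangeland at 3 (gap between 2 and 4):

```{r thresholds}
rangeland <- score_rangeland(practice_table("rangeland"))
find_threshold(rangeland$composite_score)

cropland <- score_cropland(practice_table("cropland"))
find_threshold(cropland$composite_score[cropland$system == "cropland_full"])
```

For the corn subset the widest gap is (1, 3): its upper edge 3 is the
"dividing line around 3" convention, while the midpoint convention gives 2.
Both numbers are exposed in the threshold object rather than guessing which
was intended; classification always uses the midpoint rule.

## Numerical and boundary choices

* **Bin edges.** Stocking density at exactly 5 or 10 AU/ha codes 1 (closed
  middle bin); rotation at exactly 30 d codes 0 and at exactly 10 d codes 1
  (honouring the printed "30 d or more" and "less than 10 d"); rest at
  exactly 30 d codes 1, strictly more codes 2. The published rest-period
  wording for the middle bin is internally inconsistent, so the 30-day edge
  assignment is a documented package decision; a rest between 0 and 1 day
  is coded 1 with a warning.
* **Rounding.** Gap midpoints round half *up* (4.5 → 5); base R's banker's
  rounding would report 4.
* **Gap ties.** If two gaps tie in width the higher-score gap wins, keeping
  the conventional cluster anchored at 0. The rule is deterministic and
  order-independent.
* **Errata in the packaged tables.** Two of the 88 published matrix rows
  print a composite that differs by one from the sum of their own printed
  item codes. The composite column is corroborated by the published cluster
  structure (the rangeland gap between 2 and 4 exists only with the printed
  composite), so the fixtures correct the single aberrant item code in each
  row and flag it (`erratum = TRUE`); see `?practice_table`.

## Soil metrics

The soil module starts from reported masses and assay values (lab protocol
is out of scope) and implements the closed forms: loss-on-ignition organic
matter `100·(dry − ignited)/dry`; fine particulate organic matter as the
organic portion of the 53–500 µm fraction over the initial soil mass; core
bulk density `mass/(π r² depth)` (default 8.5 × 5 cm cores); single-ring
infiltration as the ~2.51 cm head (444 mL in a 15 cm ring) over time to
saturation; and the Haney soil health score
`CO₂-C/10 + WEOC/50 + WEON/10`.

Carbon and nitrogen stocks are compared at an **equivalent soil mass**
(default 6,000 Mg/ha, roughly 0–60 cm) rather than a fixed depth, removing
compaction bias. Layer boundaries give knots of cumulative soil mass
against cumulative element mass; a cubic spline through the knots is
evaluated at the reference mass. Because an unconstrained natural cubic can
produce physically impossible non-monotone stocks, the default interpolant
is the Fritsch–Carlson monotone cubic (`stats::splinefun(method =
"monoH.FC")`), which is exact at knots, cannot overshoot the bracketing
cumulative totals, and tracks the chord more closely than the Hyman-filtered
alternative; `method = "natural"` is available for sensitivity checks. Note
that *any* interpolating cubic bends away from the piecewise-linear curve
where concentrations jump between adjacent layers — on a two-layer profile
halving from 2 %C to 1 %C the mid-knot value sits about 2.5 % above the
linear value — so agreement with a linear oracle is a smoothness diagnostic,
not an identity. The profile is never extrapolated: a profile whose total
mass falls short of the reference mass is an error, and the depth at which
the reference mass is reached is attached as a diagnostic.

## Community metrics

Diversity indices are computed from morphospecies counts: Shannon
`H = −Σ p log p` with the **natural log** (the source never states a base;
ln is the ecological default), and "DS" as the **Gini–Simpson** index
`1 − Σ p²` (the inverse form `1/Σ p²` is available behind a flag, since the
label is never defined). Richness counts species with positive counts;
trophic-guild abundances (coprophage, predator, parasitoid, herbivore,
pest) partition the total exactly, and every counted morphospecies must
carry a guild label. Vegetation metrics are the disc-pasture-meter
compression height mean (a biomass index, not calibrated mass) and ground
cover classed into half-open bins [0,25), [25,50), [50,75), [75,100] —
closed at 100 — resolving the overlapping printed class labels.

Replicate samples within an operation are **pooled** (counts summed) before
indices are computed, matching how replicate plots are composited into
single farm values; a per-sample-then-average mode exists because the
original choice is not stated.

## Validation models

`fit_score_regression()` regresses an outcome on the integer composite
score by ordinary least squares, averaging replicates to one value per
operation first; soil clay percent enters untransformed as a covariate in
carbon-related models. `fit_mixed_model()` handles resampled designs with
farm (and optionally field-within-farm) random intercepts and an optional
month fixed factor, estimated by REML via lme4. lme4 reports no p-values;
this package uses the **containment degrees-of-freedom** convention:
operation-level terms (intercept, score, clay) are tested on
`n_operations − p_between` df, within-operation terms on residual df. The
original analysis names no estimation method, so small p-value differences
against other software are expected. `variability_trend()` computes the
coefficient of variation of an outcome across operations per score level
and regresses it on score — the "standard deviation as a proportion of the
mean" pattern; levels with a single operation carry no dispersion
information and are dropped. `run_validation()` batches these fits and
reports a sign per outcome at two-sided α = 0.05, with no multiple-testing
correction (none was applied originally; the number of models is attached
so readers can apply their own).

When the farm variance is estimated at zero the mixed fit is singular and
its fixed effects coincide with least squares; the fit is returned with a
note rather than an error. A subtlety worth recording: in a world whose
farm variance is zero only *in expectation*, the REML estimate lands on the
zero boundary only about half the time, so exact agreement with least
squares is not a deterministic property of that world. The test suite
therefore realizes "zero farm variance" exactly — residuals are centred
within farm — which forces the boundary estimate and makes the
nested-model-limit check deterministic at any seed. When a grouping is
inestimable (one observation per group) the model falls back to least
squares with a classed warning.

## The synthetic world

`sim_config()` states the emulated conditions once:

* a latent regenerative class with probability 0.5, class-wise per-item
  adoption probabilities 0.9 / 0.1 sharpened by a coupling of 1 (per-item
  probability `plogis((1+coupling)·qlogis(p_class))` ≈ 0.99 / 0.01), which
  reproduces the observed bimodality and makes practices bundle within
  operations;
* four replicate fields per operation (the corn design), clay drawn once
  per operation uniformly in 10–40 % (a realistic agricultural range; clay
  is a soil property, not a replicate-level draw);
* linear outcome effects whose signs mirror the validated pattern: soil
  carbon +2 Mg/ha per score unit with a 0.5 clay slope, yield −1.5 per
  unit, pest abundance flat, profit +15 per unit; farm random intercepts
  and residual noise with SDs of realistic magnitude relative to the
  intercepts;
* score-proportional variance inflation for profit (residual SD
  `45·(1 + 0.25·score)`), chosen so the coefficient of variation rises from
  about 0.18 at score 0 to about 0.34 at score 9 — the qualitative
  "SD grows as a proportion of the mean" phenomenon; magnitudes are
  data-dependent and not reproduced;
* community richness Poisson with mean `8 + 1.5·score`, log-normal
  abundances (meanlog 2, sdlog 1, rounded up so every drawn species is
  observed), guilds assigned by fixed proportions.

Randomness is split into named substreams derived from the master seed, so
adding an outcome never perturbs the draws of another. The generator does
**not** emulate spatial structure, weather, prices, real taxonomy, or
nonlinear score effects: a green end-to-end test establishes that the
estimators recover a stated linear world with these noise structures, not
that any real farm behaves this way — the published field statistics are
not reproducible without the archived field data, which this package
deliberately does not require.

## Known limitations

* The gap threshold assumes the bimodality it was designed around; on a
  score set without a pronounced gap it still returns the widest (possibly
  width-1) gap, and in-gap classifications are flagged rather than refused.
* Containment df is one convention among several; REML singular fits are
  reported, not suppressed.
* The ESM stock depends on the interpolant between knots (see above);
  knot values are exact under every option.
* Net profit is unit-agnostic per-hectare arithmetic over direct costs and
  revenues only.
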