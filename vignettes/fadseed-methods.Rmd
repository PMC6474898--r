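---
title: "Methods: seed spot-cover morphometrics and fitness-associated dispersal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed spot-cover morphometrics and fitness-associated dispersal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadseed)
```

## The scientific question

Fitness-associated dispersal (FAD) predicts that less fit individuals
disperse — or produce more dispersible offspring — more often than fitter
ones. In an ant-dispersed (myrmecochorous) annual, the dispersibility of a
seed is largely set by how attractive it is to harvester ants, which collect
seeds for the lipid-rich elaiosome at one pole. The measurable seed trait at
the centre of this package is **spot cover**: the percentage of the seed
coat covered by dark pigmentation spots. The analysis chain asks three
linked questions:

1. Do lower-fitness mother plants (fewer total flowers) produce seeds with
   lower spot cover ("unspotted" seeds)?
2. Do unspotted seeds germinate differently (rate and spread of timing)?
3. Do ants preferentially remove unspotted seeds?

Each question maps to one module; this vignette documents the models, the
tunable parameters, and the design choices made where the procedure was
genuinely open.

## Seed imaging

A seed photograph is decomposed into three binary layers: seed body,
pigmentation spots, and elaiosome. The published description of the original
imaging tool names the layers but not the algorithm, so the segmentation
pipeline here is the package's own design, chosen as the simplest chain
consistent with the layer structure:

1. grayscale conversion (channel mean);
2. global Otsu threshold, foreground = darker than threshold (the seed coat
   is darker than the background; the pale elaiosome is deliberately *not*
   foreground here);
3. morphological opening then closing (disc radius 2 px by default) and
   hole filling;
4. 8-connected component labeling; components smaller than 0.5 % of the
   image area are treated as dust. Exactly one surviving candidate is the
   seed body — zero is a "no seed detected" error, several is an explicit
   multiple-candidates error rather than a silent pick;
5. spots: a second Otsu threshold computed *only over body pixels*; spot
   mask = body pixels at or below it;
6. elaiosome: pixels with yellowness \((R+G)/2 - B\) above 0.15, outside the
   body, cleaned and required to touch the dilated body boundary.

Two **contrast gates** guard the Otsu steps: Otsu always splits a histogram,
even a unimodal one, so a blank image would otherwise produce a spurious
"seed" and a spotless seed would produce roughly half its body as spurious
"spots". A split only counts if the class means differ by at least
`min_body_contrast = 0.10` (body step) or `min_spot_contrast = 0.08` (spot
step) on the \([0,1]\) intensity scale. These defaults are far below the
rendered contrasts (≈ 0.3) and far above the default pixel noise
(s.d. 0.02).

Spot cover is defined as
\[
\text{cover} = 100 \times \frac{\#\,\text{spot pixels}}{\#\,\text{seed-body pixels}} ,
\]
and the seed "total area" **excludes the elaiosome** — cover is a property
of the seed coat, and the elaiosome is a separate organ. That convention is
stated here because the source description is ambiguous on it. Coordinates
are row-major, origin top-left, 0-based, with half-open bounding boxes;
connectivity is 8-connected throughout.

## The synthetic-data generator

No raw images or assay logs are publicly deposited, so the package ships a
first-class generator for every input. The generator defines the study
conditions; it is not a tuning dial.

**Seed images.** An elliptical body (default semi-axes 60 × 38 px in a
200 × 200 frame) on a lighter background (shades 0.45 vs 0.75), dark spots
(0.15), and a pale yellow elaiosome disc at the major-axis pole. Spot
texture is a Gaussian random field smoothed at sigma = granularity/2
(default blob diameter 8 px) and thresholded *at the empirical quantile of
in-body field values equal to the target cover*, which makes the rendered
mask exact ground truth and hits the target cover to quantile rounding
(≪ 1 percentage point). Additive channel noise (s.d. 0.02) emulates sensor
noise. What this does **not** emulate: uneven illumination, shadows,
specular highlights, colour calibration drift between microscopes, debris,
and multi-seed scenes. Passing segmentation tests therefore demonstrate
correctness of the algorithm under controlled contrast, not robustness to
field-quality photographs.

**Plant populations.** The paper states the regression slopes of mean spot
cover on total flowers (0.062 and 0.078 percent per flower for the two
light regimes) and the sample scale (30 plants, one seed per whorl, 486
seeds), but not the flower-count distribution. Chosen once and documented
here: whorls per plant uniform on 12–20 (mean 16, matching 486/30 ≈ 16.2
seeds per plant), flowers per whorl Poisson(6), intercept 23 % cover,
plant-level noise s.d. 2.5 (which reproduces a plant-level \(R^2\) near the
reported 0.24 at the induced spread of flower totals), within-plant seed
noise s.d. 5. Covers are clipped to \([0, 100]\).

**Germination.** Germination is Bernoulli per category (defaults 0.74
unspotted, 0.898 spotted, n = 108 each, matching the reported fractions);
germinators draw a lognormal day truncated at the study horizon by inverse
CDF (so the germinated fraction is exactly the Bernoulli parameter), with
the unspotted category wider (sdlog 0.6 vs 0.3). Non-germinators are
right-censored at the horizon, 30 days by default; the true horizon is
unstated in the source, so it is a config field.

**Removal logs.** Paired trials are Bernoulli removals (default 212 trials,
p(unspotted) = 0.608, matching the reported preference) with optional
session-level heterogeneity on the logit scale. The grid assay is an
even-sided checkerboard (odd sides are rejected, not approximated); at
each step the next removal is unspotted with probability `preference`
while both categories remain, uniform within category.

All generators are pure functions of their parameter objects including the
RNG seed (via `withr::with_seed`), and all tables carry explicit category
labels — truth never depends on downstream quantile classification.

## Phenotype

The fitness proxy is the **total flower count excluding the top whorl**
(the last whorl's development is partial at harvest). A single-whorl plant
yields fitness 0 — the literal application of the omission rule — and is
flagged with a message rather than rejected.

Seed categorization is **rank-based**: the lowest `floor(0.15 n)` covers
are "unspotted", the highest `floor(0.15 n)` are "spotted". Floor is the
package's rounding rule (the source states "bottom 15 percent" without
one); it guarantees the tails never overlap and gives 72 + 72 labels at
n = 486. Ties spanning a cut are broken by stable input order and logged.
A fully degenerate distribution (all values equal) is an error, never a
silent labeling. Whether the original cut was pooled or per light regime is
unstated; the functions take plain vectors so the caller chooses, and the
analysis scripts cut per regime, mirroring the separate sampling designs.
Plant aggregation uses the unbiased (n − 1) variance, with a single-seed
plant reported as missing variance, not 0.

## Association statistics

Plant-level association is ordinary least squares of mean cover (y) on
total flowers (x) — the regression direction follows the figure axes of the
source; the slope t statistic uses n − 2 degrees of freedom and two-sided
p-values (two-sided conventions throughout; no multiple-testing correction
is applied, matching the source analysis). Seed-level association uses a
random-intercept linear model (REML via lme4); with a single group or
singleton groups it reduces — by documented design — to pooled OLS. The
restricted-likelihood choice is the package default and is recorded in the
fit's `method` field; tests assert the slope contract, not an optimizer
path.

## Germination analysis

Germination curves are **inverse Kaplan-Meier**: one minus the
product-limit survival estimate, i.e. the cumulative fraction germinated.
With no censoring this equals the empirical CDF exactly (property-tested).
Non-germinated seeds are right-censored at the last observation day.

The **rank-sum test** is implemented in the package (rather than calling a
stock routine) because its exact mode must handle midrank ties: W is the
Mann-Whitney U of the first sample; for combined n ≤ 12 the two-sided
p-value is computed by full enumeration of all group assignments of the
pooled midranks; above that, a normal approximation with tie-corrected
variance and a 0.5 continuity correction. The threshold 12 keeps exhaustive
enumeration at ≤ 924 assignments. The statistic is deliberately generic
over any numeric response: the source applied it to "germination" without
stating whether the response was the binary outcome or the day, so both
usages are supported and the analysis scripts report the day-based test.

The **log-rank test** is the standard observed-minus-expected chi-square
with 1 df (via the survival package). The source interprets its log-rank
result as "greater variance in germination time"; strictly, log-rank tests
a difference of time-to-event distributions, so the package reports it as
such and computes descriptive variances separately in the analysis script.

## Ant preference

**Paired trials.** The reproducible estimators are the per-category removal
fraction (count / total trials), the exact binomial sign test against 0.5,
and the raw odds ratio, defined as spotted/unspotted removals so that
preference for unspotted seeds gives OR < 1. The mixed-effects logistic
model (intercept-only, random intercept per time point) is provided as a
contract validated by simulation: the published mixed-model OR cannot be
reproduced because the session/time structure of the raw trials is not
recoverable. "Time point" granularity is unstated in the source; the
default is one level per distinct value of the chosen grouping column.

**Grid assay.** `grid_state()` replays the first k events against the
layout (removed + remaining = initial, per category, always);
`grid_rank_test()` ranks removals by event order and delegates to the
shared rank-sum implementation; ties in time stamps are resolved by event
index, which the log must supply. Seeds never removed are excluded from
the rank test (the analyzed source sequence was complete); a
censored-rank variant is out of scope and a category with zero removals is
an explicit error. `random_removal_null()` gives the hypergeometric upper
tail of the observed composition under category-blind removal — a sanity
null, not a claim about ant behaviour.

## Numerical choices and degenerate inputs

* Otsu threshold: 256-bin histogram on \([0,1]\); the returned cut is a bin
  edge so `value <= threshold` selects the dark class deterministically.
* Exact rank-sum p-values compare \(|U - E|\) with a 1e-9 slack so midrank
  arithmetic cannot flip a tie of the statistic.
* A constant response in OLS returns slope 0, \(R^2 = 0\), p = 1 by
  convention; constant x is an error.
* Mixed fits ignore singular-fit warnings by configuration: a zero random
  variance is a legitimate boundary estimate, and the documented reduction
  to OLS covers it.
* Generator determinism is bit-level: two calls with equal parameter
  objects produce identical arrays and tables.

## Problem sizes

The shipped test-suite and analysis scripts run at the study's own scale
where that is cheap (30 plants × 12–20 whorls, 108 seeds per germination
category, 212 trials, 8 × 8 grid) and use 50 rendered seeds for the
segmentation recovery suite, 500 replicates for slope-coverage, 200 for
mixed-logistic recovery and 2 000 for the type-I-error calibrations; the
module-level unit tests rerun the same simulations at reduced replicate
counts for speed.

## Known limitations

* Segmentation assumes one seed per frame on a contrasting background;
  multi-seed scene parsing and colour calibration are out of scope.
* The "estimated weight" of a seed appears in the source results without a
  stated formula and is therefore not computed; the output schema simply
  does not contain it.
* The rank-sum exact mode enumerates; it is not meant for combined n much
  beyond the default threshold.
* The censored-rank variant of the grid removal-order test (for incomplete
  removal sequences) is not implemented.
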