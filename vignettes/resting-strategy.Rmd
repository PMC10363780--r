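---
title: "Analysing diurnal resting strategies from GPS and activity collars"
author: "restsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing diurnal resting strategies from GPS and activity collars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restsel)
```

## The problem

Wild boars living near people are largely nocturnal: they forage at night
and spend the day at rest at a chosen resting site (RS). The daily choice
of an RS — made once, around dawn — fixes the animal's exposure to human
disturbance (walkers, vehicles, drive hunts) for the whole day. `restsel`
implements the full analysis chain for studying this strategy from
biologging data:

1. **When** does the animal rest? A 5-min collar activity score (ACT,
   0–255) is thresholded and smoothed into one consolidated diurnal
   *inactive phase* per day.
2. **Where** does it rest, and does it get disturbed? Within-phase
   *relocations* are detected from sustained ACT bouts combined with a
   >100 m shift of the mean GPS position; the daily resting location is
   the mean of the pre-relocation fixes.
3. **Which places** does it reuse? Daily locations are clustered into
   resting sites (average-linkage agglomeration, 50 m cut) and visits are
   counted by hunting season.
4. **What drives the choice?** A use–availability resource-selection
   function (RSF), selection ratios, a zero-truncated Poisson model of
   revisitation, and binomial/gamma models of relocation probability and
   distance, all as mixed models with animal-within-study-site random
   intercepts.

A synthetic landscape-and-trajectory generator with full ground truth
makes every stage testable without any field data.

## Segmentation model

Each 5-min epoch is *resting* iff ACT ≤ 40 (the threshold is
config-exposed; 40 separates the bimodal rest/active ACT distributions of
this species well). Nocturnal animals show brief activity bouts inside
the long daytime rest (posture changes, vigilance, grooming) that are
irrelevant to the day-scale pattern, so rest runs are merged across them.

The merging rule is deliberately asymmetric-safe: an active run is
absorbed when it is **shorter than 60 min** (`max_gap_minutes`) **and
shorter than both adjacent rest runs** (the left one counted after any
merges so far). The second condition is what keeps isolated one-epoch
"rest" blips at night — sensor noise during foraging — from capturing
half the night into the phase: a 5-min blip can never absorb a gap of
5 min or more. A single resting epoch wedged between active runs is
relabelled active before merging (despeckling), because it would
otherwise split a genuine activity bout in two. The greedy left-to-right
pass is followed by the same absorption rule applied at the segment level
until a fixed point, which handles compositions such as
*bout–short rest–blip–long rest* that one pass cannot resolve. The day's
phase is the longest merged segment (≥ 2 h, `min_rest_run_minutes`)
overlapping that day's `[sunrise, sunset]` window, ties broken by
earliest start; sunrise and sunset come from the NOAA solar-geometry
equations (Julian-century form, zenith 90.833°, accuracy well under a
minute at mid latitudes).

Phase bounds are therefore accurate to about one epoch; days overlapping
flagged sensor gaps (> 3 missing epochs) are marked `low_confidence`.

## Relocation detection

Candidate events are maximal supra-threshold ACT runs of ≥ 10 min (two
epochs — a single-epoch spike is indistinguishable from noise) inside a
phase. For each candidate, in time order, the pre-bout centroid is the
mean of fixes from the phase start (or the previous event's bout end) and
the post-bout centroid the mean of fixes up to the next candidate (or the
phase end); an event is emitted iff the centroids are **strictly more
than 100 m** apart. Fixes within one epoch (5 min) of the phase bounds
are excluded from centroids: bounds are only epoch-accurate, and a fix in
the first or last epoch can catch the animal still walking in or out,
which would otherwise let a kilometre-scale night position leak into a
rest centroid and fabricate an event. With 15 m GPS noise and ≥ 2 fixes
per side, a true displacement of 150 m or more is always detected and a
no-displacement bout never is; displacements between 100 and ~130 m sit
in a grey zone where measurement noise can flip the strict 100 m rule
either way, which is why the simulator keeps its true relocations above
150 m (see below).

## Resting sites

The daily resting location is the mean of the phase's fixes before the
first event's bout onset — it reflects the dawn choice, not the
post-disturbance refuge. Locations are clustered per animal with
average-linkage hierarchical clustering cut at 50 m (merges at exactly
50 m are joined; `stats::hclust` + `cutree`). Sites are summarised with
per-season visit counts; a site used in both seasons legitimately enters
both seasonal model datasets.

## Landscape covariates

*Villages* are derived from building footprints by a 50 m morphological
closing: buildings whose footprints come within 100 m of each other merge
into one cluster, the space between them is filled, the edge is shrunk
back to the peripheral buildings, and clusters larger than 1.5 ha count
as villages. The closing is computed on a raster (default 2 m cells) with
exact Euclidean distance transforms — dilation is *distance-to-buildings
≤ 50 m*, erosion is *distance-to-outside ≥ 50 m* — and cluster identity
is taken from the dilated (merged-buffer) layer, so a narrow neck between
two building groups cannot silently split a merged cluster back into two.
Geometric accuracy is one cell; the 1.5 ha rule and the merge/split
behaviour at 90 m/110 m spacing are exact well beyond that tolerance.
The signed distance to the village edge is negative inside (one
continuous covariate across the boundary). *Roads* keep only the five
traffic-bearing categories (motorway, trunk, primary, secondary,
tertiary); distance is exact point-to-segment. *Dense vegetation* is a
binary point-in-patch covariate.

The drive-hunt calendar labels each date `NHS` (closed season),
`HS_nonhunting`, or `HS_hunting_day` (Wednesdays, Saturdays, Sundays and
bank holidays inside the open season, which runs 15 August – 31 March by
default). The RSF and revisitation models use the two-level NHS/HS
collapse; the relocation models use all three levels.

## Models

All models share one fitting front-end, `fit_glmm()`, with three
families: binomial (logit), zero-truncated Poisson
(`P(Y = k | k ≥ 1) = λ^k e^{-λ} / (k! (1 - e^{-λ}))`, log link) for
visit counts — a site exists in the data only because it was visited at
least once — and gamma (log link) for positive relocation distances.
Estimation is Laplace-approximate maximum likelihood (glmmTMB) with
animal-within-study-site nested random intercepts encoded as two
independent variance components. Wald z statistics and p-values are
reported. Numerical guards: random factors with a single level are
dropped (variance pinned at 0, warning); a variance component stuck on
the zero boundary that breaks the Hessian is dropped and the model refit
(warning, recorded); a binomial response with no variation gets a
Laplace-smoothed intercept-only estimate flagged `penalized` instead of a
divergent fit. Marginal (fixed-effects) R² follows Nakagawa:
`var(Xβ) / (var(Xβ) + Σ random variances + residual variance)` with
residual variance π²/3 (binomial-logit), `log(1 + 1/mean(λ))`
(log-Poisson lognormal approximation), or `trigamma(shape)` (gamma).

**RSF.** Used RSs (once per site per season, regardless of visit count)
against 1000 uniform availability points per used site, drawn by
rejection sampling from the animal's home range — the 90% contour of a
bivariate normal-kernel utilization distribution of the *active-phase*
fixes (normal-reference bandwidth, 50 m grid). Distances are z-scored
within each seasonal dataset before fitting (raw-meter coefficients would
be ~10⁻⁴-scale); selection-ratio curves are reported back in meters.
`SR(x) = (n_available / n_used) · exp(η(x))` with η the fitted linear
predictor including the intercept: the use-density to availability-density
ratio, 1 = neutrality.

**Cross-validation.** Boyce-style k-fold: 5 folds of used points, 10
equal-width bins of the RSF score, Spearman correlation of the
area-adjusted frequency (held-out used fraction / availability fraction)
against bin rank, averaged over folds, mean ± SE over 20 replicates.
Two implementation choices matter. Bins are equal-width on the *log*
score (the linear predictor): the raw score `exp(η)` spans orders of
magnitude, and raw-scale bins would pile nearly all mass into the lowest
bin and produce strongly biased correlations even for a null model. Bins
carrying less than 1% of the availability mass are merged into their
left neighbour before the correlation — a frequency ratio with a
near-empty denominator is pure noise. CV refits use a thinned
availability sample (100 per used point by default) for tractability;
held-out scoring always uses every point.

**Behavioural models.** Revisitation: zero-truncated Poisson on per-site
seasonal visit counts with `veg × d(village) + veg × d(road)` and
log(survey length) as a control covariate (animals are monitored for
unequal durations). Relocation probability: binomial on phases
(`relocated` = any event in the phase) with the same habitat terms plus
the 3-level season factor; per-season probabilities are predicted at a
reference profile (vegetated site, distances at their data means, random
effects at zero) — the choice of profile is config-exposed. Relocation
distance: gamma log-link on the first event's distance (km) of relocated
phases; a positive continuous response with a log link is the natural
companion to the probability model, and a lognormal alternative would
differ only in tail weight.

## The synthetic generator

`sim_study()` generates a landscape (villages as building clusters dense
enough that the 50 m closing merges each into a >1.5 ha polygon; jittered
road polylines, including a residential road and a track that the filter
must drop; rectangular vegetation patches grown to a 40% cover target)
and per-animal collar series with full ground truth. Its defaults *are*
the study conditions the pipeline is calibrated for:

* **Schedule.** The inactive phase ends at `sunset + N(0, 45 min)` and
  starts at `end − 0.585·24 h + N(0, 90 min)`, so the expected rest
  fraction is exactly the 58.5% time-budget target and the start falls in
  the last hours of the night. Anchoring the start *mean* directly on
  sunrise is incompatible with a 58.5% budget (mean daylength/24 ≈ 0.51
  at these latitudes), so sunset anchoring plus a length target is the
  internally consistent formulation; the looser start spread (90 vs
  45 min sd) reproduces the end-vs-start anchoring asymmetry.
* **Activity.** Rest epochs draw ACT ~ N(15, 10), active epochs
  N(125, 38), clipped to 0–255 and rounded; with the 40 threshold this
  yields ~0.6% rest-epochs misread as active and ~1.3% the other way,
  which the despeckle/merge rules must absorb.
* **Sites.** Each animal has a pool of 60 candidate sites (≥ 120 m
  apart, inside a 1.5 km radius). Each dawn it explores a new site with
  probability 0.37 (vegetation-weighted) or revisits a known one with
  weight `visits^0.5 · exp(−0.5 · d_village/km)` — sublinear preferential
  return concentrated near villages. The exponent and exploration rate
  were calibrated once so that ~51% of sites end up visited more than
  once over a ~120-day survey, and the distance weighting makes
  near-village sites the most revisited.
* **Relocations.** Per-season daily probabilities 0.08 (NHS), 0.12 (HS
  non-hunting day), 0.17 (HS hunting day); displacement lognormal with
  237 m median, heavier-tailed on hunting days (sdlog 0.6/0.8/1.0),
  truncated below at 150 m, announced by a 15–25 min activity bout.
  The 150 m floor (not 100 m) keeps every true event identifiable under
  GPS noise, so detector recall is a meaningful 0/1 property.
* **Events live in the phase interior** (≥ 2 h from the true bounds),
  and are spaced ≥ 45 min apart. An activity bout overlapping a phase
  bound redefines the bound itself; ground truth would be ill-defined.
* **GPS.** Rest fixes jitter isotropically (sd 15 m, well under the 50 m
  clustering cut) around the current true position; nights are a
  correlated (AR(1), ρ = 0.7, stationary sd 800 m) walk around the home
  centre. Surveys start on staggered dates through the year and have
  unequal lengths (sd 30 days) so both seasons and the survey-length
  control are informative.

What the generator does **not** emulate: collar failure and irregular
fix schedules (beyond injected gaps), behaviour-dependent GPS error,
social structure, crepuscular double rest phases, habitat-dependent
night movement, or any feedback of disturbance on subsequent site
choice. Passing the recovery checks therefore demonstrates that the
estimators are correct under the stated generative model, not that field
data meet those assumptions.

## Problem sizes and determinism

The test-suite and acceptance checks run at desk scale, chosen as the
smallest sizes at which each property is statistically clean: the
segmentation/detection/clustering recoveries use 5 animals × 120 days
(~600 phases); mixed-model coverage uses 100 replicates of n = 2000 with
20 groups per family; RSF coefficient recovery uses 50 replicates of 600
used / 12 000 available points; the selection-ratio neutrality check runs
once at 20 000 used / 100 000 available points because it is a
*construction* check — at that information level sampling noise cannot
mask (or mimic) a bias; end-to-end relocation-rate recovery uses 10
animals × 150 days. All randomness flows through R's RNG, so a single
`set.seed()` reproduces any run bit-for-bit.

## Known limitations

* The bout-smoothing rule is a principled reconstruction exposed through
  `seg_params()`; other defensible rules exist, and field deployments
  should check sensitivity of phase bounds to `max_gap_minutes`.
* Village geometry is raster-accurate (one cell); sub-meter legal/ cadastral
  boundaries are out of scope.
* The RSF availability sample is uniform within the home range; no
  step-selection or path-based availability.
* Wald inference everywhere; no small-sample or bootstrap corrections.
* The relocation-distance model sees only the first event per phase by
  default (a per-event alternative is config-exposed).

## A minimal run

```{r example, eval = FALSE}
cfg <- default_config(seed = 1,
                      simulate = sim_config(n_animals = 2, survey_days = 60),
                      n_avail_per_used = 100,
                      cv = cv_config(n_reps = 5))
pl <- run_pipeline(cfg)
print(pl)
summary(pl$relocation_fit)
pl$relocation_prob
```
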