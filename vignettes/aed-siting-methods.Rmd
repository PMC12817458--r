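---
title: "Methods: risk-based AED siting on walkable networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-based AED siting on walkable networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aedplace)
```

## The problem and the model

Survival after out-of-hospital cardiac arrest (OHCA) drops steeply with
every minute to defibrillation, so a public AED only helps if a responder
can fetch it and return within a few minutes. `aedplace` formalizes AED
siting as a maximum-coverage problem on a walkable road network: choose a
set of road intersections so that as many (observed or predicted) OHCA
alerts as possible lie within a three-minute walk of a device.

Three modelling objects carry the method:

* **Isochrones.** For a candidate intersection, the 3-minute isochrone is
  the set of network nodes within `budget × speed` metres of shortest-path
  distance (default 180 s × 1.65 m/s = 297 m). The 5-minute analogue
  (495 m) only enters the placement stage. Walking speed is configurable —
  trained responders run, so 1.65 m/s is conservative.

* **Risk areas.** Each candidate's average alerts per year inside its
  isochrone is binned into an ordinal level 1–9 (1 = no alerts; 2–8 the
  half-open intervals (0–1], (1–2], (2–3], (3–4], (4–5], (5–10], (10–20];
  9 = more than 20). Binning stabilizes a target that is otherwise
  dominated by zeros and small counts. The 365.25 days/year denominator
  accommodates leap years in multi-year windows.

* **Coverage.** An alert is covered when an always-available (24/7) AED
  is within 300 m straight-line distance — the validation definition — or,
  in the alternative `network_297` mode, within 297 m of network walking
  distance from the alert's nearest road node. The two radii are nearly
  equivalent statements of "three minutes on foot"; both modes are
  first-class because the straight-line rule is simpler to audit while the
  network rule matches the isochrone construction. Devices without 24/7
  availability never participate in any computation.

## Spatial extents without a routing engine

The original formulation of an isochrone is a polygon from a routing
service. To stay reproducible without one, the package defines an
isochrone's spatial extent through its reached nodes: a point (population
tile, POI, alert) lies inside iff it is within a snap tolerance (default
50 m) of some reached node. This traces the street corridor rather than a
convex blob, at the price of a tolerance parameter; 50 m is roughly half a
short urban block, so points "on" a covered street segment are captured
while parallel uncovered streets are not. A pure Euclidean-disc mode
(radius = budget × speed) exists for degenerate or tiny test networks.
Intersections are defined as nodes of graph degree ≥ 3 — degree-2 nodes
are geometric bends of a single road, not junctions.

## Feature screening and the regression tree

Per-candidate features are population, sex ratio, counts of public
buildings, sport facilities, transport stations and parking spaces, and
residential/industrial presence flags. An `age_65_plus` column can be
carried via `include_age = TRUE` in `build_feature_table()`, but the
default feature list excludes it: age-structure data are frequently
unavailable in practice, and the default mirrors that situation while the
flag keeps the richer analysis one switch away.

Screening is two-stage and deterministic given column order: iterative
variance-inflation-factor elimination (drop the highest-VIF feature until
all VIF ≤ 10 — the conventional cut-off; exact duplicates have unbounded
VIF and are removed first) and then a per-feature one-way ANOVA F-test
against the risk-area groups at α = 0.05. The ANOVA form was chosen over a
regression F-test because the target is a small set of ordered groups; for
a null feature the two coincide in calibration, and the test suite checks
the 5% null retention rate empirically.

The tree regresses the ordinal level as a number 1–9; predictions are
rounded to the nearest integer and clamped to [1, 9] for downstream use,
while the un-rounded score is kept for tie-breaking during placement. The
80/20 split and five-fold cross-validation choose depth ∈ {2,…,6} and
minimum leaf size ∈ {5, 10, 20} by minimum CV MSE, with ties broken toward
the shallower and larger-leaved (simpler) tree; `minsplit` is set to twice
the leaf minimum. A linear-regression baseline is fitted on the same
features and reported alongside, but model selection is fixed to the tree.
A constant target degenerates to a single-leaf model with a warning rather
than an error, so pathological inputs stay diagnosable.

## The greedy placement loop

Each iteration selects the remaining candidate with the highest current
risk level; ties break by the larger raw score, then by the smallest
candidate id, making runs fully auditable. Selection removes all remaining
candidates within 297 m network distance and decays by the reduction
constant (default 2) those within 495 m, floored at level 1 — the lowest
defined level. Decay is cumulative: a candidate inside the 5-minute
isochrones of two successive selections is decayed twice, since each
iteration applies the update with no memory of earlier decays. Two
termination rules exist: a fixed device count, or exhaustion of a target
risk level ("place until no remaining candidate has current risk ≥ L").
Installed AEDs are handled by one pre-processing pass with the same
removal/decay radii; off-network devices are snapped to the nearest node
and the snap distance logged. The per-iteration audit log (chosen site,
removals, decays with before/after levels) is part of the result object.

Greedy maximization of coverage can hit local optima. The package
therefore carries `brute_force_best()`, an exhaustive-search oracle for
instances with `choose(m, n)` ≤ 10,000, used in the test suite to bound
the greedy's coverage on dozens of random small instances.
`sensitivity_sweep()` reruns the greedy per candidate decay constant and
flags the argmax; on synthetic cities the effect of the constant is small,
consistent with the design intent of the decay (balancing overlap against
later reconsideration).

## Scenarios

Six configurations are evaluated. Scenario 0 is the status quo. Scenarios
1 and 2 ignore the installed fleet and place the same number of devices
afresh — prioritized by model-predicted risk (1) or by the empirically
binned historical rates (2), using the identical greedy machinery — and
their coverage counts only the new set, so the comparison with scenario 0
is fair. Scenarios A/B/C pre-process against the installed fleet and add
model-guided devices: +20% of the fleet (A), or until risk area 5 (B) or
3 (C) is exhausted; coverage is evaluated on the union. Structural
consequences hold by construction and are asserted in tests: A can never
cover less than 0, and C never needs fewer devices than B.

## The synthetic city

Real dispatch and AED coordinates are not publicly deposited, so the
generator emulates the full input stack with known ground truth:

* a jittered `grid_nx × grid_ny` road grid (default 20 × 20 at 150 m
  spacing, jitter 10% — about 400 intersection candidates, a few
  square kilometres of "city");
* 60,000 residents allocated multinomially over a 75 m tile grid by a
  mixture of 3 Gaussian hotspots (σ 300–600 m) over a small uniform floor;
  female and 65+ shares are binomial (51%, 21%);
* POIs per category from spatial Poisson processes (rates per km² of
  roughly large-town density), 60% concentrated near hotspots;
* a planted intensity λ_i = c·softplus(w·z_i) on z-scored features with a
  population-dominated weight vector, scaled so that the expected total is
  1,000 alerts over a 5.64-year window — matching the structural
  assumption that alert risk is feature-driven with population density the
  dominant factor, while softplus keeps λ ≥ 0 and the scaling preserves
  ranking; alert counts are Poisson per candidate and scattered uniformly
  over the candidate's extent;
* 30 baseline AEDs sampled near the densest hotspot — an unplanned,
  clustered status quo.

These defaults are the package's study conditions; tests and the
acceptance script run at exactly this scale (≈ 400 candidates, ≈ 1,000
alerts, 20 replicate seeds for the qualitative claims), which keeps a full
end-to-end replicate near one second without thinning the spatial
structure.

What the generator does **not** emulate: real street topology (bridges,
rivers, dead ends), municipal boundary clipping, temporal alert patterns,
day-time population shifts, and the extreme zero-inflation of a
31,000-isochrone real city. Passing tests therefore demonstrate that the
machinery is correct and that the qualitative orderings (planned beats
clustered; historical-data placement edges out the model; marginal benefit
of extra devices diminishes) are reproduced when the model's assumptions
hold — not that any particular real city attains the same percentages.

## Numerical choices and conventions

Distance comparisons carry a 1e-9 m slack so that exact-boundary cases
(297.0 m) are included regardless of floating-point summation order.
Shortest-path ties cannot affect reached-set membership, so no tie-break
rule is needed there. Stage seeds derive from the master seed by fixed
offsets, keeping city, alerts, baseline fleet and the train/test split
independently reproducible. Geographic (lon/lat) inputs are detected by
coordinate range and projected once at read time with a local azimuthal
equidistant projection about the layer centroid — metrically faithful at
city scale and free of external CRS machinery; all core computation is in
planar metres, as every constant of the method (297 m, 495 m, 300 m,
1.65 m/s) is metric.

## Known limitations

The greedy heuristic is not an exact optimizer; no improvement heuristic
or integer-programming refinement is included. Distances are horizontal
only, and device availability is binary (24/7 or excluded) with no
time-of-day modelling. The risk model does not account for residual
spatial autocorrelation beyond what the spatial features capture. The
risk-area bin boundaries are fixed design constants of the method, not
fitted quantities.
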