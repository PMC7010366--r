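---
title: "Comparing urban habitat-loss scenarios: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing urban habitat-loss scenarios: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landsust)
```

`landsust` compares alternative patterns of urban habitat loss by coupling a
scenario engine, a stochastic metapopulation model and an outranking
multi-criteria analysis. This vignette documents the models, the parameters
that matter, the numerical conventions adopted where a published procedure
under-determines the implementation, and the limits of what the synthetic
test system can show.

## The study design in one paragraph

A present-day landscape (a mosaic of non-overlapping habitat patches with
habitat-class attributes, a city boundary inside a buffered study area, a
developments layer and a 2 × 2 km analysis grid) is degraded by six rule
sets into nine scenario landscapes each, at 10–90% cumulative loss of
present-day habitat area. For each indicator species, each scenario
landscape is reduced to a species habitat map; coarse grid-cell occurrence
records are downscaled to an ensemble of patch-level occupancy starting
conditions; incidence-function-model (IFM) parameters are fitted once per
starting condition; the IFM is simulated on every scenario landscape; five
sustainability measures are computed per replicate; and the scenarios are
ranked by PROMETHEE outranking over every (measure × loss level × species ×
starting condition) criterion. At full scale this is 5 × 9 × 10 × 200 =
90,000 criteria. Finally, occupancy-versus-loss curves are scanned for
habitat-loss thresholds.

## Units and geometric conventions

Geometry is planar, in metres (inputs are assumed already projected; no CRS
handling). Areas are reported in hectares, inter-patch distances in
kilometres, matching the units in which species dispersal distances and
minimum area requirements are tabulated. The location of a patch for all
distance computations is its area centroid — a deliberate simplification;
edge-to-edge distances matter only in the contagion scenario, where they
are computed exactly. Grid cells are half-open
(`[x0 + c·s, x0 + (c+1)·s)`), so a centroid on an interior edge belongs to
the +x/+y cell and the grid partitions the plane deterministically.

The package carries its own small planar-geometry layer (shoelace areas,
centroids, point-in-polygon, vertex-to-edge boundary distances, convex
clipping and inward offsets). Patch shapes produced by the synthetic
generator are restricted to axis-aligned rectangles and discretised circles
(48 vertices), so every geometric operation acts on convex parts and the
shrinkage scenario has closed-form checks (a circle shrunk to fraction *f*
of its area must have radius *r√f*).

## Scenario engine

All removal strategies share one arithmetic rule. "Remove patches equal to
10% of the habitat area" cannot hold exactly for discrete patches, so the
engine removes the *shortest prefix* of the strategy's ordering whose
cumulative area reaches the target (minimal overshoot). This gives testable
bounds: remaining area at loss fraction *f* lies in
`((1−f)·total − area of last removed patch, (1−f)·total]`.

- **A1/A2** order by ascending/descending area, ties broken by patch id.
- **R1** ranks habitat classes by national coverage (rank 1 = most common)
  and removes classes commonest-first, in seeded random order within a
  class; the within-class order is drawn once per series.
- **R2** is identical but ranks classes by their area in the current
  landscape, re-ranking after every 10% step, so the "locally commonest"
  class can change as loss proceeds.
- **C** orders by minimum boundary-to-boundary distance from patch to the
  nearest development and, after each 10% step, adds the removed patches to
  the developments layer before re-ordering — development begets
  development.
- **S** removes no patches: every patch is shrunk independently per level
  to `1 − level` of its area by an inward offset found by bisection
  (relative area tolerance 1e-4, ≤ 100 iterations); a patch that would
  vanish is dropped.

Freshwater-flagged classes are excluded from removal and from the habitat
total: their patches are mostly permanent water bodies whose loss to
development is not realistic. Loss levels are fractions of the
species-agnostic removable area of the base landscape.

## Species habitat maps

A species habitat map keeps patches of the species' suitable classes,
dissolves patches whose boundaries are within 3 m of each other (the scale
of paths, small roads and ownership boundaries) and discards dissolved
patches below the species' minimum area. Because patches never overlap, the
dissolve is implemented as connected-component grouping under the
"boundary distance ≤ 3 m" relation: merged area is exactly the sum of
member areas, and the merged geometry keeps all member rings as one
multipart patch. The operation is idempotent, and the suite verifies the
area bookkeeping against an independent union oracle.

## Downscaling and starting conditions

Records arrive at 2 × 2 km cell resolution, but the IFM needs patch-level
occupancy. Let *q* be the proportion of occupied cells among cells that
contain at least one suitable patch. Occupancy is assumed self-similar
across scales: within each occupied cell holding *m* patches,
`k = max(1, round(q·m))` patches are drawn without replacement with
probability proportional to area and marked occupied; patches in unoccupied
cells stay empty. Two conventions here are ours, as the published
procedure leaves them open: the denominator of *q* counts suitable cells
only (prevalence should be relative to where occupancy is possible), and
*k* is rounded half-up with a floor of one so an occupied cell is never
left without an occupied patch. The stochasticity of the draw is carried
into the analysis by repeating it (200 starting conditions at full scale).

## The incidence function model

The classic discrete-time IFM: with state *p* (1 = occupied), connectivity

&nbsp;&nbsp;*S_i = Σ_{j≠i} p_j · exp(−α d_ij) · A_j^b*,

colonisation *C_i = S_i²/(S_i² + y²)*, extinction
*E_i = min(1, e·y²/A_i^x)*, and the rescue effect multiplying extinction by
*(1 − C_i)*. Updates are synchronous with connectivity computed from the
previous state — the convention that makes the exactly enumerated Markov
chain on small systems well defined, which the test suite uses as an
oracle (one-step transition frequencies and the quasi-stationary
distribution on 2–3-patch systems). The all-empty state is absorbing and
short-circuits simulation.

Parameter conventions:

- *α* (km⁻¹) is `1 / dispersal_km` — the exponential kernel whose mean
  equals the species' mean natal dispersal distance.
- *b* = 1 (classic default; configurable).
- *e* and *y* are not separately identifiable from incidence data, so
  *y* := 1 and the compound *e·y²* (`ey2`) is the fitted extinction scalar.

**Fitting.** Pooling (patch, year) observations from a multi-year history,
the stationary incidence satisfies
*logit J_i = −ln(e·y²) + 2 ln S_i + x ln A_i*, so a Bernoulli logistic
regression of occupancy on ln *A* and ln *S* maps directly to simulation
parameters: *x* is the ln *A* coefficient and *e·y²* = exp(−intercept).
Connectivity for fitting uses the same year's occupancy of the other
patches (the records are snapshots; this is our convention). The
constrained mode enters ln *S* as an offset with its theoretical
coefficient 2; the unconstrained default estimates it freely, and a value
near 2 is a useful model-adequacy check. Observations with *S* = 0 carry no
likelihood information under the offset and are dropped (counted in the
fit object). Degenerate histories (no variation, complete separation,
fewer than 10 usable observations) are rejected with informative errors.

**Recovery experiment.** The standing validation fits histories generated
by the model itself: 400 patches with areas 0.25–15 ha scattered over a
55 × 55 km plane, generating parameters *x* = 0.8, *e·y²* = 0.3, *α* = 1,
an 80-step settling period, then a 20-year recorded history. The area
floor keeps *E* < 1 everywhere (the `min(1, ·)` cap would otherwise break
the incidence identity for the smallest patches), and the density is
chosen so connectivity is of order one — the regime in which occupancy
actually varies. Across seeded repetitions the constrained fit recovers
*x* within ±0.15 and ln(*e·y²*) within ±0.3 in about 95–98% of runs; the
residual spread reflects genuine temporal correlation in the data, not
estimator error, and is the reason the check is framed as a rate rather
than a per-run guarantee.

## Sustainability measures and thresholds

Per replicate: minimum occupancy % over all timesteps t ≥ 1 (the window is
our convention; occupancy % is the area-weighted share of the *current*
landscape's suitable area), occupancy % at the burn-in timestep (t = 175,
the point by which occupancies are typically stable), survival (any patch
occupied at the end) and city survival (any occupied patch with centroid
inside the city boundary). City green space — total suitable area with
centroid inside the city — is a landscape-level scalar. When a scenario
leaves a species no habitat, or its recorded cells hold no remaining
habitat, occupancies are recorded as zero rather than skipped, so empty
scenarios still lose comparisons rather than vanish from them.

A habitat-loss threshold is the first 10-point loss interval in which mean
occupancy (averaged over starting conditions × replicates at t = 175)
falls by *strictly more than* 30% of present-day occupancy. The statistic
is scale invariant and undefined when present-day occupancy is zero. The
package bundles a reference table of thresholds from a published UK urban
case study; tallying its interval upper bounds gives 10% loss as the modal
threshold level — small initial losses are disproportionately damaging for
the most vulnerable specialists.

## PROMETHEE ranking

Each criterion compares the six scenarios pairwise. For replicate-valued
criteria a two-sided Mann–Whitney U test gates the comparison at
P < 0.05; only then does the scenario with the larger sample mean gain the
point (the test decides *whether* the samples differ; the means decide
*who* wins). `stats::wilcox.test` supplies the test: exact for small
untied samples, normal approximation with tie correction otherwise —
appropriate for the small replicate counts and heavily tied survival
indicators that arise in practice. Scalar criteria (green space) award the
point by strict inequality; equality awards nothing. How deterministic
criteria were gated in the original procedure is unstated; strict
comparison is our choice, and green-space criteria are enumerated once per
(species, starting condition) combination like every other measure so that
all criteria carry equal weight (weighting is deliberately out of scope).

Partial matrices are 0/1 with zero diagonal and π(a,b) + π(b,a) ≤ 1; their
sum is the total preference matrix; wins (row sums, descending) and losses
(column sums, ascending) give two rankings, flagged robust when identical
including tie structure. The suite checks the whole chain — decisions,
totals, rankings, robustness — against a brute-force oracle whose
Mann–Whitney distribution is enumerated from scratch.

## The synthetic study system

The generator emulates a Nottingham-sized system: a 12 × 12 km study
square on a 2 km grid, a centred city covering 60% of the extent, 150
patches with areas drawn log-uniformly from 0.05–20 ha, class abundances
skewed towards improved grassland and arable land, and eight development
polygons clustered in the city centre. Cell-level records are generated at
a configurable prevalence (default 0.6) with a 0.05 yearly flip
probability. Defaults were fixed once, as plausible magnitudes for a UK
urban mosaic, and the generators are pure functions of their configuration
and seed.

What the synthetic system does *not* emulate: spatial autocorrelation of
land cover, realistic patch shapes, observation error in records, and the
real parameter regime of highly mobile species. On a 12 km landscape a
species dispersing 3–8 km sees near-total connectivity, so its occupancy
saturates and incidence fitting degenerates — exactly as it would on real
data for such a species at this extent. The pipeline handles this by
falling back to the generating parameters (counted in the manifest); the
species most informative about scenario differences are the
short-dispersal specialists, which is why the worked examples and the
end-to-end checks use the toad and the marsh tit. Passing tests therefore
demonstrate correctness of the machinery and of the statistical behaviour
in the regimes where occupancy varies; they do not calibrate any species
to real records.

## Problem sizes used by the checks

The full design (500 timesteps × 100 replicates × 200 starting conditions)
is a cluster-scale computation. The package's own checks run desk-scale
versions chosen to keep every property measurable: the scenario factorial
on a 150-patch base landscape; exact-chain comparisons on 2–3 patches with
50,000 sampled transitions and 10,000 replicates for the quasi-stationary
law; the recovery experiment at 100 repetitions; 200 random
PROMETHEE-versus-oracle cases; and an end-to-end experiment with 2
species × 2 strategies × 9 levels × 5 starting conditions × 10 replicates ×
200 timesteps (burn-in 175). Every default remains configurable up to the
full design.

## Known limitations

- Distances are Euclidean between centroids; no functional connectivity or
  dispersal barriers, which matter in urban matrices.
- The dissolve bridges gaps by distance, not by shared-boundary semantics;
  for overlapping input patches (which violate the landscape invariants)
  its area bookkeeping would not hold.
- `y` is fixed at 1; only the compound *e·y²* is estimated, so absolute
  colonisation rates are not identified.
- Equal criterion weights; PROMETHEE preference functions beyond the
  0/1-gated form (linear/Gaussian thresholds, GAIA) are out of scope.
- The threshold statistic inherits the noise of its occupancy means; at
  desk scale (few starting conditions/replicates) detected intervals can
  shift between seeds.
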