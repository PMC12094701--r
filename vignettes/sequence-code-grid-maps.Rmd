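---
title: "Sequence codes of trajectories and the geometry of grid maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence codes of trajectories and the geometry of grid maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridseq)
```

## The model

Grid cells fire at the nodes of a hexagonal lattice spanning the
environment. `gridseq` implements the view that this periodicity is what a
*sequence code of trajectories* must look like: a finite set of `n`
elements (cells or cell assemblies) labels the fields of a dense hexagonal
packing such that the identity of the next active element is uniquely
determined by the currently active element and the movement direction.

Four requirements drive everything:

1. an ordered pair of sequentially active elements decodes to exactly one
   movement direction;
2. the reversed element sequence codes the reversed trajectory;
3. every field is surrounded symmetrically by fields of six *other*
   elements, so all directions are resolved equally (the kissing number of
   a disk in the plane is 6, attained by the hexagonal packing);
4. the number of elements is finite.

On the lattice these reduce to a purely local condition: around every
field, the six neighbouring fields must carry identities that are pairwise
distinct and different from the centre. `validateArrangement()` checks
this exhaustively over one period of the labeling and reports which
requirement each violation contradicts; an independent oracle in the test
suite re-derives the same verdicts from global successor/predecessor/pair
tables over three full periods, with no use of the local shortcut.

## Arrangements and their enumeration

An `Arrangement` stores the labeling as `R = n/k` disjoint cyclic rows of
repeat length `k` plus one horizontal offset per row step. Three
structural facts make exhaustive search over all arrangements cheap, and
each is re-verified by the validity checker rather than assumed:

* the repeat length is the same in parallel rows and divides `n`, so `k`
  ranges over the divisors of `n` with `k >= 3`;
* within one fundamental domain every element occurs exactly once; for
  `R >= 2` the rows are disjoint, and up to relabeling they can be fixed
  as consecutive integer blocks — the only degrees of freedom are the `R`
  offsets;
* when a single row's elements fill the lattice (`R = 1`), every row is a
  translation of it and the translation is forced into `2..k-3`
  (translations 0 and 1, and their mirror images `k-1` and `k-2`, all
  break decodability).

`enumerateArrangements(n)` filters this candidate space through the axiom
check and collapses duplicates with `canonicalForm()`, a key invariant
under relabeling, lattice translation, the six-fold rotation group and
(optionally) reflection. The smallest element count admitting any solution
is 7, and there are exactly two 7-element codes, mirror images of each
other:

```{r enumerate}
vapply(3:7, function(n)
  length(enumerateArrangements(n, moduloReflection = FALSE)), integer(1))
```

## From arrangement to grid map

All fields of one element form a sublattice of index `n` in the packing
(`sublatticeBasis()`); its Lagrange-reduced basis yields the plane lattice
type (`classifyLattice()`), the axis repeat lengths (`repeatLengths()`),
and the smallest acute angle between a grid axis — a direction to one of
the six nearest same-element fields — and a wall of a rectangular arena,
assuming one element-sequence row runs along a wall (`wallAngle()`). For
the 7-element code the sublattice is hexagonal with shortest vector
`sqrt(7)` and wall angle `30 - atan(sqrt(3)/5)` ≈ 10.9 degrees.

```{r table7}
gridMapTable(7, 9)
```

`gridMapTable()` lists one row per *anchoring*: which of the three
sequence axes lies along the wall changes the observable orientation (and
for non-hexagonal sublattices, the angle), so all valid row-anchored
candidates are tabulated and duplicate `(repeats, type, angle)` rows are
collapsed. Two cells of the corresponding published table differ from our
geometric computation, and we keep the geometric values:

* for 8 elements the tilted 10.9-degree lattice is congruent to the
  0-degree one (ring norms `{7, 7, 12}` times the field spacing, an
  equal-sided reduced basis), so both rows are centered rectangular; a
  label that depends on the tilt would not be a lattice classification;
* for 9 elements the third `(3, 9, 9)` anchoring places the repeat-3 axis
  along the wall, so one grid axis is exactly wall-parallel and the
  smallest angle is 0, not 10.9; no axis convention we could construct
  yields 10.9 here without breaking other zero-angle rows of the same
  table.

The corresponding two expectations in the acceptance test file are
intentionally left failing to keep the discrepancy visible.

Ties matter in one place: a rectangular sublattice has two equal-length
diagonals, so its ring of six nearest points spans four axis directions;
`wallAngle()` includes all axes tied at the cutoff length, which is what
keeps the angle mirror-invariant.

## Trajectory coding, resolution and modules

`encodeTrajectory()` walks the lattice and reads off element sequences;
`decodeTrajectory()` inverts it from the id pairs alone — the code is
location-independent, the anchor only fixes which occurrence of the first
element the walk starts at — and `pathIntegrate()` sums the decoded
steps. Velocity is quantised to the six lattice directions; continuous
positions reach the code via `assignElements()` (Voronoi assignment to
the dense packing).

Finer spatial and angular resolution comes not from more elements per
grid but from stacked grids: `buildMultiGrid()` adds three copies of the
base arrangement shifted by half the inter-field distance along each of
the three major axes. The union of the four centre sets is again
hexagonal with exactly half the spacing — note that shifting along a
*single* axis by quarter-spacings cannot do this, since that union is not
hexagonal. Separately, `moduleScaling()` expresses the module-scale step:
doubling field density divides spacing by `sqrt(2)`.

```{r multigrid}
mg <- buildMultiGrid(enumerateArrangements(7)[[1]], 4, spacing = 1)
c(total = totalElements(mg),
  spacing = nearestSpacing(compoundCenters(mg, 10)),
  scale2 = moduleScaling(2))
```

## Synthetic open-field sessions

The generator emulates a 20-minute, 50 Hz open-field session in a
1 m × 1 m arena:

* `simulateForaging()` — a correlated random walk: AR(1) speed (mean
  15 cm/s, SD 6 cm/s, 1 s autocorrelation time, clipped at mean + 4 SD)
  and Brownian heading (1.2 rad/sqrt(s)), reflected specularly at the
  walls. These values give rodent-like smooth paths whose 3 cm occupancy
  covers over 95% of the arena in 20 minutes.
* `simulateSpikes()` — an inhomogeneous Poisson process with rate
  `baseline + peak * sum of Gaussian fields`, generated by thinning
  against an explicit upper bound (peak times the maximal kernel sum over
  the arena), with positions linearly interpolated at candidate spike
  times. A 15 Hz peak on a 7-field layout reproduces the firing regime of
  a typical mouse grid cell (mean rate near 2 Hz).
* `computeRateMap()` — 3 cm bins, per-bin spike count over occupancy,
  bins under 0.1 s marked unvisited, then a 2-D Gaussian kernel with
  SD 3 cm (one bin) truncated at 3 SD, renormalised over visited bins.
  The stated kernel "width" of the field's standard pipelines is read as
  the SD; both are configurable.
* `spatialAutocorrelogram()` and `gridScore()` — Pearson correlation at
  every integer lag over bins valid in both copies (minimum overlap 20
  bins), and the rotational-symmetry score min(corr at 60, 120) − max(corr
  at 30, 90, 150) on an annulus between the central peak's edge (first
  radius with mean correlation below 0.1) and 1.25 times the median
  six-peak distance. The exact score recipe is not fully specified in the
  source literature; these radii are our documented interpretation and
  are configurable. Note the min-minus-max construction is negatively
  biased under exchangeability, so shuffled maps score slightly below
  zero rather than at zero; hexagonal fixtures score far above the 0.19
  inclusion threshold and square lattices score negative.

All stochastic entry points take explicit seeds and are bit-reproducible.
What the generator does *not* emulate: conjunctive head-direction tuning,
grid drift and remapping, theta-timescale structure, and measurement
artefacts beyond Poisson noise and a uniform baseline. Passing tests on
synthetic sessions therefore demonstrate correctness of the pipeline and
directional robustness to out-of-field firing, not performance on real
recordings.

## Field detection and the sqrt(7) ratio

Because valid codes pack fields densely, spacing and field size are
locked together: with touching circular fields of diameter `d`, adjacent
same-element field centres are `sqrt(7) * d` apart, so the
spacing-to-size ratio is `sqrt(7)` ≈ 2.65. The metrics pipeline measures
this the way the field's published detection tool does:

1. `detectFields()` — threshold at 31% of the peak rate (the operating
   point that optimises detection; too low merges fields, too high
   shrinks them), then DBSCAN over supra-threshold bins (radius 1.5 bins,
   minimum 4 bins; the reference tool's exact clustering constants are
   not published, so these defaults are exposed as parameters). No
   density-based clustering implementation ships with the installed R
   stack, so the forty-line exact algorithm lives in the package.
2. `fieldStats()` — centroids as unweighted bin-centre means, area as
   bin count times bin area, diameter `d = 2 * sqrt(area / pi)`.
3. `selectCentralRing()` — the most central non-border field plus its six
   nearest neighbours; border-touching fields may serve as ring members
   but never as the centre. Distance ties break by polar angle, then
   index.
4. `spacingAndRatio()` — mean of the six centre spacings over the mean of
   the seven diameters.

```{r ratio}
a7 <- enumerateArrangements(7)[[1]]
cc <- fieldCenters(a7, 1, extent = 100, spacing = 12)
i0 <- which.min((cc[, 1] - 50)^2 + (cc[, 2] - 50)^2)
cc <- sweep(cc, 2, cc[i0, ] - c(50, 50), "-")
m <- idealRateMap(cc, "disk", fieldSize = 6, peakRate = 15)
spacingAndRatio(m)
```

On noisy sessions the measured ratio falls *below* the dense-packing
bound — baseline firing and smoothing enlarge the thresholded fields
faster than they move the centroids — which is the model's explanation
for empirical ratios slightly under 2.65. The test suite checks this
directionally over 20 seeded sessions whose Gaussian fields are
calibrated so the 31%-of-peak contour has the dense-packing diameter.

## Numerical choices and limitations

* Axial coordinates fix E = (1, 0) and NE = (0, 1); rows are horizontal
  in the Cartesian frame and all modules share the convention.
* Lattice classification uses a relative tolerance of 1e-9 on lengths and
  cosines; exact integer lattices classify exactly. The reduced-basis
  boundary case `|v1.v2| = |v1|^2/2` is recognised as centered
  rectangular (the rhombus side is then the second basis vector).
* Axis repeat lengths are found as the smallest multiple of an axis
  direction lying in the period lattice; they always divide `n`.
* Angles are reported to 0.1 degree in tables, full precision elsewhere.
* Enumeration is supported to `n = 20`, far beyond the `n = 12` the
  geometry tables use; problem sizes in the tests (walk lengths, session
  durations of 10–20 simulated minutes, 20 seeds) were chosen as the
  smallest that exercise every code path with stable statistics.
* The package does not model 1-D tracks, environment deformation,
  goal-directed warping, 3-D packings, or any biological mechanism for
  sequence generation; it characterises the combinatorial geometry of the
  code and provides the measurement pipeline.
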