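---
title: "Quantifying multi-axis niche partitioning from GPS tracks, land cover and diet"
author: "nichePart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-axis niche partitioning from GPS tracks, land cover and diet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichePart)
```

## The question the package answers

Two ecologically similar raptors breeding in the same small area should, on
the face of it, compete: similar body plans, both diurnal, both hunting
terrestrial prey. Classical niche theory predicts that stable coexistence
requires segregation somewhere — and that several weak segregations along
different axes can multiply into strong overall separation (niche
complementarity). `nichePart` operationalizes that prediction as a
reproducible pipeline over four axes:

1. **Geographic foraging area** — where each individual actually forages,
   from GPS fixes;
2. **Foraging-habitat type** — which land-cover classes the foraging
   points fall on, against availability;
3. **Diel foraging timing** — how foraging activity distributes over the
   12 daytime hours;
4. **Diet** — per-nest prey-taxon composition from pellets and remains.

Axes 2–4 are all reduced to the same object, a `CompositionMatrix`
(sampling units × categories), and pass through one shared statistical
layer; axis 1 has its own spatial machinery. The final summary is the
product of the per-axis Bray–Curtis similarities between the species: a
number near 0 means the species hardly share resources even if every
single axis overlaps substantially.

## From GPS fixes to foraging areas

A fix is kept as a **standing point** when its tag-reported ground speed is
strictly below 4 m/s; ground speeds of large soaring raptors are strongly
bimodal around that value (flapping/soaring transit above, perching and
ground-hunting below). Three further filters are applied in a fixed order:

* **Nest vicinity** — activity within 0.15 km (near-nest species) or
  1.5 km (commuting species) of the nest is dominated by social
  interaction, not foraging, and is excluded (strict `<`; a point at
  exactly the radius stays).
* **Point density** — commuting species reach their foraging grounds
  through straight "flight corridors". Corridors contain occasional slow
  fixes, but at much lower spatial density than true foraging patches, so
  points are binned on a 500 m grid and cells below the median (q = 0.5)
  of the nonzero cell counts are discarded. The method is stated in the
  source workflow, its cell size and quantile are not; both are exposed in
  `qcPolicy()` and the defaults are this package's own declaration.
* **Quality control** — sets with fewer than 51 points and individuals
  that never reached chick-rearing are dropped, with machine-readable
  exclusion logs. An individual tracked over two consecutive seasons with
  similar seasonal ranges (seasonal UDOI > 0, config-exposed) contributes
  the mean of its two seasonal summaries.

Seasons are analysed in two windows: each species' *whole* breeding season
and the *shared* window (March 25 – July 15, both boundary days inclusive;
the dates are approximate in the source and therefore config-exposed).

The utilization distribution (UD) is a fixed-bandwidth isotropic bivariate
Gaussian KDE. The "smoothing factor" h ∈ {250, 500, 1000} m is interpreted
as the kernel standard deviation (the adehabitat convention). The UD is
evaluated on a grid with cell ≤ h/5, padded ≥ 4h beyond the point bounding
box, and renormalized; with that padding the truncated mass is < 1e-4 and
the single-point UD matches the analytic Gaussian to ≤ 1e-6 per cell.

The **95% isopleth** ("foraging area") is the smallest set of cells whose
cumulative mass reaches 0.95, *including ties at the threshold density* —
so a uniform UD yields its full support rather than an arbitrary 95% of
it. Area is cell count × cell area; whether the published areas were
cell-count or contour areas is not stated, the two differ by less than the
grid resolution, and the cell-count choice is deterministic and
resolution-controlled. Against the closed form, the 95% area of a
single-point UD (π(2.4477 h)²) is reproduced within 2% at the default
resolution.

**UDOI** (utilization distribution overlap index) between two individuals
is A₁,₂ · Σ UD₁·UD₂ / cellArea, with A₁,₂ the intersection area of the two
95% regions; 0 for disjoint ranges, 1 for identical uniform use, > 1 for
concentrated joint use. UDs built on different grids are re-evaluated from
their stored source points on a common grid. Pair-group comparisons
(within species A, within B, between) use the arcsine-square-root
transform after clipping at 1 (UDOI may exceed 1; exceedances are
counted and reported), one-way ANOVA and Bonferroni-adjusted pairwise
t-tests.

## Composition axes

**Habitat.** Each standing point is assigned the land-cover class of the
raster cell underneath it (point-in-cell lookup; overlaying the whole KDE
polygon would weight habitat by area rather than by use). Per individual,
class proportions form the composition row. Use is compared with
availability (class cell fractions of the study area) by per-class
one-sample t-tests; zero-variance degenerate cases are flagged explicitly
rather than silently dropped.

**Timing.** For high-frequency (5-min) individuals only, the proportion of
foraging-area fixes per hour bin [h, h+1), h = 7..18. The duty cycle
(06:55–19:05) only partially covers the 06 and 19 bins, which the 07:00–
19:00 analysis range excludes by construction. The source text is
ambiguous about whether all fixes or only foraging-area fixes enter this
profile; this package restricts to in-region fixes, which is the reading
consistent with "timing of foraging".

**Diet.** Nest-seasons with fewer than 8 identified prey items are
excluded (boundary: exactly 8 passes). To avoid pseudo-replicating
territories across years, each nest's value per taxon is the mean count
over its retained years; the filter-plus-averaging step is idempotent.
Prey categories (reptile / bird / mammal / arthropod) and the reptile
subcategories (snake / lizard) are compared between species with Welch
t-tests on per-nest fractions; the lizard-versus-snake contrast is
implemented as a two-sample test on the per-nest paired difference
(lizard − snake fraction), which is the species × subcategory interaction.
Exact replication of the published repeated-measures F statistic would
require the raw field data; direction and significance are the test
surface here.

## The shared statistical layer

* **Bray–Curtis** d(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ) (via `vegan::vegdist`). No
  square-root or other pre-transformation is applied by default; because
  the source software commonly applies √, a `transform = "sqrt"` hook
  exists and is flagged prominently — it changes every similarity value.
* **nMDS** — Kruskal stress-1 via `vegan::metaMDS`, 20 random starts,
  monotone regression on ranks.
* **ANOSIM** — Global R = (r̄_between − r̄_within)/(M/2) on dissimilarity
  mid-ranks. p by random label permutations with the add-one convention,
  or by exact enumeration of all distinct label assignments when that set
  is small (≤ 10⁴); the exact path is cross-checked against brute-force
  enumeration and `vegan::anosim` in the tests. Note one discreteness
  artifact: with two equal-sized groups every assignment and its
  complement give the same R, so exact p values move in steps of
  2/n_assignments.
* **SIMPER** — between-group: per category, the mean over cross-group
  pairs of |xⱼ−yⱼ|/Σ(x+y), as percent of overall average dissimilarity
  (sums to 100); within-group typicality uses 2·min(xⱼ,yⱼ)/Σ(x+y) on
  similarity. Contributions match `vegan::simper` exactly on fixtures;
  the within-group decomposition and identical-group degenerate case
  (explicit empty result) are this package's own surface.
* **Similarity grouping** — UPGMA clustering cut at similarity
  thresholds (e.g. 40%/60% contours).

## Niche metrics and null models

* **Pianka** O = Σpq/√(Σp²Σq²). Within-group and between-group means are
  reported as means over unit pairs; the between-species value is *also*
  computed on the group-pooled mean profiles, and the pooled variant is
  the headline number because a single published overlap per comparison
  does not disambiguate the two.
* **RA3 null model** — each iteration permutes every row's utilization
  values across all categories: niche breadth is retained exactly
  (Levins B is permutation-invariant, asserted per iteration in tests),
  which categories are used is randomized. 1000 iterations by default;
  both tails are reported with the add-one convention, because the
  direction convention of the original software is unstated.
* **Levins breadth** B = 1/Σp², unstandardized: the published breadth
  values exceed 1, which rules out the standardized B_A form.
* **Chao1** S_obs + F1²/(2F2), or the bias-corrected
  S_obs + F1(F1−1)/(2(F2+1)) when F2 = 0. Sample-based rarefaction draws,
  for each m = 1..n nests, `nBoot` subsets without replacement and reports
  mean and SD of Chao1 on the pooled counts — supporting comparison of two
  species' curves at a matched m. Mean counts from year-averaging are
  rounded to integers before Chao1.
* **Combined score** — the product of per-axis between-species Bray–Curtis
  similarities (1 − mean between-group dissimilarity), reported rounded to
  2 decimals with the raw product retained.

## Dyadic attraction–repulsion

A meeting is a pair of fixes (one per track) within 500 m and 150 s (half
the 5-min fix interval); all three parameters are config-exposed since the
original analysis software does not state its values. The null
distribution comes from circular time-shifts of the second track — shifts
uniform over the span, at least one day so that daily routines decouple
(mid-span shifts for tracks shorter than two days), and *quantized to the
sampling interval*: both tags report on the same fix lattice, so an
off-lattice shift makes meetings impossible by construction and would
bias the null toward zero. This scheme preserves each track's spatial
footprint and autocorrelation; it is a declared replacement for the
unspecified permutation of the original software. The index is the
mid-rank of the observed meeting count in the null, scaled to [0, 1]:
0.5 neutral, ≤ 0.25 reported as repulsion, ≥ 0.75 as attraction; pairs
never co-observed are blank. Calibration: over independent stationary
track pairs the index is uniform with mean 0.5; identical tracks score
≥ 0.99.

Spatial clustering of pooled foraging points uses Euclidean k-means with
k = 5 and multiple seeded restarts, reporting per-cluster species
composition.

## The synthetic study system

`simConfig()` parameterizes a generative model whose *defaults are the
study conditions*: two species, 13 and 11 tagged individuals (9 and 8
reaching chick-rearing), a 12-h duty cycle 06:55–19:05 sampled at 5-min
(solar tags) or 90-min (regular tags) intervals, mean nest-to-patch
distances 2.35 km vs 13.03 km, shared season March 25 – July 15, 37 vs 63
territories with denser nest packing in the commuting species, ~39 vs ~24
prey items per nest over a shared 53-taxon list (12 snake, 8 lizard, 15
bird, 10 mammal, 8 arthropod taxa), and about 10% of nest-years forced
under the 8-item filter.

Movement is a two-state central-place walk: idle at the nest, straight
commutes to foraging patches at truncated-Gaussian transit speeds
(≥ 4 m/s as reported), low-speed foraging inside patches. The source
describes no generative model — only signatures — so these are package
choices, made once:

* Ground speed is *written into the record* per behavioural state, as a
  tag would report it, not derived from displacement; the two state
  distributions are truncated strictly either side of 4 m/s so the
  speed rule is exercised exactly and the generator's state labels are an
  exact oracle for the classifier.
* Diel activity draws are intended *forage-bout midpoints* (uniform, or
  truncated Gaussian peaking at 13:00 ± 2 h for the midday mode — the
  source gives no distributional form, this is a declared stand-in);
  departures are back-computed so the realized foraging-time distribution
  follows the mode instead of being pushed late by trip serialization.
* The commuting species draws its patches from a species-shared pool of
  5 locations, reproducing high within-species range overlap and shared
  flight corridors; the near-nest species uses private patches.
* Habitat preference is imposed at the point level: each foraging fix
  draws its land-cover class from the species' use vector and snaps to
  one of the few nearest cells of that class, keeping patches dense so
  the corridor filter does not distort realized use.
* Transit fixes get a 2% chance of a slow "pause", producing the sparse
  corridor standing points the density filter exists to remove.
* The landscape is an iid categorical raster at 100 m resolution with
  availability 28/12/37/23% over four classes; diets are multinomial
  per nest-year from species vectors with geometrically decaying
  within-category taxon weights, the specialist restricted to the 30
  commonest taxa (hence shared taxa and a ~60% richness gap).

Everything derives deterministically from one master seed; an identical
config reproduces byte-identical tracks, rasters and diet tables.

What the generator does **not** emulate: GPS measurement error and fix
loss, spatially autocorrelated (patchy) landscapes, within-patch
area-restricted-search movement, thermals/aerodynamics, prey availability
dynamics, or observation error in prey identification. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers known
structure of this class — central-place movement with compositional
preferences — not that it is robust to every artifact of real field data.

## Numerical choices and degenerate inputs

Tolerances: proportion rows must sum to 1 ± 1e-9 (hard error, not a
warning); UD mass 1 ± 1e-9; UDOI symmetry holds to 1e-12; nMDS runs 20
starts with stress tolerance 1e-6. Quantiles in the density filter use
the order statistic (type 1), so thresholds are reproducible across
platforms. Ties: isopleth membership includes threshold-density ties;
ANOSIM uses mid-ranks; the attraction index mid-ranks its ties. Degenerate
inputs are explicit: empty standing-point sets error on distance; all-zero
composition rows error; single-category matrices make RA3 a flagged no-op;
identical SIMPER groups return an empty decomposition; never-co-observed
pairs return a blank index.

## Problem sizes used by the tests and the acceptance script

The unit fixtures are small and analytic. End-to-end checks run the full
default *structure* at reduced size — 4 solar-tagged individuals per
species over a three-week window on a 50 km landscape, 30 territories per
species, one field season — which keeps the whole suite around two minutes
while leaving every stage (filters, QC, KDE at three smoothing factors,
both windows, all four axes, null models) exercised. Null-model
calibrations use 500–1000 simulated datasets at 6–8 units each, where the
exact permutation sets are enumerable. The acceptance script reruns the
same reduced pipeline from its `--seed` and additionally recomputes the
in-study arithmetic (the combined score, distance and area ratios, and the
Chao1 excess) from the published per-species summary values, which are
inputs to that arithmetic.

## Known limitations

* The local transverse Mercator projection is spherical; over ~100 km
  extents the distance error is far below the 100 m raster resolution,
  but continental-scale inputs should be pre-projected.
* Isopleth polygons are exported as unions of grid-cell squares, not
  smoothed contours.
* Attraction indices on tracks with very different sampling schedules are
  conservative (few candidate meetings); the pipeline thins both tracks
  to a common cap before testing.
* RA3 assumes all categories are equally available to every unit; a
  preference that merely tracks availability will still look "non-random"
  against it. This mirrors the cited algorithm's own assumption.
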