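# nichePart

Multi-axis niche-partitioning analysis for two sympatric central-place
foraging species — written for movement ecologists who have GPS tracks, a
land-cover raster, nest locations and per-nest diet tables, and want to
quantify *how* two similar predators manage to coexist.

The package measures segregation along four niche axes and combines them:

1. **Geographic foraging area.** GPS fixes with tag-reported ground speed
   < 4 m/s ("standing points"), minus nest-vicinity and sparse
   flight-corridor points, feed a fixed-bandwidth Gaussian kernel
   utilization distribution (smoothing factor h ∈ {250, 500, 1000} m).
   The 95% isopleth is the foraging area; pairwise overlap uses the
   utilization distribution overlap index
   UDOI = A₁,₂ · ∬ UD₁·UD₂, compared across within/between-species pair
   groups (arcsin-√ transform, ANOVA, Bonferroni).
2. **Foraging-habitat type.** Land-cover class under each standing point,
   per individual, versus class availability (one-sample t-tests).
3. **Diel timing.** Proportion of foraging-area fixes per daytime hour
   (07:00–19:00), for high-frequency tags.
4. **Diet.** Per-nest prey-taxon counts (nests with < 8 items excluded,
   years averaged per territory), with Chao1 richness rarefaction and
   Levins breadth B = 1/Σp².

Each compositional axis goes through a common statistical layer —
Bray–Curtis dissimilarity, nMDS, ANOSIM (Global R, permutation or exact
p), SIMPER decomposition, Pianka overlap O = Σpq/√(Σp²Σq²) under an RA3
randomization null (row-wise category permutation, which preserves niche
breadth) — and the axes multiply into one segregation score: the product
of per-axis between-species Bray–Curtis similarities.

A first-class synthetic-data module (`simConfig()`, `generateScenario()`)
simulates the whole study system — categorical landscape, clustered
nests, two-state central-place GPS tracks with corridors and duty cycles,
multinomial diets — so the entire pipeline is testable end-to-end with no
field data. All spatial containers, composition matrices and test results
are S4 classes with validity checks and accessors.

## Worked example

Run the full pipeline on a reduced synthetic scenario (4 tracked
individuals and 30 diet territories per species, three weeks of 5-min
fixes on a 50 km landscape):

```r
library(nichePart)

cfg <- simConfig(seed = 1,
  species = list(
    LLB = list(nTagged = 4L, nAnalyzable = 4L, regularTagFrac = 0,
               nTerritories = 30L, seasonStart = "03-25", seasonEnd = "04-14"),
    STE = list(nTagged = 4L, nAnalyzable = 4L, regularTagFrac = 0,
               nTerritories = 30L, seasonStart = "03-25", seasonEnd = "04-21")),
  landscape = list(extentKm = 50, cellM = 100),
  breedingRadiusKm = 6, years = 2013L)

res <- runAll(cfg, "pipeline_out")

res$table1[, c("species", "n", "dist_mean_km", "area_shared_h500_mean")]
round(res$axisSimilarity, 2)
res$combined$rounded
```

Output (about 40 s on one CPU):

```
 species n dist_mean_km dist_se_km area_shared_h500_mean area_shared_h500_se
     LLB 4         2.38      0.142                  12.7                1.10
     STE 4        13.15      0.772                  15.4                0.28

axis similarities:
habitat    diet  timing
   0.52    0.35    0.75
combined score: 0.13
diet ANOSIM: R = 0.89, p = 0.001
habitat Pianka between species: 0.51
Chao1: LLB 51.2 vs STE 30.0
```

Reading it: the two simulated species were configured to forage at mean
nest distances of 2.35 and 13.03 km — the pipeline recovers 2.38 and
13.15 km, a 5.5× ratio. Their habitat, diet and timing compositions
overlap moderately axis by axis (similarities 0.52, 0.35, 0.75), yet the
product, 0.13, shows they share only ~13% of their combined resource
space. The diet ANOSIM (R = 0.89, p = 0.001) confirms species-level
separation of nest diets, and the Chao1 estimates recover the configured
richness gap between the generalist and the specialist.

`runAll()` also writes `table1.csv` (per-species distance and area
summaries at every smoothing factor and season window), `table2.csv`
(qualitative four-axis summary), `overlap_report.csv`,
`nullmodel_report.csv`, `diet_report.csv`, `interaction_matrix.csv` and a
`manifest.json` with per-stage row counts and exclusion logs. A thin CLI
wrapper lives in `inst/scripts/run_pipeline.R`.

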