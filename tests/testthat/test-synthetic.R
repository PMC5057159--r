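test_that("landscape class proportions match configured availability", {
  ## symmetric two-class case
  cfg2 <- simConfig(seed = 3, landscape = list(
    extentKm = 10, cellM = 100,
    availability = c(a = 0.5, b = 0.5)))
  ls2 <- generateLandscape(cfg2)
  pr <- availability(ls2)
  expect_true(all(pr >= 0.48 & pr <= 0.52))

  ## single class: uniform raster
  cfg1 <- simConfig(seed = 3, landscape = list(
    extentKm = 5, cellM = 100, availability = c(only = 1)))
  expect_true(all(gridValues(generateLandscape(cfg1)) == 1))

  ## four classes: chi-square goodness of fit not rejected at alpha 0.01
  p4 <- c(cultivated = 0.37, low_natural_vegetation = 0.12,
          rocky = 0.30, uncultivated = 0.21)
  cfg4 <- simConfig(seed = 11, landscape = list(
    extentKm = 10, cellM = 100, availability = p4))
  ls4 <- generateLandscape(cfg4)
  counts <- table(factor(gridValues(ls4), levels = 1:4))
  expect_gt(chisq.test(counts, p = p4)$p.value, 0.01)

  ## invalid proportions error
  expect_error(simConfig(seed = 1, landscape = list(
    extentKm = 5, cellM = 100, availability = c(a = 0.6, b = 0.6))),
    "sum to 1")
})

test_that("tracks respect the duty cycle, fix schedule and speed structure", {
  cfg <- scaledStudyConfig()
  scen <- generateScenario(cfg)
  for (fs in scen$tracks[c(1, 5)]) {
    f <- fixData(fs)
    expect_true(all(diff(as.numeric(f$timestamp)) > 0))
    hm <- as.integer(format(f$timestamp, "%H")) * 60 +
      as.integer(format(f$timestamp, "%M"))
    expect_true(all(hm >= 6 * 60 + 55 & hm <= 19 * 60 + 5))
    ## within a day, consecutive fixes are at the configured interval
    day1 <- f[format(f$timestamp, "%d") == format(f$timestamp[1], "%d"), ]
    expect_true(all(diff(as.numeric(day1$timestamp)) == 300))
    ## ground-speed bimodality: states map cleanly across 4 m/s
    expect_true(all(f$speed[f$state == "transit"] >= 4))
    expect_true(all(f$speed[f$state %in% c("forage", "nest")] < 4))
  }
})

test_that("transit-only configuration yields no slow fixes away from the nest", {
  cfg <- simConfig(seed = 5,
    species = list(
      LLB = list(nTagged = 1L, nAnalyzable = 1L, regularTagFrac = 0,
                 nTerritories = 2L, seasonStart = "04-01",
                 seasonEnd = "04-07",
                 forageBoutMin = c(mean = 0, sd = 0), pauseProb = 0),
      STE = list(nTagged = 1L, nAnalyzable = 1L, regularTagFrac = 0,
                 nTerritories = 2L, seasonStart = "04-01",
                 seasonEnd = "04-07")),
    landscape = list(extentKm = 40, cellM = 200),
    breedingRadiusKm = 3, years = 2013L)
  scen <- generateScenario(cfg)
  fs <- scen$tracks[["LLB_001"]]
  f <- fixData(fs)
  nd <- nestData(scen$nests)
  nest <- nd[nd$nest_id == "LLB_001" & nd$year == 2013, ]
  dNest <- sqrt((f$x - nest$x)^2 + (f$y - nest$y)^2)
  expect_true(all(dNest[f$speed < 4] <= 150))
})

test_that("standing points recover the configured nest-to-patch distance", {
  ## near-nest species, many patches, ~20k fixes: the empirical mean
  ## standing-point distance lands within 15% of 2.35 km
  cfg <- simConfig(seed = 21,
    species = list(
      LLB = list(nTagged = 2L, nAnalyzable = 2L, regularTagFrac = 0,
                 nTerritories = 3L, nPatches = 10L,
                 seasonStart = "03-25", seasonEnd = "05-31"),
      STE = list(nTagged = 1L, nAnalyzable = 1L, regularTagFrac = 0,
                 nTerritories = 2L, seasonStart = "04-01",
                 seasonEnd = "04-03")),
    landscape = list(extentKm = 40, cellM = 100),
    breedingRadiusKm = 3, years = 2013L)
  scen <- generateScenario(cfg)
  nd <- nestData(scen$nests)
  d <- vapply(c("LLB_001", "LLB_002"), function(id) {
    f <- fixData(scen$tracks[[id]])
    expect_gt(nrow(f), 9000)   # two tracks together exceed 20k fixes
    nest <- nd[nd$nest_id == id & nd$year == 2013, ]
    fp <- f[f$state == "forage", ]
    mean(sqrt((fp$x - nest$x)^2 + (fp$y - nest$y)^2)) / 1000
  }, numeric(1))
  expect_lt(abs(mean(d) - 2.35) / 2.35, 0.15)
})

test_that("commuting corridors connect nest and patches and stay sparse", {
  cfg <- scaledStudyConfig(seed = 19)
  scen <- generateScenario(cfg)
  fs <- scen$tracks[["STE_001"]]
  f <- fixData(fs)
  nd <- nestData(scen$nests)
  nest <- nd[nd$nest_id == "STE_001" & nd$year == 2013, ]
  dNest <- sqrt((f$x - nest$x)^2 + (f$y - nest$y)^2)
  ## transit fixes span the whole nest-to-patch distance range: binned by
  ## distance, no gap of more than 2 km up to the 95th percentile
  dt <- sort(dNest[f$state == "transit"])
  dt <- dt[dt <= quantile(dt, 0.95)]
  expect_gt(max(dt), 8000)
  expect_lt(max(diff(dt)), 2000)
  ## standing-point density by generator truth: foraging-patch cells are
  ## at least 10x denser than corridor-pause cells
  slow <- f[f$speed < 4 & dNest > 1500, ]
  key <- paste(floor(slow$x / 500), floor(slow$y / 500))
  isPatch <- slow$state == "forage"
  patchDens <- sum(isPatch) / length(unique(key[isPatch]))
  corrDens <- sum(!isPatch) / length(unique(key[!isPatch]))
  expect_gt(patchDens, 10 * corrDens)
})

test_that("diet generation is multinomial per nest-year with the expected structure", {
  cfg <- scaledStudyConfig(seed = 13)
  scen <- generateScenario(cfg)
  d <- dietData(scen$diets)
  expect_true(all(d$count == round(d$count) & d$count > 0))
  ## the configured fraction of small nests appears
  totals <- aggregate(count ~ nest_id + year, d, sum)
  expect_gt(sum(totals$count < 8), 0)
  ## unknown taxon in the metadata join errors
  cfgBad <- scaledStudyConfig(seed = 13)
  pBad <- simParams(cfgBad)
  pBad$taxonomy <- pBad$taxonomy[-1, ]
  cfgBad@params <- pBad
  expect_error(generateDiets(cfgBad, scen$nests), "missing from metadata")
})

test_that("identical and disjoint diet vectors give the limiting overlaps", {
  tax <- defaultTaxonomy()
  pv <- simParams(scaledStudyConfig())$species$LLB$dietProbs
  ## identical vectors: pooled profiles converge, Pianka -> 1
  cfgSame <- scaledStudyConfig(seed = 31)
  ps <- simParams(cfgSame)
  ps$species$STE$dietProbs <- ps$species$LLB$dietProbs
  ps$species$LLB$smallNestFrac <- 0; ps$species$STE$smallNestFrac <- 0
  ps$species$LLB$itemsPerNestMean <- 200
  ps$species$STE$itemsPerNestMean <- 200
  cfgSame@params <- ps
  scen <- generateScenario(cfgSame)
  dm <- dietMatrix(scen$diets)
  ov <- groupOverlap(dm)
  expect_gt(ov$betweenPooled, 0.99)

  ## disjoint vectors: Bray-Curtis dissimilarity between species = 1
  cfgDis <- scaledStudyConfig(seed = 33)
  pd <- simParams(cfgDis)
  va <- pv; va[27:53] <- 0; va <- va / sum(va)
  vb <- pv; vb[1:26] <- 0; vb <- vb / sum(vb)
  pd$species$LLB$dietProbs <- va
  pd$species$STE$dietProbs <- vb
  cfgDis@params <- pd
  scenD <- generateScenario(cfgDis)
  dmD <- dietMatrix(scenD$diets)
  dd <- as.matrix(brayCurtis(dmD)@d)
  g <- groupLabels(dmD)
  expect_equal(unname(c(dd[g == "LLB", g == "STE"])),
               rep(1, sum(g == "LLB") * sum(g == "STE")))
})

test_that("identical configs generate byte-identical scenarios", {
  cfg <- scaledStudyConfig(seed = 17)
  s1 <- generateScenario(cfg)
  s2 <- generateScenario(scaledStudyConfig(seed = 17))
  expect_identical(gridValues(s1$landscape), gridValues(s2$landscape))
  expect_identical(nestData(s1$nests), nestData(s2$nests))
  expect_identical(lapply(s1$tracks, fixData), lapply(s2$tracks, fixData))
  expect_identical(dietData(s1$diets), dietData(s2$diets))
})
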