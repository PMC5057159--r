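test_that("movebank CSV round-trips through readFixes with QC logging", {
  cfg <- scaledStudyConfig()
  scen <- generateScenario(cfg)
  tr3 <- scen$tracks[1:3]
  csv <- file.path(tempdir(), "fixes3.csv")
  writeFixesCsv(tr3, csv)
  back <- readFixes(csv, crs = list(type = "lonlat",
                                    origin = simParams(cfg)$originLonLat))
  expect_length(back, 3)
  for (id in names(tr3)) {
    a <- fixData(tr3[[id]]); b <- fixData(back[[id]])
    expect_equal(nrow(a), nrow(b))
    ## planar coordinates survive the lon/lat round trip to sub-meter
    expect_lt(max(abs(b$x - (a$x - 25000))), 1)
    expect_lt(max(abs(b$y - (a$y - 25000))), 1)
  }

  ## out-of-order rows are sorted (with warning), duplicates dropped
  raw <- read.csv(csv, check.names = FALSE)
  one <- raw[raw$`individual-local-identifier` == names(tr3)[1], ]
  mangled <- rbind(one[c(5, 1:4), ], one[3, ])
  csv2 <- file.path(tempdir(), "fixes_mangled.csv")
  write.csv(mangled, csv2, row.names = FALSE)
  expect_warning(back2 <- readFixes(csv2), "out-of-order")
  expect_equal(nrow(fixData(back2[[1]])), 5)
  log <- attr(back2, "log")
  expect_equal(log$count[grepl("duplicate", log$reason)], 1)

  ## a missing required column is a format error
  raw$`ground-speed` <- NULL
  csv3 <- file.path(tempdir(), "fixes_nocol.csv")
  write.csv(raw, csv3, row.names = FALSE)
  expect_error(readFixes(csv3), "ground-speed")
})

test_that("standing-point rule is a strict 4 m/s threshold", {
  xy <- matrix(0, 3, 2)
  fs <- mkFS("b1", xy, speed = c(3.9, 4.0, 4.1))
  sps <- classifyStandingPoints(fs)
  expect_equal(nrow(pointData(sps)), 1)
  expect_equal(pointData(sps)$speed, 3.9)

  fs2 <- mkFS("b2", xy, speed = c(4.0, 5, 7))
  expect_equal(nrow(pointData(classifyStandingPoints(fs2))), 0)

  ## retained fraction matches the generator's slow-state bookkeeping
  scen <- generateScenario(scaledStudyConfig())
  fs3 <- scen$tracks[["LLB_002"]]
  f <- fixData(fs3)
  expect_gt(nrow(f), 2000)
  frac <- nrow(pointData(classifyStandingPoints(fs3))) / nrow(f)
  truth <- mean(f$state %in% c("forage", "nest", "transit_pause"))
  expect_lt(abs(frac - truth), 0.02)

  ## absent speed: error unless the displacement fallback is enabled
  fNA <- fixData(mkFS("b3", cbind(0:5 * 100, 0)))
  fNA$speed <- NA_real_
  fsNA <- new("FixSeries", individualId = "b3", species = "A", fixes = fNA)
  expect_error(classifyStandingPoints(fsNA), "fallback")
  spsF <- classifyStandingPoints(fsNA, fallback = TRUE)
  expect_match(appliedFilters(spsF), "fallback")
  expect_equal(nrow(pointData(spsF)), 5)  # 100 m / 300 s < 4 m/s
})

test_that("nest-vicinity exclusion is strict and species-specific", {
  ## all points at the nest vanish
  atNest <- mkSPS(matrix(rep(c(1000, 1000), 10), ncol = 2, byrow = TRUE),
                  sp = "LLB")
  expect_equal(nrow(pointData(excludeNestVicinity(atNest, c(1000, 1000)))), 0)

  ## a point at exactly the radius is retained
  exact <- mkSPS(rbind(c(1150, 1000)), sp = "LLB")
  expect_equal(nrow(pointData(excludeNestVicinity(exact, c(1000, 1000)))), 1)
  inside <- mkSPS(rbind(c(1149.9, 1000)), sp = "LLB")
  expect_equal(nrow(pointData(excludeNestVicinity(inside, c(1000, 1000)))), 0)

  ## commuting species: 1.5 km radius keeps only the outer ring
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  ring <- rbind(cbind(100 * cos(th), 100 * sin(th)),
                cbind(2000 * cos(th), 2000 * sin(th)))
  sps <- mkSPS(ring, sp = "STE")
  kept <- pointData(excludeNestVicinity(sps, c(0, 0)))
  expect_equal(nrow(kept), 20)
  expect_true(all(sqrt(kept$x^2 + kept$y^2) > 1999))

  ## unknown species has no configured radius
  expect_error(excludeNestVicinity(mkSPS(ring, sp = "XX"), c(0, 0)),
               "radius")
})

test_that("density filter removes sparse corridor cells", {
  ## all in one cell: retained at any quantile
  one <- mkSPS(matrix(runif(200, 0, 400), ncol = 2))
  expect_equal(nrow(pointData(densityFilter(one, 500, 0.9))), 100)

  ## q = 0 is the identity
  spread <- mkSPS(cbind(runif(300, 0, 20000), runif(300, 0, 20000)))
  expect_equal(nrow(pointData(densityFilter(spread, 500, 0))), 300)

  ## dense patch + sparse corridor: patch survives, corridor goes
  set.seed(42)
  patch <- cbind(rnorm(5000, 30000, 600), rnorm(5000, 1000, 600))
  corridor <- cbind(runif(50, 1000, 16000), rnorm(50, 500, 120))
  sps <- mkSPS(rbind(patch, corridor))
  kept <- pointData(densityFilter(sps, 500, 0.5))
  inPatch <- kept$x > 25000
  expect_gte(sum(inPatch) / 5000, 0.99)
  expect_gte(1 - sum(!inPatch) / 50, 0.90)

  expect_error(densityFilter(spread, -1, 0.5), "cellM")
})

test_that("season windows are inclusive of boundary days", {
  days <- as.POSIXct(c("2013-03-24 12:00:00", "2013-03-25 12:00:00",
                       "2013-07-15 12:00:00", "2013-07-16 12:00:00"),
                     tz = "UTC")
  f <- data.frame(timestamp = days, lon = 0, lat = 0, speed = 1,
                  heading = 0, x = 1:4, y = 0)
  fs <- new("FixSeries", individualId = "s1", species = "LLB", fixes = f)
  shared <- fixData(seasonWindow(fs, "shared"))
  expect_equal(shared$x, 2:3)   # Mar 24 out, Mar 25 and Jul 15 in

  ## near-nest species season nests inside the shared window, so whole
  ## and shared results coincide
  whole <- fixData(seasonWindow(fs, "whole", start = "03-25", end = "07-15"))
  expect_identical(whole, shared)
})

test_that("QC rules: point minimum, chick-rearing, two-season averaging", {
  nests <- new("NestSet", nests = data.frame(
    nest_id = c("i1", "i2", "i3"), species = "LLB", year = 2013L,
    lon = 0, lat = 0, x = 0, y = 0,
    reached_chick_rearing = c(TRUE, TRUE, FALSE)))
  mk <- function(id, n) {
    s <- mkSPS(cbind(runif(n, 5000, 6000), runif(n, 5000, 6000)), id = id)
    s
  }
  res <- qcFilter(list(mk("i1", 51), mk("i2", 50), mk("i3", 500)), nests)
  ids <- vapply(res$eligible, individualId, "")
  expect_equal(ids, "i1")
  expect_setequal(res$log$reason, c("lt_min_points", "no_chick_rearing"))
  expect_equal(nrow(res$log), 2)

  ## consecutive overlapping seasons average; disjoint ones stay separate
  expect_equal(averageSeasons(c(`2012` = 20, `2013` = 30), udoi = 0.4), 25)
  expect_equal(averageSeasons(c(`2012` = 20, `2013` = 30), udoi = 0),
               c(20, 30))
  expect_equal(averageSeasons(c(`2013` = 12)), 12)
})

test_that("mean nest distance is the plain average of point distances", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- cbind(1000 * cos(th), 1000 * sin(th))
  expect_equal(meanDistanceToNest(mkSPS(ring), c(0, 0)), 1.0)
  two <- mkSPS(rbind(c(1000, 0), c(3000, 0)))
  expect_equal(meanDistanceToNest(two, c(0, 0)), 2.0)
  empty <- mkSPS(matrix(numeric(0), 0, 2))
  expect_error(meanDistanceToNest(empty, c(0, 0)), "empty")
})

test_that("the convenience pipeline equals the manual filter composition", {
  scen <- generateScenario(scaledStudyConfig())
  fs <- scen$tracks[["STE_002"]]
  nd <- nestData(scen$nests)
  nest <- unlist(nd[nd$nest_id == "STE_002" & nd$year == 2013, c("x", "y")])
  pol <- qcPolicy()
  auto <- standingPointPipeline(fs, nest, pol, window = "shared")
  manual <- densityFilter(
    excludeNestVicinity(
      classifyStandingPoints(seasonWindow(fs, "shared", pol), pol,
                             window = "shared"),
      nest, pol),
    pol@densityCellM, pol@densityQuantile)
  expect_identical(pointData(auto), pointData(manual))
  expect_equal(appliedFilters(auto),
               c("speed<threshold", "nest_vicinity", "density"))
})
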