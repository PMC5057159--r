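mkRaster <- function(vals, cellM = 100, classes = NULL) {
  if (is.null(classes)) classes <- paste0("class", seq_len(max(vals)))
  new("HabitatRaster", values = vals, origin = c(0, 0), cellSize = cellM,
      classNames = classes)
}

test_that("habitat composition is a per-individual point-in-cell tally", {
  ras <- mkRaster(matrix(rep(1:2, each = 50), 10, 10), cellM = 100)
  ## columns 1..5 are class 1 (x < 500), columns 6..10 class 2
  allOne <- mkSPS(cbind(runif(30, 0, 490), runif(30, 0, 990)))
  cm <- habitatComposition(list(allOne), ras)
  expect_equal(unname(compValues(cm)[1, ]), c(1, 0))

  ## 40 of 100 points on class 2
  xy <- rbind(cbind(runif(60, 0, 490), runif(60, 0, 990)),
              cbind(runif(40, 510, 990), runif(40, 0, 990)))
  cm2 <- habitatComposition(list(mkSPS(xy)), ras)
  expect_equal(unname(compValues(cm2)[1, ]), c(0.6, 0.4))

  ## points outside the raster are dropped and counted
  xyOut <- rbind(xy, cbind(runif(5, 2000, 3000), runif(5, 0, 990)))
  cm3 <- habitatComposition(list(mkSPS(xyOut)), ras)
  expect_equal(unname(attr(cm3, "outside")), 5)
  expect_equal(unname(compValues(cm3)[1, ]), c(0.6, 0.4))

  allOut <- mkSPS(cbind(runif(10, 5000, 6000), runif(10, 5000, 6000)))
  expect_error(habitatComposition(list(allOut), ras), "outside")
})

test_that("availability counts cells, optionally under a mask", {
  uni <- mkRaster(matrix(1, 5, 5))
  expect_equal(unname(availability(uni)), 1)
  half <- mkRaster(matrix(rep(1:2, each = 50), 10, 10))
  expect_equal(unname(availability(half)), c(0.5, 0.5))

  ## a 37% cultivated fixture reproduces its availability
  set.seed(6)
  v <- matrix(sample(1:2, 400, replace = TRUE, prob = c(0.37, 0.63)), 20, 20)
  ras <- mkRaster(v, classes = c("cultivated", "other"))
  expect_equal(unname(availability(ras)["cultivated"]), mean(v == 1))
  expect_lt(abs(availability(ras)[["cultivated"]] - 0.37), 0.07)

  mask <- matrix(FALSE, 20, 20)
  expect_error(availability(ras, mask), "empty mask")
})

test_that("use-vs-availability t-tests match hand computation", {
  v <- rbind(c(0.5, 0.5), c(0.6, 0.4), c(0.7, 0.3))
  cm <- mkCM(v, rep("A", 3), kind = "proportion")
  colnames(cm@values) <- c("cultivated", "other")
  res <- useVsAvailability(cm, c(cultivated = 0.12, other = 0.88))
  row <- res[res$category == "cultivated", ]
  expect_equal(row$t, (0.6 - 0.12) / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(row$df, 2)
  expect_equal(row$direction, "preference")

  ## all units at availability: t = 0, p = 1
  v0 <- matrix(rep(c(0.12, 0.88), each = 3), 3)
  cm0 <- mkCM(v0, rep("A", 3), kind = "proportion")
  colnames(cm0@values) <- c("cultivated", "other")
  res0 <- useVsAvailability(cm0, c(cultivated = 0.12, other = 0.88))
  expect_equal(res0$t, c(0, 0))
  expect_equal(res0$p, c(1, 1))
  expect_true(all(res0$degenerate))

  ## zero variance off the target: infinite t, p -> 0, flagged
  v1 <- matrix(rep(c(0.5, 0.5), each = 3), 3)
  cm1 <- mkCM(v1, rep("A", 3), kind = "proportion")
  colnames(cm1@values) <- c("cultivated", "other")
  res1 <- useVsAvailability(cm1, c(cultivated = 0.12, other = 0.88))
  expect_true(is.infinite(res1$t[1]) && res1$t[1] > 0)
  expect_equal(res1$p[1], 0)
  expect_true(res1$degenerate[1])
})

test_that("hourly activity bins are half-open and normalized over 07-19", {
  ## uniform coverage: every bin gets 1/12
  t0 <- as.POSIXct("2013-04-01 07:00:00", tz = "UTC")
  ts <- t0 + seq(0, 12 * 3600 - 1, by = 300)
  f <- data.frame(timestamp = ts, lon = 0, lat = 0, speed = 1, heading = 0,
                  x = 0, y = 0)
  fs <- new("FixSeries", individualId = "t1", species = "A", fixes = f)
  act <- hourlyActivity(fs)
  expect_equal(unname(act), rep(1 / 12, 12), tolerance = 1e-12)

  ## fixes only 11:00-14:59 load exactly bins 11-14
  sel <- ts[format(ts, "%H") %in% c("11", "12", "13", "14")]
  fs2 <- new("FixSeries", individualId = "t2", species = "A",
             fixes = f[f$timestamp %in% sel, ])
  act2 <- hourlyActivity(fs2)
  expect_equal(sum(act2[c("h11", "h12", "h13", "h14")]), 1)
  expect_equal(sum(act2) - sum(act2[c("h11", "h12", "h13", "h14")]), 0)

  ## coarse schedules are rejected
  f90 <- f[seq(1, nrow(f), by = 18), ]
  fs90 <- new("FixSeries", individualId = "t3", species = "A", fixes = f90)
  expect_error(hourlyActivity(fs90), "too coarse")
})

test_that("diet matrix applies the 8-item filter and per-nest year averaging", {
  d <- data.frame(
    nest_id = c(rep("n1", 2), rep("n1", 2), rep("n2", 2), "n3"),
    species = "LLB",
    year = c(2011L, 2011L, 2012L, 2012L, 2011L, 2011L, 2011L),
    taxon = c("X", "Y", "X", "Y", "X", "Y", "Z"),
    count = c(4L, 6L, 8L, 2L, 4L, 3L, 9L),
    category = "reptile",
    subcategory = c("snake", "lizard", "snake", "lizard", "snake",
                    "lizard", "snake"))
  dt <- new("DietTable", data = d)
  cm <- dietMatrix(dt)
  ## n2 had 7 items in its only season: excluded and logged
  expect_false("n2" %in% rownames(compValues(cm)))
  log <- attr(cm, "log")
  expect_equal(log$nest, "n2")
  ## n1 averages its two 10-item years: X (4+8)/2, Y (6+2)/2
  expect_equal(compValues(cm)["n1", c("X", "Y")], c(X = 6, Y = 4))
  ## one-taxon nest has proportion row (1)
  pr <- asProportions(cm)
  expect_equal(unname(compValues(pr)["n3", "Z"]), 1)

  ## idempotence: filtering the already-filtered table changes nothing
  keep <- d[d$nest_id != "n2", ]
  cm2 <- dietMatrix(new("DietTable", data = keep))
  expect_equal(compValues(cm2), compValues(cm))

  ## 8 items exactly passes the boundary
  d8 <- d; d8$count[5:6] <- c(4L, 4L)
  cm8 <- dietMatrix(new("DietTable", data = d8))
  expect_true("n2" %in% rownames(compValues(cm8)))
})

test_that("diet category summary recovers configured lizard/snake directions", {
  ## species A weighted to lizards, B to snakes (30 nests each)
  tax <- defaultTaxonomy()
  cfg <- scaledStudyConfig(seed = 23)
  p <- simParams(cfg)
  p$species$LLB$smallNestFrac <- 0
  p$species$STE$smallNestFrac <- 0
  cfg@params <- p
  scen <- generateScenario(cfg)
  cats <- dietCategorySummary(scen$diets)
  fr <- cats$fractions
  mLiz <- tapply(fr$lizard, fr$species, mean)
  mSnk <- tapply(fr$snake, fr$species, mean)
  expect_gt(mLiz[["LLB"]], mLiz[["STE"]])
  expect_gt(mSnk[["STE"]], mSnk[["LLB"]])
  expect_lt(cats$subcategoryTest$p, 0.05)
  ## reptile fraction higher in STE, as configured
  rep_ <- cats$categoryTests[cats$categoryTests$category == "reptile", ]
  expect_lt(rep_$p, 0.05)
})

test_that("synthetic habitat preference is recovered within 3 percent", {
  run <- scaledRun()
  cm <- run$habitat
  v <- compValues(cm); g <- groupLabels(cm)
  useLLB <- colMeans(v[g == "LLB", , drop = FALSE])
  useSTE <- colMeans(v[g == "STE", , drop = FALSE])
  cfgUse <- simParams(scaledStudyConfig())$species
  expect_lt(max(abs(useLLB - cfgUse$LLB$habitatUse[names(useLLB)])), 0.03)
  expect_lt(max(abs(useSTE - cfgUse$STE$habitatUse[names(useSTE)])), 0.03)

  ## direction recovery: preferences and avoidances as configured
  ua <- run$useVsAvailability
  get <- function(sp, cat) ua[ua$species == sp & ua$category == cat, ]
  expect_equal(get("LLB", "low_natural_vegetation")$direction, "preference")
  expect_equal(get("LLB", "cultivated")$direction, "avoidance")
  expect_equal(get("STE", "cultivated")$direction, "preference")
  expect_equal(get("STE", "low_natural_vegetation")$direction, "avoidance")
})

test_that("midday-peak species peaks between 11:00 and 15:00, uniform does not", {
  run <- scaledRun()
  tm <- run$timing
  v <- compValues(tm); g <- groupLabels(tm)
  ste <- colMeans(v[g == "STE", , drop = FALSE])
  peakBin <- names(which.max(ste))
  expect_true(peakBin %in% c("h11", "h12", "h13", "h14"))
  ## uniform species: no bin dominates strongly
  llb <- colMeans(v[g == "LLB", , drop = FALSE])
  expect_lt(max(llb) / (1 / 12), max(ste) / (1 / 12))
})
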