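## Shared fixtures, all built in code.

.cache <- new.env(parent = emptyenv())

## A composition matrix with dimnames filled in.
mkCM <- function(v, groups, kind = "count") {
  v <- as.matrix(v)
  if (is.null(colnames(v))) colnames(v) <- paste0("c", seq_len(ncol(v)))
  if (is.null(rownames(v))) rownames(v) <- paste0("u", seq_len(nrow(v)))
  new("CompositionMatrix", values = v, groups = groups, kind = kind)
}

## A minimal FixSeries from planar coordinates at a regular interval.
mkFS <- function(id, xy, t0 = as.POSIXct("2013-04-01 07:00:00", tz = "UTC"),
                 dtS = 300, sp = "A", speed = 1) {
  n <- nrow(xy)
  f <- data.frame(timestamp = t0 + (0:(n - 1)) * dtS,
                  lon = 0, lat = 0,
                  speed = rep_len(speed, n), heading = 0,
                  x = xy[, 1], y = xy[, 2])
  new("FixSeries", individualId = id, species = sp, fixes = f)
}

## A StandingPointSet straight from coordinates.
mkSPS <- function(xy, id = "u1", sp = "LLB", window = "whole", speed = 1) {
  p <- data.frame(x = xy[, 1], y = xy[, 2],
                  timestamp = as.POSIXct("2013-04-01", tz = "UTC") +
                    seq_len(nrow(xy)) * 300,
                  speed = rep_len(speed, nrow(xy)))
  new("StandingPointSet", individualId = id, species = sp, window = window,
      year = 2013L, points = p, filters = "speed<threshold", eligible = NA)
}

## Stationary mean-reverting track (for attraction neutrality).
ouTrack <- function(n, center = c(0, 0), sd = 300, phi = 0.95) {
  x <- matrix(0, n, 2)
  x[1, ] <- center + rnorm(2, 0, sd)
  for (i in 2:n)
    x[i, ] <- center + phi * (x[i - 1, ] - center) +
      rnorm(2, 0, sd * sqrt(1 - phi^2))
  x
}

## Scaled synthetic study: full default structure (distances 2.35 vs
## 13.03 km, habitat preference, uniform vs midday timing, distinct
## diets) at reduced size - 4 solar-tagged individuals per species over a
## three-week window on a 50 km landscape.
scaledStudyConfig <- function(seed = 7L) {
  simConfig(seed = seed,
    species = list(
      LLB = list(nTagged = 4L, nAnalyzable = 4L, regularTagFrac = 0,
                 nTerritories = 30L,
                 seasonStart = "03-25", seasonEnd = "04-14"),
      STE = list(nTagged = 4L, nAnalyzable = 4L, regularTagFrac = 0,
                 nTerritories = 30L,
                 seasonStart = "03-25", seasonEnd = "04-21")),
    landscape = list(extentKm = 50, cellM = 100),
    breedingRadiusKm = 6, years = 2013L)
}

## One cached pipeline run shared by the end-to-end tests.
scaledRun <- function() {
  if (is.null(.cache$run)) {
    opts <- nichePart:::pipelineOptions(
      attraction = list(enabled = FALSE), nIter = 300L)
    .cache$run <- suppressWarnings(
      runAll(scaledStudyConfig(), file.path(tempdir(), "nichepart_scaled"),
             options = opts))
  }
  .cache$run
}

## Adjusted Rand index (independent check for the clustering test).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab))); sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
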