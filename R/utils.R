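## Internal helpers.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

## Spherical transverse Mercator centered on `origin` = c(lon0, lat0), in
## meters. Adequate for study areas of ~100 km; all analysis distances are
## planar Euclidean.
projectLonLat <- function(lon, lat, origin) {
  R <- 6371008.8
  lam <- (lon - origin[1]) * pi / 180
  phi <- lat * pi / 180
  phi0 <- origin[2] * pi / 180
  B <- cos(phi) * sin(lam)
  x <- R * atanh(B)
  y <- R * (atan2(tan(phi), cos(lam)) - phi0)
  cbind(x = x, y = y)
}

## Inverse of projectLonLat (used by the synthetic writers so planar
## synthetic coordinates round-trip through Movebank-style lon/lat columns).
unprojectXY <- function(x, y, origin) {
  R <- 6371008.8
  phi0 <- origin[2] * pi / 180
  D <- y / R + phi0
  lon <- origin[1] + atan2(sinh(x / R), cos(D)) * 180 / pi
  lat <- asin(sin(D) / cosh(x / R)) * 180 / pi
  cbind(lon = lon, lat = lat)
}

## Deterministic order-statistic quantile (type 1).
quantileType1 <- function(x, q) unname(stats::quantile(x, q, type = 1))

## Row-normalize a non-negative matrix to proportions.
rowProportions <- function(m) {
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("cannot normalize an all-zero row")
  sweep(m, 1, rs, "/")
}

## mean +- SE formatting used in the report tables.
meanSe <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  c(mean = mean(x), se = if (n > 1) stats::sd(x) / sqrt(n) else 0, n = n)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
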