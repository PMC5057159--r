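#' @import methods
NULL

## Central data containers. All spatial objects live in a planar metric CRS
## (meters); lon/lat input is projected on read (see projectLonLat).

#' FixSeries: the time-ordered GPS record of one individual
#'
#' Holds one tagged individual's fixes: timestamp, raw lon/lat, tag-reported
#' ground speed (m/s), heading (deg), and projected planar coordinates x/y
#' (m). Synthetic tracks carry an extra `state` column with the generator's
#' true behavioural state ("nest", "transit", "forage"), used only as ground
#' truth in tests.
#'
#' @slot individualId single identifier string.
#' @slot species species label.
#' @slot fixes data.frame with columns timestamp (POSIXct), lon, lat,
#'   speed, heading, x, y (and optionally state).
#' @export
setClass("FixSeries",
  slots = c(individualId = "character", species = "character",
            fixes = "data.frame"))

setValidity("FixSeries", function(object) {
  f <- object@fixes
  need <- c("timestamp", "lon", "lat", "speed", "heading", "x", "y")
  if (!all(need %in% names(f)))
    return(paste("fixes must have columns:", paste(need, collapse = ", ")))
  if (nrow(f) > 1 && any(diff(as.numeric(f$timestamp)) <= 0))
    return("timestamps must be strictly increasing")
  if (any(f$speed < 0, na.rm = TRUE)) return("ground speed must be >= 0")
  if (any(!is.finite(f$x)) || any(!is.finite(f$y)))
    return("projected coordinates must be finite")
  TRUE
})

#' NestSet: nest locations with breeding outcome
#'
#' @slot nests data.frame with columns nest_id, species, year, lon, lat,
#'   x, y, reached_chick_rearing (logical).
#' @export
setClass("NestSet", slots = c(nests = "data.frame"))

setValidity("NestSet", function(object) {
  n <- object@nests
  need <- c("nest_id", "species", "year", "lon", "lat", "x", "y",
            "reached_chick_rearing")
  if (!all(need %in% names(n)))
    return(paste("nests must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(n[, c("nest_id", "year")]))
    return("(nest_id, year) must be unique")
  if (any(!is.finite(n$x)) || any(!is.finite(n$y)))
    return("nest coordinates must be finite")
  TRUE
})

#' StandingPointSet: filtered low-speed fixes of one individual-season
#'
#' The unit of the space-use analysis: fixes below the ground-speed
#' threshold, progressively filtered (nest vicinity, point density, QC).
#' `filters` records which filters have been applied, in order.
#'
#' @slot individualId,species,window,year identity of the set; window is
#'   "whole" or "shared".
#' @slot points data.frame with columns x, y, timestamp, speed.
#' @slot filters character vector of applied filter tags.
#' @slot eligible logical; TRUE once the set passed QC.
#' @export
setClass("StandingPointSet",
  slots = c(individualId = "character", species = "character",
            window = "character", year = "integer",
            points = "data.frame", filters = "character",
            eligible = "logical"))

setValidity("StandingPointSet", function(object) {
  p <- object@points
  if (!all(c("x", "y", "timestamp", "speed") %in% names(p)))
    return("points must have columns x, y, timestamp, speed")
  if (!object@window %in% c("whole", "shared"))
    return("window must be 'whole' or 'shared'")
  TRUE
})

#' QCPolicy: thresholds of the foraging-point classification and QC rules
#'
#' Defaults follow the study design: standing point = ground speed < 4 m/s;
#' nest-vicinity exclusion radius 0.15 km (near-nest species) and 1.5 km
#' (commuting species); polygons with < 51 points excluded; nests with < 8
#' prey items in a season excluded; shared season window Mar 25 - Jul 15
#' (boundary days inclusive); individuals that never reached chick-rearing
#' excluded.
#'
#' @slot speedThreshold m/s, strict "<".
#' @slot nestRadiusKm named numeric, exclusion radius per species (km).
#' @slot minPoints minimum standing points for an analysis-eligible set.
#' @slot minDietItems minimum prey items per nest-season.
#' @slot sharedStart,sharedEnd month-day strings "MM-DD".
#' @slot requireChickRearing drop individuals whose nest failed early.
#' @slot densityCellM,densityQuantile point-density corridor filter: grid
#'   cell side (m) and the quantile of nonzero cell counts below which
#'   cells are discarded.
#' @export
setClass("QCPolicy",
  slots = c(speedThreshold = "numeric", nestRadiusKm = "numeric",
            minPoints = "integer", minDietItems = "integer",
            sharedStart = "character", sharedEnd = "character",
            requireChickRearing = "logical",
            densityCellM = "numeric", densityQuantile = "numeric"))

setValidity("QCPolicy", function(object) {
  if (object@speedThreshold <= 0) return("speedThreshold must be > 0")
  if (any(object@nestRadiusKm <= 0)) return("nestRadiusKm must be > 0")
  if (object@minPoints <= 0L || object@minDietItems <= 0L)
    return("minPoints and minDietItems must be > 0")
  if (object@densityCellM <= 0) return("densityCellM must be > 0")
  if (object@densityQuantile < 0 || object@densityQuantile > 1)
    return("densityQuantile must be in [0, 1]")
  TRUE
})

#' HabitatRaster: categorical land-cover raster in planar meters
#'
#' @slot values integer matrix of class codes; rows index y (row 1 at the
#'   bottom edge), columns index x.
#' @slot origin numeric (x0, y0), coordinates of the lower-left corner.
#' @slot cellSize cell side length (m).
#' @slot classNames names of the habitat classes (code i = classNames[i]).
#' @export
setClass("HabitatRaster",
  slots = c(values = "matrix", origin = "numeric", cellSize = "numeric",
            classNames = "character"))

setValidity("HabitatRaster", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric/integer matrix")
  if (length(object@origin) != 2) return("origin must be length 2")
  if (object@cellSize <= 0) return("cellSize must be > 0")
  k <- length(object@classNames)
  if (any(v < 1 | v > k)) return("class codes must index classNames")
  TRUE
})

#' UtilizationGrid: discretized utilization distribution
#'
#' Cell probability masses of a fixed-bandwidth bivariate Gaussian KDE.
#' The source points are retained so two UDs can be re-evaluated on a
#' common grid for overlap computation.
#'
#' @slot z matrix of cell masses (rows = y, row 1 at bottom); sums to 1.
#' @slot origin (x0, y0) of the lower-left grid corner (m).
#' @slot cellSize cell side (m); must be <= h/5.
#' @slot h kernel standard deviation ("smoothing factor", m).
#' @slot points n x 2 matrix of the source coordinates.
#' @export
setClass("UtilizationGrid",
  slots = c(z = "matrix", origin = "numeric", cellSize = "numeric",
            h = "numeric", points = "matrix"))

setValidity("UtilizationGrid", function(object) {
  if (any(object@z < 0)) return("cell masses must be >= 0")
  if (abs(sum(object@z) - 1) > 1e-9) return("total mass must be 1 +- 1e-9")
  if (object@cellSize > object@h / 5 + 1e-9)
    return("cell size must be <= h/5")
  TRUE
})

#' IsoplethRegion: smallest cell set holding a given UD mass
#'
#' @slot level isopleth level (default 0.95).
#' @slot member logical matrix marking member cells (same layout as the UD).
#' @slot origin,cellSize grid geometry (m).
#' @slot areaKm2 member cell count times cell area, km^2.
#' @export
setClass("IsoplethRegion",
  slots = c(level = "numeric", member = "matrix", origin = "numeric",
            cellSize = "numeric", areaKm2 = "numeric"))

#' OverlapMatrix: pairwise UDOI values with species labels
#'
#' @slot ids individual ids (row/col names of values).
#' @slot values symmetric matrix of UDOI values, NA diagonal.
#' @slot groups species label per id.
#' @export
setClass("OverlapMatrix",
  slots = c(ids = "character", values = "matrix", groups = "character"))

setValidity("OverlapMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v) | lower.tri(v)]
  if (any(off < 0, na.rm = TRUE)) return("UDOI values must be >= 0")
  if (any(abs(v - t(v)) > 1e-9, na.rm = TRUE)) return("matrix must be symmetric")
  TRUE
})

#' CompositionMatrix: sampling units x categories
#'
#' The common currency of the overlap and multivariate layer: rows are
#' individuals (habitat use, hourly activity) or nests (diet), columns are
#' categories, values are proportions or mean counts.
#'
#' @slot values numeric matrix, rownames = unit ids, colnames = categories.
#' @slot groups species label per unit (named by unit id).
#' @slot kind "proportion", "count" or "mean_count".
#' @export
setClass("CompositionMatrix",
  slots = c(values = "matrix", groups = "character", kind = "character"))

setValidity("CompositionMatrix", function(object) {
  v <- object@values
  if (any(v < 0)) return("values must be >= 0")
  if (is.null(colnames(v))) return("categories (colnames) required")
  if (is.null(rownames(v))) return("unit ids (rownames) required")
  if (length(object@groups) != nrow(v))
    return("one group label per unit required")
  if (object@kind == "proportion" &&
      any(abs(rowSums(v) - 1) > 1e-9))
    return("proportion rows must sum to 1 +- 1e-9")
  TRUE
})

#' DietTable: per-nest, per-year prey-taxon counts
#'
#' @slot data data.frame with columns nest_id, species, year, taxon, count,
#'   category (reptile/bird/mammal/arthropod), subcategory (snake/lizard/
#'   other/na).
#' @export
setClass("DietTable", slots = c(data = "data.frame"))

setValidity("DietTable", function(object) {
  d <- object@data
  need <- c("nest_id", "species", "year", "taxon", "count", "category",
            "subcategory")
  if (!all(need %in% names(d)))
    return(paste("diet table must have columns:", paste(need, collapse = ", ")))
  if (any(d$count <= 0) || any(d$count != round(d$count)))
    return("counts must be positive integers")
  map <- unique(d[, c("taxon", "category")])
  if (anyDuplicated(map$taxon)) return("taxon->category mapping must be single-valued")
  TRUE
})

#' NullModelResult: observed statistic plus Monte-Carlo null distribution
#'
#' @slot statistic name(s) of the statistic(s).
#' @slot observed named numeric of observed values.
#' @slot null matrix (iterations x statistics) of null values.
#' @slot pHigh,pLow named tail probabilities, add-one convention:
#'   pHigh = (1 + #\{null >= obs\}) / (nIter + 1); both tails reported, so
#'   pHigh + pLow >= 1.
#' @slot nIter,seed,algorithm bookkeeping ("RA3").
#' @export
setClass("NullModelResult",
  slots = c(statistic = "character", observed = "numeric", null = "matrix",
            pHigh = "numeric", pLow = "numeric", nIter = "integer",
            seed = "integer", algorithm = "character"))

setValidity("NullModelResult", function(object) {
  if (nrow(object@null) != object@nIter)
    return("null distribution length must equal nIter")
  if (any(object@pHigh + object@pLow < 1 - 1e-12))
    return("pHigh + pLow must be >= 1 (overlapping tails)")
  TRUE
})

#' RichnessEstimate: Chao1 richness with sample-based rarefaction
#'
#' @slot sObs,f1,f2 observed richness, singletons, doubletons.
#' @slot chao1 Chao1 estimate on the pooled counts.
#' @slot curve data.frame (m, mean, sd): mean and bootstrap SD of Chao1
#'   over resamples of m sampling units.
#' @slot nBoot,seed bookkeeping.
#' @export
setClass("RichnessEstimate",
  slots = c(sObs = "integer", f1 = "integer", f2 = "integer",
            chao1 = "numeric", curve = "data.frame", nBoot = "integer",
            seed = "integer"))

setValidity("RichnessEstimate", function(object) {
  if (object@chao1 < object@sObs - 1e-9) return("Chao1 must be >= S_obs")
  TRUE
})

#' AttractionResult: dyadic attraction-repulsion permutation test
#'
#' Index in [0, 1]: 0.5 is neutral (mutually random movement), values near
#' 1 indicate attraction, near 0 repulsion.
#'
#' @slot pair the two individual ids.
#' @slot observed observed meeting count.
#' @slot null meeting counts under circular time-shift permutations.
#' @slot index rank-based index in [0, 1]; NA when the tracks never
#'   co-occur in time.
#' @slot nPerm,seed,meetDistM,timeTolS test parameters.
#' @export
setClass("AttractionResult",
  slots = c(pair = "character", observed = "numeric", null = "numeric",
            index = "numeric", nPerm = "integer", seed = "integer",
            meetDistM = "numeric", timeTolS = "numeric"))

#' ClusterResult: k-means clustering of foraging locations
#'
#' @slot k number of clusters.
#' @slot assignments cluster id per point (1..k).
#' @slot centroids k x 2 matrix.
#' @slot composition k x n_species matrix of species fractions per cluster.
#' @export
setClass("ClusterResult",
  slots = c(k = "integer", assignments = "integer", centroids = "matrix",
            composition = "matrix"))

setValidity("ClusterResult", function(object) {
  if (any(object@assignments < 1 | object@assignments > object@k))
    return("assignments must be in 1..k")
  if (any(abs(rowSums(object@composition) - 1) > 1e-9))
    return("composition fractions per cluster must sum to 1")
  TRUE
})

#' DissimilarityMatrix: Bray-Curtis dissimilarities with group labels
#'
#' @slot ids unit ids.
#' @slot d "dist" object of pairwise Bray-Curtis dissimilarities in [0,1].
#' @slot groups group label per unit.
#' @export
setClass("DissimilarityMatrix",
  slots = c(ids = "character", d = "ANY", groups = "character"))

setValidity("DissimilarityMatrix", function(object) {
  dv <- as.numeric(object@d)
  if (any(dv < -1e-12 | dv > 1 + 1e-12)) return("dissimilarities must be in [0,1]")
  TRUE
})

#' AnosimResult: ANOSIM Global R with permutation p-value
#'
#' @slot R Global R in [-1, 1].
#' @slot p permutation p-value (add-one convention, or exact when the
#'   permutation set was fully enumerated).
#' @slot nPerm number of permutations used (0 when exact).
#' @slot exact TRUE when all label assignments were enumerated.
#' @slot seed RNG seed.
#' @export
setClass("AnosimResult",
  slots = c(R = "numeric", p = "numeric", nPerm = "integer",
            exact = "logical", seed = "integer"))

setValidity("AnosimResult", function(object) {
  if (object@R < -1 - 1e-9 || object@R > 1 + 1e-9) return("R must be in [-1,1]")
  if (object@p <= 0 || object@p > 1) return("p must be in (0,1]")
  TRUE
})

#' SimperResult: per-category decomposition of Bray-Curtis structure
#'
#' @slot between data.frame (category, contribution, percent, cumPercent)
#'   decomposing the average between-group dissimilarity; percents sum
#'   to 100.
#' @slot overallDissimilarity average between-group dissimilarity (%).
#' @slot within named list of data.frames: per-group average similarity
#'   decomposition (typicality).
#' @slot withinSimilarity named numeric: average within-group similarity (%).
#' @export
setClass("SimperResult",
  slots = c(between = "data.frame", overallDissimilarity = "numeric",
            within = "list", withinSimilarity = "numeric"))

#' SimConfig: full parameterization of the synthetic study system
#'
#' See [simConfig()] for the fields and defaults.
#' @slot params named list of generator parameters.
#' @export
setClass("SimConfig", slots = c(params = "list"))
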