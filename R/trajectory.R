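## Foraging-point classification and quality control. The filter order is
## fixed: speed -> nest vicinity -> point density -> QC.

#' Construct a QC policy
#'
#' @param speedThreshold standing-point ground-speed threshold, m/s
#'   (strict `<`).
#' @param nestRadiusKm named numeric: per-species nest-vicinity exclusion
#'   radius (km), strict `<`.
#' @param minPoints minimum standing points for an analysis-eligible set.
#' @param minDietItems minimum prey items per nest-season.
#' @param sharedStart,sharedEnd shared-window month-day strings, inclusive.
#' @param requireChickRearing exclude individuals whose nest failed before
#'   chick-rearing.
#' @param densityCellM,densityQuantile corridor filter grid cell (m) and
#'   nonzero-cell-count quantile.
#' @return a [QCPolicy-class]
#' @export
qcPolicy <- function(speedThreshold = 4,
                     nestRadiusKm = c(LLB = 0.15, STE = 1.5),
                     minPoints = 51L, minDietItems = 8L,
                     sharedStart = "03-25", sharedEnd = "07-15",
                     requireChickRearing = TRUE,
                     densityCellM = 500, densityQuantile = 0.5) {
  new("QCPolicy", speedThreshold = speedThreshold,
      nestRadiusKm = nestRadiusKm, minPoints = as.integer(minPoints),
      minDietItems = as.integer(minDietItems), sharedStart = sharedStart,
      sharedEnd = sharedEnd, requireChickRearing = requireChickRearing,
      densityCellM = densityCellM, densityQuantile = densityQuantile)
}

#' Keep fixes within a breeding-season window
#'
#' `mode = "shared"` keeps fixes whose date (month-day, any year) lies in
#' the policy's shared window, boundary days inclusive. `mode = "whole"`
#' keeps the species' full configured season (`start`/`end` month-day
#' strings; defaults keep everything).
#'
#' @param fs a [FixSeries-class]
#' @param mode "whole" or "shared"
#' @param policy a [QCPolicy-class]
#' @param start,end month-day "MM-DD" bounds for `mode = "whole"`
#' @return a [FixSeries-class]
#' @export
seasonWindow <- function(fs, mode = c("shared", "whole"), policy = qcPolicy(),
                         start = "01-01", end = "12-31") {
  mode <- match.arg(mode)
  f <- fixData(fs)
  md <- format(f$timestamp, "%m-%d")
  if (mode == "shared") { start <- policy@sharedStart; end <- policy@sharedEnd }
  keep <- md >= start & md <= end
  initialize(fs, fixes = f[keep, , drop = FALSE])
}

#' Classify standing points by the ground-speed rule
#'
#' Retains exactly the fixes with tag-reported ground speed strictly below
#' the threshold (default 4 m/s). When the speed field is absent,
#' `fallback = TRUE` derives speed from displacement / time difference
#' (flagged in the filter log); otherwise it is an error.
#'
#' @param fs a [FixSeries-class]
#' @param policy a [QCPolicy-class]
#' @param window window tag carried on the output ("whole"/"shared")
#' @param fallback use finite-difference speed when the field is missing
#' @return a [StandingPointSet-class]
#' @export
classifyStandingPoints <- function(fs, policy = qcPolicy(),
                                   window = "whole", fallback = FALSE) {
  f <- fixData(fs)
  filters <- "speed<threshold"
  if (all(is.na(f$speed))) {
    if (!fallback) stop("ground speed absent and fallback disabled")
    dt <- diff(as.numeric(f$timestamp))
    dd <- sqrt(diff(f$x)^2 + diff(f$y)^2)
    f$speed <- c(dd / dt, NA)
    filters <- "speed<threshold(fallback)"
  }
  keep <- !is.na(f$speed) & f$speed < policy@speedThreshold
  yr <- if (nrow(f)) as.integer(format(f$timestamp[1], "%Y")) else NA_integer_
  new("StandingPointSet", individualId = individualId(fs),
      species = speciesLabel(fs), window = window, year = yr,
      points = f[keep, c("x", "y", "timestamp", "speed"), drop = FALSE],
      filters = filters, eligible = NA)
}

#' Remove standing points in the nest's social-interaction zone
#'
#' Drops points with Euclidean distance to the nest strictly below the
#' species' configured radius (0.15 km near-nest, 1.5 km commuting
#' species by default); a point at exactly the radius is retained.
#'
#' @param sps a [StandingPointSet-class]
#' @param nest numeric (x, y) of the nest, same CRS (m)
#' @param policy a [QCPolicy-class]
#' @return the filtered [StandingPointSet-class]
#' @export
excludeNestVicinity <- function(sps, nest, policy = qcPolicy()) {
  rad <- policy@nestRadiusKm[speciesLabel(sps)]
  if (is.na(rad)) stop("no nest-exclusion radius configured for species ",
                       speciesLabel(sps))
  p <- pointData(sps)
  d <- sqrt((p$x - nest[1])^2 + (p$y - nest[2])^2)
  keep <- d >= rad * 1000
  initialize(sps, points = p[keep, , drop = FALSE],
             filters = c(appliedFilters(sps), "nest_vicinity"))
}

## Cell keys of points on a square grid anchored at the coordinate origin.
gridKeys <- function(x, y, cellM) {
  paste(floor(x / cellM), floor(y / cellM))
}

#' Point-density corridor filter
#'
#' Bins standing points on a square grid and retains points in cells whose
#' count reaches the q-th quantile (order statistic) of the nonzero cell
#' counts. Flight corridors - long sparse bands of pause points between
#' nest and foraging patches - fall below the quantile and are removed;
#' `q = 0` is the identity.
#'
#' @param sps a [StandingPointSet-class]
#' @param cellM grid cell side (m)
#' @param q quantile of nonzero cell counts in [0, 1]
#' @return the filtered [StandingPointSet-class]
#' @export
densityFilter <- function(sps, cellM = 500, q = 0.5) {
  if (cellM <= 0) stop("cellM must be > 0")
  p <- pointData(sps)
  if (nrow(p) == 0) stop("density filter needs at least one point")
  key <- gridKeys(p$x, p$y, cellM)
  counts <- table(key)
  thr <- quantileType1(as.numeric(counts), q)
  keep <- counts[key] >= thr
  initialize(sps, points = p[keep, , drop = FALSE],
             filters = c(appliedFilters(sps), "density"))
}

#' Quality-control filter over a collection of standing-point sets
#'
#' Applies the QC rules: (1) sets with fewer than `minPoints` points are
#' excluded; (2) individuals whose nest failed before chick-rearing are
#' excluded (when required); surviving sets are marked eligible. Every
#' exclusion is logged with a machine-readable reason. Per-individual
#' summaries over two consecutive eligible seasons are averaged downstream
#' (see [averageSeasons()]).
#'
#' @param sets list of [StandingPointSet-class]
#' @param nests a [NestSet-class] (for the chick-rearing flag, matched on
#'   individual id = nest id and year)
#' @param policy a [QCPolicy-class]
#' @return list(eligible = list of eligible sets, log = data.frame)
#' @export
qcFilter <- function(sets, nests, policy = qcPolicy()) {
  nd <- nestData(nests)
  log <- data.frame(individual = character(0), year = integer(0),
                    reason = character(0))
  keep <- list()
  for (s in sets) {
    id <- individualId(s); yr <- s@year
    row <- nd[nd$nest_id == id & nd$year == yr, ]
    if (policy@requireChickRearing &&
        (nrow(row) == 0 || !row$reached_chick_rearing[1])) {
      log <- rbind(log, data.frame(individual = id, year = yr,
                                   reason = "no_chick_rearing"))
      next
    }
    if (nrow(pointData(s)) < policy@minPoints) {
      log <- rbind(log, data.frame(individual = id, year = yr,
                                   reason = "lt_min_points"))
      next
    }
    keep[[length(keep) + 1L]] <- initialize(s, eligible = TRUE,
      filters = c(appliedFilters(s), "qc"))
  }
  list(eligible = keep, log = log)
}

#' Average a per-individual summary over two consecutive seasons
#'
#' QC rule: individuals tracked over two consecutive breeding seasons with
#' similar foraging areas contribute the mean of the two seasonal values.
#' Similarity criterion: the seasonal 95% regions overlap (seasonal UDOI
#' > `udoiMin`); otherwise the seasons are kept separate.
#'
#' @param values numeric per-season values (named by year)
#' @param udoi seasonal overlap between the two seasons (ignored when only
#'   one season)
#' @param udoiMin similarity criterion on the seasonal UDOI
#' @return numeric vector of reported value(s)
#' @export
averageSeasons <- function(values, udoi = NA, udoiMin = 0) {
  if (length(values) <= 1) return(unname(values))
  yrs <- as.integer(names(values))
  if (length(values) == 2 && diff(sort(yrs)) == 1 &&
      !is.na(udoi) && udoi > udoiMin)
    return(mean(values))
  unname(values)
}

#' Mean distance from standing points to the nest
#'
#' @param sps a [StandingPointSet-class]
#' @param nest numeric (x, y) in meters
#' @return mean Euclidean distance in km
#' @export
meanDistanceToNest <- function(sps, nest) {
  p <- pointData(sps)
  if (nrow(p) == 0) stop("cannot compute mean distance of an empty set")
  mean(sqrt((p$x - nest[1])^2 + (p$y - nest[2])^2)) / 1000
}

#' Full standing-point pipeline for one individual
#'
#' Fixed composition: season window -> speed rule -> nest vicinity ->
#' density filter.
#'
#' @param fs a [FixSeries-class]
#' @param nest numeric (x, y)
#' @param policy a [QCPolicy-class]
#' @param window "whole" or "shared"
#' @param start,end whole-season bounds (month-day)
#' @return a [StandingPointSet-class]
#' @export
standingPointPipeline <- function(fs, nest, policy = qcPolicy(),
                                  window = "shared",
                                  start = "01-01", end = "12-31") {
  fs2 <- seasonWindow(fs, window, policy, start = start, end = end)
  sps <- classifyStandingPoints(fs2, policy, window = window)
  sps <- excludeNestVicinity(sps, nest, policy)
  densityFilter(sps, policy@densityCellM, policy@densityQuantile)
}
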