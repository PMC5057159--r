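## Nest nearest-neighbour structure, k-means foraging clusters, dyadic
## attraction-repulsion permutation tests.

#' Nearest-neighbour nest distances
#'
#' For each focal nest, the distance to the nearest nest of the target
#' set: `mode = "intra"` within `speciesFrom` (excluding the focal nest),
#' `mode = "inter"` from `speciesFrom` nests to the nearest `speciesTo`
#' nest. Inter mode is directional: mean(A to B) need not equal mean(B to
#' A) when the sets are unbalanced.
#'
#' @param nests a [NestSet-class]
#' @param mode "intra" or "inter"
#' @param year breeding season to use
#' @param speciesFrom focal species
#' @param speciesTo target species (inter mode)
#' @return list(distances, meanKm, seKm, n)
#' @export
nnDistances <- function(nests, mode = c("intra", "inter"), year,
                        speciesFrom, speciesTo = NULL) {
  mode <- match.arg(mode)
  nd <- nestData(nests)
  nd <- nd[nd$year == year, ]
  from <- nd[nd$species == speciesFrom, ]
  to <- if (mode == "intra") from else nd[nd$species == speciesTo, ]
  if (nrow(from) < 1 || nrow(to) < (if (mode == "intra") 2 else 1))
    stop("insufficient nests for nearest-neighbour analysis")
  d <- vapply(seq_len(nrow(from)), function(i) {
    dx <- to$x - from$x[i]; dy <- to$y - from$y[i]
    dd <- sqrt(dx^2 + dy^2)
    if (mode == "intra") dd[i] <- Inf    # exclude self
    min(dd)
  }, numeric(1)) / 1000
  ms <- meanSe(d)
  list(distances = d, meanKm = unname(ms["mean"]), seKm = unname(ms["se"]),
       n = nrow(from))
}

#' K-means clustering of foraging locations
#'
#' Euclidean k-means (default k = 5) on pooled standing-point coordinates,
#' best of `nRestarts` seeded starts by within-cluster sum of squares;
#' reports the species composition of each cluster.
#'
#' @param points matrix/data.frame with columns x, y
#' @param species species label per point
#' @param k number of clusters
#' @param nRestarts random restarts
#' @param seed RNG seed
#' @return a [ClusterResult-class]
#' @export
kmeansClusters <- function(points, species, k = 5L, nRestarts = 10L,
                           seed = 1L) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  if (nrow(pts) < k) stop("k exceeds the number of points")
  fit <- withSeed(seed, stats::kmeans(pts, centers = k, nstart = nRestarts,
                                      iter.max = 100))
  spl <- sort(unique(species))
  comp <- t(vapply(seq_len(k), function(ci) {
    tab <- table(factor(species[fit$cluster == ci], levels = spl))
    as.numeric(tab / sum(tab))
  }, numeric(length(spl))))
  dimnames(comp) <- list(paste0("cluster_", seq_len(k)), spl)
  new("ClusterResult", k = as.integer(k),
      assignments = as.integer(fit$cluster),
      centroids = fit$centers, composition = comp)
}

#' Dyadic attraction-repulsion index from paired tracks
#'
#' A meeting is a pair of fixes (one per track) within `meetDistM` meters
#' and `timeTolS` seconds. The observed meeting count is compared with a
#' null distribution obtained by circular time-shifts of track b (uniform
#' shifts of at least one day, wrapping within b's observation span),
#' which preserve each track's spatial footprint and autocorrelation.
#' The index is the mid-rank of the observed count within the null,
#' scaled to [0, 1]: about 0.5 for mutually random movement, near 1 for
#' attraction, near 0 for repulsion.
#'
#' @param fsA,fsB [FixSeries-class] objects
#' @param meetDistM meeting distance (m)
#' @param timeTolS meeting time tolerance (s)
#' @param nPerm number of circular-shift permutations
#' @param seed RNG seed
#' @return an [AttractionResult-class]; index is NA when the observation
#'   periods do not overlap
#' @export
attractionIndex <- function(fsA, fsB, meetDistM = 500, timeTolS = 150,
                            nPerm = 999L, seed = 1L) {
  a <- fixData(fsA); b <- fixData(fsB)
  ta <- as.numeric(a$timestamp); tb <- as.numeric(b$timestamp)
  if (max(ta) < min(tb) || max(tb) < min(ta)) {
    return(new("AttractionResult",
               pair = c(individualId(fsA), individualId(fsB)),
               observed = NA_real_, null = numeric(0), index = NA_real_,
               nPerm = as.integer(nPerm), seed = as.integer(seed),
               meetDistM = meetDistM, timeTolS = timeTolS))
  }
  ## spatially close fix pairs, computed once (chunked over a's fixes)
  pairsI <- list(); pi <- 0L
  chunk <- max(1L, floor(2e6 / length(tb)))
  for (s0 in seq(1, length(ta), by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, length(ta))
    d2 <- outer(a$x[idx], b$x, "-")^2 + outer(a$y[idx], b$y, "-")^2
    w <- which(d2 <= meetDistM^2, arr.ind = TRUE)
    if (nrow(w)) {
      pi <- pi + 1L
      pairsI[[pi]] <- cbind(idx[w[, 1]], w[, 2])
    }
  }
  if (pi == 0L) {
    obs <- 0; null <- rep(0, nPerm)
  } else {
    pr <- do.call(rbind, pairsI)
    dta <- ta[pr[, 1]]
    dtb <- tb[pr[, 2]]
    obs <- sum(abs(dta - dtb) <= timeTolS)
    span <- max(tb) - min(tb) + stats::median(diff(tb))
    ## null meeting for shift s: the circular time offset (tb - ta + s)
    ## mod span falls within the tolerance of 0. Sorting the offsets once
    ## makes each shift a pair of binary searches.
    gs <- sort((dtb - dta) %% span)
    circCount <- function(s) {
      c0 <- (-s) %% span
      a <- (c0 - timeTolS) %% span; b <- (c0 + timeTolS) %% span
      if (a <= b) {
        findInterval(b, gs) - findInterval(a - 1e-9, gs)
      } else {
        (length(gs) - findInterval(a - 1e-9, gs)) + findInterval(b, gs)
      }
    }
    null <- withSeed(seed, {
      ## shifts of at least one day, so daily routines are decoupled; for
      ## tracks shorter than two days, fall back to mid-span shifts.
      ## Shifts are quantized to the sampling interval: both tags report
      ## on the same fix lattice, so an off-lattice shift would make
      ## meetings impossible by construction and bias the null low
      lag <- if (span > 2 * 86400) 86400 else 0.1 * span
      dtMed <- stats::median(diff(tb))
      shifts <- stats::runif(nPerm, lag, span - lag)
      if (is.finite(dtMed) && dtMed > 0)
        shifts <- round(shifts / dtMed) * dtMed
      vapply(shifts, circCount, numeric(1))
    })
  }
  index <- (sum(null < obs) + 0.5 * (sum(null == obs) + 1)) / (nPerm + 1)
  new("AttractionResult",
      pair = c(individualId(fsA), individualId(fsB)),
      observed = obs, null = null, index = index,
      nPerm = as.integer(nPerm), seed = as.integer(seed),
      meetDistM = meetDistM, timeTolS = timeTolS)
}

#' Interpretation band of an attraction index
#'
#' Default reporting bands: <= 0.25 repulsion, >= 0.75 attraction, else
#' neutral; NA for pairs never co-observed.
#' @param index numeric attraction index (or [AttractionResult-class])
#' @param low,high band boundaries
#' @return character
#' @export
attractionBand <- function(index, low = 0.25, high = 0.75) {
  if (is(index, "AttractionResult")) index <- attractionValue(index)
  ifelse(is.na(index), NA_character_,
         ifelse(index <= low, "repulsion",
                ifelse(index >= high, "attraction", "neutral")))
}
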