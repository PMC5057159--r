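## Community-statistics layer: Bray-Curtis, nMDS, ANOSIM, SIMPER,
## threshold similarity grouping. Applied identically to habitat, timing
## and diet composition matrices. No pre-transformation is applied by
## default; `transform = "sqrt"` square-roots the values first (a common
## convention in the source workflows) and changes all similarity values.

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), in [0, 1].
#'
#' @param cm a [CompositionMatrix-class]
#' @param transform "none" (default) or "sqrt"
#' @return a [DissimilarityMatrix-class]
#' @export
brayCurtis <- function(cm, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  v <- compValues(cm)
  if (any(rowSums(v) == 0)) stop("all-zero row in composition matrix")
  if (transform == "sqrt") v <- sqrt(v)
  d <- vegan::vegdist(v, method = "bray")
  new("DissimilarityMatrix", ids = rownames(v), d = d,
      groups = groupLabels(cm))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 nMDS on a Bray-Curtis matrix, best of `nStarts`
#' seeded random starts (monotone regression on dissimilarity ranks).
#'
#' @param dm a [DissimilarityMatrix-class]
#' @param dims embedding dimension
#' @param nStarts random starts
#' @param seed RNG seed
#' @return list(coordinates, stress) with stress in [0, 1]
#' @export
nmdsOrdination <- function(dm, dims = 2L, nStarts = 20L, seed = 1L) {
  n <- length(dm@ids)
  if (n < dims + 1) stop("need at least dims + 1 units")
  ## metaMDS warns when stress is ~0; that is the expected outcome for
  ## well-separated small fixtures, not a failure
  fit <- withSeed(seed, withCallingHandlers(
    vegan::metaMDS(dm@d, k = dims, trymax = nStarts,
                   autotransform = FALSE, trace = 0, wascores = FALSE),
    warning = function(w) {
      if (grepl("stress is .nearly. zero", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  if (!is.finite(fit$stress)) stop("nMDS failed to converge in all starts")
  coords <- fit$points
  rownames(coords) <- dm@ids
  list(coordinates = coords, stress = fit$stress, converged = fit$converged)
}

## Global R from a dist and a group factor: mean rank of between-group
## dissimilarities minus mean rank of within-group, scaled by M/2.
anosimR <- function(dmat, groups) {
  r <- rank(dmat)
  n <- length(groups)
  between <- as.numeric(outer(groups, groups, "!=")[lower.tri(matrix(0, n, n))])
  M <- length(r)
  (mean(r[between == 1]) - mean(r[between == 0])) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Global R contrasting between- vs within-group dissimilarity ranks
#' (mid-ranks for ties). p is estimated by random label permutations with
#' the add-one convention p = (1 + #\{R_perm >= R_obs\}) / (nPerm + 1), or
#' computed exactly by enumerating all distinct label assignments when
#' `exact = TRUE` (feasible for small groups).
#'
#' @param dm a [DissimilarityMatrix-class]
#' @param nPerm permutations (ignored when exact)
#' @param seed RNG seed
#' @param exact enumerate all label assignments; NULL (default) chooses
#'   exact when there are at most 10000 assignments
#' @return an [AnosimResult-class]
#' @export
anosimTest <- function(dm, nPerm = 999L, seed = 1L, exact = NULL) {
  g <- factor(groupLabels(dm))
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("each group needs at least two units")
  dv <- as.numeric(dm@d)
  obs <- anosimR(dv, g)
  nAssign <- exp(lfactorial(length(g)) -
                 sum(lfactorial(table(g))))
  if (is.null(exact)) exact <- nAssign <= 10000
  if (exact) {
    perms <- uniquePermutations(as.integer(g))
    rs <- apply(perms, 1, function(p) anosimR(dv, p))
    p <- sum(rs >= obs - 1e-12) / length(rs)
    return(new("AnosimResult", R = obs, p = p, nPerm = 0L, exact = TRUE,
               seed = as.integer(seed)))
  }
  rs <- withSeed(seed, vapply(seq_len(nPerm), function(i)
    anosimR(dv, sample(g)), numeric(1)))
  p <- (1 + sum(rs >= obs - 1e-12)) / (nPerm + 1)
  new("AnosimResult", R = obs, p = p, nPerm = as.integer(nPerm),
      exact = FALSE, seed = as.integer(seed))
}

## All distinct arrangements of a label vector (multiset permutations).
uniquePermutations <- function(labels) {
  n <- length(labels)
  rec <- function(remaining) {
    if (length(remaining) == 1) return(matrix(remaining, 1, 1))
    out <- list()
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      sub <- rec(rest)
      out[[length(out) + 1L]] <- cbind(u, sub)
    }
    do.call(rbind, out)
  }
  m <- rec(sort(labels))
  colnames(m) <- NULL
  m
}

#' SIMPER: per-category contributions to Bray-Curtis structure
#'
#' Between-group: for each category j, the average over cross-group unit
#' pairs of |x_j - y_j| / sum_k(x_k + y_k), expressed as percent of the
#' overall average between-group dissimilarity (contributions sum to
#' 100). Within-group: the analogous typicality decomposition of average
#' Bray-Curtis similarity, using 2 min(x_j, y_j) / sum_k(x_k + y_k).
#'
#' @param cm a [CompositionMatrix-class] with exactly two groups
#' @param transform "none" or "sqrt"
#' @return a [SimperResult-class]; identical groups (zero overall
#'   dissimilarity) give an explicit empty between-table
#' @export
simperAnalysis <- function(cm, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  v <- compValues(cm); g <- groupLabels(cm)
  if (transform == "sqrt") v <- sqrt(v)
  sp <- unique(g)
  stopIfNot(length(sp) == 2, "SIMPER requires exactly two groups")
  stopIfNot(all(table(g) >= 1), "empty group")
  ia <- which(g == sp[1]); ib <- which(g == sp[2])
  categories <- colnames(v)
  ## between-group decomposition
  contrib <- matrix(0, 0, length(categories))
  for (i in ia) for (j in ib) {
    tot <- sum(v[i, ] + v[j, ])
    contrib <- rbind(contrib, abs(v[i, ] - v[j, ]) / tot)
  }
  avg <- colMeans(contrib)
  overall <- sum(avg)
  if (overall <= 0) {
    between <- data.frame(category = character(0), contribution = numeric(0),
                          percent = numeric(0), cumPercent = numeric(0))
  } else {
    o <- order(avg, decreasing = TRUE)
    pct <- 100 * avg[o] / overall
    between <- data.frame(category = categories[o], contribution = avg[o],
                          percent = pct, cumPercent = cumsum(pct),
                          row.names = NULL)
  }
  ## within-group typicality
  within <- list(); withinSim <- numeric(0)
  for (s in sp) {
    ii <- which(g == s)
    if (length(ii) < 2) {
      within[[s]] <- data.frame(category = character(0),
                                contribution = numeric(0),
                                percent = numeric(0))
      withinSim[s] <- NA_real_
      next
    }
    simc <- matrix(0, 0, length(categories))
    for (a in seq_along(ii)[-length(ii)]) for (b in (a + 1):length(ii)) {
      i <- ii[a]; j <- ii[b]
      tot <- sum(v[i, ] + v[j, ])
      simc <- rbind(simc, 2 * pmin(v[i, ], v[j, ]) / tot)
    }
    avgS <- colMeans(simc)
    tot <- sum(avgS)
    o <- order(avgS, decreasing = TRUE)
    within[[s]] <- data.frame(category = categories[o],
                              contribution = avgS[o],
                              percent = if (tot > 0) 100 * avgS[o] / tot else
                                rep(NA_real_, length(o)),
                              row.names = NULL)
    withinSim[s] <- 100 * tot
  }
  new("SimperResult", between = between,
      overallDissimilarity = 100 * overall, within = within,
      withinSimilarity = withinSim)
}

#' Threshold similarity grouping (UPGMA cut)
#'
#' Group-average hierarchical clustering on the dissimilarities, cut at
#' similarity = `thresholdPct` (i.e. height 1 - threshold/100). Used to
#' read claims like "only a single unit of one species falls within the
#' 60% similarity cluster of the other".
#'
#' @param dm a [DissimilarityMatrix-class]
#' @param thresholdPct similarity threshold in percent
#' @return named integer partition (cluster id per unit)
#' @export
similarityGroups <- function(dm, thresholdPct) {
  stopIfNot(thresholdPct >= 0 && thresholdPct <= 100,
            "threshold must be in [0, 100]")
  hc <- stats::hclust(stats::as.dist(dm@d), method = "average")
  part <- stats::cutree(hc, h = 1 - thresholdPct / 100 + 1e-12)
  stats::setNames(part, dm@ids)
}
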