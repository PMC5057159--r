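## Niche overlap, breadth, richness, RA3 null models, combined score.

#' Pianka's niche-overlap index
#'
#' O = sum(p_i q_i) / sqrt(sum(p_i^2) sum(q_i^2)); symmetric, in [0, 1].
#'
#' @param p,q non-negative resource-proportion vectors of equal length,
#'   each summing to 1 (+- 1e-9)
#' @return numeric overlap
#' @export
pianka <- function(p, q) {
  stopIfNot(length(p) == length(q), "vectors must have equal length")
  stopIfNot(all(p >= 0) && all(q >= 0), "proportions must be non-negative")
  stopIfNot(sum(p) > 0 && sum(q) > 0, "zero vector")
  stopIfNot(abs(sum(p) - 1) <= 1e-9 && abs(sum(q) - 1) <= 1e-9,
            "proportion vectors must sum to 1 +- 1e-9")
  sum(p * q) / sqrt(sum(p^2) * sum(q^2))
}

#' Within- and between-group mean Pianka overlap
#'
#' Mean pairwise overlap within each group and across groups. The
#' between-group overlap is reported two ways: the mean over all
#' cross-group unit pairs, and the overlap of the two group-pooled mean
#' proportion profiles (the headline variant).
#'
#' @param cm a [CompositionMatrix-class] (rows are normalized internally)
#' @return list(within = named numeric, betweenPairs, betweenPooled)
#' @export
groupOverlap <- function(cm) {
  overlapCore(rowProportions(compValues(cm)), groupLabels(cm))
}

## Plain-matrix core of groupOverlap; also called once per RA3 iteration.
## Pianka on rows is a normalized cross-product, so all pairs come from
## one matrix product.
overlapCore <- function(v, g) {
  sp <- unique(g)
  norms <- sqrt(rowSums(v^2))
  cross <- (v %*% t(v)) / outer(norms, norms)
  within <- numeric(0)
  for (s in sp) {
    ii <- which(g == s)
    stopIfNot(length(ii) >= 2, paste("need >= 2 units in group", s))
    within[s] <- mean(cross[ii, ii][upper.tri(cross[ii, ii])])
  }
  betweenPairs <- NA_real_; betweenPooled <- NA_real_
  if (length(sp) == 2) {
    ia <- which(g == sp[1]); ib <- which(g == sp[2])
    betweenPairs <- mean(cross[ia, ib])
    pa <- colMeans(v[ia, , drop = FALSE]); pa <- pa / sum(pa)
    pb <- colMeans(v[ib, , drop = FALSE]); pb <- pb / sum(pb)
    betweenPooled <- pianka(pa, pb)
  }
  list(within = within, betweenPairs = betweenPairs,
       betweenPooled = betweenPooled)
}

## The overlap statistics recomputed inside the RA3 loop.
overlapStats <- function(v, g, sp) {
  ov <- overlapCore(v, g)
  out <- c(between_pairs = ov$betweenPairs,
           between_pooled = ov$betweenPooled)
  for (s in sp) out[paste0("within_", s)] <- ov$within[[s]]
  out
}

#' RA3 randomization null model for niche overlap
#'
#' Each iteration independently permutes each row's utilization values
#' across all resource categories - retaining every unit's niche breadth
#' while randomizing which categories it uses - and recomputes the
#' overlap statistics. Tail probabilities use the add-one convention and
#' both tails are reported.
#'
#' @param cm a [CompositionMatrix-class]
#' @param nIter iterations (default 1000)
#' @param seed RNG seed
#' @param keepPermutations store the permuted matrices (small fixtures
#'   only) in `attr(, "permutations")` for invariant checks
#' @return a [NullModelResult-class] with statistics between_pairs,
#'   between_pooled and within_<group>. A single-category matrix is
#'   degenerate: the null equals the observed (flagged with a warning).
#' @export
ra3Null <- function(cm, nIter = 1000L, seed = 1L, keepPermutations = FALSE) {
  v <- rowProportions(compValues(cm))
  g <- groupLabels(cm)
  sp <- unique(g)
  obs <- overlapStats(v, g, sp)
  k <- ncol(v)
  if (k == 1) warning("single category: RA3 null is degenerate")
  perms <- if (keepPermutations) vector("list", nIter)
  null <- withSeed(seed, {
    t(vapply(seq_len(nIter), function(i) {
      vp <- if (k == 1) v else t(apply(v, 1, sample))
      colnames(vp) <- colnames(v); rownames(vp) <- rownames(v)
      if (keepPermutations) perms[[i]] <<- vp
      overlapStats(vp, g, sp)
    }, obs))
  })
  pHigh <- (1 + colSums(null >= rep(obs, each = nIter) - 1e-12)) / (nIter + 1)
  pLow <- (1 + colSums(null <= rep(obs, each = nIter) + 1e-12)) / (nIter + 1)
  out <- new("NullModelResult", statistic = names(obs), observed = obs,
             null = null, pHigh = pHigh, pLow = pLow,
             nIter = as.integer(nIter), seed = as.integer(seed),
             algorithm = "RA3")
  if (keepPermutations) attr(out, "permutations") <- perms
  out
}

#' Levins' niche breadth
#'
#' B = 1 / sum(p_i^2), unstandardized: 1 for a single resource, k for
#' uniform use of k resources.
#'
#' @param p proportion vector summing to 1 (+- 1e-9)
#' @return numeric breadth
#' @export
levinsB <- function(p) {
  stopIfNot(all(p >= 0), "proportions must be non-negative")
  stopIfNot(sum(p) > 0, "zero vector")
  stopIfNot(abs(sum(p) - 1) <= 1e-9, "proportions must sum to 1 +- 1e-9")
  1 / sum(p^2)
}

#' Chao1 richness estimator
#'
#' S_obs + F1^2 / (2 F2) when doubletons are present; the bias-corrected
#' form S_obs + F1 (F1 - 1) / (2 (F2 + 1)) when F2 = 0.
#'
#' @param counts non-negative integer taxon counts
#' @return numeric Chao1 estimate
#' @export
chao1 <- function(counts) {
  stopIfNot(length(counts) > 0, "empty count vector")
  stopIfNot(all(counts >= 0) && all(counts == round(counts)),
            "counts must be non-negative integers")
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1); f2 <- sum(counts == 2)
  if (f2 > 0) sObs + f1^2 / (2 * f2)
  else sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Sample-based Chao1 rarefaction with bootstrap SD
#'
#' For each accumulation level m = 1..n sampling units (nests), Chao1 is
#' computed on the pooled counts of `nBoot` random subsets of m units
#' drawn without replacement; the curve reports mean and SD per m. At
#' m = n there is a single subset, so the mean equals Chao1 of the pooled
#' counts and the SD is 0. Curves of two groups are compared at a common
#' m.
#'
#' @param counts units x taxa count matrix
#' @param nBoot resamples per level (default 1000)
#' @param seed RNG seed
#' @return a [RichnessEstimate-class]
#' @export
rarefyChao1 <- function(counts, nBoot = 1000L, seed = 1L) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  stopIfNot(n >= 2, "need at least two sampling units")
  stopIfNot(nBoot >= 2, "nBoot must be >= 2")
  pooled <- colSums(counts)
  curve <- withSeed(seed, {
    do.call(rbind, lapply(seq_len(n), function(m) {
      vals <- if (m == n) chao1(round(pooled)) else
        vapply(seq_len(nBoot), function(b) {
          sub <- colSums(counts[sample.int(n, m), , drop = FALSE])
          chao1(round(sub))
        }, numeric(1))
      data.frame(m = m, mean = mean(vals),
                 sd = if (length(vals) > 1) stats::sd(vals) else 0)
    }))
  })
  pr <- round(pooled)
  new("RichnessEstimate", sObs = sum(pr > 0), f1 = sum(pr == 1),
      f2 = sum(pr == 2), chao1 = chao1(pr), curve = curve,
      nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Combined multi-axis segregation score
#'
#' The product of per-axis Bray-Curtis similarities (1 - mean
#' between-group dissimilarity per axis). Low products indicate strong
#' combined segregation even when each single axis overlaps
#' substantially.
#'
#' @param similarities named numeric, each in [0, 1], one per axis
#' @return list(raw, rounded, axes); `rounded` is the 2-decimal reporting
#'   value
#' @export
combinedSimilarity <- function(similarities) {
  stopIfNot(all(similarities >= 0 & similarities <= 1),
            "per-axis similarities must be in [0, 1]")
  raw <- prod(similarities)
  list(raw = raw, rounded = round(raw, 2), axes = similarities)
}
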