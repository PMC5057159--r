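test_that("Pianka overlap: hand values, symmetry, scale invariance, errors", {
  expect_equal(pianka(c(.5, .5, 0), c(0, .5, .5)), 0.5, tolerance = 1e-12)
  p <- c(.2, .3, .5); q <- c(.6, .3, .1)
  expect_identical(pianka(p, q), pianka(q, p))
  expect_equal(pianka(p, p), 1, tolerance = 1e-12)
  expect_equal(pianka(c(1, 0), c(0, 1)), 0)
  ## scale invariance before normalization
  r <- c(4, 6, 10); r2 <- r * 7
  expect_equal(pianka(p, r / sum(r)), pianka(p, r2 / sum(r2)),
               tolerance = 1e-12)
  expect_error(pianka(c(0, 0), c(1, 0)), "zero vector|sum to 1")
  expect_error(pianka(c(.5, .6), c(.5, .5)), "sum to 1")
  expect_error(pianka(c(1), c(.5, .5)), "equal length")
})

test_that("group overlap means equal brute-force pair averages", {
  ## identical rows: all means 1
  vid <- matrix(rep(c(.2, .8), each = 4), 4)
  ovId <- groupOverlap(mkCM(vid, rep(c("A", "B"), each = 2),
                            kind = "proportion"))
  expect_equal(unname(ovId$within), c(1, 1), tolerance = 1e-12)
  expect_equal(ovId$betweenPairs, 1, tolerance = 1e-12)
  expect_equal(ovId$betweenPooled, 1, tolerance = 1e-12)

  ## internally identical, mutually disjoint groups
  vd <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  ovD <- groupOverlap(mkCM(vd, rep(c("A", "B"), each = 2)))
  expect_equal(unname(ovD$within), c(1, 1))
  expect_equal(ovD$betweenPairs, 0)

  ## 4-unit fixture vs direct enumeration
  set.seed(12)
  v <- matrix(abs(rnorm(20)), 4); v <- v / rowSums(v)
  g <- c("A", "A", "B", "B")
  ov <- groupOverlap(mkCM(v, g, kind = "proportion"))
  pk <- function(i, j) sum(v[i, ] * v[j, ]) /
    sqrt(sum(v[i, ]^2) * sum(v[j, ]^2))
  expect_equal(ov$within[["A"]], pk(1, 2), tolerance = 1e-12)
  expect_equal(ov$within[["B"]], pk(3, 4), tolerance = 1e-12)
  expect_equal(ov$betweenPairs,
               mean(c(pk(1, 3), pk(1, 4), pk(2, 3), pk(2, 4))),
               tolerance = 1e-12)
})

test_that("RA3 null matches exact enumeration on two-category matrices", {
  ## with 2 categories each row either keeps or swaps its entries; the
  ## null distribution of the between-group pooled overlap must match the
  ## uniform enumeration over all 2^n arrangements
  v <- rbind(c(.8, .2), c(.3, .7), c(.6, .4), c(.1, .9))
  g <- c("A", "A", "B", "B")
  cm <- mkCM(v, g, kind = "proportion")
  res <- ra3Null(cm, nIter = 4000, seed = 3)
  stat <- "between_pooled"
  nullVals <- res@null[, stat]
  ## brute force over 16 keep/swap patterns
  enum <- apply(expand.grid(rep(list(c(FALSE, TRUE)), 4)), 1, function(sw) {
    vp <- v
    for (i in 1:4) if (sw[i]) vp[i, ] <- rev(vp[i, ])
    pa <- colMeans(vp[1:2, ]); pa <- pa / sum(pa)
    pb <- colMeans(vp[3:4, ]); pb <- pb / sum(pb)
    sum(pa * pb) / sqrt(sum(pa^2) * sum(pb^2))
  })
  uv <- sort(unique(round(enum, 12)))
  expect_true(all(round(nullVals, 12) %in% uv))
  ## frequencies agree with the uniform enumeration probabilities
  pEnum <- table(factor(round(enum, 12), levels = uv)) / length(enum)
  pNull <- table(factor(round(nullVals, 12), levels = uv)) / length(nullVals)
  expect_lt(max(abs(pEnum - pNull)), 0.03)

  ## tails satisfy the overlapping convention
  expect_true(all(res@pHigh + res@pLow >= 1))
})

test_that("RA3 permutations preserve each row's Levins breadth", {
  set.seed(9)
  v <- matrix(abs(rnorm(24)), 4); v <- v / rowSums(v)
  cm <- mkCM(v, c("A", "A", "B", "B"), kind = "proportion")
  res <- ra3Null(cm, nIter = 25, seed = 2, keepPermutations = TRUE)
  b0 <- unname(apply(v, 1, levinsB))
  for (vp in attr(res, "permutations"))
    expect_equal(unname(apply(vp, 1, levinsB)), b0, tolerance = 1e-12)
})

test_that("RA3 detects identical rows as excess overlap", {
  v <- matrix(rep(c(.4, .3, .2, .05, .05), 6), 6, byrow = TRUE)
  cm <- mkCM(v, rep(c("A", "B"), each = 3), kind = "proportion")
  res <- suppressWarnings(ra3Null(cm, nIter = 1000, seed = 5))
  expect_equal(res@observed[["between_pooled"]], 1)
  expect_lte(res@pHigh[["between_pooled"]], 0.05)
})

test_that("Levins breadth hand values and bounds", {
  expect_equal(levinsB(rep(1 / 7, 7)), 7, tolerance = 1e-12)
  expect_equal(levinsB(c(1, 0, 0)), 1)
  expect_equal(levinsB(c(.5, .25, .25)), 1 / 0.375, tolerance = 1e-12)
  expect_error(levinsB(c(.5, .6)), "sum to 1")
})

test_that("Chao1 branches and invariants", {
  expect_equal(chao1(c(rep(1, 4), rep(2, 2), rep(7, 4))), 10 + 16 / 4)
  expect_equal(chao1(c(1, 1, 1, 5, 6)), 5 + 3 * 2 / 2)  # F2 = 0 branch
  expect_equal(chao1(c(3, 4, 5)), 3)                    # no singletons
  expect_error(chao1(numeric(0)), "empty")
  expect_error(chao1(c(1.5, 2)), "integers")
  ## Chao1 >= S_obs over random count vectors
  set.seed(20)
  for (i in 1:50) {
    x <- rpois(30, lambda = runif(1, 0.5, 3))
    if (sum(x) == 0) next
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("Chao1 rarefaction endpoints and ordering", {
  set.seed(14)
  counts <- matrix(rpois(10 * 20, 0.8), 10, 20)
  counts[, 1] <- counts[, 1] + 1
  r <- rarefyChao1(counts, nBoot = 100, seed = 4)
  ## at m = n the curve equals pooled Chao1 with zero SD
  last <- r@curve[r@curve$m == 10, ]
  expect_equal(last$mean, chao1(colSums(counts)))
  expect_equal(last$sd, 0)
  expect_equal(r@chao1, chao1(colSums(counts)))
  expect_gte(r@chao1, r@sObs)

  ## duplicated identical nests: flat curve beyond m = 1
  dup <- matrix(rep(c(3, 1, 0, 2), 5), 5, 4, byrow = TRUE)
  rd <- rarefyChao1(dup, nBoot = 50, seed = 6)
  expect_equal(diff(range(rd@curve$mean[-1] - rd@curve$mean[2])), 0)
  expect_error(rarefyChao1(counts, nBoot = 1), "nBoot")

  ## a 60% larger taxon pool yields the higher curve at matched m
  set.seed(15)
  bigPool <- t(replicate(12, rmultinom(1, 30, rep(1 / 48, 48))[, 1]))
  smallPool <- t(replicate(12, rmultinom(1, 30, rep(1 / 30, 30))[, 1]))
  rBig <- rarefyChao1(bigPool, nBoot = 100, seed = 7)
  rSmall <- rarefyChao1(smallPool, nBoot = 100, seed = 7)
  m <- 8
  expect_gt(rBig@curve$mean[m], rSmall@curve$mean[m])
})

test_that("combined similarity score multiplies the axes", {
  res <- combinedSimilarity(c(habitat = 0.50, hours = 0.83, diet = 0.29))
  expect_equal(res$rounded, 0.12)
  expect_equal(res$raw, 0.50 * 0.83 * 0.29, tolerance = 1e-12)
  expect_equal(combinedSimilarity(c(a = 1, b = 0.37))$raw, 0.37)
  expect_equal(combinedSimilarity(c(a = 0, b = 0.9, c = 0.5))$raw, 0)
  expect_error(combinedSimilarity(c(a = 1.2)), "in \\[0, 1\\]")
})
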