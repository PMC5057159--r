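## Utilization distributions, 95% isopleths, UDOI.

## Gaussian KDE evaluated on a grid. Exact per-point evaluation for small
## point sets; for large sets, points are binned to grid cells and the
## count grid is convolved with the (separable) kernel - the binning
## offset is at most half a cell, i.e. <= h/10 at the default resolution.
evalKde <- function(pts, xc, yc, h, exactMax = 2000L) {
  np <- nrow(pts)
  if (np <= exactMax) {
    WY <- outer(yc, pts[, 2], function(a, b) stats::dnorm(a, b, h))
    WX <- outer(xc, pts[, 1], function(a, b) stats::dnorm(a, b, h))
    WY %*% t(WX)
  } else {
    cs <- xc[2] - xc[1]
    ci <- pmin(pmax(round((pts[, 1] - xc[1]) / cs) + 1, 1), length(xc))
    ri <- pmin(pmax(round((pts[, 2] - yc[1]) / cs) + 1, 1), length(yc))
    C <- matrix(0, length(yc), length(xc))
    tab <- table(ri, ci)
    C[cbind(as.integer(rownames(tab))[row(tab)],
            as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
    KY <- outer(yc, yc, function(a, b) stats::dnorm(a, b, h))
    KX <- outer(xc, xc, function(a, b) stats::dnorm(a, b, h))
    KY %*% C %*% KX
  }
}

#' Fixed-bandwidth kernel utilization distribution
#'
#' Isotropic bivariate Gaussian KDE with kernel standard deviation equal
#' to the smoothing factor h, evaluated on a square grid padded at least
#' 4h beyond the point bounding box, and normalized to total mass 1.
#'
#' @param sps a [StandingPointSet-class] or a 2-column coordinate matrix
#' @param h smoothing factor (kernel sigma), m; conventionally one of
#'   250, 500, 1000.
#' @param cellM grid cell side (m); must be <= h/5 (default h/5).
#' @param minPoints QC minimum number of points.
#' @param bbox optional c(xmin, xmax, ymin, ymax) to force a common grid.
#' @return a [UtilizationGrid-class]
#' @export
kdeUD <- function(sps, h = 500, cellM = h / 5, minPoints = 1L, bbox = NULL) {
  pts <- if (is(sps, "StandingPointSet"))
    as.matrix(pointData(sps)[, c("x", "y")]) else as.matrix(sps)
  if (nrow(pts) < minPoints)
    stop("fewer than minPoints (", minPoints, ") points")
  if (cellM > h / 5 + 1e-9) stop("cellM must be <= h/5")
  if (is.null(bbox))
    bbox <- c(min(pts[, 1]) - 4 * h, max(pts[, 1]) + 4 * h,
              min(pts[, 2]) - 4 * h, max(pts[, 2]) + 4 * h)
  xc <- seq(bbox[1], bbox[2], by = cellM)
  yc <- seq(bbox[3], bbox[4], by = cellM)
  dens <- evalKde(pts, xc, yc, h)
  z <- dens / sum(dens)
  new("UtilizationGrid", z = z,
      origin = c(xc[1] - cellM / 2, yc[1] - cellM / 2),
      cellSize = cellM, h = h, points = pts)
}

#' Isopleth region of a utilization distribution
#'
#' Cells are ranked by density; the smallest cell set whose cumulative
#' mass reaches `level` is the region (the 95% region is the operational
#' "foraging area"). Area is cell count times cell area.
#'
#' @param ud a [UtilizationGrid-class]
#' @param level isopleth level in (0, 1), default 0.95
#' @return an [IsoplethRegion-class]
#' @export
isopleth <- function(ud, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- gridValues(ud)
  o <- order(z, decreasing = TRUE)
  k <- which(cumsum(z[o]) >= level)[1]
  ## all cells at or above the k-th density: ties at the threshold are
  ## included, so a uniform UD yields its full support
  thr <- z[o[k]]
  member <- z >= thr * (1 - 1e-9)
  k <- sum(member)
  new("IsoplethRegion", level = level, member = member,
      origin = gridOrigin(ud), cellSize = cellSizeM(ud),
      areaKm2 = k * (cellSizeM(ud) / 1000)^2)
}

## Re-evaluate two UDs on a shared grid covering both point sets.
commonGrid <- function(ud1, ud2, level) {
  h <- max(smoothingH(ud1), smoothingH(ud2))
  cs <- min(cellSizeM(ud1), cellSizeM(ud2))
  p1 <- ud1@points; p2 <- ud2@points
  if (nrow(p1) == 0 || nrow(p2) == 0)
    stop("incompatible grids and no source points for resampling")
  all <- rbind(p1, p2)
  bbox <- c(min(all[, 1]) - 4 * h, max(all[, 1]) + 4 * h,
            min(all[, 2]) - 4 * h, max(all[, 2]) + 4 * h)
  list(a = kdeUD(p1, h = smoothingH(ud1), cellM = cs, bbox = bbox),
       b = kdeUD(p2, h = smoothingH(ud2), cellM = cs, bbox = bbox))
}

sameGrid <- function(a, b) {
  all(dim(gridValues(a)) == dim(gridValues(b))) &&
    all(abs(gridOrigin(a) - gridOrigin(b)) < 1e-6) &&
    abs(cellSizeM(a) - cellSizeM(b)) < 1e-9
}

#' Utilization Distribution Overlap Index
#'
#' UDOI = A_int * sum(UD1 * UD2) / cellArea, where A_int is the area of
#' intersection of the two `level` isopleth regions (m^2) and the sum runs
#' over cell probability masses on a common grid. Zero when the isopleths
#' are disjoint; 1 for identical uniform distributions; values above 1
#' indicate concentrated joint use. UDs on incompatible grids are
#' re-evaluated on a shared grid from their stored source points.
#'
#' @param ud1,ud2 [UtilizationGrid-class] objects
#' @param level isopleth level defining the intersection area
#' @return numeric UDOI value
#' @export
udoi <- function(ud1, ud2, level = 0.95) {
  if (!sameGrid(ud1, ud2)) {
    g <- commonGrid(ud1, ud2, level)
    ud1 <- g$a; ud2 <- g$b
  }
  m1 <- isopleth(ud1, level)@member
  m2 <- isopleth(ud2, level)@member
  inter <- m1 & m2
  if (!any(inter)) return(0)
  cellArea <- cellSizeM(ud1)^2
  aInt <- sum(inter) * cellArea
  aInt * sum(gridValues(ud1) * gridValues(ud2)) / cellArea
}

#' Pairwise UDOI matrix for a set of individuals
#'
#' @param uds named list of [UtilizationGrid-class]
#' @param species named character: species label per individual id
#' @param level isopleth level
#' @return an [OverlapMatrix-class]
#' @export
pairwiseUdoi <- function(uds, species, level = 0.95) {
  ids <- names(uds)
  n <- length(ids)
  v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v[i, j] <- v[j, i] <- udoi(uds[[i]], uds[[j]], level)
  }
  new("OverlapMatrix", ids = ids, values = v,
      groups = unname(species[ids]))
}

#' Compare UDOI between pair groups (within-A, within-B, between)
#'
#' Values are clipped to [0, 1] (UDOI can exceed 1; exceedances are
#' reported), arcsine-square-root transformed, and compared across the
#' three pair groups with a one-way ANOVA followed by Bonferroni-adjusted
#' pairwise t-tests.
#'
#' @param om an [OverlapMatrix-class] with exactly two species
#' @return list with F, df, p, the pairwise p matrix, group means, and
#'   the number of clipped values
#' @export
groupUdoiTest <- function(om) {
  v <- compValues(om); g <- groupLabels(om)
  sp <- unique(g)
  stopIfNot(length(sp) == 2, "exactly two species required")
  n <- nrow(v)
  val <- c(); grp <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    val <- c(val, v[i, j])
    grp <- c(grp, if (g[i] == g[j]) paste0("within_", g[i]) else "between")
  }
  if (any(table(grp) < 2)) stop("each pair group needs >= 2 pairs")
  clipped <- sum(val > 1)
  tv <- asin(sqrt(pmin(pmax(val, 0), 1)))
  grp <- factor(grp)
  if (stats::var(tv) == 0) {
    return(list(F = 0, df = c(nlevels(grp) - 1, length(tv) - nlevels(grp)),
                p = 1, pairwise = NULL,
                groupMeans = tapply(val, grp, mean), clipped = clipped))
  }
  fit <- stats::aov(tv ~ grp)
  an <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(tv, grp, p.adjust.method = "bonferroni")
  list(F = an$`F value`[1], df = an$Df, p = an$`Pr(>F)`[1],
       pairwise = pw$p.value,
       groupMeans = tapply(val, grp, mean), clipped = clipped)
}
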