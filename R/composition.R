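## Composition matrices: habitat use, hourly activity, diet.

## Class code of the raster cell under each point; NA outside the extent.
rasterLookup <- function(raster, x, y) {
  v <- gridValues(raster); cs <- cellSizeM(raster); org <- gridOrigin(raster)
  col <- floor((x - org[1]) / cs) + 1
  row <- floor((y - org[2]) / cs) + 1
  ok <- col >= 1 & col <= ncol(v) & row >= 1 & row <= nrow(v)
  out <- rep(NA_integer_, length(x))
  out[ok] <- v[cbind(row[ok], col[ok])]
  out
}

#' Habitat composition of standing points
#'
#' Per individual, the proportion of standing points over each habitat
#' class, by point-in-cell lookup (no polygon-area weighting). Points
#' outside the raster are dropped and counted in `attr(, "outside")`.
#'
#' @param sets list of [StandingPointSet-class]
#' @param raster a [HabitatRaster-class]
#' @return a proportion [CompositionMatrix-class] (units x classes)
#' @export
habitatComposition <- function(sets, raster) {
  cls <- classNames(raster)
  outside <- integer(0)
  rows <- lapply(sets, function(s) {
    p <- pointData(s)
    code <- rasterLookup(raster, p$x, p$y)
    outside[[individualId(s)]] <<- sum(is.na(code))
    code <- code[!is.na(code)]
    if (!length(code)) stop("all points of ", individualId(s),
                            " fall outside the raster")
    as.numeric(table(factor(code, levels = seq_along(cls))) / length(code))
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(vapply(sets, individualId, ""), cls)
  cm <- new("CompositionMatrix", values = m,
            groups = vapply(sets, speciesLabel, ""), kind = "proportion")
  attr(cm, "outside") <- outside
  cm
}

#' Habitat-class availability
#'
#' Class cell counts divided by total cells, optionally within a logical
#' mask of the same dimensions.
#'
#' @param raster a [HabitatRaster-class]
#' @param mask optional logical matrix selecting cells
#' @return named numeric proportions over classes
#' @export
availability <- function(raster, mask = NULL) {
  v <- gridValues(raster)
  if (!is.null(mask)) {
    stopIfNot(all(dim(mask) == dim(v)), "mask dimensions must match raster")
    v <- v[mask]
    if (!length(v)) stop("empty mask")
  }
  cls <- classNames(raster)
  stats::setNames(as.numeric(table(factor(v, levels = seq_along(cls)))) /
                    length(v), cls)
}

#' Use versus availability: per-category one-sample t-tests
#'
#' For each species and habitat class, a two-sided one-sample t-test of
#' the individual use proportions against the availability constant.
#' Direction is "preference" when mean use exceeds availability,
#' "avoidance" otherwise. Zero-variance rows off the availability value
#' are reported with infinite t and p = 0 (flagged).
#'
#' @param cm a proportion [CompositionMatrix-class]
#' @param avail named availability proportions (same categories)
#' @return data.frame: species, category, meanUse, availability, t, df, p,
#'   direction, degenerate
#' @export
useVsAvailability <- function(cm, avail) {
  v <- compValues(cm); g <- groupLabels(cm)
  stopIfNot(all(colnames(v) %in% names(avail)),
            "availability must cover all categories")
  out <- list()
  for (sp in unique(g)) {
    sub <- v[g == sp, , drop = FALSE]
    if (nrow(sub) < 2) stop("need >= 2 units per group")
    for (cat in colnames(v)) {
      x <- sub[, cat]; mu <- avail[[cat]]
      degen <- stats::sd(x) == 0
      if (degen) {
        tt <- list(statistic = if (mean(x) == mu) 0 else Inf * sign(mean(x) - mu),
                   parameter = length(x) - 1,
                   p.value = if (mean(x) == mu) 1 else 0)
      } else {
        tt <- stats::t.test(x, mu = mu)
      }
      out[[length(out) + 1L]] <- data.frame(
        species = sp, category = cat, meanUse = mean(x), availability = mu,
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value,
        direction = if (mean(x) >= mu) "preference" else "avoidance",
        degenerate = degen)
    }
  }
  do.call(rbind, out)
}

#' Hourly foraging-activity profile of one individual
#'
#' Proportion of in-region fixes per daytime hour bin [h, h+1) for h =
#' 7..18 (covering 07:00-19:00), normalized over the 12 bins. Only
#' high-frequency (5-min) series support this analysis; the fix interval
#' is checked against `maxIntervalMin`.
#'
#' @param fs a [FixSeries-class]
#' @param region an [IsoplethRegion-class] (the individual's foraging
#'   area); NULL to use all fixes
#' @param hours integer bin starts (default 7:18)
#' @param maxIntervalMin reject series sampled less often than this
#' @return named numeric proportion row (one per hour bin)
#' @export
hourlyActivity <- function(fs, region = NULL, hours = 7:18,
                           maxIntervalMin = 30) {
  f <- fixData(fs)
  med <- stats::median(diff(as.numeric(f$timestamp))) / 60
  if (is.finite(med) && med > maxIntervalMin)
    stop("fix interval too coarse for timing analysis: ", individualId(fs))
  if (!is.null(region)) {
    m <- region@member; cs <- cellSizeM(region); org <- gridOrigin(region)
    col <- floor((f$x - org[1]) / cs) + 1
    row <- floor((f$y - org[2]) / cs) + 1
    ok <- col >= 1 & col <= ncol(m) & row >= 1 & row <= nrow(m)
    inReg <- ok
    inReg[ok] <- m[cbind(row[ok], col[ok])]
    f <- f[inReg, , drop = FALSE]
  }
  if (!nrow(f)) stop("no in-region fixes for ", individualId(fs))
  hr <- as.integer(format(f$timestamp, "%H"))
  hr <- hr[hr %in% hours]
  if (!length(hr)) stop("no fixes within the analysis hours")
  cnt <- table(factor(hr, levels = hours))
  stats::setNames(as.numeric(cnt / sum(cnt)), sprintf("h%02d", hours))
}

#' Hourly-activity composition matrix for several individuals
#'
#' @param tracks named list of [FixSeries-class]
#' @param regions optional named list of [IsoplethRegion-class] matching
#'   the track names
#' @param ... passed to [hourlyActivity()]
#' @return a proportion [CompositionMatrix-class]
#' @export
activityMatrix <- function(tracks, regions = NULL, ...) {
  rows <- lapply(names(tracks), function(id)
    hourlyActivity(tracks[[id]], regions[[id]], ...))
  m <- do.call(rbind, rows)
  rownames(m) <- names(tracks)
  new("CompositionMatrix", values = m,
      groups = vapply(tracks, speciesLabel, ""), kind = "proportion")
}

#' Per-nest diet matrix with the minimum-items filter and year averaging
#'
#' Nest-years with fewer than `minDietItems` prey items are excluded
#' (logged); for each retained nest (territory), the value per taxon is
#' the mean count across its retained years, which removes
#' pseudo-replication of territories across seasons. The operation is
#' idempotent.
#'
#' @param diets a [DietTable-class]
#' @param policy a [QCPolicy-class]
#' @return a mean-count [CompositionMatrix-class] (nests x taxa) with the
#'   exclusion log in `attr(, "log")`
#' @export
dietMatrix <- function(diets, policy = qcPolicy()) {
  d <- dietData(diets)
  taxa <- sort(unique(d$taxon))
  totals <- stats::aggregate(count ~ nest_id + year, d, sum)
  bad <- totals[totals$count < policy@minDietItems, ]
  log <- if (nrow(bad)) data.frame(nest = bad$nest_id, year = bad$year,
                                   reason = "lt_min_diet_items")
         else data.frame(nest = character(0), year = integer(0),
                         reason = character(0))
  keep <- merge(d, totals[totals$count >= policy@minDietItems,
                          c("nest_id", "year")])
  if (!nrow(keep)) stop("no nest-years left after the diet filter")
  nests <- sort(unique(keep$nest_id))
  m <- matrix(0, length(nests), length(taxa), dimnames = list(nests, taxa))
  grp <- character(length(nests)); names(grp) <- nests
  for (nid in nests) {
    sub <- keep[keep$nest_id == nid, ]
    yrs <- unique(sub$year)
    tc <- stats::aggregate(count ~ taxon, sub, sum)
    m[nid, tc$taxon] <- tc$count / length(yrs)
    grp[nid] <- sub$species[1]
  }
  cm <- new("CompositionMatrix", values = m, groups = unname(grp),
            kind = "mean_count")
  attr(cm, "log") <- log
  cm
}

#' Convert a count-valued CompositionMatrix to proportions
#' @param cm a [CompositionMatrix-class]
#' @return a proportion [CompositionMatrix-class]
#' @export
asProportions <- function(cm) {
  v <- compValues(cm)
  new("CompositionMatrix", values = rowProportions(v),
      groups = groupLabels(cm), kind = "proportion")
}

#' Prey-category and reptile-subcategory summaries per nest
#'
#' Per nest: the fraction of items in each category (reptile, bird,
#' mammal, arthropod) and, within reptiles, the snake and lizard
#' fractions of the total diet. Two tests mirror the diet contrasts:
#' Welch two-sample t-tests per category between species, and a species x
#' subcategory interaction test on the per-nest paired (lizard - snake)
#' fractions.
#'
#' @param diets a [DietTable-class]
#' @param policy a [QCPolicy-class]
#' @return list(fractions = per-nest data.frame, categoryTests,
#'   subcategoryTest)
#' @export
dietCategorySummary <- function(diets, policy = qcPolicy()) {
  d <- dietData(diets)
  totals <- stats::aggregate(count ~ nest_id + year, d, sum)
  keep <- merge(d, totals[totals$count >= policy@minDietItems,
                          c("nest_id", "year")])
  cats <- c("reptile", "bird", "mammal", "arthropod")
  rows <- list()
  for (nid in sort(unique(keep$nest_id))) {
    sub <- keep[keep$nest_id == nid, ]
    perYear <- lapply(split(sub, sub$year), function(sy) {
      tot <- sum(sy$count)
      c(vapply(cats, function(cc) sum(sy$count[sy$category == cc]) / tot,
               numeric(1)),
        snake = sum(sy$count[sy$subcategory == "snake"]) / tot,
        lizard = sum(sy$count[sy$subcategory == "lizard"]) / tot)
    })
    fr <- colMeans(do.call(rbind, perYear))
    rows[[nid]] <- data.frame(nest_id = nid, species = sub$species[1],
                              t(fr))
  }
  fr <- do.call(rbind, rows)
  sp <- unique(fr$species)
  categoryTests <- NULL
  subcategoryTest <- NULL
  if (length(sp) == 2) {
    categoryTests <- do.call(rbind, lapply(cats, function(cc) {
      tt <- stats::t.test(fr[[cc]] ~ fr$species)
      data.frame(category = cc,
                 mean1 = tt$estimate[1], mean2 = tt$estimate[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, row.names = NULL)
    }))
    diffLS <- fr$lizard - fr$snake
    tt <- stats::t.test(diffLS ~ fr$species)
    subcategoryTest <- data.frame(
      contrast = "lizard_minus_snake",
      mean1 = tt$estimate[1], mean2 = tt$estimate[2],
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
      row.names = NULL)
  }
  list(fractions = fr, categoryTests = categoryTests,
       subcategoryTest = subcategoryTest, speciesOrder = sort(sp))
}
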