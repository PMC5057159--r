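## Synthetic-data generators. Each takes the SimConfig and derives its own
## RNG stream from the master seed, so identical configs give identical
## output.

#' Generate a categorical habitat landscape
#'
#' Cells are drawn iid from the configured class-availability proportions
#' on a square grid in planar meters, so realized class proportions match
#' the configured availability to sampling error.
#'
#' @param config a [SimConfig-class]
#' @return a [HabitatRaster-class]
#' @export
generateLandscape <- function(config) {
  p <- simParams(config)
  av <- p$landscape$availability
  stopIfNot(sum(av > 0) >= 1, "at least one class with positive availability")
  n <- round(p$landscape$extentKm * 1000 / p$landscape$cellM)
  vals <- withSeed(p$seed + 101L, {
    matrix(sample.int(length(av), n * n, replace = TRUE, prob = av), n, n)
  })
  new("HabitatRaster", values = vals, origin = c(0, 0),
      cellSize = p$landscape$cellM, classNames = names(av))
}

## Sequential-inhibition placement: uniform proposals in a disc, rejected
## when closer than dmin to an accepted nest of the same species.
placeNests <- function(n, center, radiusM, dminM) {
  pts <- matrix(NA_real_, n, 2)
  got <- 0L; tries <- 0L
  while (got < n && tries < n * 2000L) {
    tries <- tries + 1L
    r <- radiusM * sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
    cand <- center + r * c(cos(a), sin(a))
    if (got == 0L ||
        min(sqrt(colSums((t(pts[seq_len(got), , drop = FALSE]) - cand)^2))) >= dminM) {
      got <- got + 1L
      pts[got, ] <- cand
    }
  }
  if (got < n) stop("could not place nests at the requested spacing")
  pts
}

#' Generate nest locations for both species
#'
#' Territories cluster in a central breeding area; each territory is
#' observed in a subset of the configured years. The first
#' `nTagged` territories of each species belong to the GPS-tagged
#' individuals (tracked in `trackYear`); of these, only the first
#' `nAnalyzable` reach the chick-rearing phase.
#'
#' @param config a [SimConfig-class]
#' @param landscape a [HabitatRaster-class] (nests must fall inside it)
#' @return a [NestSet-class]
#' @export
generateNests <- function(config, landscape) {
  p <- simParams(config)
  ext <- p$landscape$extentKm * 1000
  center <- c(ext / 2, ext / 2)
  rows <- withSeed(p$seed + 202L, {
    out <- list()
    for (sp in names(p$species)) {
      s <- p$species[[sp]]
      xy <- placeNests(s$nTerritories, center, p$breedingRadiusKm * 1000,
                       s$nestMinSpacingKm * 1000)
      sampleYears <- function(yrs) {
        if (length(yrs) == 1) return(yrs)
        sample(yrs, sample(seq_along(yrs), 1))
      }
      for (i in seq_len(s$nTerritories)) {
        tagged <- i <= s$nTagged
        yrs <- if (tagged) unique(c(p$trackYear, sampleYears(p$years)))
               else sampleYears(p$years)
        ok <- if (tagged) i <= s$nAnalyzable else stats::runif(1) > 0.1
        for (yr in sort(yrs)) {
          out[[length(out) + 1L]] <- data.frame(
            nest_id = sprintf("%s_%03d", sp, i), species = sp,
            year = as.integer(yr), x = xy[i, 1], y = xy[i, 2],
            reached_chick_rearing = ok)
        }
      }
    }
    do.call(rbind, out)
  })
  stopIfNot(all(rows$x >= 0 & rows$x <= ext & rows$y >= 0 & rows$y <= ext),
            "nests must lie inside the landscape")
  ll <- unprojectXY(rows$x - ext / 2, rows$y - ext / 2, p$originLonLat)
  rows$lon <- ll[, "lon"]; rows$lat <- ll[, "lat"]
  new("NestSet", nests = rows[, c("nest_id", "species", "year", "lon", "lat",
                                  "x", "y", "reached_chick_rearing")])
}

## Truncated-normal draw via rejection (vectorized, cheap at these sizes).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

## Intended forage-bout midpoints (minutes of day) under the configured
## diel mode; trip departures are back-computed from these so the realized
## foraging-time distribution follows the mode.
drawBoutMidpoints <- function(n, s, dutyStartMin, dutyEndMin) {
  if (n == 0L) return(numeric(0))
  if (identical(s$dielMode, "midday")) {
    sort(rtruncnorm(n, s$peakHour * 60, s$peakSdH * 60,
                    dutyStartMin, dutyEndMin - 30))
  } else {
    sort(stats::runif(n, dutyStartMin, dutyEndMin - 30))
  }
}

hmToMin <- function(hm) {
  v <- as.integer(strsplit(hm, ":")[[1]])
  v[1] * 60 + v[2]
}

## Per-class cell lookup near a patch, for habitat-preference placement.
## Only the few cells of each class closest to the patch center are used,
## so each class's foraging points stay concentrated (foraging patches are
## dense by construction; the corridor filter must not thin them).
patchHabitatLookup <- function(landscape, center, radii = c(500, 1500),
                               maxCells = 3L) {
  vals <- gridValues(landscape); cs <- cellSizeM(landscape)
  org <- gridOrigin(landscape)
  out <- vector("list", max(vals))
  for (rad in radii) {
    cmin <- pmax(1, floor((center - rad - org) / cs) + 1)
    cmax <- pmin(dim(vals)[c(2, 1)], floor((center + rad - org) / cs) + 1)
    if (any(cmin > cmax)) next
    cols <- cmin[1]:cmax[1]; rows <- cmin[2]:cmax[2]
    sub <- vals[rows, cols, drop = FALSE]
    for (cl in seq_along(out)) {
      if (!is.null(out[[cl]])) next
      hit <- which(sub == cl, arr.ind = TRUE)
      if (nrow(hit)) {
        xy <- cbind(x = org[1] + (cols[hit[, 2]] - 0.5) * cs,
                    y = org[2] + (rows[hit[, 1]] - 0.5) * cs)
        d2 <- (xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2
        out[[cl]] <- xy[order(d2)[seq_len(min(nrow(xy), maxCells))], ,
                        drop = FALSE]
      }
    }
    if (!any(vapply(out, is.null, TRUE))) break
  }
  out
}

## Simulate one individual's full season. Returns the fix data.frame.
simulateIndividual <- function(s, nest, landscape, year, seed, interval,
                               dutyStartMin, dutyEndMin, patchPool = NULL) {
  ext <- dim(gridValues(landscape))[1] * cellSizeM(landscape)
  withSeed(seed, {
    ## foraging patches: either drawn around the own nest (direction
    ## uniform, distance ~ trunc normal) or sampled from the species'
    ## shared patch pool (commuting species converging on common areas)
    minD <- max(300, s$nestRadiusKm * 1500)
    if (!is.null(patchPool)) {
      idx <- sample.int(nrow(patchPool), s$nPatches,
                        replace = nrow(patchPool) < s$nPatches)
      patches <- patchPool[idx, , drop = FALSE]
    } else {
      patches <- matrix(NA_real_, s$nPatches, 2)
      for (j in seq_len(s$nPatches)) {
        repeat {
          d <- rtruncnorm(1, s$nestDistKm * 1000, s$nestDistSdKm * 1000,
                          lower = minD)
          a <- stats::runif(1, 0, 2 * pi)
          cand <- nest + d * c(cos(a), sin(a))
          if (all(cand > 500) && all(cand < ext - 500)) break
        }
        patches[j, ] <- cand
      }
    }
    lookups <- lapply(seq_len(s$nPatches), function(j)
      patchHabitatLookup(landscape, patches[j, ]))
    useProb <- s$habitatUse[classNames(landscape)]
    useProb[is.na(useProb)] <- 0
    stopIfNot(sum(useProb) > 0,
              "habitatUse classes must match the landscape classes")

    days <- seq(as.Date(sprintf("%d-%s", year, s$seasonStart)),
                as.Date(sprintf("%d-%s", year, s$seasonEnd)), by = "day")
    fixMin <- seq(dutyStartMin, dutyEndMin, by = interval)
    nf <- length(fixMin)
    res <- vector("list", length(days))
    for (di in seq_along(days)) {
      nTrips <- if (s$tripsPerDay > 0) max(0L, stats::rpois(1, s$tripsPerDay)) else 0L
      mids <- drawBoutMidpoints(nTrips, s, dutyStartMin, dutyEndMin)
      state <- rep("nest", nf)
      px <- rep(nest[1], nf); py <- rep(nest[2], nf)
      tCur <- dutyStartMin
      for (tr in seq_len(nTrips)) {
        j <- sample.int(s$nPatches, 1)
        d <- sqrt(sum((patches[j, ] - nest)^2))
        commute <- d / s$transitSpeed[["mean"]] / 60
        bout <- if (s$forageBoutMin[["mean"]] > 0)
          max(0, stats::rnorm(1, s$forageBoutMin[["mean"]], s$forageBoutMin[["sd"]]))
          else 0
        t0 <- max(mids[tr] - commute - bout / 2, tCur, dutyStartMin)
        if (t0 >= dutyEndMin) break
        tOut <- t0 + commute; tEnd <- tOut + bout; tHome <- tEnd + commute
        io <- fixMin >= t0 & fixMin < tOut
        frac <- (fixMin[io] - t0) / commute
        px[io] <- nest[1] + frac * (patches[j, 1] - nest[1])
        py[io] <- nest[2] + frac * (patches[j, 2] - nest[2])
        state[io] <- "transit"
        ifo <- fixMin >= tOut & fixMin < tEnd
        if (any(ifo)) {
          k <- sum(ifo)
          cls <- sample.int(length(useProb), k, replace = TRUE, prob = useProb)
          for (q in seq_len(k)) {
            cand <- lookups[[j]][[cls[q]]]
            idx <- which(ifo)[q]
            if (is.null(cand)) {        # class absent near patch: stay at patch
              ang <- stats::runif(1, 0, 2 * pi)
              rr <- s$patchRadiusM * sqrt(stats::runif(1))
              px[idx] <- patches[j, 1] + rr * cos(ang)
              py[idx] <- patches[j, 2] + rr * sin(ang)
            } else {
              ci <- sample.int(nrow(cand), 1)
              cs <- cellSizeM(landscape)
              px[idx] <- cand[ci, 1] + stats::runif(1, -cs / 2, cs / 2)
              py[idx] <- cand[ci, 2] + stats::runif(1, -cs / 2, cs / 2)
            }
          }
          state[ifo] <- "forage"
        }
        ih <- fixMin >= tEnd & fixMin < tHome
        frac <- (fixMin[ih] - tEnd) / commute
        px[ih] <- patches[j, 1] + frac * (nest[1] - patches[j, 1])
        py[ih] <- patches[j, 2] + frac * (nest[2] - patches[j, 2])
        state[ih] <- "transit"
        tCur <- tHome
      }
      ## corridor noise and occasional slow pauses during transit
      it <- state == "transit"
      if (any(it)) {
        px[it] <- px[it] + stats::rnorm(sum(it), 0, 100)
        py[it] <- py[it] + stats::rnorm(sum(it), 0, 100)
        pause <- it & stats::runif(nf) < s$pauseProb
        state[pause] <- "transit_pause"
      }
      inest <- state == "nest"
      px[inest] <- px[inest] + stats::rnorm(sum(inest), 0, 20)
      py[inest] <- py[inest] + stats::rnorm(sum(inest), 0, 20)

      ## tag-reported ground speed per behavioural state; the generator
      ## keeps the two modes strictly either side of the 4 m/s threshold
      speed <- numeric(nf)
      speed[state == "transit"] <- rtruncnorm(sum(state == "transit"),
        s$transitSpeed[["mean"]], s$transitSpeed[["sd"]], lower = 4.2)
      slow <- state != "transit"
      sMean <- ifelse(state[slow] == "forage", s$forageSpeed[["mean"]], 0.4)
      speed[slow] <- abs(stats::rnorm(sum(slow), sMean,
                                      s$forageSpeed[["sd"]]))
      speed[slow] <- pmin(speed[slow], 3.9)
      res[[di]] <- data.frame(
        timestamp = as.POSIXct(days[di], tz = "UTC") + fixMin * 60,
        x = px, y = py, speed = speed,
        heading = stats::runif(nf, 0, 360), state = state)
    }
    do.call(rbind, res)
  })
}

#' Simulate GPS tracks for all tagged individuals
#'
#' Two-state (transit/forage) central-place movement: each individual
#' commutes from its nest to a small set of foraging patches in straight
#' "corridors" at transit speed (>= 4 m/s as reported by the tag) and
#' forages at low speed (< 4 m/s) inside the patches; idle time is spent
#' at the nest. Fixes are emitted only within the duty cycle at the
#' species' configured interval. Ground speed is written into the fix
#' record as a tag would report it (not derived from displacement). The
#' `state` column carries the generator's true behavioural state.
#'
#' @param config a [SimConfig-class]
#' @param nests a [NestSet-class] from [generateNests()]
#' @param landscape a [HabitatRaster-class]
#' @return named list of [FixSeries-class], one per tagged individual
#' @export
generateTracks <- function(config, nests, landscape) {
  p <- simParams(config)
  nd <- nestData(nests)
  ext <- dim(gridValues(landscape))[1] * cellSizeM(landscape)
  dutyStartMin <- hmToMin(p$dutyStart); dutyEndMin <- hmToMin(p$dutyEnd)
  out <- list()
  for (sp in names(p$species)) {
    s <- p$species[[sp]]
    nReg <- round(s$regularTagFrac * s$nTagged)
    ## shared patch pool: common foraging areas the species converges on,
    ## placed around the breeding-area center
    pool <- NULL
    if (!is.null(s$patchPool) && s$patchPool > 0) {
      center <- rep(ext / 2, 2)
      pool <- withSeed(p$seed + 555L * match(sp, names(p$species)), {
        m <- matrix(NA_real_, s$patchPool, 2)
        for (j in seq_len(s$patchPool)) {
          repeat {
            d <- rtruncnorm(1, s$nestDistKm * 1000, s$nestDistSdKm * 1000,
                            lower = max(300, s$nestRadiusKm * 1500))
            a <- stats::runif(1, 0, 2 * pi)
            cand <- center + d * c(cos(a), sin(a))
            if (all(cand > 500) && all(cand < ext - 500)) break
          }
          m[j, ] <- cand
        }
        m
      })
    }
    for (i in seq_len(s$nTagged)) {
      id <- sprintf("%s_%03d", sp, i)
      nrow_i <- nd[nd$nest_id == id & nd$year == p$trackYear, ]
      stopIfNot(nrow(nrow_i) == 1, sprintf("no nest for individual %s", id))
      nest <- c(nrow_i$x, nrow_i$y)
      stopIfNot(all(nest >= 0 & nest <= ext), "nest outside landscape")
      ## the last nReg tagged individuals carry regular (90-min) tags
      interval <- if (i > s$nTagged - nReg) 90 else s$fixIntervalMin
      fx <- simulateIndividual(s, nest, landscape, p$trackYear,
                               p$seed + 977L * match(sp, names(p$species)) + i,
                               interval, dutyStartMin, dutyEndMin,
                               patchPool = pool)
      ll <- unprojectXY(fx$x - ext / 2, fx$y - ext / 2, p$originLonLat)
      fx$lon <- ll[, "lon"]; fx$lat <- ll[, "lat"]
      out[[id]] <- new("FixSeries", individualId = id, species = sp,
                       fixes = fx[, c("timestamp", "lon", "lat", "speed",
                                      "heading", "x", "y", "state")])
    }
  }
  out
}

#' Simulate per-nest diet tables
#'
#' Each observed nest-year receives a multinomial draw of prey items from
#' its species' taxon probability vector; item totals are Poisson around
#' the species mean, and a configurable fraction of nest-years is forced
#' below 8 items to exercise the diet filter downstream. Category and
#' subcategory labels are joined from the taxonomy; a taxon missing from
#' the metadata is an error.
#'
#' @param config a [SimConfig-class]
#' @param nests a [NestSet-class]
#' @return a [DietTable-class]
#' @export
generateDiets <- function(config, nests) {
  p <- simParams(config)
  nd <- nestData(nests)
  tax <- p$taxonomy
  rows <- withSeed(p$seed + 404L, {
    out <- list()
    for (r in seq_len(nrow(nd))) {
      s <- p$species[[nd$species[r]]]
      stopIfNot(!is.null(s), "nest species missing from config")
      nItems <- if (stats::runif(1) < s$smallNestFrac) sample(1:7, 1)
                else max(1L, stats::rpois(1, s$itemsPerNestMean))
      cnt <- stats::rmultinom(1, nItems, s$dietProbs)[, 1]
      keep <- which(cnt > 0)
      if (!length(keep)) next
      taxon <- names(s$dietProbs)[keep]
      mi <- match(taxon, tax$taxon)
      if (anyNA(mi)) stop("taxon missing from metadata: ",
                          paste(taxon[is.na(mi)], collapse = ", "))
      out[[length(out) + 1L]] <- data.frame(
        nest_id = nd$nest_id[r], species = nd$species[r],
        year = nd$year[r], taxon = taxon, count = cnt[keep],
        category = tax$category[mi], subcategory = tax$subcategory[mi])
    }
    do.call(rbind, out)
  })
  new("DietTable", data = rows)
}

#' Generate the complete synthetic scenario
#'
#' Convenience wrapper: landscape, nests, tracks and diets from one
#' config.
#'
#' @param config a [SimConfig-class]
#' @return list with elements landscape, nests, tracks, diets, config
#' @export
generateScenario <- function(config) {
  landscape <- generateLandscape(config)
  nests <- generateNests(config, landscape)
  tracks <- generateTracks(config, nests, landscape)
  diets <- generateDiets(config, nests)
  list(landscape = landscape, nests = nests, tracks = tracks,
       diets = diets, config = config)
}
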