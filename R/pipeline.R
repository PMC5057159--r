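## Full-pipeline orchestration: one call runs every stage on a synthetic
## scenario (or user-supplied inputs) and emits the report tables.

pipelineOptions <- function(hSet = c(250, 500, 1000), level = 0.95,
                            nIter = 1000L, kmeansK = 5L,
                            attraction = list(enabled = TRUE, nPerm = 199L,
                                              maxFixes = 2000L,
                                              meetDistM = 500,
                                              timeTolS = 150)) {
  list(hSet = hSet, level = level, nIter = as.integer(nIter),
       kmeansK = as.integer(kmeansK), attraction = attraction)
}

## Thin a track to at most maxFixes by regular subsampling (pipeline-scale
## control for the dyadic permutation tests).
thinTrack <- function(fs, maxFixes) {
  f <- fixData(fs)
  if (nrow(f) <= maxFixes) return(fs)
  idx <- unique(round(seq(1, nrow(f), length.out = maxFixes)))
  initialize(fs, fixes = f[idx, , drop = FALSE])
}

speciesSeason <- function(cfg, sp) {
  c(start = cfg$species[[sp]]$seasonStart, end = cfg$species[[sp]]$seasonEnd)
}

#' Run the full four-axis niche-partitioning analysis
#'
#' Orchestrates every stage on a synthetic scenario: track processing
#' (speed rule, nest-vicinity and corridor filters, QC), space use (KDE
#' utilization distributions, 95% isopleth areas at each smoothing
#' factor, pairwise UDOI and the pair-group test), interaction (k-means
#' foraging clusters, dyadic attraction indices), composition (habitat
#' use vs availability, hourly activity, diet matrices), community
#' statistics (Bray-Curtis, nMDS, ANOSIM, SIMPER) and niche metrics
#' (Pianka overlap with RA3 nulls, Levins breadth, Chao1 rarefaction),
#' and the combined multiplicative segregation score. Writes table1.csv,
#' table2.csv, overlap_report.csv, nullmodel_report.csv, diet_report.csv,
#' interaction_matrix.csv and manifest.json into `outDir`. Deterministic
#' given the config (which carries the seed).
#'
#' @param config a [SimConfig-class]
#' @param outDir output directory (created if needed)
#' @param policy a [QCPolicy-class]
#' @param options see `pipelineOptions` defaults: smoothing factors
#'   250/500/1000 m, 95% isopleths, 1000 null iterations, k = 5 clusters
#' @return (invisibly) a list with every intermediate and final result
#' @export
runAll <- function(config, outDir, policy = NULL, options = pipelineOptions()) {
  cfg <- simParams(config)
  if (is.null(policy)) {
    radii <- vapply(cfg$species, function(s) s$nestRadiusKm, numeric(1))
    policy <- qcPolicy(nestRadiusKm = radii, sharedStart = cfg$sharedStart,
                       sharedEnd = cfg$sharedEnd)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  scen <- generateScenario(config)
  tracks <- scen$tracks; nests <- scen$nests; landscape <- scen$landscape
  nd <- nestData(nests)
  spNames <- names(cfg$species)

  ## ---- trajectory processing, with per-stage count bookkeeping -------
  stageCounts <- list()
  sets <- list(whole = list(), shared = list())
  for (id in names(tracks)) {
    fs <- tracks[[id]]
    sp <- speciesLabel(fs)
    nestRow <- nd[nd$nest_id == id & nd$year == cfg$trackYear, ]
    nest <- c(nestRow$x, nestRow$y)
    sea <- speciesSeason(cfg, sp)
    for (win in c("whole", "shared")) {
      n0 <- nrow(fixData(fs))
      fsw <- seasonWindow(fs, win, policy, start = sea["start"],
                          end = sea["end"])
      n1 <- nrow(fixData(fsw))
      sps <- classifyStandingPoints(fsw, policy, window = win)
      n2 <- nrow(pointData(sps))
      sps <- excludeNestVicinity(sps, nest, policy)
      n3 <- nrow(pointData(sps))
      sps <- densityFilter(sps, policy@densityCellM, policy@densityQuantile)
      n4 <- nrow(pointData(sps))
      sets[[win]][[id]] <- sps
      stageCounts[[paste(id, win, sep = ":")]] <- data.frame(
        individual = id, window = win, fixes = n0, in_season = n1,
        standing = n2, after_nest_vicinity = n3, after_density = n4)
    }
  }
  qcWhole <- qcFilter(sets$whole, nests, policy)
  qcShared <- qcFilter(sets$shared, nests, policy)
  eligWhole <- qcWhole$eligible; eligShared <- qcShared$eligible
  names(eligWhole) <- vapply(eligWhole, individualId, "")
  names(eligShared) <- vapply(eligShared, individualId, "")
  ## analysis proceeds on individuals eligible in both windows
  ids <- intersect(names(eligWhole), names(eligShared))
  speciesOf <- vapply(ids, function(id) speciesLabel(tracks[[id]]), "")

  ## ---- space use ------------------------------------------------------
  distKm <- vapply(ids, function(id) {
    nr <- nd[nd$nest_id == id & nd$year == cfg$trackYear, ]
    meanDistanceToNest(eligWhole[[id]], c(nr$x, nr$y))
  }, numeric(1))

  areas <- list()
  for (win in c("whole", "shared")) {
    el <- if (win == "whole") eligWhole else eligShared
    for (h in options$hSet) {
      a <- vapply(ids, function(id)
        areaKm2(isopleth(kdeUD(el[[id]], h = h), options$level)),
        numeric(1))
      areas[[paste(win, h, sep = "_")]] <- a
    }
  }

  table1 <- do.call(rbind, lapply(spNames, function(sp) {
    sel <- speciesOf == sp
    row <- data.frame(species = sp, n = sum(sel),
                      dist_mean_km = meanSe(distKm[sel])["mean"],
                      dist_se_km = meanSe(distKm[sel])["se"])
    for (win in c("whole", "shared")) for (h in options$hSet) {
      a <- areas[[paste(win, h, sep = "_")]][sel]
      row[[sprintf("area_%s_h%d_mean", win, h)]] <- meanSe(a)["mean"]
      row[[sprintf("area_%s_h%d_se", win, h)]] <- meanSe(a)["se"]
    }
    row
  }))

  udsShared <- lapply(ids, function(id) kdeUD(eligShared[[id]], h = 500))
  names(udsShared) <- ids
  om <- pairwiseUdoi(udsShared, speciesOf, options$level)
  udoiTest <- tryCatch(groupUdoiTest(om), error = function(e) NULL)

  ## ---- interaction ----------------------------------------------------
  pooled <- do.call(rbind, lapply(ids, function(id) {
    p <- pointData(eligShared[[id]])
    data.frame(x = p$x, y = p$y, species = unname(speciesOf[id]),
               row.names = NULL)
  }))
  clusters <- kmeansClusters(pooled, pooled$species, k = options$kmeansK,
                             seed = cfg$seed + 11L)

  attMat <- NULL
  if (isTRUE(options$attraction$enabled) && length(ids) >= 2) {
    attMat <- matrix(NA_real_, length(ids), length(ids),
                     dimnames = list(ids, ids))
    thin <- lapply(tracks[ids], thinTrack,
                   maxFixes = options$attraction$maxFixes)
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      ar <- attractionIndex(thin[[i]], thin[[j]],
                            meetDistM = options$attraction$meetDistM,
                            timeTolS = options$attraction$timeTolS,
                            nPerm = options$attraction$nPerm,
                            seed = cfg$seed + 100L * i + j)
      attMat[i, j] <- attMat[j, i] <- attractionValue(ar)
    }
  }

  ## ---- composition ----------------------------------------------------
  habitat <- habitatComposition(eligShared[ids], landscape)
  avail <- availability(landscape)
  useAvail <- useVsAvailability(habitat, avail)

  ## timing: high-frequency individuals only, fixes inside their own
  ## foraging area
  hf <- ids[vapply(ids, function(id) {
    f <- fixData(tracks[[id]])
    stats::median(diff(as.numeric(f$timestamp))) / 60 <= 30
  }, logical(1))]
  regions <- lapply(hf, function(id)
    isopleth(udsShared[[id]], options$level))
  names(regions) <- hf
  timing <- activityMatrix(tracks[hf], regions)
  timingOk <- all(table(groupLabels(timing)) >= 2) &&
    length(unique(groupLabels(timing))) == 2

  diet <- dietMatrix(scen$diets, policy)
  dietProp <- asProportions(diet)
  dietCats <- dietCategorySummary(scen$diets, policy)

  ## ---- multivariate + niche metrics per axis --------------------------
  axes <- list(habitat = habitat, diet = dietProp)
  if (timingOk) axes$timing <- timing
  axisStats <- list(); simAxis <- c()
  for (ax in names(axes)) {
    cm <- axes[[ax]]
    dm <- brayCurtis(cm)
    an <- anosimTest(dm, nPerm = 999L, seed = cfg$seed + 7L)
    sim <- simperAnalysis(cm)
    ord <- tryCatch(nmdsOrdination(dm, seed = cfg$seed + 5L),
                    error = function(e) NULL)
    ov <- groupOverlap(cm)
    nm <- ra3Null(cm, nIter = options$nIter, seed = cfg$seed + 13L)
    ## per-axis similarity: 1 - mean between-group Bray-Curtis
    g <- groupLabels(dm)
    dmat <- as.matrix(dm@d)
    betw <- dmat[g == spNames[1], g == spNames[2]]
    simAxis[ax] <- 1 - mean(betw)
    axisStats[[ax]] <- list(dissimilarity = dm, anosim = an, simper = sim,
                            nmds = ord, overlap = ov, nullModel = nm)
  }
  combined <- combinedSimilarity(simAxis)

  ## ---- richness / breadth ---------------------------------------------
  dv <- compValues(diet); dg <- groupLabels(diet)
  richness <- list(); breadth <- c()
  for (sp in spNames) {
    sub <- dv[dg == sp, , drop = FALSE]
    richness[[sp]] <- rarefyChao1(sub, nBoot = 200L, seed = cfg$seed + 17L)
    pool <- colSums(sub); breadth[sp] <- levinsB(pool / sum(pool))
  }

  ## ---- reports ---------------------------------------------------------
  writeReports(outDir, cfg, policy, table1, om, udoiTest, clusters, attMat,
               useAvail, axisStats, simAxis, combined, richness, breadth,
               dietCats, stageCounts, qcWhole$log, qcShared$log, distKm,
               speciesOf)

  invisible(list(scenario = scen, sets = sets,
                 eligible = list(whole = eligWhole, shared = eligShared),
                 table1 = table1, distances = distKm, areas = areas,
                 overlapMatrix = om, udoiTest = udoiTest,
                 clusters = clusters, attraction = attMat,
                 habitat = habitat, availability = avail,
                 useVsAvailability = useAvail, timing = if (timingOk) timing,
                 diet = diet, dietCategories = dietCats,
                 axisStats = axisStats, axisSimilarity = simAxis,
                 combined = combined, richness = richness,
                 breadth = breadth, outDir = outDir))
}

#' Distance and area ratios from a species summary table
#'
#' Given a two-species table in the layout written by [runAll()]
#' (`table1.csv`: per-species mean nest distance and mean 95% foraging
#' area at each smoothing factor and season window), computes the
#' commuting/near-nest ratios - the larger species mean over the smaller -
#' rounded to 1 decimal: one distance ratio and one area ratio per
#' window x smoothing factor.
#'
#' @param table1 data.frame with columns species, dist_mean_km and
#'   area_<window>_h<h>_mean
#' @return list(distanceRatio, areaRatios = named numeric)
#' @export
tableRatios <- function(table1) {
  stopIfNot(nrow(table1) == 2, "expected exactly two species rows")
  hi <- which.max(table1$dist_mean_km); lo <- 3 - hi
  distanceRatio <- round(table1$dist_mean_km[hi] / table1$dist_mean_km[lo], 1)
  areaCols <- grep("^area_.*_mean$", names(table1), value = TRUE)
  areaRatios <- vapply(areaCols, function(cc)
    round(table1[[cc]][hi] / table1[[cc]][lo], 1), numeric(1))
  names(areaRatios) <- sub("^area_(.*)_mean$", "\\1", areaCols)
  list(distanceRatio = distanceRatio, areaRatios = areaRatios)
}

tagLog <- function(win, lg) {
  if (nrow(lg)) return(cbind(window = win, lg))
  data.frame(window = character(0), individual = character(0),
             year = integer(0), reason = character(0))
}

writeReports <- function(outDir, cfg, policy, table1, om, udoiTest, clusters,
                         attMat, useAvail, axisStats, simAxis, combined,
                         richness, breadth, dietCats, stageCounts, logWhole,
                         logShared, distKm, speciesOf) {
  pth <- function(f) file.path(outDir, f)
  utils::write.csv(table1, pth("table1.csv"), row.names = FALSE)

  ## qualitative four-axis summary (structure of the published summary
  ## table), derived from the computed quantities
  spNames <- names(cfg$species)
  dBar <- tapply(distKm, speciesOf, mean)
  nearSp <- names(which.min(dBar))
  prefer <- function(sp) {
    ua <- useAvail[useAvail$species == sp & useAvail$direction == "preference", ]
    if (!nrow(ua)) return("none")
    ua$category[which.max(ua$meanUse - ua$availability)]
  }
  table2 <- do.call(rbind, lapply(spNames, function(sp) {
    data.frame(species = sp,
               foraging_area = sprintf("mean nest distance %.2f km (%s)",
                                       dBar[[sp]],
                                       if (sp == nearSp) "near-nest" else "commuting"),
               habitat = sprintf("prefers %s", prefer(sp)),
               diet_breadth = sprintf("Levins B = %.1f, Chao1 = %.1f",
                                      breadth[[sp]], richness[[sp]]@chao1))
  }))
  utils::write.csv(table2, pth("table2.csv"), row.names = FALSE)

  ## overlap report: UDOI group means + per-axis Pianka
  ovRows <- list()
  if (!is.null(udoiTest)) {
    gm <- udoiTest$groupMeans
    for (nm in names(gm))
      ovRows[[length(ovRows) + 1L]] <- data.frame(
        axis = "space_udoi", statistic = nm, observed = gm[[nm]],
        p_high = NA, p_low = NA)
    ovRows[[length(ovRows) + 1L]] <- data.frame(
      axis = "space_udoi", statistic = "anova_F", observed = udoiTest$F,
      p_high = udoiTest$p, p_low = NA)
  }
  for (ax in names(axisStats)) {
    nm <- axisStats[[ax]]$nullModel
    for (s in names(nm@observed))
      ovRows[[length(ovRows) + 1L]] <- data.frame(
        axis = ax, statistic = s, observed = nm@observed[[s]],
        p_high = nm@pHigh[[s]], p_low = nm@pLow[[s]])
  }
  utils::write.csv(do.call(rbind, ovRows), pth("overlap_report.csv"),
                   row.names = FALSE)

  nmRows <- do.call(rbind, lapply(names(axisStats), function(ax) {
    an <- axisStats[[ax]]$anosim
    data.frame(axis = ax, anosim_R = an@R, anosim_p = an@p,
               nmds_stress = if (!is.null(axisStats[[ax]]$nmds))
                 axisStats[[ax]]$nmds$stress else NA,
               similarity = simAxis[[ax]])
  }))
  nmRows <- rbind(nmRows, data.frame(axis = "combined", anosim_R = NA,
                                     anosim_p = NA, nmds_stress = NA,
                                     similarity = combined$rounded))
  utils::write.csv(nmRows, pth("nullmodel_report.csv"), row.names = FALSE)

  dietRows <- do.call(rbind, lapply(names(richness), function(sp) {
    r <- richness[[sp]]
    data.frame(species = sp, s_obs = r@sObs, chao1 = r@chao1,
               levins_B = breadth[[sp]])
  }))
  utils::write.csv(dietRows, pth("diet_report.csv"), row.names = FALSE)

  if (!is.null(attMat)) {
    utils::write.csv(as.data.frame(attMat), pth("interaction_matrix.csv"),
                     row.names = TRUE)
  } else {
    utils::write.csv(as.data.frame(clusters@composition),
                     pth("interaction_matrix.csv"), row.names = TRUE)
  }

  ## manifest: config digest, seed, per-stage counts, exclusions
  cfgFile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[c("seed", "sharedStart", "sharedEnd", "trackYear")],
                   cfgFile)
  manifest <- list(
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfgFile)),
    stages = do.call(rbind, stageCounts),
    exclusions = rbind(tagLog("whole", logWhole),
                       tagLog("shared", logShared)))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  unlink(cfgFile)
  invisible(NULL)
}
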