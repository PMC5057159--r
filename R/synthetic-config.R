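#' Default prey-taxon metadata table
#'
#' A synthetic taxonomy of 53 prey taxa in four categories (reptile, bird,
#' mammal, arthropod), with reptiles split into snake and lizard
#' subcategories (12 snakes, 8 lizards). Non-reptile taxa carry
#' subcategory "n/a". This is the shared taxon list both simulated species
#' draw their diets from.
#'
#' @return data.frame with columns taxon, category, subcategory.
#' @export
defaultTaxonomy <- function() {
  tax <- rbind(
    data.frame(taxon = sprintf("snake_%02d", 1:12), category = "reptile",
               subcategory = "snake"),
    data.frame(taxon = sprintf("lizard_%02d", 1:8), category = "reptile",
               subcategory = "lizard"),
    data.frame(taxon = sprintf("bird_%02d", 1:15), category = "bird",
               subcategory = "n/a"),
    data.frame(taxon = sprintf("mammal_%02d", 1:10), category = "mammal",
               subcategory = "n/a"),
    data.frame(taxon = sprintf("arthropod_%02d", 1:8), category = "arthropod",
               subcategory = "n/a"))
  tax
}

## Geometric within-category taxon weights; poolSizes caps the number of
## taxa a species actually uses per category (richness differs between
## species; the commoner taxa are shared).
dietVector <- function(taxonomy, categoryWeights, snakeFrac,
                       poolSizes = NULL, decay = 0.7) {
  p <- numeric(nrow(taxonomy))
  names(p) <- taxonomy$taxon
  for (cat in names(categoryWeights)) {
    idx <- which(taxonomy$category == cat)
    if (cat == "reptile") {
      for (sub in c("snake", "lizard")) {
        sidx <- idx[taxonomy$subcategory[idx] == sub]
        if (!is.null(poolSizes)) sidx <- sidx[seq_len(min(length(sidx), poolSizes[[sub]]))]
        w <- decay^(seq_along(sidx) - 1)
        subW <- if (sub == "snake") snakeFrac else 1 - snakeFrac
        p[sidx] <- categoryWeights[[cat]] * subW * w / sum(w)
      }
    } else {
      if (!is.null(poolSizes)) idx <- idx[seq_len(min(length(idx), poolSizes[[cat]]))]
      w <- decay^(seq_along(idx) - 1)
      p[idx] <- categoryWeights[[cat]] * w / sum(w)
    }
  }
  p / sum(p)
}

defaultSpeciesParams <- function() {
  tax <- defaultTaxonomy()
  list(
    LLB = list(                      # near-nest forager
      nTagged = 13L,
      nAnalyzable = 9L,              # tagged minus early nest failures
      nestDistKm = 2.35, nestDistSdKm = 0.62,
      nPatches = 3L, patchRadiusM = 300, patchPool = 0L,
      transitSpeed = c(mean = 8, sd = 1.5),
      forageSpeed = c(mean = 1.2, sd = 0.8),
      dielMode = "uniform", peakHour = NA_real_, peakSdH = NA_real_,
      fixIntervalMin = 5, regularTagFrac = 5 / 13,
      seasonStart = "03-25", seasonEnd = "07-15",
      tripsPerDay = 3, forageBoutMin = c(mean = 90, sd = 20),
      pauseProb = 0.02,
      nestRadiusKm = 0.15,
      habitatUse = c(rocky = 0.27, low_natural_vegetation = 0.41,
                     cultivated = 0.12, uncultivated = 0.20),
      nTerritories = 37L, nestMinSpacingKm = 1.5,
      itemsPerNestMean = 39, smallNestFrac = 0.10,
      dietProbs = dietVector(
        tax,
        c(reptile = 0.478, bird = 0.29, mammal = 0.16, arthropod = 0.072),
        snakeFrac = 0.25)
    ),
    STE = list(                      # commuting forager
      nTagged = 11L,
      nAnalyzable = 8L,
      nestDistKm = 13.03, nestDistSdKm = 2.20,
      nPatches = 3L, patchRadiusM = 300, patchPool = 5L,
      transitSpeed = c(mean = 9, sd = 1.5),
      forageSpeed = c(mean = 1.0, sd = 0.7),
      dielMode = "midday", peakHour = 13, peakSdH = 2,
      fixIntervalMin = 5, regularTagFrac = 8 / 11,
      seasonStart = "03-25", seasonEnd = "09-01",
      tripsPerDay = 3, forageBoutMin = c(mean = 90, sd = 20),
      pauseProb = 0.02,
      nestRadiusKm = 1.5,
      habitatUse = c(rocky = 0.16, low_natural_vegetation = 0.07,
                     cultivated = 0.59, uncultivated = 0.18),
      nTerritories = 63L, nestMinSpacingKm = 0.6,
      itemsPerNestMean = 24, smallNestFrac = 0.10,
      dietProbs = dietVector(
        tax,
        c(reptile = 0.763, bird = 0.06, mammal = 0.077, arthropod = 0.10),
        snakeFrac = 0.714,
        poolSizes = list(snake = 8, lizard = 4, bird = 7, mammal = 6,
                         arthropod = 5))
    )
  )
}

#' Build a synthetic-study configuration
#'
#' Parameterizes the whole synthetic system: a categorical landscape, two
#' central-place-foraging species with distinct nest-to-patch distances
#' (2.35 km vs 13.03 km by default), a 12-h duty cycle (06:55-19:05) at
#' 5-min (solar tags) or 90-min (regular tags) fix intervals, bimodal
#' ground speeds either side of 4 m/s, uniform vs midday-peaked diel
#' activity, species-specific habitat preference, and multinomial diets
#' over a shared 53-taxon list with species-specific taxon pools.
#'
#' @param seed integer master seed; every generator derives its stream
#'   from it, so an identical config yields byte-identical outputs.
#' @param ... named overrides merged (recursively) into the defaults, e.g.
#'   `species = list(LLB = list(nTagged = 3L))`, `landscape =
#'   list(extentKm = 20)`, `years = 2013L`.
#' @return a [SimConfig-class] object.
#' @export
simConfig <- function(seed = 1L, ...) {
  defaults <- list(
    seed = as.integer(seed),
    species = defaultSpeciesParams(),
    landscape = list(
      extentKm = 80, cellM = 100,
      availability = c(rocky = 0.28, low_natural_vegetation = 0.12,
                       cultivated = 0.37, uncultivated = 0.23)),
    breedingRadiusKm = 9,          # nests cluster in a central breeding area
    dutyStart = "06:55", dutyEnd = "19:05",
    trackYear = 2013L,
    years = 2011:2013,             # diet-collection seasons
    sharedStart = "03-25", sharedEnd = "07-15",
    originLonLat = c(35.0, 31.7),  # anchor for lon/lat round-tripping
    taxonomy = defaultTaxonomy()
  )
  over <- list(...)
  over$seed <- NULL
  cfg <- utils::modifyList(defaults, over)
  cfg$seed <- as.integer(seed)
  validateSimConfig(cfg)
  new("SimConfig", params = cfg)
}

validateSimConfig <- function(cfg) {
  av <- cfg$landscape$availability
  stopIfNot(length(av) >= 1 && all(av >= 0),
            "availability proportions must be non-negative")
  stopIfNot(abs(sum(av) - 1) <= 1e-9,
            "availability proportions must sum to 1 +- 1e-9")
  for (sp in names(cfg$species)) {
    s <- cfg$species[[sp]]
    stopIfNot(abs(sum(s$dietProbs) - 1) <= 1e-9,
              sprintf("%s diet probabilities must sum to 1 +- 1e-9", sp))
    stopIfNot(s$forageSpeed[["mean"]] < 4 && s$transitSpeed[["mean"]] > 4,
              sprintf("%s: forage speed mean < 4 m/s < transit speed mean required", sp))
    stopIfNot(s$nTagged > 0 && s$nTerritories > 0 && s$nPatches > 0,
              sprintf("%s: all counts must be positive", sp))
    stopIfNot(abs(sum(s$habitatUse) - 1) <= 1e-9,
              sprintf("%s habitat-use proportions must sum to 1 +- 1e-9", sp))
  }
  invisible(TRUE)
}

#' Read a SimConfig from a YAML file
#'
#' @param path YAML file of overrides; must contain a `seed` entry.
#' @return a [SimConfig-class]
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  stopIfNot(!is.null(y$seed), "config file must set a seed")
  seed <- y$seed
  y$seed <- NULL
  ## yaml reads named vectors as lists; coerce the numeric-vector fields
  y <- rapply(y, function(x) x, how = "replace")
  do.call(simConfig, c(list(seed = seed), y))
}
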