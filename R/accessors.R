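## Accessors and show methods. Slot access from user code should go through
## these.

#' @describeIn FixSeries-class id accessor
#' @param object a FixSeries
#' @export
setGeneric("individualId", function(object) standardGeneric("individualId"))
#' @export
setMethod("individualId", "FixSeries", function(object) object@individualId)
#' @export
setMethod("individualId", "StandingPointSet", function(object) object@individualId)

#' Species label of a track or standing-point set
#' @param object a FixSeries or StandingPointSet
#' @export
setGeneric("speciesLabel", function(object) standardGeneric("speciesLabel"))
#' @export
setMethod("speciesLabel", "FixSeries", function(object) object@species)
#' @export
setMethod("speciesLabel", "StandingPointSet", function(object) object@species)

#' Fix table of a FixSeries
#' @param object a FixSeries
#' @export
setGeneric("fixData", function(object) standardGeneric("fixData"))
#' @export
setMethod("fixData", "FixSeries", function(object) object@fixes)

#' Point table of a StandingPointSet
#' @param object a StandingPointSet
#' @export
setGeneric("pointData", function(object) standardGeneric("pointData"))
#' @export
setMethod("pointData", "StandingPointSet", function(object) object@points)

#' Applied filter tags of a StandingPointSet
#' @param object a StandingPointSet
#' @export
setGeneric("appliedFilters", function(object) standardGeneric("appliedFilters"))
#' @export
setMethod("appliedFilters", "StandingPointSet", function(object) object@filters)

#' Nest table of a NestSet
#' @param object a NestSet
#' @export
setGeneric("nestData", function(object) standardGeneric("nestData"))
#' @export
setMethod("nestData", "NestSet", function(object) object@nests)

#' Cell values / geometry of raster-like objects
#' @param object a HabitatRaster or UtilizationGrid
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
#' @export
setMethod("gridValues", "HabitatRaster", function(object) object@values)
#' @export
setMethod("gridValues", "UtilizationGrid", function(object) object@z)

#' @rdname gridValues
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))
#' @export
setMethod("gridOrigin", "HabitatRaster", function(object) object@origin)
#' @export
setMethod("gridOrigin", "UtilizationGrid", function(object) object@origin)
#' @export
setMethod("gridOrigin", "IsoplethRegion", function(object) object@origin)

#' @rdname gridValues
#' @export
setGeneric("cellSizeM", function(object) standardGeneric("cellSizeM"))
#' @export
setMethod("cellSizeM", "HabitatRaster", function(object) object@cellSize)
#' @export
setMethod("cellSizeM", "UtilizationGrid", function(object) object@cellSize)
#' @export
setMethod("cellSizeM", "IsoplethRegion", function(object) object@cellSize)

#' Habitat class names of a HabitatRaster
#' @param object a HabitatRaster
#' @export
setGeneric("classNames", function(object) standardGeneric("classNames"))
#' @export
setMethod("classNames", "HabitatRaster", function(object) object@classNames)

#' Smoothing factor (kernel sigma, m) of a UtilizationGrid
#' @param object a UtilizationGrid
#' @export
setGeneric("smoothingH", function(object) standardGeneric("smoothingH"))
#' @export
setMethod("smoothingH", "UtilizationGrid", function(object) object@h)

#' Area (km^2) of an IsoplethRegion
#' @param object an IsoplethRegion
#' @export
setGeneric("areaKm2", function(object) standardGeneric("areaKm2"))
#' @export
setMethod("areaKm2", "IsoplethRegion", function(object) object@areaKm2)

#' Values matrix of a CompositionMatrix or OverlapMatrix
#' @param object the object
#' @export
setGeneric("compValues", function(object) standardGeneric("compValues"))
#' @export
setMethod("compValues", "CompositionMatrix", function(object) object@values)
#' @export
setMethod("compValues", "OverlapMatrix", function(object) object@values)

#' Group (species) labels
#' @param object the object
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))
#' @export
setMethod("groupLabels", "CompositionMatrix", function(object) object@groups)
#' @export
setMethod("groupLabels", "OverlapMatrix", function(object) object@groups)
#' @export
setMethod("groupLabels", "DissimilarityMatrix", function(object) object@groups)

#' Diet records of a DietTable
#' @param object a DietTable
#' @export
setGeneric("dietData", function(object) standardGeneric("dietData"))
#' @export
setMethod("dietData", "DietTable", function(object) object@data)

#' Parameters of a SimConfig
#' @param object a SimConfig
#' @export
setGeneric("simParams", function(object) standardGeneric("simParams"))
#' @export
setMethod("simParams", "SimConfig", function(object) object@params)

#' Attraction index value
#' @param object an AttractionResult
#' @export
setGeneric("attractionValue", function(object) standardGeneric("attractionValue"))
#' @export
setMethod("attractionValue", "AttractionResult", function(object) object@index)

setMethod("show", "FixSeries", function(object) {
  f <- object@fixes
  cat("FixSeries", object@individualId, "(", object@species, ")\n")
  cat(" ", nrow(f), "fixes")
  if (nrow(f))
    cat(",", format(min(f$timestamp)), "to", format(max(f$timestamp)))
  cat("\n")
})

setMethod("show", "StandingPointSet", function(object) {
  cat("StandingPointSet", object@individualId, "(", object@species, ")",
      "window:", object@window, "year:", object@year, "\n")
  cat(" ", nrow(object@points), "points; filters:",
      paste(object@filters, collapse = " -> "), "\n")
})

setMethod("show", "NestSet", function(object) {
  cat("NestSet:", nrow(object@nests), "nest-years,",
      length(unique(object@nests$species)), "species\n")
})

setMethod("show", "HabitatRaster", function(object) {
  cat("HabitatRaster:", nrow(object@values), "x", ncol(object@values),
      "cells @", object@cellSize, "m;",
      length(object@classNames), "classes\n")
})

setMethod("show", "UtilizationGrid", function(object) {
  cat("UtilizationGrid:", nrow(object@z), "x", ncol(object@z),
      "cells @", object@cellSize, "m; h =", object@h, "m;",
      nrow(object@points), "source points\n")
})

setMethod("show", "IsoplethRegion", function(object) {
  cat(sprintf("IsoplethRegion: level %.2f, %d cells, %.2f km^2\n",
              object@level, sum(object@member), object@areaKm2))
})

setMethod("show", "CompositionMatrix", function(object) {
  cat("CompositionMatrix (", object@kind, "): ", nrow(object@values),
      " units x ", ncol(object@values), " categories; groups: ",
      paste(unique(object@groups), collapse = ", "), "\n", sep = "")
})

setMethod("show", "DietTable", function(object) {
  d <- object@data
  cat("DietTable:", sum(d$count), "items,", length(unique(d$taxon)),
      "taxa,", length(unique(d$nest_id)), "nests\n")
})

setMethod("show", "NullModelResult", function(object) {
  cat("NullModelResult [", object@algorithm, "], ", object@nIter,
      " iterations\n", sep = "")
  print(data.frame(statistic = names(object@observed),
                   observed = round(object@observed, 4),
                   p_high = round(object@pHigh, 4),
                   p_low = round(object@pLow, 4), row.names = NULL))
})

setMethod("show", "RichnessEstimate", function(object) {
  cat(sprintf("RichnessEstimate: S_obs = %d, F1 = %d, F2 = %d, Chao1 = %.1f\n",
              object@sObs, object@f1, object@f2, object@chao1))
})

setMethod("show", "AttractionResult", function(object) {
  cat(sprintf("AttractionResult %s ~ %s: index = %s (obs meetings %d, %d perms)\n",
              object@pair[1], object@pair[2],
              ifelse(is.na(object@index), "NA (no co-observation)",
                     sprintf("%.3f", object@index)),
              as.integer(object@observed), object@nPerm))
})

setMethod("show", "AnosimResult", function(object) {
  cat(sprintf("ANOSIM: Global R = %.3f, p = %.4g (%s)\n", object@R, object@p,
              if (object@exact) "exact" else paste0(object@nPerm, " permutations")))
})

setMethod("show", "SimperResult", function(object) {
  cat(sprintf("SIMPER: overall between-group dissimilarity %.1f%%\n",
              object@overallDissimilarity))
  print(utils::head(object@between, 5))
})

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig: seed", p$seed, "-",
      paste(names(p$species), collapse = " vs "), "\n")
})
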