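## File interfaces: Movebank-style fix CSV, GeoJSON nests, Esri ASCII grid
## rasters, diet CSV. All plain-text.

movebankCols <- c(id = "individual-local-identifier", species = "taxon",
                  timestamp = "timestamp", lon = "location-long",
                  lat = "location-lat", speed = "ground-speed",
                  heading = "heading")

#' Read GPS fixes from a Movebank-style CSV
#'
#' Expects columns individual-local-identifier, taxon, timestamp
#' (ISO-8601), location-long, location-lat, ground-speed (m/s), heading
#' (deg). Rows with missing coordinates or unparseable timestamps are
#' dropped and counted; out-of-order timestamps are sorted with a
#' warning; duplicated (individual, timestamp) rows are deduplicated.
#'
#' @param path CSV file.
#' @param crs either `list(type = "planar")` when location columns already
#'   hold planar meters, or `list(type = "lonlat", origin = c(lon0, lat0))`
#'   to project with a local transverse Mercator; origin defaults to the
#'   data centroid.
#' @return named list of [FixSeries-class]; the drop/dedup log is attached
#'   as `attr(, "log")` (data.frame reason/count).
#' @export
readFixes <- function(path, crs = list(type = "lonlat", origin = NULL)) {
  raw <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(unname(movebankCols), names(raw))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  df <- data.frame(id = raw[[movebankCols["id"]]],
                   species = raw[[movebankCols["species"]]],
                   ts = raw[[movebankCols["timestamp"]]],
                   lon = as.numeric(raw[[movebankCols["lon"]]]),
                   lat = as.numeric(raw[[movebankCols["lat"]]]),
                   speed = as.numeric(raw[[movebankCols["speed"]]]),
                   heading = as.numeric(raw[[movebankCols["heading"]]]))
  log <- data.frame(reason = character(0), count = integer(0))
  addLog <- function(reason, count) {
    if (count > 0) log <<- rbind(log, data.frame(reason = reason, count = count))
  }
  ts <- as.POSIXct(df$ts, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  addLog("unparseable_timestamp", sum(is.na(ts) & !is.na(df$ts)))
  bad <- is.na(ts) | is.na(df$lon) | is.na(df$lat)
  addLog("missing_coordinates", sum(is.na(df$lon) | is.na(df$lat)))
  df <- df[!bad, ]; ts <- ts[!bad]
  df$timestamp <- ts

  if (identical(crs$type, "planar")) {
    df$x <- df$lon; df$y <- df$lat
  } else {
    org <- crs$origin
    if (is.null(org)) org <- c(mean(df$lon), mean(df$lat))
    xy <- projectLonLat(df$lon, df$lat, org)
    df$x <- xy[, "x"]; df$y <- xy[, "y"]
  }
  out <- list()
  for (id in unique(df$id)) {
    d <- df[df$id == id, ]
    o <- order(d$timestamp)
    if (is.unsorted(d$timestamp)) {
      addLog(paste0("out_of_order:", id), sum(o != seq_along(o)))
      warning("out-of-order timestamps sorted for ", id)
      d <- d[o, ]
    }
    dup <- duplicated(d$timestamp)
    addLog(paste0("duplicate_timestamp:", id), sum(dup))
    d <- d[!dup, ]
    out[[as.character(id)]] <- new("FixSeries",
      individualId = as.character(id), species = as.character(d$species[1]),
      fixes = d[, c("timestamp", "lon", "lat", "speed", "heading", "x", "y")])
  }
  attr(out, "log") <- log
  out
}

#' Write tracks as a Movebank-style CSV
#'
#' @param tracks list of [FixSeries-class]
#' @param path output CSV
#' @export
writeFixesCsv <- function(tracks, path) {
  rows <- lapply(tracks, function(fs) {
    f <- fixData(fs)
    data.frame(check.names = FALSE,
      `individual-local-identifier` = individualId(fs),
      taxon = speciesLabel(fs),
      timestamp = format(f$timestamp, "%Y-%m-%dT%H:%M:%S"),
      `location-long` = f$lon, `location-lat` = f$lat,
      `ground-speed` = f$speed, heading = f$heading)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write / read nests as GeoJSON
#'
#' Point features with properties nest_id, species, year,
#' reached_chick_rearing, and the planar x/y.
#' @param nests a [NestSet-class]
#' @param path output file
#' @export
writeNestsGeoJSON <- function(nests, path) {
  nd <- nestData(nests)
  feats <- lapply(seq_len(nrow(nd)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(nd$lon[i], nd$lat[i])),
    properties = list(nest_id = nd$nest_id[i], species = nd$species[i],
                      year = nd$year[i], x = nd$x[i], y = nd$y[i],
                      reached_chick_rearing = nd$reached_chick_rearing[i])))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNestsGeoJSON
#' @export
readNestsGeoJSON <- function(path) {
  g <- jsonlite::read_json(path)
  rows <- do.call(rbind, lapply(g$features, function(f) {
    pr <- f$properties
    data.frame(nest_id = pr$nest_id, species = pr$species,
               year = as.integer(pr$year),
               lon = f$geometry$coordinates[[1]],
               lat = f$geometry$coordinates[[2]],
               x = pr$x, y = pr$y,
               reached_chick_rearing = isTRUE(pr$reached_chick_rearing))
  }))
  new("NestSet", nests = rows)
}

#' Write / read a grid as Esri ASCII raster (plain text)
#'
#' Used for both the habitat landscape (with a sidecar `<path>.classes`
#' legend) and utilization grids.
#' @param obj a [HabitatRaster-class] or [UtilizationGrid-class]
#' @param path output .asc file
#' @export
writeAsciiGrid <- function(obj, path) {
  v <- gridValues(obj)
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.6f", gridOrigin(obj)[1]),
           sprintf("yllcorner %.6f", gridOrigin(obj)[2]),
           sprintf("cellsize %.6f", cellSizeM(obj)),
           "NODATA_value -9999")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  ## ASCII grid rows run north to south; our row 1 is the south edge
  utils::write.table(v[nrow(v):1, , drop = FALSE], con, row.names = FALSE,
                     col.names = FALSE)
  if (is(obj, "HabitatRaster"))
    writeLines(classNames(obj), paste0(path, ".classes"))
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @param type "habitat" or "ud"
#' @param h smoothing factor to attach when type = "ud"
#' @export
readAsciiGrid <- function(path, type = c("habitat", "ud"), h = NULL) {
  type <- match.arg(type)
  lines <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(lines, " +"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v <- v[nrow(v):1, , drop = FALSE]
  org <- c(hdr[["xllcorner"]], hdr[["yllcorner"]])
  if (type == "habitat") {
    cls <- readLines(paste0(path, ".classes"))
    new("HabitatRaster", values = v, origin = org,
        cellSize = hdr[["cellsize"]], classNames = cls)
  } else {
    new("UtilizationGrid", z = v / sum(v), origin = org,
        cellSize = hdr[["cellsize"]], h = h,
        points = matrix(numeric(0), 0, 2))
  }
}

#' Write a DietTable as CSV
#' @param diets a [DietTable-class]
#' @param path output CSV
#' @export
writeDietCsv <- function(diets, path) {
  utils::write.csv(dietData(diets), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDietCsv
#' @export
readDietCsv <- function(path) {
  new("DietTable", data = utils::read.csv(path))
}

#' Export an isopleth region as GeoJSON
#'
#' The region is written as a MultiPolygon of its member grid cells (not a
#' dissolved outline); area and level are attached as properties.
#' @param region an [IsoplethRegion-class]
#' @param path output file
#' @export
writeIsoplethGeoJSON <- function(region, path) {
  m <- region@member; cs <- cellSizeM(region); org <- gridOrigin(region)
  idx <- which(m, arr.ind = TRUE)
  polys <- lapply(seq_len(nrow(idx)), function(i) {
    x0 <- org[1] + (idx[i, 2] - 1) * cs; y0 <- org[2] + (idx[i, 1] - 1) * cs
    list(list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
              c(x0, y0 + cs), c(x0, y0)))
  })
  jsonlite::write_json(list(
    type = "Feature",
    geometry = list(type = "MultiPolygon", coordinates = polys),
    properties = list(level = region@level, area_km2 = region@areaKm2)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
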