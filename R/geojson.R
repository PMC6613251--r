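# GeoJSON (RFC 7946) reading and writing for polygons and points, plus the
# delimited-text point readers.  GeoJSON coordinates are geographic (WGS84)
# on input and are projected to the local planar frame with a
# ProjectionSpec.

#' Read a GeoJSON FeatureCollection
#'
#' Low-level reader returning geometry type, raw coordinates and properties
#' per feature.  Supports Point, Polygon and MultiPolygon.
#'
#' @param path file path.
#' @return list of features: `type`, `coordinates` (nested lists as in the
#'   file), `properties` (named list).
#' @export
readGeoJSONFeatures <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop(path, " is not a GeoJSON FeatureCollection")
  lapply(g$features, function(f) {
    list(type = f$geometry$type, coordinates = f$geometry$coordinates,
         properties = if (is.null(f$properties)) list() else f$properties)
  })
}

.ringFromGeoJSON <- function(coords, spec) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  if (!is.null(spec)) m <- projectPoints(m, spec)
  m
}

.polygonFromGeoJSON <- function(type, coords, spec) {
  ringSets <- if (type == "Polygon") list(coords)
  else if (type == "MultiPolygon") coords
  else stop("unsupported geometry type: ", type)
  rings <- list()
  for (poly in ringSets)
    for (ring in poly)
      rings <- c(rings, list(.ringFromGeoJSON(ring, spec)))
  planarPolygon(rings)
}

#' Read census blocks from GeoJSON
#'
#' Expects polygon features with properties `block_id`, `total_population`,
#' `housing_units` and optionally `group_quarters_population` (defaults to 0
#' with a warning when absent) and `pph`.
#'
#' @param path GeoJSON file path (geographic coordinates, WGS84).
#' @param spec a [ProjectionSpec-class]; when `NULL` one is centred on the
#'   block bounding box.
#' @return a [CensusBlocks-class] in the planar frame, with the projection
#'   used stored in attribute `projection`.
#' @export
readCensusBlocksGeoJSON <- function(path, spec = NULL) {
  feats <- readGeoJSONFeatures(path)
  if (is.null(spec)) {
    all <- do.call(rbind, lapply(feats, function(f) {
      do.call(rbind, lapply(unlist(list(f$coordinates), recursive = FALSE),
                            function(ring)
                              do.call(rbind, lapply(ring, function(p)
                                c(p[[1]], p[[2]])))))
    }))
    spec <- projectionSpec(mean(range(all[, 1])), mean(range(all[, 2])))
  }
  prop <- function(f, name, default = NULL) {
    v <- f$properties[[name]]
    if (is.null(v)) default else v
  }
  gqMissing <- FALSE
  geoms <- vector("list", length(feats))
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geoms[[i]] <- .polygonFromGeoJSON(f$type, f$coordinates, spec)
    gq <- prop(f, "group_quarters_population")
    if (is.null(gq)) { gq <- 0; gqMissing <- TRUE }
    rows[[i]] <- data.frame(
      block_id = as.character(prop(f, "block_id", sprintf("blk%04d", i))),
      total_population = as.numeric(prop(f, "total_population", 0)),
      group_quarters_population = as.numeric(gq),
      housing_units = as.numeric(prop(f, "housing_units", 0)),
      pph = as.numeric(prop(f, "pph", NA)), stringsAsFactors = FALSE)
  }
  if (gqMissing)
    warning("group_quarters_population missing for some blocks; assuming 0")
  d <- do.call(rbind, rows)
  blocks <- censusBlocks(geoms, d$block_id, d$total_population,
                         d$group_quarters_population, d$housing_units,
                         pph = if (all(is.na(d$pph))) NULL else d$pph)
  attr(blocks, "projection") <- spec
  blocks
}

#' Read points from GeoJSON or delimited text
#'
#' CSV input must carry `lon` and `lat` columns; GeoJSON input must be Point
#' features.  All other columns/properties are kept.
#'
#' @param path `.geojson`/`.json` or delimited-text file path.
#' @param spec optional [ProjectionSpec-class]; when given, planar `x`, `y`
#'   columns are added.
#' @return data.frame with `lon`, `lat` (and `x`, `y` when projected).
#' @export
readPoints <- function(path, spec = NULL) {
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    feats <- readGeoJSONFeatures(path)
    rows <- lapply(feats, function(f) {
      if (f$type != "Point") stop("expected Point features in ", path)
      p <- c(lon = f$coordinates[[1]], lat = f$coordinates[[2]])
      props <- f$properties
      c(as.list(p), props)
    })
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("lon", "lat") %in% names(df)))
      stop(path, " must have lon and lat columns")
  }
  if (!is.null(spec)) {
    xy <- projectPoints(cbind(df$lon, df$lat), spec)
    df$x <- xy[, 1L]; df$y <- xy[, 2L]
  }
  df
}

.ringToGeoJSON <- function(ring, spec) {
  if (!is.null(spec)) ring <- unprojectPoints(ring, spec)
  lapply(seq_len(nrow(ring)), function(i) as.list(unname(ring[i, ])))
}

#' Write census blocks to GeoJSON
#'
#' Inverse-projects the planar geometries back to geographic coordinates.
#'
#' @param blocks a [CensusBlocks-class].
#' @param path output path.
#' @param spec the [ProjectionSpec-class] of the planar frame.
#' @return `path`, invisibly.
#' @export
writeCensusBlocksGeoJSON <- function(blocks, path, spec) {
  d <- blocks@data
  feats <- lapply(seq_len(length(blocks)), function(i) {
    poly <- geometries(blocks)[[i]]
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = lapply(poly@rings, .ringToGeoJSON,
                                              spec = spec)),
         properties = list(block_id = d$block_id[i],
                           total_population = d$total_population[i],
                           group_quarters_population =
                             d$group_quarters_population[i],
                           housing_units = d$housing_units[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a point table to CSV with geographic coordinates
#'
#' @param df data.frame with planar `x`, `y` columns.
#' @param path output path.
#' @param spec the [ProjectionSpec-class] of the planar frame.
#' @return `path`, invisibly.
#' @export
writePointsCSV <- function(df, path, spec) {
  ll <- unprojectPoints(cbind(df$x, df$y), spec)
  out <- df[, setdiff(names(df), c("x", "y")), drop = FALSE]
  out$lon <- ll[, 1L]; out$lat <- ll[, 2L]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
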