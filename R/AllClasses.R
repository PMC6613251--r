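#' @import methods
NULL

#' Planar polygonal region
#'
#' A polygonal region in a planar (projected, metre-based) coordinate frame,
#' stored as one or more closed rings under the even-odd fill rule: a point is
#' inside the region when it falls inside an odd number of rings.  A simple
#' polygon is a single ring; a polygon with holes carries its hole rings
#' alongside the outer ring; a multi-part region (as produced by clipping a
#' non-convex shape) may carry several outer rings.
#'
#' Each ring is a closed two-column numeric matrix (first vertex repeated as
#' the last).  Rings must not self-intersect.  Construct with
#' [planarPolygon()], which validates closure and finiteness.
#'
#' @slot rings list of closed two-column coordinate matrices (metres).
#' @seealso [planarPolygon()], [polygonArea()], [clipPolygons()],
#'   [dissolvePolygons()], [containsPoint()]
#' @export
setClass("PlanarPolygon", representation(rings = "list"))

setValidity("PlanarPolygon", function(object) {
  msgs <- character()
  for (i in seq_along(object@rings)) {
    r <- object@rings[[i]]
    if (!is.matrix(r) || !is.numeric(r) || ncol(r) != 2L)
      return(sprintf("ring %d is not a two-column numeric matrix", i))
    if (nrow(r) < 4L)
      return(sprintf("ring %d has fewer than 3 distinct vertices", i))
    if (!all(is.finite(r)))
      return(sprintf("ring %d contains non-finite coordinates", i))
    if (any(r[1L, ] != r[nrow(r), ]))
      return(sprintf("ring %d is not closed (first vertex != last vertex)", i))
  }
  if (length(msgs)) msgs else TRUE
})

#' Local azimuthal equal-area projection
#'
#' Specification of a Lambert azimuthal equal-area projection on the authalic
#' sphere, centred inside the study region.  Equal-area behaviour is required
#' because proportional population allocation weights by intersected area;
#' distances within a few hundred km of the centre are preserved to well under
#' 0.5 percent.
#'
#' @slot centerLon projection centre longitude, decimal degrees (WGS84).
#' @slot centerLat projection centre latitude, decimal degrees.
#' @seealso [projectionSpec()], [projectPoints()], [unprojectPoints()]
#' @export
setClass("ProjectionSpec",
         representation(centerLon = "numeric", centerLat = "numeric"))

setValidity("ProjectionSpec", function(object) {
  if (length(object@centerLon) != 1L || length(object@centerLat) != 1L)
    return("centerLon and centerLat must be scalars")
  if (!is.finite(object@centerLon) || !is.finite(object@centerLat))
    return("projection centre must be finite")
  if (abs(object@centerLat) > 90) return("centerLat outside [-90, 90]")
  if (abs(object@centerLon) > 360) return("centerLon outside [-360, 360]")
  TRUE
})

#' Census blocks with population and housing attributes
#'
#' The smallest census aggregation polygons, each carrying total population,
#' group-quarters population (institutional residents: prisons, dormitories)
#' and the census housing-unit count.  These attributes drive both estimators:
#' persons-per-household (ABODE) and population density (PPA).
#'
#' @slot geometry list of [PlanarPolygon-class] block geometries.
#' @slot data data.frame with columns `block_id`, `total_population`,
#'   `group_quarters_population`, `housing_units` and optionally `pph`
#'   (a published average-household-size override).
#' @seealso [censusBlocks()], [personsPerHousehold()], [populationDensity()]
#' @export
setClass("CensusBlocks",
         representation(geometry = "list", data = "data.frame"))

setValidity("CensusBlocks", function(object) {
  d <- object@data
  need <- c("block_id", "total_population", "group_quarters_population",
            "housing_units")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste("missing block columns:", paste(miss, collapse = ", ")))
  if (length(object@geometry) != nrow(d))
    return("geometry list length differs from number of block rows")
  if (!all(vapply(object@geometry, is, logical(1), "PlanarPolygon")))
    return("geometry entries must be PlanarPolygon objects")
  if (anyDuplicated(d$block_id)) return("duplicate block_id values")
  if (any(d$total_population < 0) || any(d$housing_units < 0) ||
      any(d$group_quarters_population < 0))
    return("negative population or housing-unit counts")
  if (any(d$group_quarters_population > d$total_population))
    return("group_quarters_population exceeds total_population")
  TRUE
})

#' Gridded land-use classification
#'
#' A regular raster of integer land-use class codes (30 m cells by default)
#' used for dasymetric censoring: candidate dwelling points falling in
#' excluded classes (built-up commercial / industrial / institutional) are
#' removed before allocation.  Cells are half-open,
#' `[x0 + (j-1)s, x0 + j s) x [y0 + (i-1)s, y0 + i s)`, so every in-extent
#' point maps to exactly one cell; row 1 of `classes` is the southernmost row.
#'
#' @slot originX,originY lower-left corner of the grid (planar metres).
#' @slot cellSize cell edge length in metres.
#' @slot classes integer matrix (rows = south-to-north, cols = west-to-east);
#'   `NA` marks NODATA cells.
#' @slot excludedClasses integer codes censored as non-residential.
#' @seealso [landUseGrid()], [lookupLandUse()], [censorNonresidential()]
#' @export
setClass("LandUseGrid",
         representation(originX = "numeric", originY = "numeric",
                        cellSize = "numeric", classes = "matrix",
                        excludedClasses = "integer"))

setValidity("LandUseGrid", function(object) {
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    return("cellSize must be a positive scalar")
  if (!is.numeric(object@classes))
    return("classes must be a numeric/integer matrix")
  TRUE
})

#' Evaluation metrics bundle
#'
#' Container for the agreement statistics comparing candidate housing-unit
#' counts to census counts, or one allocation method to another: FAC2, MAPE,
#' Spearman rank correlation, fractional bias, the Wilcoxon signed-rank test
#' and agreement-category counts, together with the number of pairs each
#' metric actually used after its exclusion rules.
#'
#' @slot fac2,mape,spearmanRho,fractionalBias,wilcoxonZ,wilcoxonP scalar
#'   statistics (`NA` when undefined for the input).
#' @slot nUsed named integer vector of pairs used per metric.
#' @slot agreementCounts named integer vector of agreement-category counts.
#' @seealso [metricsReport()], [fac2()], [mape()], [fractionalBias()],
#'   [wilcoxonSignedRank()]
#' @export
setClass("MetricsReport",
         representation(fac2 = "numeric", mape = "numeric",
                        spearmanRho = "numeric", fractionalBias = "numeric",
                        wilcoxonZ = "numeric", wilcoxonP = "numeric",
                        nUsed = "integer", agreementCounts = "integer"))
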