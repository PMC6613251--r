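#' @rdname polygonArea
#' @export
setGeneric("polygonArea", function(x) standardGeneric("polygonArea"))

#' @rdname containsPoint
#' @export
setGeneric("containsPoint",
           function(x, points) standardGeneric("containsPoint"))

#' @rdname censusBlocks
#' @export
setGeneric("blockIds", function(x) standardGeneric("blockIds"))

#' @rdname censusBlocks
#' @export
setGeneric("geometries", function(x) standardGeneric("geometries"))

#' @rdname censusBlocks
#' @export
setGeneric("totalPopulation", function(x) standardGeneric("totalPopulation"))

#' @rdname censusBlocks
#' @export
setGeneric("groupQuartersPopulation",
           function(x) standardGeneric("groupQuartersPopulation"))

#' @rdname censusBlocks
#' @export
setGeneric("housingUnits", function(x) standardGeneric("housingUnits"))

#' @rdname personsPerHousehold
#' @export
setGeneric("personsPerHousehold",
           function(x, ...) standardGeneric("personsPerHousehold"))

#' @rdname populationDensity
#' @export
setGeneric("populationDensity",
           function(x, ...) standardGeneric("populationDensity"))
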