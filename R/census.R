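# Census block container and the two block-level derivations everything else
# rests on: persons per household (ABODE) and population density (PPA).

#' Construct a census block set
#'
#' @param geometry list of [PlanarPolygon-class] block geometries (planar
#'   frame).
#' @param blockId character vector of unique block identifiers.
#' @param totalPopulation persons per block (including group quarters).
#' @param groupQuartersPopulation institutional (prison, dormitory) persons
#'   per block; must not exceed `totalPopulation`.
#' @param housingUnits census housing-unit counts per block.
#' @param pph optional published average-household-size column; when supplied
#'   it overrides the derivation in [personsPerHousehold()].
#' @return a [CensusBlocks-class] object.
#' @export
censusBlocks <- function(geometry, blockId, totalPopulation,
                         groupQuartersPopulation = 0, housingUnits,
                         pph = NULL) {
  n <- length(blockId)
  d <- data.frame(block_id = as.character(blockId),
                  total_population = rep_len(as.numeric(totalPopulation), n),
                  group_quarters_population =
                    rep_len(as.numeric(groupQuartersPopulation), n),
                  housing_units = rep_len(as.numeric(housingUnits), n),
                  stringsAsFactors = FALSE)
  if (!is.null(pph)) d$pph <- rep_len(as.numeric(pph), n)
  new("CensusBlocks", geometry = geometry, data = d)
}

#' Accessors for census block sets
#'
#' @param x a [CensusBlocks-class].
#' @return `blockIds`: character ids; `geometries`: list of
#'   [PlanarPolygon-class]; the remaining accessors: numeric vectors in block
#'   order.
#' @name censusBlocks
#' @aliases blockIds geometries totalPopulation groupQuartersPopulation
#'   housingUnits
NULL

#' @rdname censusBlocks
#' @export
setMethod("blockIds", "CensusBlocks", function(x) x@data$block_id)

#' @rdname censusBlocks
#' @export
setMethod("geometries", "CensusBlocks", function(x) x@geometry)

#' @rdname censusBlocks
#' @export
setMethod("totalPopulation", "CensusBlocks",
          function(x) x@data$total_population)

#' @rdname censusBlocks
#' @export
setMethod("groupQuartersPopulation", "CensusBlocks",
          function(x) x@data$group_quarters_population)

#' @rdname censusBlocks
#' @export
setMethod("housingUnits", "CensusBlocks", function(x) x@data$housing_units)

#' @export
setMethod("length", "CensusBlocks", function(x) nrow(x@data))

setMethod("show", "CensusBlocks", function(object) {
  cat(sprintf("CensusBlocks: %d blocks, %s persons, %s housing units\n",
              length(object), format(sum(totalPopulation(object))),
              format(sum(housingUnits(object)))))
})

#' @export
setMethod("[", "CensusBlocks", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@data$block_id)
  initialize(x, geometry = x@geometry[i],
             data = x@data[i, , drop = FALSE])
})

#' Persons per household
#'
#' The block household population (total minus group quarters) divided by the
#' census housing-unit count.  Blocks with zero housing units get a pph of 0
#' and are flagged degenerate: any housing unit mistakenly located in such a
#' block contributes no population.  When the block set carries a published
#' `pph` column (the census "average household size" table) that value is
#' used instead of the derivation.
#'
#' @param x a [CensusBlocks-class].
#' @param ... unused.
#' @return numeric vector of persons per household, with attribute
#'   `degenerate`: logical vector marking zero-housing-unit blocks.
#' @examples
#' sq <- planarPolygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)))
#' b <- censusBlocks(list(sq), "b1", totalPopulation = 10,
#'                   groupQuartersPopulation = 2, housingUnits = 4)
#' personsPerHousehold(b)  # (10 - 2) / 4 = 2
#' @export
setMethod("personsPerHousehold", "CensusBlocks", function(x, ...) {
  validObject(x)
  d <- x@data
  degenerate <- d$housing_units == 0
  if (!is.null(d$pph)) {
    out <- ifelse(degenerate, 0, d$pph)
  } else {
    out <- ifelse(degenerate, 0,
                  (d$total_population - d$group_quarters_population) /
                    d$housing_units)
  }
  attr(out, "degenerate") <- degenerate
  out
})

#' Population density of census blocks
#'
#' Population divided by the geometric block area, in persons per square
#' metre.  `mode = "total"` (default, the standard census density) includes
#' group-quarters persons; `mode = "household"` excludes them, mirroring the
#' household population ABODE allocates.
#'
#' @param x a [CensusBlocks-class].
#' @param mode `"total"` or `"household"`.
#' @param ... unused.
#' @return numeric vector, persons per square metre.
#' @export
setMethod("populationDensity", "CensusBlocks",
          function(x, mode = c("total", "household"), ...) {
  mode <- match.arg(mode)
  validObject(x)
  areas <- vapply(x@geometry, polygonArea, numeric(1))
  if (any(areas <= 0)) {
    bad <- x@data$block_id[areas <= 0]
    stop("zero-area geometry for block(s): ", paste(bad, collapse = ", "))
  }
  pop <- if (mode == "total") x@data$total_population else
    x@data$total_population - x@data$group_quarters_population
  pop / areas
})

#' Square-mile to square-metre conversion (exact)
#'
#' Census population densities are published as persons per square mile;
#' 1 mi^2 = 2 589 988.110336 m^2 exactly.
#' @export
M2_PER_MI2 <- 2589988.110336
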