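# The two estimators.
#
# ABODE (allocation by occupied domicile estimation) counts the residential
# housing units of each census block i that fall inside an area j and
# allocates the block's average persons per household to each:
#
#   Pop_j = sum_i RHU_ij * f_i * pph_i
#
# with f_i = 1 (uncapped) or a block-level cap factor that scales RHU counts
# down when more units were geocoded in a block than the census reports
# (guarding against non-residential contamination and post-census growth).
#
# PPA (proportional population allocation) is areal weighting: the area of
# each block's overlap with the zone times the block's population density.

#' Radial well areas with per-block clipped intersections
#'
#' Builds the buffer polygon for each well and clips every overlapping
#' census block to it, recording the clipped areas PPA weights by.
#'
#' @param wells data.frame with columns `well_id`, `x`, `y` (planar metres)
#'   and optionally `state`, `facility_id`.
#' @param radius buffer radius in metres, > 0.
#' @param blocks a [CensusBlocks-class].
#' @param nSegments buffer polygon resolution (see [bufferPoint()]).
#' @return list of well-area records: `well_id`, `center`, `radius`,
#'   `polygon` ([PlanarPolygon-class]) and `intersections` (data.frame of
#'   `block_id`, `clipped_area`).
#' @export
makeWellAreas <- function(wells, radius, blocks, nSegments = 64L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive scalar")
  stopifnot(is(blocks, "CensusBlocks"))
  ids <- blockIds(blocks)
  geoms <- geometries(blocks)
  bboxes <- t(vapply(geoms, .bboxOf, numeric(4)))
  lapply(seq_len(nrow(wells)), function(i) {
    ctr <- c(wells$x[i], wells$y[i])
    poly <- bufferPoint(ctr, radius, nSegments)
    near <- which(bboxes[, "xmin"] <= ctr[1L] + radius &
                    bboxes[, "xmax"] >= ctr[1L] - radius &
                    bboxes[, "ymin"] <= ctr[2L] + radius &
                    bboxes[, "ymax"] >= ctr[2L] - radius)
    inter <- lapply(near, function(k) {
      piece <- clipPolygons(geoms[[k]], poly)
      a <- polygonArea(piece)
      if (a > 0) data.frame(block_id = ids[k], clipped_area = a,
                            stringsAsFactors = FALSE) else NULL
    })
    inter <- do.call(rbind, inter)
    if (is.null(inter))
      inter <- data.frame(block_id = character(), clipped_area = numeric(),
                          stringsAsFactors = FALSE)
    list(well_id = as.character(wells$well_id[i]), center = ctr,
         radius = radius, polygon = poly, intersections = inter)
  })
}

#' Count housing units inside an area, by census block
#'
#' Counts the RHUs inside or on the boundary of the area, grouped by the
#' block each RHU is anchored to (the block containing it, which for a unit
#' near a block edge need not be the block contributing most overlap area).
#' For a radial well area the test is the exact circle (`distance <=
#' radius`, boundary inclusive); the inscribed buffer polygon is only PPA's
#' area-clipping approximation of that circle.
#'
#' @param area one well-area record from [makeWellAreas()] (circle test), or
#'   a bare [PlanarPolygon-class] (containment test).
#' @param rhus assigned RHU data.frame (`x`, `y`, `block_id`).
#' @return named integer vector: RHU count per block id (only blocks with a
#'   positive count).
#' @export
rhusInArea <- function(area, rhus) {
  if (!nrow(rhus)) return(integer(0))
  pts <- cbind(rhus$x, rhus$y)
  keep <- if (is(area, "PlanarPolygon")) {
    containsPoint(area, pts)
  } else {
    sqrt((pts[, 1L] - area$center[1L])^2 +
           (pts[, 2L] - area$center[2L])^2) <= area$radius
  }
  keep <- keep & !is.na(rhus$block_id)
  if (!any(keep)) return(integer(0))
  tab <- table(rhus$block_id[keep])
  stats::setNames(as.integer(tab), names(tab))
}

#' Block-level cap factor
#'
#' Scaling factor `min(1, housing_units / block-wide RHU count)` applied to
#' every area's per-block RHU count under the capped estimator.  Capping at
#' the census housing-unit count guards against inflation from
#' non-residential addresses and post-census growth while preserving the
#' intra-block spatial pattern of units.  A block with no geocoded units
#' gets factor 1 (nothing to scale); a block the census says has no housing
#' units gets factor 0 and contributes nothing.
#'
#' @param housingUnits census housing-unit count(s), >= 0.
#' @param rhuTotalInBlock RHUs assigned to the block over its whole extent,
#'   >= 0.
#' @return numeric factor(s) in `[0, 1]`.
#' @export
blockCapFactor <- function(housingUnits, rhuTotalInBlock) {
  if (any(housingUnits < 0) || any(rhuTotalInBlock < 0))
    stop("negative inputs to blockCapFactor")
  ifelse(rhuTotalInBlock == 0, 1, pmin(1, housingUnits / rhuTotalInBlock))
}

.blockRhuTotals <- function(blocks, rhus) {
  tab <- table(factor(rhus$block_id, levels = blockIds(blocks)))
  stats::setNames(as.integer(tab), blockIds(blocks))
}

#' ABODE population of one area
#'
#' Implements `Pop_j = sum_i RHU_ij * f_i * pph_i` for one well area.  The
#' estimate excludes group-quarters populations by construction, so a
#' warning flag is raised whenever any intersected block houses
#' group-quarters persons.
#'
#' @param area a well-area record ([makeWellAreas()]).
#' @param blocks a [CensusBlocks-class].
#' @param rhus assigned RHU data.frame.
#' @param capped apply the block-level cap (default `TRUE`).
#' @param capMode `"scale"` multiplies RHU_ij by the block cap factor
#'   (preserves spatial pattern); `"hard"` truncates each area's per-block
#'   count at the block's census housing units.
#' @param blockRhuTotals optional precomputed block-wide RHU counts (named by
#'   block id) to avoid recounting per well.
#' @return list: `well_id`, `method`, `population`, `rhu_count` (uncapped),
#'   `gq_warning`.
#' @export
abodePopulation <- function(area, blocks, rhus, capped = TRUE,
                            capMode = c("scale", "hard"),
                            blockRhuTotals = NULL) {
  capMode <- match.arg(capMode)
  counts <- rhusInArea(area, rhus)
  pph <- stats::setNames(personsPerHousehold(blocks), blockIds(blocks))
  gq <- stats::setNames(groupQuartersPopulation(blocks), blockIds(blocks))
  hu <- stats::setNames(housingUnits(blocks), blockIds(blocks))
  interBlocks <- unique(c(names(counts), area$intersections$block_id))
  gqWarning <- length(interBlocks) > 0 && any(gq[interBlocks] > 0)
  if (!length(counts)) {
    return(list(well_id = area$well_id, method = if (capped) "abode_capped"
                else "abode_uncapped", population = 0, rhu_count = 0L,
                gq_warning = gqWarning))
  }
  eff <- as.numeric(counts)
  if (capped) {
    if (is.null(blockRhuTotals)) blockRhuTotals <- .blockRhuTotals(blocks, rhus)
    if (capMode == "scale") {
      f <- blockCapFactor(hu[names(counts)], blockRhuTotals[names(counts)])
      eff <- eff * f
    } else {
      eff <- pmin(eff, hu[names(counts)])
    }
  }
  list(well_id = area$well_id,
       method = if (capped) "abode_capped" else "abode_uncapped",
       population = sum(eff * pph[names(counts)]),
       rhu_count = sum(as.integer(counts)), gq_warning = gqWarning)
}

#' PPA population of an area
#'
#' Areal weighting: for every census block overlapping the area, the clipped
#' overlap area times the block's population density, summed over blocks.
#'
#' @param area a well-area record from [makeWellAreas()] (its precomputed
#'   intersections are used), or a bare [PlanarPolygon-class] which is then
#'   clipped against all blocks.
#' @param blocks a [CensusBlocks-class].
#' @param densityMode passed to [populationDensity()] (`"total"` includes
#'   group quarters, the standard census density; `"household"` excludes
#'   them).
#' @return list: `well_id` (or `NA` for a bare polygon), `method = "ppa"`,
#'   `population`, `rhu_count = NA`.
#' @export
ppaPopulation <- function(area, blocks, densityMode = c("total", "household")) {
  densityMode <- match.arg(densityMode)
  dens <- stats::setNames(populationDensity(blocks, densityMode),
                          blockIds(blocks))
  if (is(area, "PlanarPolygon")) {
    geoms <- geometries(blocks)
    ids <- blockIds(blocks)
    bb <- .bboxOf(area)
    pop <- 0
    for (k in seq_along(geoms)) {
      gb <- .bboxOf(geoms[[k]])
      if (gb["xmin"] > bb["xmax"] || bb["xmin"] > gb["xmax"] ||
          gb["ymin"] > bb["ymax"] || bb["ymin"] > gb["ymax"]) next
      a <- polygonArea(clipPolygons(geoms[[k]], area))
      pop <- pop + a * dens[k]
    }
    return(list(well_id = NA_character_, method = "ppa",
                population = unname(pop), rhu_count = NA_integer_))
  }
  inter <- area$intersections
  pop <- if (nrow(inter)) sum(inter$clipped_area * dens[inter$block_id]) else 0
  list(well_id = area$well_id, method = "ppa", population = unname(pop),
       rhu_count = NA_integer_)
}

#' Classify method agreement for one area
#'
#' The false-positive taxonomy: a zone with no physical housing units has a
#' true nighttime residential population of zero, so a positive PPA estimate
#' there is a confirmed false positive (low: at most one person; high: more
#' than one).  `other` (ABODE positive, PPA zero) closes the taxonomy.
#'
#' @param abode,ppa non-negative population estimates (vectorised).
#' @return character vector with levels `both_positive`, `both_zero`,
#'   `fp_low`, `fp_high`, `other`.
#' @export
classifyAgreement <- function(abode, ppa) {
  if (any(abode < 0) || any(ppa < 0))
    stop("negative population estimates")
  ifelse(abode == 0 & ppa == 0, "both_zero",
    ifelse(abode == 0 & ppa <= 1, "fp_low",
      ifelse(abode == 0, "fp_high",
        ifelse(ppa > 0, "both_positive", "other"))))
}

#' Per-well allocation under both methods
#'
#' Runs ABODE (capped and uncapped) and PPA for every well and classifies
#' the agreement.  Per-well rows use individual (possibly overlapping)
#' buffers; see [universeTotals()] for double-counting-free totals.
#'
#' @inheritParams makeWellAreas
#' @param rhus assigned RHU data.frame.
#' @param capMode,densityMode see [abodePopulation()], [ppaPopulation()].
#' @return data.frame: `well_id`, `state` (if present on `wells`),
#'   `radius_m`, `rhu_count`, `abode_capped`, `abode_uncapped`, `ppa`,
#'   `diff` (capped ABODE minus PPA), `agreement_class`, `gq_warning`.
#' @export
allocateWells <- function(wells, radius, blocks, rhus,
                          capMode = c("scale", "hard"),
                          densityMode = c("total", "household"),
                          nSegments = 64L) {
  capMode <- match.arg(capMode)
  densityMode <- match.arg(densityMode)
  areas <- makeWellAreas(wells, radius, blocks, nSegments)
  totals <- .blockRhuTotals(blocks, rhus)
  rows <- lapply(areas, function(a) {
    cap <- abodePopulation(a, blocks, rhus, capped = TRUE, capMode = capMode,
                           blockRhuTotals = totals)
    unc <- abodePopulation(a, blocks, rhus, capped = FALSE)
    ppa <- ppaPopulation(a, blocks, densityMode)
    data.frame(well_id = a$well_id, radius_m = radius,
               rhu_count = cap$rhu_count, abode_capped = cap$population,
               abode_uncapped = unc$population, ppa = ppa$population,
               diff = cap$population - ppa$population,
               agreement_class = classifyAgreement(cap$population,
                                                   ppa$population),
               gq_warning = cap$gq_warning, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(wells$state)) out <- cbind(state = wells$state, out)
  if (!is.null(wells$facility_id))
    out <- cbind(facility_id = wells$facility_id, out)
  out
}

#' Universe totals over the dissolved union of well areas
#'
#' State- and study-wide totals must not double count people where buffers
#' overlap: the well areas are dissolved into a disjoint union first.  For
#' PPA the dissolved union is intersected with the blocks and area-weighted;
#' for ABODE each housing unit is counted once no matter how many buffers
#' contain it.
#'
#' @inheritParams allocateWells
#' @return data.frame row: `well_id = "UNIVERSE"`, `rhu_count`,
#'   `abode_capped`, `abode_uncapped`, `ppa`, `gq_warning`.
#' @export
universeTotals <- function(wells, radius, blocks, rhus,
                           capMode = c("scale", "hard"),
                           densityMode = c("total", "household"),
                           nSegments = 64L) {
  capMode <- match.arg(capMode)
  densityMode <- match.arg(densityMode)
  buffers <- lapply(seq_len(nrow(wells)), function(i)
    bufferPoint(c(wells$x[i], wells$y[i]), radius, nSegments))
  dissolved <- dissolvePolygons(buffers)

  # ABODE: membership of each RHU in >= 1 well circle (counted once)
  inAny <- rep(FALSE, nrow(rhus))
  if (nrow(rhus)) {
    pts <- cbind(rhus$x, rhus$y)
    for (i in seq_len(nrow(wells))) {
      d2 <- (pts[, 1L] - wells$x[i])^2 + (pts[, 2L] - wells$y[i])^2
      inAny <- inAny | d2 <= radius^2
    }
  }
  sel <- inAny & !is.na(rhus$block_id)
  counts <- if (any(sel)) table(rhus$block_id[sel]) else NULL
  pph <- stats::setNames(personsPerHousehold(blocks), blockIds(blocks))
  hu <- stats::setNames(housingUnits(blocks), blockIds(blocks))
  totals <- .blockRhuTotals(blocks, rhus)
  gq <- stats::setNames(groupQuartersPopulation(blocks), blockIds(blocks))
  if (is.null(counts)) {
    abodeUnc <- 0; abodeCap <- 0; rhuCount <- 0L; gqWarn <- FALSE
  } else {
    ids <- names(counts)
    cnt <- as.numeric(counts)
    abodeUnc <- sum(cnt * pph[ids])
    effF <- if (capMode == "scale") cnt * blockCapFactor(hu[ids], totals[ids])
            else pmin(cnt, hu[ids])
    abodeCap <- sum(effF * pph[ids])
    rhuCount <- sum(as.integer(counts))
    gqWarn <- any(gq[ids] > 0)
  }

  # PPA over the dissolved union
  dens <- stats::setNames(populationDensity(blocks, densityMode),
                          blockIds(blocks))
  geoms <- geometries(blocks)
  ppaPop <- 0
  for (k in seq_along(geoms)) {
    gb <- .bboxOf(geoms[[k]])
    for (comp in dissolved) {
      cb <- .bboxOf(comp)
      if (gb["xmin"] > cb["xmax"] || cb["xmin"] > gb["xmax"] ||
          gb["ymin"] > cb["ymax"] || cb["ymin"] > gb["ymax"]) next
      a <- polygonArea(clipPolygons(geoms[[k]], comp))
      ppaPop <- ppaPop + a * dens[k]
    }
  }
  data.frame(well_id = "UNIVERSE", radius_m = radius, rhu_count = rhuCount,
             abode_capped = unname(abodeCap), abode_uncapped = unname(abodeUnc),
             ppa = unname(ppaPop), gq_warning = gqWarn,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Setback conflicts between wells and housing units
#'
#' For each well with an applicable state setback rule, counts the housing
#' units within the setback distance (boundary inclusive: a dwelling at
#' exactly the setback distance is a conflict) and estimates the setback
#' population under both methods.  Wells in states without a setback rule
#' (e.g. California) are skipped with a warning.
#'
#' @param wells data.frame with `well_id`, `x`, `y`, `state` and optionally
#'   `facility_id`.
#' @param setbackRules data.frame with columns `state`, `setback_ft`.
#' @param blocks a [CensusBlocks-class].
#' @param rhus assigned RHU data.frame.
#' @param capMode,densityMode,nSegments see [allocateWells()].
#' @return data.frame per well with an applicable rule: `well_id`, `state`,
#'   `facility_id` (if supplied), `setback_ft`, `setback_m`, `n_conflict`,
#'   `abode_capped`, `abode_uncapped`, `ppa`.
#' @export
setbackConflicts <- function(wells, setbackRules, blocks, rhus,
                             capMode = c("scale", "hard"),
                             densityMode = c("total", "household"),
                             nSegments = 64L) {
  capMode <- match.arg(capMode)
  densityMode <- match.arg(densityMode)
  if (any(setbackRules$setback_ft <= 0)) stop("setback distances must be > 0")
  ft <- stats::setNames(setbackRules$setback_ft, setbackRules$state)
  missing <- setdiff(unique(wells$state), names(ft))
  if (length(missing)) {
    warning("no setback rule for state(s): ",
            paste(missing, collapse = ", "), "; wells skipped")
    wells <- wells[!(wells$state %in% missing), , drop = FALSE]
  }
  if (!nrow(wells)) {
    return(data.frame(well_id = character(), state = character(),
                      setback_ft = numeric(), setback_m = numeric(),
                      n_conflict = integer(), abode_capped = numeric(),
                      abode_uncapped = numeric(), ppa = numeric(),
                      stringsAsFactors = FALSE))
  }
  totals <- .blockRhuTotals(blocks, rhus)
  rows <- lapply(seq_len(nrow(wells)), function(i) {
    sFt <- ft[[wells$state[i]]]
    sM <- feetToMetres(sFt)
    area <- makeWellAreas(wells[i, , drop = FALSE], sM, blocks,
                          nSegments)[[1L]]
    cap <- abodePopulation(area, blocks, rhus, capped = TRUE,
                           capMode = capMode, blockRhuTotals = totals)
    unc <- abodePopulation(area, blocks, rhus, capped = FALSE)
    ppa <- ppaPopulation(area, blocks, densityMode)
    nConf <- if (nrow(rhus)) {
      d <- sqrt((rhus$x - wells$x[i])^2 + (rhus$y - wells$y[i])^2)
      sum(d <= sM)
    } else 0L
    out <- data.frame(well_id = as.character(wells$well_id[i]),
                      state = wells$state[i], setback_ft = sFt,
                      setback_m = sM, n_conflict = as.integer(nConf),
                      abode_capped = cap$population,
                      abode_uncapped = unc$population,
                      ppa = ppa$population, stringsAsFactors = FALSE)
    if (!is.null(wells$facility_id)) out$facility_id <- wells$facility_id[i]
    out
  })
  do.call(rbind, rows)
}
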