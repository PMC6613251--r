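# From candidate points to residential housing units (RHUs): dasymetric
# censoring, manual-verification removals, and census-block assignment.
#
# Candidate and RHU tables are plain data.frames with columns
#   candidate_id, x, y, source, verified_removed
# (planar metres); assignment adds block_id.  Duplicate coordinates are
# legitimate: multi-unit buildings are represented by duplicate address
# points, each one housing unit.

.checkCandidates <- function(candidates) {
  need <- c("candidate_id", "x", "y")
  miss <- setdiff(need, names(candidates))
  if (length(miss))
    stop("candidate table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(candidates$candidate_id))
    stop("candidate_id values must be unique")
  if (!all(is.finite(candidates$x)) || !all(is.finite(candidates$y)))
    stop("non-finite candidate coordinates")
  invisible(candidates)
}

#' Censor non-residential candidate points
#'
#' Removes candidate dwelling points whose land-use cell is one of the
#' excluded (commercial / industrial / institutional) classes.  Points in
#' unknown land use (off-grid or NODATA) are retained by default -
#' precautionary over-inclusion, consistent with preferring to overestimate
#' the population at risk.  Duplicate coordinates survive censoring: each
#' duplicate is one housing unit in a multi-unit building.  Candidates with
#' `verified_removed = TRUE` are also dropped here.
#'
#' @param candidates candidate data.frame (see above).
#' @param grid a [LandUseGrid-class] with `excludedClasses` configured.
#' @param keepUnknown keep points whose class is unknown (default `TRUE`).
#' @param dedupeSources sources (e.g. `"building_centroid"`) for which exact
#'   coordinate duplicates are collapsed to one point, where duplication is a
#'   data artifact rather than a multi-unit building.
#' @return the retained rows, with a `land_use` column added; attribute
#'   `n_censored` records how many rows each rule removed.
#' @export
censorNonresidential <- function(candidates, grid, keepUnknown = TRUE,
                                 dedupeSources = character()) {
  .checkCandidates(candidates)
  stopifnot(is(grid, "LandUseGrid"))
  cls <- lookupLandUse(grid, cbind(candidates$x, candidates$y))
  candidates$land_use <- cls
  excluded <- !is.na(cls) & cls %in% grid@excludedClasses
  unknown <- is.na(cls)
  keep <- !excluded & (keepUnknown | !unknown)
  nVerified <- 0L
  if (!is.null(candidates$verified_removed)) {
    vr <- candidates$verified_removed %in% TRUE
    nVerified <- sum(vr & keep)
    keep <- keep & !vr
  }
  out <- candidates[keep, , drop = FALSE]
  nDeduped <- 0L
  if (length(dedupeSources) && nrow(out) && !is.null(out$source)) {
    inScope <- out$source %in% dedupeSources
    key <- paste(out$x, out$y, out$source)
    dup <- inScope & duplicated(key)
    nDeduped <- sum(dup)
    out <- out[!dup, , drop = FALSE]
  }
  attr(out, "n_censored") <- c(land_use = sum(excluded),
                               unknown = sum(!keepUnknown & unknown),
                               verified = nVerified, deduped = nDeduped)
  out
}

#' Apply manual-verification removals
#'
#' Visual verification against aerial imagery can only remove housing units
#' that do not represent an inhabitable structure - it never adds any, so the
#' output count is exactly the input count minus the number of removal ids.
#'
#' @param rhus RHU data.frame.
#' @param removalIds character ids to remove; every id must be present.
#' @return `rhus` without the listed rows.
#' @export
applyVerification <- function(rhus, removalIds) {
  removalIds <- as.character(removalIds)
  unknown <- setdiff(removalIds, rhus$candidate_id)
  if (length(unknown))
    stop("removal id(s) not present: ", paste(unknown, collapse = ", "))
  rhus[!(rhus$candidate_id %in% removalIds), , drop = FALSE]
}

#' Assign housing units to census blocks
#'
#' Each point is assigned to the census block containing it (boundary
#' inclusive).  A point on a shared block boundary is assigned to the block
#' with the lexicographically smallest `block_id` - a stable, reproducible
#' tie-break.  Points contained in no block get `block_id = NA` and are
#' excluded from allocation.
#'
#' @param rhus RHU data.frame with planar `x`, `y`.
#' @param blocks a [CensusBlocks-class].
#' @return `rhus` with a `block_id` column.
#' @export
assignBlocks <- function(rhus, blocks) {
  stopifnot(is(blocks, "CensusBlocks"))
  n <- nrow(rhus)
  ids <- blockIds(blocks)
  ord <- order(ids)  # visit in id order so the first hit is the tie-break
  assigned <- rep(NA_character_, n)
  if (n == 0L) {
    rhus$block_id <- character(0)
    return(rhus)
  }
  pts <- cbind(rhus$x, rhus$y)
  todo <- rep(TRUE, n)
  for (k in ord) {
    if (!any(todo)) break
    g <- geometries(blocks)[[k]]
    bb <- .bboxOf(g)
    cand <- which(todo & pts[, 1L] >= bb["xmin"] & pts[, 1L] <= bb["xmax"] &
                    pts[, 2L] >= bb["ymin"] & pts[, 2L] <= bb["ymax"])
    if (!length(cand)) next
    hit <- cand[containsPoint(g, pts[cand, , drop = FALSE])]
    assigned[hit] <- ids[k]
    todo[hit] <- FALSE
  }
  rhus$block_id <- assigned
  rhus
}

#' Full candidate-to-RHU pipeline step
#'
#' Convenience wrapper: censor against land use, apply manual removals,
#' assign blocks, and drop unassigned points, logging the count after each
#' stage.
#'
#' @param candidates candidate data.frame.
#' @param grid a [LandUseGrid-class].
#' @param blocks a [CensusBlocks-class].
#' @param removalIds manual-verification removal ids (may be empty).
#' @param keepUnknown,dedupeSources passed to [censorNonresidential()].
#' @return assigned RHU data.frame; attribute `counts` holds the candidate /
#'   censored / verified / assigned totals for the run log.
#' @export
buildRhus <- function(candidates, grid, blocks, removalIds = character(),
                      keepUnknown = TRUE, dedupeSources = character()) {
  censored <- censorNonresidential(candidates, grid, keepUnknown,
                                   dedupeSources)
  verified <- applyVerification(censored, removalIds)
  assigned <- assignBlocks(verified, blocks)
  kept <- assigned[!is.na(assigned$block_id), , drop = FALSE]
  attr(kept, "counts") <- c(candidates = nrow(candidates),
                            censored = nrow(censored),
                            verified = nrow(verified),
                            assigned = nrow(kept))
  kept
}
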