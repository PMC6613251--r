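# Pipeline orchestration: configuration, the full study run
# (project -> censor -> assign -> allocate -> totals -> metrics -> tables),
# and the report tables (state summary, top wells, setbacks).

#' Build a run configuration
#'
#' @param blocks,candidates,land_use,wells input file paths (GeoJSON / CSV /
#'   ESRI ASCII grid).  `land_use` may be `NULL` to skip dasymetric
#'   censoring.
#' @param setback_rules optional CSV path with columns `state`,
#'   `setback_ft`.
#' @param removals optional one-column CSV of manually removed candidate
#'   ids.
#' @param radius_m search radius in metres (default 200, the pipeline-
#'   hazard high-consequence distance).
#' @param cap_mode `"scale"` or `"hard"` (see [abodePopulation()]).
#' @param ppa_density `"total"` or `"household"` (see
#'   [populationDensity()]).
#' @param fb_standard use the conventional fractional bias (no leading 1/n).
#' @param excluded_classes integer land-use codes to censor.
#' @param keep_unknown retain candidates in unknown land use.
#' @param center_lon,center_lat optional projection centre; default is the
#'   midpoint of the block extent.  Must match the frame of `land_use`,
#'   which is already planar.
#' @param out output directory (`NULL` = return results only).
#' @param seed integer recorded in the manifest (the run itself is
#'   deterministic).
#' @param verbose print progress.
#' @return validated configuration list (class `"RunConfig"`).
#' @export
runConfig <- function(blocks, candidates, wells, land_use = NULL,
                      setback_rules = NULL, removals = NULL, radius_m = 200,
                      cap_mode = c("scale", "hard"),
                      ppa_density = c("total", "household"),
                      fb_standard = FALSE, excluded_classes = 2L,
                      keep_unknown = TRUE, center_lon = NULL,
                      center_lat = NULL, out = NULL, seed = 1L,
                      verbose = FALSE) {
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m <= 0)
    stop("radius_m must be a positive scalar")
  cfg <- list(blocks = blocks, candidates = candidates, wells = wells,
              land_use = land_use, setback_rules = setback_rules,
              removals = removals, radius_m = radius_m,
              cap_mode = match.arg(cap_mode),
              ppa_density = match.arg(ppa_density),
              fb_standard = isTRUE(fb_standard),
              excluded_classes = as.integer(excluded_classes),
              keep_unknown = isTRUE(keep_unknown),
              center_lon = center_lon, center_lat = center_lat,
              out = out, seed = as.integer(seed), verbose = isTRUE(verbose))
  for (f in c("blocks", "candidates", "wells"))
    if (!file.exists(cfg[[f]]))
      stop("input file for '", f, "' not found: ", cfg[[f]])
  for (f in c("land_use", "setback_rules", "removals"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file for '", f, "' not found: ", cfg[[f]])
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from a flat key=value (INI dialect) file
#'
#' Keys match the arguments of [runConfig()]; `#` starts a comment;
#' relative paths are resolved against the config file's directory.
#'
#' @param path config file path.
#' @param ... overrides passed straight to [runConfig()].
#' @return a `"RunConfig"`.
#' @export
readRunConfig <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- stats::setNames(lapply(kv, function(x)
    paste(x[-1L], collapse = "=")), vapply(kv, `[[`, "", 1L))
  numeric_keys <- c("radius_m", "center_lon", "center_lat", "seed")
  logical_keys <- c("fb_standard", "keep_unknown", "verbose")
  path_keys <- c("blocks", "candidates", "wells", "land_use",
                 "setback_rules", "removals", "out")
  base <- dirname(normalizePath(path))
  for (k in names(args)) {
    if (k %in% numeric_keys) args[[k]] <- as.numeric(args[[k]])
    if (k %in% logical_keys) args[[k]] <- toupper(args[[k]]) %in%
        c("TRUE", "1", "YES")
    if (k == "excluded_classes")
      args[[k]] <- as.integer(strsplit(args[[k]], "[,;[:space:]]+")[[1L]])
    if (k %in% path_keys && !grepl("^/", args[[k]]))
      args[[k]] <- file.path(base, args[[k]])
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(runConfig, args)
}

#' Run the full allocation study
#'
#' Executes the whole pipeline: read and project inputs, censor candidates
#' against land use, apply manual removals, assign housing units to blocks,
#' allocate per well under ABODE (capped and uncapped) and PPA, compute
#' dissolved-union universe totals (overall and per state), evaluation
#' metrics, and the report tables.  When `cfg$out` is set, CSV tables, a
#' JSON run manifest and a plain-text log are written there.
#'
#' @param cfg a `"RunConfig"` from [runConfig()] or [readRunConfig()].
#' @return list: `perWell`, `stateSummary`, `topWells`, `setbacks` (or
#'   `NULL`), `metrics` ([MetricsReport-class]), `universe`, `rhus`,
#'   `log` (character vector of step counts).
#' @export
runStudy <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (cfg$verbose) message(msg)
    log <<- c(log, msg)
  }

  spec <- if (!is.null(cfg$center_lon) && !is.null(cfg$center_lat))
    projectionSpec(cfg$center_lon, cfg$center_lat) else NULL
  blocks <- readCensusBlocksGeoJSON(cfg$blocks, spec)
  spec <- attr(blocks, "projection")
  say("read %d census blocks from %s", length(blocks), cfg$blocks)

  candidates <- readPoints(cfg$candidates, spec)
  if (is.null(candidates$candidate_id))
    candidates$candidate_id <- sprintf("c%06d", seq_len(nrow(candidates)))
  say("read %d candidate points from %s", nrow(candidates), cfg$candidates)

  wells <- readPoints(cfg$wells, spec)
  if (is.null(wells$well_id))
    wells$well_id <- sprintf("w%05d", seq_len(nrow(wells)))
  say("read %d wells from %s", nrow(wells), cfg$wells)

  removals <- if (!is.null(cfg$removals)) {
    r <- utils::read.csv(cfg$removals, stringsAsFactors = FALSE)
    as.character(r[[1L]])
  } else character()

  if (!is.null(cfg$land_use)) {
    grid <- readAsciiGrid(cfg$land_use, cfg$excluded_classes)
    rhus <- buildRhus(candidates, grid, blocks, removals,
                      keepUnknown = cfg$keep_unknown)
  } else {
    verified <- applyVerification(candidates, removals)
    assigned <- assignBlocks(verified, blocks)
    rhus <- assigned[!is.na(assigned$block_id), , drop = FALSE]
    attr(rhus, "counts") <- c(candidates = nrow(candidates),
                              censored = nrow(candidates),
                              verified = nrow(verified),
                              assigned = nrow(rhus))
  }
  cnt <- attr(rhus, "counts")
  say("candidates %d -> censored %d -> verified %d -> assigned %d",
      cnt[["candidates"]], cnt[["censored"]], cnt[["verified"]],
      cnt[["assigned"]])

  perWell <- allocateWells(wells, cfg$radius_m, blocks, rhus,
                           capMode = cfg$cap_mode,
                           densityMode = cfg$ppa_density)
  say("allocated %d wells at radius %g m", nrow(perWell), cfg$radius_m)

  universe <- universeTotals(wells, cfg$radius_m, blocks, rhus,
                             capMode = cfg$cap_mode,
                             densityMode = cfg$ppa_density)
  stateSummary <- summarizeByState(perWell, wells, blocks, rhus,
                                   cfg$radius_m, capMode = cfg$cap_mode,
                                   densityMode = cfg$ppa_density)
  topWells <- topWellsTable(perWell, min(10L, nrow(perWell)))
  metrics <- metricsReport(perWell$abode_capped, perWell$ppa,
                           agreement = perWell$agreement_class)

  setbacks <- NULL
  setbackSummary <- NULL
  if (!is.null(cfg$setback_rules)) {
    rules <- utils::read.csv(cfg$setback_rules, stringsAsFactors = FALSE)
    setbacks <- setbackConflicts(wells, rules, blocks, rhus,
                                 capMode = cfg$cap_mode,
                                 densityMode = cfg$ppa_density)
    setbackSummary <- setbackTable(setbacks, rules)
    say("setback conflicts computed for %d wells", nrow(setbacks))
  }

  res <- list(perWell = perWell, stateSummary = stateSummary,
              topWells = topWells, setbacks = setbacks,
              setbackSummary = setbackSummary, metrics = metrics,
              universe = universe, rhus = rhus, projection = spec,
              log = log)

  if (!is.null(cfg$out)) {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) utils::write.csv(
      df, file.path(cfg$out, name), row.names = FALSE)
    wr(perWell, "per_well.csv")
    wr(stateSummary, "state_summary.csv")
    wr(topWells, "top_wells.csv")
    if (!is.null(setbacks)) {
      wr(setbacks, "setback_conflicts.csv")
      wr(setbackSummary, "setback_summary.csv")
    }
    wr(data.frame(metric = c("fac2", "mape", "spearman_rho",
                             "fractional_bias", "wilcoxon_z", "wilcoxon_p"),
                  value = c(metrics@fac2, metrics@mape, metrics@spearmanRho,
                            metrics@fractionalBias, metrics@wilcoxonZ,
                            metrics@wilcoxonP)), "metrics.csv")
    manifest <- list(inputs = cfg[c("blocks", "candidates", "wells",
                                    "land_use", "setback_rules",
                                    "removals")],
                     config = cfg[c("radius_m", "cap_mode", "ppa_density",
                                    "fb_standard", "excluded_classes",
                                    "keep_unknown", "seed")],
                     projection = list(center_lon = spec@centerLon,
                                       center_lat = spec@centerLat),
                     package_version = as.character(
                       utils::packageVersion("abode")))
    jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log, file.path(cfg$out, "run.log"))
  }
  res
}

#' Append a total row with printed-value reconciliation
#'
#' Sums the named numeric columns over the rows and appends a `Total` row.
#' When published (printed) totals are supplied, each is compared with the
#' computed column sum and any disagreement is recorded in the `mismatches`
#' attribute - published tables do not always sum exactly, and silently
#' reproducing a printed total would hide that.
#'
#' @param df data.frame of per-stratum rows.
#' @param labelCol name of the stratum column to carry the `"Total"` label.
#' @param cols numeric columns to sum (default: all numeric columns).
#' @param printed optional named vector of published totals to reconcile.
#' @return `df` with a total row appended; attribute `mismatches` is a named
#'   list of `c(computed, printed)` pairs for columns that disagree.
#' @export
addTotalRow <- function(df, labelCol, cols = NULL, printed = NULL) {
  if (is.null(cols))
    cols <- names(df)[vapply(df, is.numeric, logical(1))]
  tot <- df[1L, , drop = FALSE]
  for (nm in names(tot)) tot[[nm]] <- NA
  tot[[labelCol]] <- "Total"
  for (nm in cols) tot[[nm]] <- sum(df[[nm]], na.rm = TRUE)
  out <- rbind(df, tot)
  mism <- list()
  if (!is.null(printed)) {
    for (nm in intersect(names(printed), cols)) {
      if (!isTRUE(all.equal(unname(printed[[nm]]), tot[[nm]])))
        mism[[nm]] <- c(computed = tot[[nm]],
                        printed = unname(printed[[nm]]))
    }
  }
  attr(out, "mismatches") <- mism
  out
}

#' State-level summary of population at risk
#'
#' One row per state: wells with at least one housing unit in range (count
#' and integer percent), dissolved-union housing-unit and population totals
#' under each method, and the per-well Wilcoxon signed-rank comparison of
#' capped ABODE against PPA.  The total row re-aggregates across all states
#' with the same dissolved-union logic (it is not the sum of the state rows
#' wherever well areas cross state lines).
#'
#' @param perWell per-well results from [allocateWells()].
#' @param wells wells data.frame (with `state`).
#' @param blocks a [CensusBlocks-class].
#' @param rhus assigned RHU data.frame.
#' @param radius radius in metres.
#' @param capMode,densityMode estimator options.
#' @return data.frame with columns `state`, `wells`, `wells_with_rhu`,
#'   `pct_with_rhu`, `uncapped_rhus`, `par_ppa`, `par_abode_capped`,
#'   `par_abode_uncapped`, `wilcoxon_z`, `wilcoxon_p`; last row is the
#'   all-state total.  Attribute `column_sums` holds the plain sums of the
#'   state rows for reconciliation with the dissolved total row.
#' @export
summarizeByState <- function(perWell, wells, blocks, rhus, radius,
                             capMode = c("scale", "hard"),
                             densityMode = c("total", "household")) {
  capMode <- match.arg(capMode)
  densityMode <- match.arg(densityMode)
  if (is.null(wells$state)) wells$state <- "ALL"
  if (is.null(perWell$state))
    perWell$state <- wells$state[match(perWell$well_id, wells$well_id)]
  states <- sort(unique(wells$state))
  oneRow <- function(w, pw, label) {
    uni <- universeTotals(w, radius, blocks, rhus, capMode = capMode,
                          densityMode = densityMode)
    wt <- wilcoxonSignedRank(pw$abode_capped, pw$ppa)
    data.frame(state = label, wells = nrow(w),
               wells_with_rhu = sum(pw$rhu_count > 0),
               pct_with_rhu = round(100 * sum(pw$rhu_count > 0) / nrow(w)),
               uncapped_rhus = uni$rhu_count, par_ppa = uni$ppa,
               par_abode_capped = uni$abode_capped,
               par_abode_uncapped = uni$abode_uncapped,
               wilcoxon_z = wt$z, wilcoxon_p = wt$p,
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(states, function(s)
    oneRow(wells[wells$state == s, , drop = FALSE],
           perWell[perWell$state == s, , drop = FALSE], s)))
  total <- oneRow(wells, perWell, "Total")
  out <- rbind(rows, total)
  attr(out, "column_sums") <- colSums(rows[, c("wells", "wells_with_rhu",
                                               "uncapped_rhus", "par_ppa",
                                               "par_abode_capped",
                                               "par_abode_uncapped")])
  out
}

#' Top wells ranked by capped-ABODE population at risk
#'
#' @param perWell per-well results from [allocateWells()].
#' @param k number of rows to return; when `k` exceeds the number of wells
#'   all rows are returned with a warning.
#' @return ranked data.frame: rank, well id (ties in the ABODE estimate are
#'   broken by well id for a deterministic order), housing units, capped
#'   ABODE, PPA, the ABODE - PPA difference, and each well's rank under
#'   PPA.
#' @export
topWellsTable <- function(perWell, k = 10L) {
  if (k > nrow(perWell)) {
    warning("k = ", k, " exceeds ", nrow(perWell), " wells; returning all")
    k <- nrow(perWell)
  }
  ppaRank <- rank(-perWell$ppa, ties.method = "min")
  ord <- order(-perWell$abode_capped, perWell$well_id)
  sel <- ord[seq_len(k)]
  out <- data.frame(rank = seq_len(k), well_id = perWell$well_id[sel],
                    stringsAsFactors = FALSE)
  if (!is.null(perWell$state)) out$state <- perWell$state[sel]
  out$rhus <- perWell$rhu_count[sel]
  out$par_abode_capped <- perWell$abode_capped[sel]
  out$par_ppa <- perWell$ppa[sel]
  out$par_difference <- perWell$abode_capped[sel] - perWell$ppa[sel]
  out$ppa_par_rank <- ppaRank[sel]
  out
}

#' State-level setback-conflict table
#'
#' One row per state with an applicable setback rule: the facilities and
#' wells with at least one housing unit inside the setback distance, the
#' housing units inside setbacks, and the setback-area population under
#' both methods; plus a column-sum total row.
#'
#' @param conflicts per-well records from [setbackConflicts()].
#' @param setbackRules data.frame `state`, `setback_ft`.
#' @return data.frame with a `Total` row (via [addTotalRow()]).
#' @export
setbackTable <- function(conflicts, setbackRules) {
  states <- sort(unique(setbackRules$state))
  rows <- lapply(states, function(s) {
    c1 <- conflicts[conflicts$state == s, , drop = FALSE]
    hit <- c1[c1$n_conflict > 0, , drop = FALSE]
    data.frame(state = s,
               setback_ft = setbackRules$setback_ft[
                 match(s, setbackRules$state)],
               facilities_with_conflict = if (!is.null(hit$facility_id))
                 length(unique(hit$facility_id)) else NA_integer_,
               wells_with_conflict = nrow(hit),
               rhus_within_setback = sum(c1$n_conflict),
               par_ppa = sum(c1$ppa),
               par_abode = sum(c1$abode_capped), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  addTotalRow(df, "state",
              cols = c("facilities_with_conflict", "wells_with_conflict",
                       "rhus_within_setback", "par_ppa", "par_abode"))
}

#' Write a synthetic region to pipeline input files
#'
#' Writes the blocks (GeoJSON), candidates and wells (CSV with lon/lat),
#' land use (ESRI ASCII grid, planar frame of the anchor projection), truth
#' table, and a small JSON manifest recording the anchor projection centre
#' and seed, so that a [runStudy()] on the files reproduces the in-memory
#' scenario.
#'
#' @param region result of [generateRegion()].
#' @param dir output directory (created if needed).
#' @param anchor [ProjectionSpec-class] giving the geographic anchor of the
#'   planar frame (default centres the region near 40.9 N, 81.5 W).
#' @return named character vector of file paths, invisibly.
#' @export
writeRegionFiles <- function(region, dir,
                             anchor = projectionSpec(-81.5, 40.9)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(blocks = file.path(dir, "blocks.geojson"),
             candidates = file.path(dir, "candidates.csv"),
             wells = file.path(dir, "wells.csv"),
             land_use = file.path(dir, "landuse.asc"),
             truth = file.path(dir, "truth.csv"),
             manifest = file.path(dir, "region.json"))
  writeCensusBlocksGeoJSON(region$blocks, paths[["blocks"]], anchor)
  writePointsCSV(region$candidates, paths[["candidates"]], anchor)
  writePointsCSV(region$wells, paths[["wells"]], anchor)
  writeAsciiGrid(region$landUse, paths[["land_use"]])
  utils::write.csv(region$truth, paths[["truth"]], row.names = FALSE)
  jsonlite::write_json(list(center_lon = anchor@centerLon,
                            center_lat = anchor@centerLat,
                            seed = region$config$seed),
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
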