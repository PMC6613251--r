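# Seeded synthetic study region: jittered-grid census blocks, household
# points (uniform or clustered along block boundaries, the roadway pattern
# that stresses areal weighting), multi-unit duplicate points,
# non-residential contaminant points in commercial land-use cells, wells,
# and a per-dwelling ground truth for estimator validation.

#' Scenario configuration for the synthetic region
#'
#' All lengths are metres.  Defaults describe a suburban-to-exurban region:
#' 500 m blocks, ~40 housing units per block with strong overdispersion
#' across blocks, mean household size 2.5, homes strung within 30 m of
#' block-edge roads, occasional multi-unit buildings and non-residential
#' contaminant addresses.
#'
#' @param nx,ny number of blocks per axis.
#' @param blockSize nominal block edge length (m).
#' @param boundaryJitter corner jitter as a fraction of `blockSize`
#'   (interior grid corners are displaced up to half this fraction each way,
#'   so blocks stay simple polygons that tile without gaps).
#' @param meanHuPerBlock,huDispersion negative-binomial mean and size for
#'   per-block housing-unit counts (overdispersed across blocks).
#' @param householdSizeMean,householdSizeSd household size distribution:
#'   rounded normal truncated below at 1 person.  `householdSizeSd = 0`
#'   gives a constant household size (used for exact-recovery checks).
#' @param gqFraction probability a block hosts a group-quarters facility.
#' @param gqMean mean group-quarters population where present (Poisson).
#' @param placement `"uniform"` or `"boundary_clustered"` (within
#'   `boundaryBandwidth` of a block edge).
#' @param boundaryBandwidth roadway bandwidth for clustered placement (m).
#' @param multiunitRate probability a housing unit shares the coordinates of
#'   an earlier unit in its block (duplicate address point = multi-unit
#'   building).
#' @param nonresidentialRate contaminant (non-residential address) count as
#'   a fraction of total housing units; contaminants are placed in
#'   commercial land-use cells and carry zero persons in the truth table.
#' @param commercialCellFraction fraction of land-use cells marked
#'   commercial; chosen among cells containing no housing unit so that
#'   dasymetric censoring removes contaminants and nothing else.
#' @param cellSize land-use cell size (m).
#' @param nWells number of wells.
#' @param wellPlacement `"uniform"` or `"near_boundary"` (wells biased to
#'   within `boundaryBandwidth` of block edges, the adversarial case for
#'   areal weighting).
#' @param nStates number of states (vertical strips of blocks and wells).
#' @param seed integer seed; the whole region is a deterministic function of
#'   the configuration.
#' @return validated configuration list (class `"ScenarioConfig"`).
#' @export
scenarioConfig <- function(nx = 8L, ny = 8L, blockSize = 500,
                           boundaryJitter = 0.15, meanHuPerBlock = 40,
                           huDispersion = 5, householdSizeMean = 2.5,
                           householdSizeSd = 1.2, gqFraction = 0.05,
                           gqMean = 30, placement = c("boundary_clustered",
                                                      "uniform"),
                           boundaryBandwidth = 30, multiunitRate = 0.1,
                           nonresidentialRate = 0.05,
                           commercialCellFraction = 0.05, cellSize = 30,
                           nWells = 50L, wellPlacement = c("uniform",
                                                           "near_boundary"),
                           nStates = 1L, seed = 1L) {
  placement <- match.arg(placement)
  wellPlacement <- match.arg(wellPlacement)
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny),
              blockSize = blockSize, boundaryJitter = boundaryJitter,
              meanHuPerBlock = meanHuPerBlock, huDispersion = huDispersion,
              householdSizeMean = householdSizeMean,
              householdSizeSd = householdSizeSd, gqFraction = gqFraction,
              gqMean = gqMean, placement = placement,
              boundaryBandwidth = boundaryBandwidth,
              multiunitRate = multiunitRate,
              nonresidentialRate = nonresidentialRate,
              commercialCellFraction = commercialCellFraction,
              cellSize = cellSize, nWells = as.integer(nWells),
              wellPlacement = wellPlacement, nStates = as.integer(nStates),
              seed = as.integer(seed))
  for (f in c("nx", "ny", "blockSize", "cellSize", "nWells", "huDispersion",
              "meanHuPerBlock", "householdSizeMean", "nStates"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop("invalid scenario field: ", f)
  for (f in c("boundaryJitter", "gqFraction", "multiunitRate",
              "nonresidentialRate", "commercialCellFraction"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid scenario field (rate outside [0,1]): ", f)
  if (cfg$householdSizeSd < 0) stop("invalid scenario field: householdSizeSd")
  if (cfg$boundaryBandwidth <= 0)
    stop("invalid scenario field: boundaryBandwidth")
  structure(cfg, class = "ScenarioConfig")
}

.distToRing <- function(pts, ring) {
  # minimum distance from points to the closed ring's edges
  n <- nrow(ring) - 1L
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- pmin(1, pmax(0, ((pts[, 1L] - a[1L]) * ab[1L] +
                            (pts[, 2L] - a[2L]) * ab[2L]) / len2))
    dx <- pts[, 1L] - (a[1L] + t * ab[1L])
    dy <- pts[, 2L] - (a[2L] + t * ab[2L])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

.samplePointsInRing <- function(n, ring, bandwidth = NULL) {
  # rejection sampling from the ring's bounding box; when a bandwidth is
  # given, additionally require proximity to the ring boundary (roadway
  # clustering)
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  xr <- range(ring[, 1L]); yr <- range(ring[, 2L])
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    m <- max(32L, 4L * (n - got))
    cand <- cbind(stats::runif(m, xr[1L], xr[2L]),
                  stats::runif(m, yr[1L], yr[2L]))
    code <- sp::point.in.polygon(cand[, 1L], cand[, 2L], ring[, 1L],
                                 ring[, 2L])
    ok <- code == 1L
    if (!is.null(bandwidth))
      ok <- ok & .distToRing(cand, ring) <= bandwidth
    take <- which(ok)[seq_len(min(sum(ok), n - got))]
    if (length(take)) {
      out[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
  }
  out
}

#' Generate a synthetic study region
#'
#' Deterministic given the configuration seed.  The draw order is fixed:
#' corner jitter, per-block housing-unit counts, per-block point placement
#' and multi-unit duplication, household sizes, group quarters, commercial
#' cells, contaminant points, wells.
#'
#' @param cfg a [scenarioConfig()] configuration.
#' @return list with elements `blocks` ([CensusBlocks-class], planar),
#'   `candidates` (data.frame `candidate_id`, `x`, `y`, `source`,
#'   `verified_removed`), `landUse` ([LandUseGrid-class], class 1 =
#'   residential, 2 = commercial/excluded), `wells` (data.frame `well_id`,
#'   `facility_id`, `state`, `x`, `y`) and `truth` (data.frame
#'   `candidate_id`, `x`, `y`, `persons`; contaminants carry 0 persons).
#' @export
generateRegion <- function(cfg) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  })
  set.seed(cfg$seed)

  s <- cfg$blockSize
  nx <- cfg$nx; ny <- cfg$ny
  # lattice corners with jitter on interior nodes only: blocks tile exactly
  gx <- outer(0:nx * s, rep(1, ny + 1L))
  gy <- outer(rep(1, nx + 1L), 0:ny * s)
  jx <- matrix(stats::runif((nx + 1L) * (ny + 1L), -0.5, 0.5), nx + 1L) *
    cfg$boundaryJitter * s
  jy <- matrix(stats::runif((nx + 1L) * (ny + 1L), -0.5, 0.5), nx + 1L) *
    cfg$boundaryJitter * s
  jx[c(1L, nx + 1L), ] <- 0; jx[, c(1L, ny + 1L)] <- 0
  jy[c(1L, nx + 1L), ] <- 0; jy[, c(1L, ny + 1L)] <- 0
  gx <- gx + jx; gy <- gy + jy

  geoms <- vector("list", nx * ny)
  ids <- character(nx * ny)
  k <- 0L
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    k <- k + 1L
    ring <- rbind(c(gx[ix, iy], gy[ix, iy]),
                  c(gx[ix + 1L, iy], gy[ix + 1L, iy]),
                  c(gx[ix + 1L, iy + 1L], gy[ix + 1L, iy + 1L]),
                  c(gx[ix, iy + 1L], gy[ix, iy + 1L]))
    geoms[[k]] <- planarPolygon(rbind(ring, ring[1L, ]))
    ids[k] <- sprintf("B%02d_%02d", ix, iy)
  }

  huCounts <- stats::rnbinom(nx * ny, size = cfg$huDispersion,
                             mu = cfg$meanHuPerBlock)

  ptList <- vector("list", nx * ny)
  band <- if (cfg$placement == "boundary_clustered") cfg$boundaryBandwidth
  for (k in seq_len(nx * ny)) {
    ring <- geoms[[k]]@rings[[1L]]
    pts <- .samplePointsInRing(huCounts[k], ring, band)
    if (huCounts[k] >= 2L && cfg$multiunitRate > 0) {
      for (u in 2:huCounts[k]) {
        if (stats::runif(1) < cfg$multiunitRate) {
          src <- sample.int(u - 1L, 1L)
          pts[u, ] <- pts[src, ]
        }
      }
    }
    ptList[[k]] <- pts
  }

  nHu <- sum(huCounts)
  sizes <- if (cfg$householdSizeSd == 0) {
    rep(max(1, round(cfg$householdSizeMean)), nHu)
  } else {
    pmax(1, round(stats::rnorm(nHu, cfg$householdSizeMean,
                               cfg$householdSizeSd)))
  }
  blockOfHu <- rep(seq_len(nx * ny), huCounts)
  hhPop <- vapply(seq_len(nx * ny),
                  function(k) sum(sizes[blockOfHu == k]), numeric(1))
  gqPop <- ifelse(stats::runif(nx * ny) < cfg$gqFraction,
                  stats::rpois(nx * ny, cfg$gqMean), 0)

  blocks <- censusBlocks(geoms, ids, totalPopulation = hhPop + gqPop,
                         groupQuartersPopulation = gqPop,
                         housingUnits = huCounts)

  # land-use grid over the exact region extent
  ncols <- ceiling(nx * s / cfg$cellSize)
  nrows <- ceiling(ny * s / cfg$cellSize)
  classes <- matrix(1L, nrows, ncols)
  huPts <- do.call(rbind, ptList)
  if (cfg$commercialCellFraction > 0) {
    col <- floor(huPts[, 1L] / cfg$cellSize) + 1L
    row <- floor(huPts[, 2L] / cfg$cellSize) + 1L
    occupied <- unique((col - 1L) * nrows + row)
    free <- setdiff(seq_len(nrows * ncols), occupied)
    nCom <- min(length(free),
                round(cfg$commercialCellFraction * nrows * ncols))
    com <- sample(free, nCom)
    classes[cbind(((com - 1L) %% nrows) + 1L, ((com - 1L) %/% nrows) + 1L)] <- 2L
  }
  grid <- landUseGrid(0, 0, cfg$cellSize, classes, excludedClasses = 2L)

  # contaminant (non-residential) candidate points inside commercial cells
  nCon <- round(cfg$nonresidentialRate * nHu)
  conPts <- matrix(numeric(0), ncol = 2L)
  comCells <- which(classes == 2L, arr.ind = TRUE)
  if (nCon > 0L && nrow(comCells)) {
    pick <- comCells[sample.int(nrow(comCells), nCon, replace = TRUE), ,
                     drop = FALSE]
    conPts <- cbind((pick[, 2L] - 1L + stats::runif(nCon)) * cfg$cellSize,
                    (pick[, 1L] - 1L + stats::runif(nCon)) * cfg$cellSize)
    # keep contaminants strictly inside their (HU-free) cell
  } else if (nCon > 0L) {
    nCon <- 0L
  }

  candId <- sprintf("C%06d", seq_len(nHu + nCon))
  candidates <- data.frame(
    candidate_id = candId,
    x = c(huPts[, 1L], conPts[, 1L]),
    y = c(huPts[, 2L], conPts[, 2L]),
    source = rep(c("address", "address"), c(nHu, nCon)),
    verified_removed = FALSE, stringsAsFactors = FALSE)
  truth <- data.frame(candidate_id = candId,
                      x = candidates$x, y = candidates$y,
                      persons = c(sizes, rep(0, nCon)),
                      stringsAsFactors = FALSE)

  # wells
  regionRing <- rbind(c(0, 0), c(nx * s, 0), c(nx * s, ny * s),
                      c(0, ny * s), c(0, 0))
  if (cfg$wellPlacement == "uniform") {
    wx <- stats::runif(cfg$nWells, 0, nx * s)
    wy <- stats::runif(cfg$nWells, 0, ny * s)
  } else {
    wpts <- matrix(NA_real_, cfg$nWells, 2L)
    got <- 0L
    while (got < cfg$nWells) {
      m <- 4L * (cfg$nWells - got) + 32L
      cand <- cbind(stats::runif(m, 0, nx * s), stats::runif(m, 0, ny * s))
      near <- rep(FALSE, m)
      for (k in seq_len(nx * ny)) {
        ring <- geoms[[k]]@rings[[1L]]
        inBlk <- sp::point.in.polygon(cand[, 1L], cand[, 2L], ring[, 1L],
                                      ring[, 2L]) == 1L
        if (any(inBlk & !near))
          near[inBlk & !near] <-
            .distToRing(cand[inBlk & !near, , drop = FALSE],
                        ring) <= cfg$boundaryBandwidth
      }
      take <- which(near)[seq_len(min(sum(near), cfg$nWells - got))]
      if (length(take)) {
        wpts[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
    wx <- wpts[, 1L]; wy <- wpts[, 2L]
  }
  stateOf <- function(x) sprintf("S%d", pmin(cfg$nStates,
                                             floor(x / (nx * s) *
                                                     cfg$nStates) + 1L))
  wells <- data.frame(well_id = sprintf("W%04d", seq_len(cfg$nWells)),
                      facility_id = sprintf("F%03d",
                                            ((seq_len(cfg$nWells) - 1L) %/%
                                               5L) + 1L),
                      state = stateOf(wx), x = wx, y = wy,
                      stringsAsFactors = FALSE)

  list(blocks = blocks, candidates = candidates, landUse = grid,
       wells = wells, truth = truth, config = cfg)
}

#' Ground-truth population of an area
#'
#' Exact sum of persons over the synthetic household points inside or on
#' the area: the oracle the estimators are validated against.
#'
#' @param truth truth data.frame from [generateRegion()].
#' @param area a [PlanarPolygon-class], or a list with `center` and `radius`
#'   for the exact-circle test.
#' @return persons (exact).
#' @export
truthPopulation <- function(truth, area) {
  if (!nrow(truth)) return(0)
  pts <- cbind(truth$x, truth$y)
  inside <- if (is(area, "PlanarPolygon")) containsPoint(area, pts)
  else sqrt((pts[, 1L] - area$center[1L])^2 +
              (pts[, 2L] - area$center[2L])^2) <= area$radius
  sum(truth$persons[inside])
}
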