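# Gridded land-use model and the dasymetric censoring step: candidate
# dwelling points in built-up commercial / industrial / institutional cells
# are not residential housing units and are removed before allocation.

#' Construct a land-use grid
#'
#' @param originX,originY lower-left corner of the grid (planar metres).
#' @param cellSize cell edge length in metres (30 in the source land-use
#'   model).
#' @param classes integer matrix of land-use class codes; row 1 is the
#'   southernmost row, column 1 the westernmost column.  `NA` = NODATA.
#' @param excludedClasses integer class codes to censor as non-residential.
#'   The code list is configuration, not logic: supply whatever codes your
#'   classification scheme uses for commercial/industrial/institutional use.
#' @return a [LandUseGrid-class].
#' @export
landUseGrid <- function(originX, originY, cellSize, classes,
                        excludedClasses = integer()) {
  m <- as.matrix(classes)
  storage.mode(m) <- "integer"
  new("LandUseGrid", originX = as.numeric(originX),
      originY = as.numeric(originY), cellSize = as.numeric(cellSize),
      classes = m, excludedClasses = as.integer(excludedClasses))
}

setMethod("show", "LandUseGrid", function(object) {
  cat(sprintf(
    "LandUseGrid: %d x %d cells of %g m, origin (%g, %g), %d excluded class(es)\n",
    ncol(object@classes), nrow(object@classes), object@cellSize,
    object@originX, object@originY, length(object@excludedClasses)))
})

#' Look up land-use classes at points
#'
#' Cells are half-open (`[x0 + (j-1)s, x0 + j s)` and likewise in y), so a
#' point on a shared cell edge belongs to the lower-index cell and every
#' in-extent point maps to exactly one cell.  Points outside the grid extent
#' (and NODATA cells) return `NA`, the "unknown" class.
#'
#' @param grid a [LandUseGrid-class].
#' @param points two-column matrix of planar coordinates.
#' @return integer vector of class codes, `NA` for unknown.
#' @export
lookupLandUse <- function(grid, points) {
  stopifnot(is(grid, "LandUseGrid"))
  p <- .asCoordMatrix(points)
  col <- floor((p[, 1L] - grid@originX) / grid@cellSize) + 1
  row <- floor((p[, 2L] - grid@originY) / grid@cellSize) + 1
  ok <- col >= 1 & col <= ncol(grid@classes) &
    row >= 1 & row <= nrow(grid@classes)
  out <- rep(NA_integer_, nrow(p))
  out[ok] <- grid@classes[cbind(row[ok], col[ok])]
  out
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by rows of class codes, the first file row being the
#' northernmost.
#'
#' @param path file path.
#' @param excludedClasses integer codes to censor (stored on the grid).
#' @return a [LandUseGrid-class].
#' @export
readAsciiGrid <- function(path, excludedClasses = integer()) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ASCII grid header missing: ", paste(miss, collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # file top row = north
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  landUseGrid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, m, excludedClasses)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [LandUseGrid-class].
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999L) {
  m <- grid@classes
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid@originX),
           sprintf("yllcorner %.10g", grid@originY),
           sprintf("cellsize %.10g", grid@cellSize),
           sprintf("NODATA_value %d", nodata))
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1L, paste,
                collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
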