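# Local Lambert azimuthal equal-area projection on the authalic sphere.
# Equal-area is non-negotiable here: PPA weights population by intersected
# area, so an area-distorting projection would bias the estimator itself.

.AUTHALIC_RADIUS <- 6371007.181  # metres

#' Metres per foot (exact)
#'
#' Setback distances are legislated in feet (100-300 ft); all internal
#' lengths are metres.  1 ft = 0.3048 m exactly.
#' @export
FT_PER_M <- 0.3048

#' Convert feet to metres
#'
#' @param ft distance in feet.
#' @return distance in metres (exact conversion, 1 ft = 0.3048 m).
#' @examples
#' feetToMetres(200)  # 60.96 m, the PA/WV setback radius
#' @export
feetToMetres <- function(ft) ft * FT_PER_M

#' Construct a projection specification
#'
#' @param centerLon,centerLat projection centre in decimal degrees (WGS84).
#'   Place the centre inside the study region; distance distortion grows with
#'   distance from the centre (< 0.5 percent within ~300 km).
#' @return a [ProjectionSpec-class] object.
#' @examples
#' projectionSpec(-81.4, 40.8)
#' @export
projectionSpec <- function(centerLon, centerLat) {
  new("ProjectionSpec", centerLon = as.numeric(centerLon),
      centerLat = as.numeric(centerLat))
}

.asCoordMatrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, 1:2])
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = FALSE)
  storage.mode(points) <- "double"
  points
}

#' Project geographic coordinates to the local planar frame
#'
#' Forward Lambert azimuthal equal-area projection: longitude/latitude
#' degrees to planar metres with the projection centre at the origin.
#'
#' @param points two-column matrix or data.frame of (lon, lat) in degrees.
#' @param spec a [ProjectionSpec-class].
#' @return two-column matrix of planar (x, y) metres, attribute
#'   `frame = "planar"`.
#' @examples
#' sp <- projectionSpec(0, 45)
#' projectPoints(cbind(0, 45), sp)       # the centre maps to (0, 0)
#' @export
projectPoints <- function(points, spec) {
  stopifnot(is(spec, "ProjectionSpec"))
  validObject(spec)
  p <- .asCoordMatrix(points)
  bad <- which(!is.finite(p[, 1L]) | !is.finite(p[, 2L]))
  if (length(bad))
    stop("non-finite coordinates at point index ", paste(bad, collapse = ", "))
  bad <- which(abs(p[, 2L]) > 90)
  if (length(bad))
    stop("latitude outside [-90, 90] at point index ",
         paste(bad, collapse = ", "))
  lam <- (p[, 1L] - spec@centerLon) * pi / 180
  phi <- p[, 2L] * pi / 180
  phi0 <- spec@centerLat * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  if (any(denom <= 1e-12))
    stop("point antipodal to projection centre")
  k <- sqrt(2 / denom)
  out <- cbind(x = .AUTHALIC_RADIUS * k * cos(phi) * sin(lam),
               y = .AUTHALIC_RADIUS * k *
                 (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam)))
  attr(out, "frame") <- "planar"
  out
}

#' Inverse of [projectPoints()]
#'
#' @param points two-column matrix of planar (x, y) metres.
#' @param spec a [ProjectionSpec-class].
#' @return two-column matrix of (lon, lat) degrees.
#' @export
unprojectPoints <- function(points, spec) {
  stopifnot(is(spec, "ProjectionSpec"))
  p <- .asCoordMatrix(points)
  R <- .AUTHALIC_RADIUS
  rho <- sqrt(p[, 1L]^2 + p[, 2L]^2)
  c0 <- 2 * asin(pmin(1, rho / (2 * R)))
  phi0 <- spec@centerLat * pi / 180
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(c0) * sin(phi0) + p[, 2L] * sin(c0) * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, 0,
                atan2(p[, 1L] * sin(c0),
                      rho * cos(phi0) * cos(c0) - p[, 2L] * sin(phi0) * sin(c0)))
  out <- cbind(lon = spec@centerLon + lam * 180 / pi, lat = phi * 180 / pi)
  attr(out, "frame") <- "geographic"
  out
}

#' Choose a projection centre from data extents
#'
#' Centres the local equal-area frame on the midpoint of the combined
#' longitude/latitude bounding box of the supplied coordinate sets.
#'
#' @param ... two-column (lon, lat) matrices or data.frames.
#' @return a [ProjectionSpec-class] centred on the pooled bounding box.
#' @export
autoProjection <- function(...) {
  mats <- lapply(list(...), .asCoordMatrix)
  all <- do.call(rbind, mats)
  projectionSpec(mean(range(all[, 1L])), mean(range(all[, 2L])))
}
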