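## Spherical geometry primitives. All distances are great-circle on a sphere
## of radius 6371.0088 km; every threshold in the pipeline is tens of km, so
## the < 0.5% sphere-vs-ellipsoid error is immaterial.

.EARTH_RADIUS_KM <- 6371.0088

#' Normalise longitudes to (-180, 180]
#' @param lon numeric vector of longitudes in degrees.
#' @return numeric vector in (-180, 180].
#' @export
normalizeLon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorised and
#' safe across the antimeridian (relevant for East Russian Arctic tracks).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (recycled).
#' @return distance(s) in km.
#' @examples
#' gcDistKm(0, 0, 0, 1)  # one degree of equatorial arc, 111.195 km
#' @export
gcDistKm <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_KM)
}

#' Ground speed between two fixes
#'
#' @param lat1,lon1,t1 position and POSIXct time of the earlier fix.
#' @param lat2,lon2,t2 position and time of the later fix; must be strictly
#'   after \code{t1}.
#' @return speed in km/h.
#' @export
groundSpeedKmh <- function(lat1, lon1, t1, lat2, lon2, t2) {
  dtH <- as.numeric(difftime(t2, t1, units = "hours"))
  if (any(dtH <= 0))
    stop("ground speed requires strictly increasing timestamps")
  gcDistKm(lat1, lon1, lat2, lon2) / dtH
}

#' Per-fix ground speed along a trajectory
#'
#' Speed of each fix over its preceding segment; the first fix takes the
#' speed of its following segment so that every fix has a defined speed.
#'
#' @param timestamp POSIXct vector (strictly increasing).
#' @param lat,lon coordinates.
#' @return numeric vector of speeds (km/h); NA for a single fix.
#' @export
segmentSpeeds <- function(timestamp, lat, lon) {
  n <- length(timestamp)
  if (n < 2) return(rep(NA_real_, n))
  d <- gcDistKm(lat[-n], lon[-n], lat[-1], lon[-1])
  dtH <- diff(as.numeric(timestamp)) / 3600
  sp <- d / dtH
  c(sp[1], sp)
}

#' Spherical centroid of a point set
#'
#' Normalised (optionally weighted) mean of unit vectors on the sphere.
#'
#' @param lat,lon coordinates in degrees.
#' @param w optional non-negative weights.
#' @return named numeric \code{c(lat, lon)}.
#' @export
sphericalCentroid <- function(lat, lon, w = NULL) {
  if (length(lat) == 0) stop("cannot take the centroid of an empty set")
  if (is.null(w)) w <- rep(1, length(lat))
  rl <- lat * pi / 180; rn <- lon * pi / 180
  x <- sum(w * cos(rl) * cos(rn)); y <- sum(w * cos(rl) * sin(rn))
  z <- sum(w * sin(rl))
  nrm <- sqrt(x^2 + y^2 + z^2)
  if (nrm < 1e-12 * sum(w))
    stop("degenerate (antipodal) point set: zero resultant")
  c(lat = asin(z / nrm) * 180 / pi,
    lon = normalizeLon(atan2(y / nrm, x / nrm) * 180 / pi))
}

#' Polygonal region on the sphere
#'
#' A named simple polygon given as lon/lat vertex rings (treated as closed;
#' edges follow plate-carree straight lines, adequate for the study-area
#' boxes used here). Must not cross the antimeridian.
#'
#' @param name region name.
#' @param lat,lon vertex coordinates (first vertex need not be repeated).
#' @return object of class \code{"siteRegion"}.
#' @export
region <- function(name, lat, lon) {
  stopifnot(length(lat) == length(lon), length(lat) >= 3)
  if (lat[1] == lat[length(lat)] && lon[1] == lon[length(lon)]) {
    lat <- lat[-length(lat)]; lon <- lon[-length(lon)]
  }
  structure(list(name = name, lat = as.numeric(lat), lon = as.numeric(lon)),
            class = "siteRegion")
}

#' Axis-aligned box region
#' @param name region name.
#' @param latMin,latMax,lonMin,lonMax box bounds in degrees.
#' @return a \code{"siteRegion"}.
#' @export
boxRegion <- function(name, latMin, latMax, lonMin, lonMax) {
  region(name, lat = c(latMin, latMin, latMax, latMax),
         lon = c(lonMin, lonMax, lonMax, lonMin))
}

#' Point-in-region test
#'
#' Even-odd rule inclusion; points on the boundary count as inside.
#'
#' @param lat,lon point coordinates (vectorised).
#' @param reg a \code{\link{region}}.
#' @return logical vector.
#' @export
pointInRegion <- function(lat, lon, reg) {
  stopifnot(inherits(reg, "siteRegion"))
  px <- reg$lon; py <- reg$lat
  nv <- length(px)
  inside <- rep(FALSE, length(lat))
  onEdge <- rep(FALSE, length(lat))
  eps <- 1e-9
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- px[j]; y1 <- py[j]; x2 <- px[i]; y2 <- py[i]
    ## boundary: point within eps of segment (x1,y1)-(x2,y2)
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) pmin(1, pmax(0, ((lon - x1) * dx + (lat - y1) * dy) /
                                      len2)) else 0
    d2 <- (lon - (x1 + t * dx))^2 + (lat - (y1 + t * dy))^2
    onEdge <- onEdge | d2 < eps
    ## even-odd ray crossing (horizontal ray to +x)
    crosses <- ((y1 > lat) != (y2 > lat)) &
      (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

## local azimuthal-equidistant projection about a centre point -----------------

## initial great-circle bearing (degrees clockwise from north), spherical
.sphBearing <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  th <- atan2(sin(dl) * cos(p2),
              cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  th * 180 / pi
}

#' Project lon/lat to a local azimuthal-equidistant plane (km)
#' @param lat,lon points to project.
#' @param centerLat,centerLon projection centre.
#' @return matrix with columns \code{x} (east) and \code{y} (north), km.
#' @keywords internal
projectAeqd <- function(lat, lon, centerLat, centerLon) {
  d <- gcDistKm(centerLat, centerLon, lat, lon)
  b <- .sphBearing(centerLat, centerLon, lat, lon)
  b[is.na(b)] <- 0  # coincident with centre
  br <- b * pi / 180
  cbind(x = d * sin(br), y = d * cos(br))
}

#' Inverse of \code{projectAeqd}
#' @param xy matrix of local east/north coordinates in km.
#' @param centerLat,centerLon projection centre.
#' @return matrix with columns \code{lat}, \code{lon}.
#' @keywords internal
unprojectAeqd <- function(xy, centerLat, centerLon) {
  d <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  b <- atan2(xy[, 1], xy[, 2]) * 180 / pi
  p <- geosphere::destPoint(cbind(centerLon, centerLat), b, d * 1000,
                            r = .EARTH_RADIUS_KM * 1000)
  cbind(lat = p[, 2], lon = normalizeLon(p[, 1]))
}

#' Interpolate along a great circle
#'
#' Spherical linear interpolation between two points at fractions \code{f}.
#' @param lat1,lon1,lat2,lon2 endpoints (degrees).
#' @param f fractions in [0, 1] (vectorised).
#' @return matrix with columns \code{lat}, \code{lon}.
#' @keywords internal
gcInterpolate <- function(lat1, lon1, lat2, lon2, f) {
  toVec <- function(lat, lon) {
    rl <- lat * pi / 180; rn <- lon * pi / 180
    c(cos(rl) * cos(rn), cos(rl) * sin(rn), sin(rl))
  }
  v1 <- toVec(lat1, lon1); v2 <- toVec(lat2, lon2)
  om <- acos(pmin(1, pmax(-1, sum(v1 * v2))))
  if (om < 1e-12) {
    out <- matrix(rep(c(lat1, lon1), each = length(f)), ncol = 2)
    colnames(out) <- c("lat", "lon")
    return(out)
  }
  a <- sin((1 - f) * om) / sin(om)
  b <- sin(f * om) / sin(om)
  v <- cbind(a * v1[1] + b * v2[1], a * v1[2] + b * v2[2],
             a * v1[3] + b * v2[3])
  nrm <- sqrt(rowSums(v^2))
  cbind(lat = asin(v[, 3] / nrm) * 180 / pi,
        lon = normalizeLon(atan2(v[, 2], v[, 1]) * 180 / pi))
}
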