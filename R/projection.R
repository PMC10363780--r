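# Planar projection: spherical Lambert conformal conic with two standard
# parallels (Snyder's closed forms). All pipeline distances and thresholds
# (100 m relocation, 50 m clustering, 1.5 ha villages) are metric, so every
# lon/lat input is projected once on ingest and never touched again.

#' Define a Lambert conformal conic projection
#'
#' Builds a projection descriptor used by [lcc_project()] and
#' [lcc_unproject()]. The default parameters give a metric grid centred on
#' southern France (the kind of landscape the pipeline was developed for);
#' any mid-latitude study area is served by moving the origin and standard
#' parallels.
#'
#' @param lon0,lat0 Origin of the grid (degrees). The origin maps to (0, 0).
#' @param lat1,lat2 Standard parallels (degrees).
#' @param radius Sphere radius in meters (authalic Earth radius by default).
#' @return An object of class `lcc_projection`.
#' @export
lcc_projection <- function(lon0 = 3.9, lat0 = 43.8, lat1 = 43, lat2 = 46,
                           radius = 6371008.8) {
  stopifnot(lat1 != lat2, abs(lat1) < 90, abs(lat2) < 90)
  d2r <- pi / 180
  p1 <- lat1 * d2r; p2 <- lat2 * d2r; p0 <- lat0 * d2r
  n <- log(cos(p1) / cos(p2)) /
    log(tan(pi / 4 + p2 / 2) / tan(pi / 4 + p1 / 2))
  f <- cos(p1) * tan(pi / 4 + p1 / 2)^n / n
  rho0 <- radius * f / tan(pi / 4 + p0 / 2)^n
  structure(list(lon0 = lon0, lat0 = lat0, lat1 = lat1, lat2 = lat2,
                 radius = radius, n = n, f = f, rho0 = rho0),
            class = "lcc_projection")
}

#' Project lon/lat to planar meters
#'
#' @param lon,lat Coordinates in degrees.
#' @param proj An [lcc_projection()] object.
#' @return A two-column matrix with columns `x`, `y` (meters).
#' @export
lcc_project <- function(lon, lat, proj = lcc_projection()) {
  d2r <- pi / 180
  rho <- proj$radius * proj$f / tan(pi / 4 + lat * d2r / 2)^proj$n
  theta <- proj$n * (lon - proj$lon0) * d2r
  cbind(x = rho * sin(theta), y = proj$rho0 - rho * cos(theta))
}

#' Inverse-project planar meters to lon/lat
#'
#' Exact closed-form inverse of [lcc_project()].
#'
#' @param x,y Planar coordinates in meters.
#' @param proj An [lcc_projection()] object.
#' @return A two-column matrix with columns `lon`, `lat` (degrees).
#' @export
lcc_unproject <- function(x, y, proj = lcc_projection()) {
  r2d <- 180 / pi
  rho <- sign(proj$n) * sqrt(x^2 + (proj$rho0 - y)^2)
  theta <- atan2(x, proj$rho0 - y)
  lat <- (2 * atan((proj$radius * proj$f / rho)^(1 / proj$n)) - pi / 2) * r2d
  lon <- proj$lon0 + theta * r2d / proj$n
  cbind(lon = lon, lat = lat)
}

#' @export
print.lcc_projection <- function(x, ...) {
  cat(sprintf(
    "Lambert conformal conic (spherical): origin %.3fE %.3fN, parallels %g/%g\n",
    x$lon0, x$lat0, x$lat1, x$lat2))
  invisible(x)
}
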