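# Great-circle distances on a sphere of radius 6371 km.

.EARTH_RADIUS_KM <- 6371

#' Great-circle distance in kilometres
#'
#' Haversine distance between two points (or two equal-length sets of points)
#' given in decimal degrees, on a sphere of radius 6371 km.  This is the
#' spatial metric used in the exponential correlation function of the latent
#' field.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance(s) in km.
#' @examples
#' haversine_km(55, 0, 56, 0)   # one degree of latitude, ~111.19 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_KM * 1000) / 1000
}

#' Pairwise great-circle distance matrix between grid-cell centroids
#'
#' @param grid A [grid_spec()].
#' @return A symmetric `ncell x ncell` matrix of distances in km.
#' @export
centroid_distances_km <- function(grid) {
  p <- cbind(grid$lon_mid, grid$lat_mid)
  hav <- function(a, b) geosphere::distHaversine(a, b, r = .EARTH_RADIUS_KM * 1000)
  geosphere::distm(p, fun = hav) / 1000
}
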