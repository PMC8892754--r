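# Spherical geometry helpers shared across modules. All great-circle
# quantities use a sphere of radius 6371 km; geosphere's own default is the
# WGS84 equatorial radius, so the radius is always passed explicitly.

EARTH_RADIUS_KM <- 6371

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over all
#' arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in kilometres.
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial great-circle bearing between coordinate pairs
#'
#' @inheritParams gc_dist_km
#' @return Bearing(s) in compass degrees in [0, 360).
#' @export
gc_bearing <- function(lon1, lat1, lon2, lat2) {
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  (b + 360) %% 360
}

# Destination point along an initial bearing; d in km.
gc_destination <- function(lon, lat, bearing, d_km) {
  geosphere::destPoint(cbind(lon, lat), bearing, d_km * 1000,
                       r = EARTH_RADIUS_KM * 1000)
}

#' Ground speed between two relocations
#'
#' Haversine distance (R = 6371 km) divided by elapsed time.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees.
#' @param t1,t2 POSIXct timestamps, `t2 > t1`.
#' @return Speed in km/h; `NA` (with a warning) where elapsed time is zero.
#' @export
ground_speed <- function(lon1, lat1, t1, lon2, lat2, t2) {
  dt_h <- as.numeric(difftime(t2, t1, units = "hours"))
  d <- gc_dist_km(lon1, lat1, lon2, lat2)
  bad <- dt_h <= 0
  if (any(bad, na.rm = TRUE)) {
    warning("zero or negative elapsed time between relocations; speed undefined")
  }
  ifelse(bad, NA_real_, d / dt_h)
}

# Wrap an angular difference into (-180, 180].
wrap_angle <- function(x) {
  out <- (x + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}
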