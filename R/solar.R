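# Solar geometry: sunrise/sunset, day length and solar phase of a fix.
# Standard NOAA low-precision solar position approximation; sunrise/sunset
# are defined at a solar elevation of -0.833 degrees (refraction plus solar
# radius), the convention used by civil almanacs.

DEG <- pi / 180
SUN_HORIZON_DEG <- -0.833

# fractional year (radians) at a given UTC time
solar_gamma <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  2 * pi / 365 * (lt$yday + (lt$hour + lt$min / 60 + lt$sec / 3600 - 12) / 24)
}

# equation of time (minutes) and solar declination (radians)
solar_eqtime <- function(g) {
  229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
              0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
}

solar_decl <- function(g) {
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) - 0.006758 * cos(2 * g) +
    0.000907 * sin(2 * g) - 0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

#' Solar elevation angle
#'
#' @param lon,lat Coordinates in degrees.
#' @param time POSIXct (UTC).
#' @return Elevation of the sun above the horizon, in degrees. Vectorised.
#' @export
sun_elevation <- function(lon, lat, time) {
  g <- solar_gamma(time)
  decl <- solar_decl(g)
  lt <- as.POSIXlt(time, tz = "UTC")
  tst <- (lt$hour * 60 + lt$min + lt$sec / 60 + solar_eqtime(g) + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * DEG
  sin_el <- sin(lat * DEG) * sin(decl) + cos(lat * DEG) * cos(decl) * cos(ha)
  asin(pmin(pmax(sin_el, -1), 1)) / DEG
}

#' Sunrise, sunset and day length for a date and location
#'
#' @param lon,lat Coordinates in degrees.
#' @param date A `Date` (or something coercible).
#' @return A list with POSIXct `sunrise`, `sunset` (UTC; `NA` under polar
#'   day/night), and numeric `daylight_hours`, `dark_hours` (24/0 or 0/24 at
#'   the poles).
#' @export
solar_events <- function(lon, lat, date) {
  date <- as.Date(date)
  noon <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC")
  g <- solar_gamma(noon)
  decl <- solar_decl(g)
  eq <- solar_eqtime(g)
  cos_ha <- (sin(SUN_HORIZON_DEG * DEG) - sin(lat * DEG) * sin(decl)) /
    (cos(lat * DEG) * cos(decl))
  polar_day <- cos_ha < -1
  polar_night <- cos_ha > 1
  ha_deg <- acos(pmin(pmax(cos_ha, -1), 1)) / DEG
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  sunrise <- day0 + 60 * (720 - 4 * (lon + ha_deg) - eq)
  sunset <- day0 + 60 * (720 - 4 * (lon - ha_deg) - eq)
  daylight <- 8 * ha_deg / 60
  daylight[polar_day] <- 24
  daylight[polar_night] <- 0
  sunrise[polar_day | polar_night] <- NA
  sunset[polar_day | polar_night] <- NA
  list(sunrise = sunrise, sunset = sunset,
       daylight_hours = daylight, dark_hours = 24 - daylight)
}

#' Classify the solar phase of relocations
#'
#' A fix is `dawn_dusk` when it falls within one hour of a sunrise or sunset
#' event (the events of the fix's UTC date and its neighbours are all
#' considered, so longitudes where events straddle the UTC date line are
#' handled); otherwise it is `day` when the sun stands above -0.833 degrees
#' and `night` when below. Under polar day/night the phase is forced to
#' day/night and day length to 24/0 h.
#'
#' @param lon,lat Coordinates in degrees (vectorised).
#' @param time POSIXct timestamps (UTC).
#' @return A `tibble` with columns `phase` (factor day/dawn_dusk/night),
#'   `daylight_hours`, `dark_hours`.
#' @export
solar_phase <- function(lon, lat, time) {
  n <- max(length(lon), length(lat), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  time <- rep(time, length.out = n)
  elev <- sun_elevation(lon, lat, time)
  date <- as.Date(time, tz = "UTC")
  ev <- solar_events(lon, lat, date)
  near_event <- rep(FALSE, n)
  for (off in -1:1) {
    e <- solar_events(lon, lat, date + off)
    for (w in c("sunrise", "sunset")) {
      dt <- abs(as.numeric(difftime(time, e[[w]], units = "hours")))
      near_event <- near_event | (!is.na(dt) & dt <= 1)
    }
  }
  phase <- ifelse(near_event, "dawn_dusk",
                  ifelse(elev > SUN_HORIZON_DEG, "day", "night"))
  tibble::tibble(
    phase = factor(phase, levels = c("day", "dawn_dusk", "night")),
    daylight_hours = ev$daylight_hours,
    dark_hours = ev$dark_hours)
}
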