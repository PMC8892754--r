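# Annotation of relocations and segments with weather at the matching
# pressure level, tailwind/crosswind support, and land-cover overlap.

PRESSURE_LEVELS <- c(1000, 925, 850, 700, 600, 500, 400, 300)

#' Convert altitude to pressure (International Standard Atmosphere)
#'
#' @param altitude_m Altitude(s) above sea level, metres.
#' @return Pressure in hPa.
#' @export
altitude_to_pressure <- function(altitude_m) {
  1013.25 * (1 - 0.0065 * altitude_m / 288.15)^5.255
}

#' Nearest standard pressure level for a GPS altitude
#'
#' The altitude is converted to pressure with the ISA barometric formula and
#' matched to the nearest of the 1000...300 mb reanalysis levels. Altitudes
#' outside [-500 m, 16 km] are clamped with a warning.
#'
#' @param altitude_m GPS altitude(s), metres above sea level.
#' @return Level(s) in mb.
#' @export
nearest_pressure_level <- function(altitude_m) {
  out_of_range <- altitude_m < -500 | altitude_m > 16000
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range), " altitude(s) outside [-500 m, 16 km] clamped")
  }
  h <- pmin(pmax(altitude_m, -500), 16000)
  p <- altitude_to_pressure(h)
  PRESSURE_LEVELS[apply(abs(outer(p, PRESSURE_LEVELS, "-")), 1, which.min)]
}

# which variables live on pressure levels / are time-interpolated
LEVEL_VARS <- c("u", "v", "air_temp", "vertical_flow")
WIND_VARS <- c("u", "v")

#' Interpolate a weather-grid variable to a point
#'
#' Bilinear interpolation in lon/lat. Wind components are additionally
#' interpolated linearly in time between the bracketing 6-h steps; all other
#' variables are only defined at the synoptic hours themselves (mirroring a
#' pipeline that annotates non-wind weather at 00/06/12/18 UTC fixes only)
#' and return `NA` off those hours.
#'
#' @param grid A `weather_grid` (see [generate_weather_grid()]).
#' @param var Variable name (`"u"`, `"v"`, `"air_temp"`, `"vertical_flow"`,
#'   `"surface_temp"`, `"precip"`, `"cloud"`).
#' @param lon,lat Point coordinates, degrees.
#' @param time POSIXct (UTC).
#' @param level Pressure level in mb (required for level variables).
#' @return Interpolated value(s); `NA` outside the grid hull.
#' @export
interpolate_field <- function(grid, var, lon, lat, time, level = NULL) {
  stopifnot(inherits(grid, "weather_grid"))
  on_levels <- var %in% LEVEL_VARS
  if (on_levels && is.null(level)) stop("variable ", var, " needs a pressure level")
  n <- max(length(lon), length(lat), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  time <- rep(time, length.out = n)
  if (on_levels) level <- rep_len(level, n)

  tt <- as.numeric(grid$times)
  qt <- as.numeric(time)
  space <- function(arr3, ti, li) {
    # arr3: array [lon, lat, time(, level)]; bilinear at one time index
    gx <- grid$lon; gy <- grid$lat
    i <- pmin(pmax(findInterval(lon, gx), 1), length(gx) - 1)
    j <- pmin(pmax(findInterval(lat, gy), 1), length(gy) - 1)
    fx <- (lon - gx[i]) / (gx[i + 1] - gx[i])
    fy <- (lat - gy[j]) / (gy[j + 1] - gy[j])
    pick <- function(ii, jj) {
      if (on_levels) arr3[cbind(ii, jj, ti, li)] else arr3[cbind(ii, jj, ti)]
    }
    (1 - fx) * (1 - fy) * pick(i, j) + fx * (1 - fy) * pick(i + 1, j) +
      (1 - fx) * fy * pick(i, j + 1) + fx * fy * pick(i + 1, j + 1)
  }
  arr <- grid[[var]]
  li <- if (on_levels) match(level, grid$levels) else NULL
  inside <- lon >= min(grid$lon) & lon <= max(grid$lon) &
    lat >= min(grid$lat) & lat <= max(grid$lat) &
    qt >= tt[1] & qt <= tt[length(tt)]
  if (var %in% WIND_VARS) {
    t0 <- pmin(pmax(findInterval(qt, tt), 1), length(tt) - 1)
    ft <- (qt - tt[t0]) / (tt[t0 + 1] - tt[t0])
    val <- (1 - ft) * space(arr, t0, li) + ft * space(arr, t0 + 1, li)
  } else {
    ti <- match(qt, tt)
    val <- rep(NA_real_, n)
    ok <- !is.na(ti)
    if (any(ok)) {
      sub_ti <- ti[ok]
      full <- space(arr, ifelse(is.na(ti), 1, ti), li)
      val[ok] <- full[ok]
    }
  }
  val[!inside] <- NA_real_
  val
}

#' Tailwind and crosswind from wind components and a track bearing
#'
#' The wind vector (u east, v north, m/s) defines where the air moves
#' toward; theta is the angular difference between the bird's movement
#' direction and that vector. Tailwind support is `fa = y cos(theta)` with
#' `y` the wind speed; it is positive when the wind blows along the track.
#' Crosswind is `y sin(theta)`, positive when the wind comes from the
#' bird's left.
#'
#' @param bearing Movement direction(s), compass degrees.
#' @param u,v Wind components, m/s.
#' @return Tibble with `y` (wind speed), `theta_deg`, `tailwind`,
#'   `crosswind`.
#' @export
tailwind_crosswind <- function(bearing, u, v) {
  y <- sqrt(u^2 + v^2)
  wind_to <- (atan2(u, v) / DEG) %% 360
  theta <- wrap_angle(wind_to - bearing)
  tibble::tibble(y = y, theta_deg = theta,
                 tailwind = y * cos(theta * DEG),
                 crosswind = y * sin(theta * DEG))
}

#' Annotate a flight-classified track with wind support
#'
#' For fixes in flight with a defined movement bearing (the step starting at
#' the fix), winds are interpolated at the fix position and time at the
#' pressure level nearest the GPS altitude, and decomposed into tailwind and
#' crosswind.
#'
#' @param rt Flight-classified `resampled_track`.
#' @param grid A `weather_grid`.
#' @return `rt` with columns `u`, `v`, `tailwind`, `crosswind`.
#' @export
annotate_wind <- function(rt, grid) {
  n <- nrow(rt)
  bearing <- c(gc_bearing(rt$lon[-n], rt$lat[-n], rt$lon[-1], rt$lat[-1]),
               NA)
  same_id <- c(rt$id[-n] == rt$id[-1], FALSE)
  moving <- rt$flight %in% TRUE & same_id &
    gc_dist_km(rt$lon, rt$lat, c(rt$lon[-1], NA), c(rt$lat[-1], NA)) > 0
  lev <- nearest_pressure_level(ifelse(is.na(rt$gps_altitude), 0,
                                       rt$gps_altitude))
  u <- v <- tw <- cw <- rep(NA_real_, n)
  if (any(moving)) {
    u[moving] <- interpolate_field(grid, "u", rt$lon[moving], rt$lat[moving],
                                   rt$slot_time[moving], lev[moving])
    v[moving] <- interpolate_field(grid, "v", rt$lon[moving], rt$lat[moving],
                                   rt$slot_time[moving], lev[moving])
    dec <- tailwind_crosswind(bearing[moving], u[moving], v[moving])
    tw[moving] <- dec$tailwind
    cw[moving] <- dec$crosswind
  }
  rt$u <- u; rt$v <- v; rt$tailwind <- tw; rt$crosswind <- cw
  rt
}

#' Proportion of aquatic habitat along a buffered traveling segment
#'
#' The segment polyline is buffered `buffer_km` on each side in the
#' raster's local metric frame; the proportion is water cells (IGBP 11 or
#' 17) over all cells whose centres fall inside the buffer. Invariant to
#' reversing the segment direction.
#'
#' @param seg Segment relocation tibble (>= 2 fixes).
#' @param landscape A `landscape_raster` covering the buffered segment.
#' @param buffer_km Buffer half-width in km.
#' @return Proportion in `[0, 1]`.
#' @export
water_overlap_segment <- function(seg, landscape, buffer_km = 5) {
  if (nrow(seg) < 2) stop("segment needs at least two relocations")
  p <- lonlat_to_xy(landscape, seg$lon, seg$lat)
  ext <- raster_extent_km(landscape)
  if (any(p$x < 0 | p$y < 0 | p$x > ext["x"] | p$y > ext["y"])) {
    stop("segment lies outside the land-cover raster")
  }
  res_km <- landscape$res_m / 1000
  ny <- nrow(landscape$values); nx <- ncol(landscape$values)
  inside <- matrix(FALSE, ny, nx)
  n <- length(p$x)
  for (k in seq_len(n - 1)) {
    x1 <- p$x[k]; y1 <- p$y[k]; x2 <- p$x[k + 1]; y2 <- p$y[k + 1]
    j0 <- max(1L, floor((min(x1, x2) - buffer_km) / res_km) + 1L)
    j1 <- min(nx, ceiling((max(x1, x2) + buffer_km) / res_km))
    i0 <- max(1L, floor((min(y1, y2) - buffer_km) / res_km) + 1L)
    i1 <- min(ny, ceiling((max(y1, y2) + buffer_km) / res_km))
    if (j0 > j1 || i0 > i1) next
    xc <- ((j0:j1) - 0.5) * res_km
    yc <- ((i0:i1) - 0.5) * res_km
    X <- matrix(xc, length(yc), length(xc), byrow = TRUE)
    Y <- matrix(yc, length(yc), length(xc))
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    t_par <- if (len2 == 0) 0 else
      pmin(pmax(((X - x1) * dx + (Y - y1) * dy) / len2, 0), 1)
    d2 <- (X - (x1 + t_par * dx))^2 + (Y - (y1 + t_par * dy))^2
    blk <- d2 <= buffer_km^2
    inside[i0:i1, j0:j1] <- inside[i0:i1, j0:j1] | blk
  }
  vals <- landscape$values[inside]
  if (!length(vals)) return(NA_real_)
  mean(vals == IGBP_WATER | vals == IGBP_WETLAND)
}
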