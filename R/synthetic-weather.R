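# Synthetic 6-hourly pressure-level weather grids. The layout emulates a
# reanalysis product: a regular lon/lat grid (2.5 degrees by default),
# synoptic times 00/06/12/18 UTC, wind and air temperature on the eight
# standard levels, plus surface fields.

#' Generate a synthetic weather grid
#'
#' Scenarios: `"zero_wind"` (u = v = 0 everywhere), `"constant_wind"`
#' (spatially and temporally uniform `u`, `v`), `"rotating_wind"` (uniform
#' in space; the wind vector of magnitude `sqrt(u^2+v^2)` rotates by
#' `rotation_deg` per 6-h step, so time interpolation is exercised with a
#' known closed form). Air temperature follows an ISA-like lapse by level;
#' surface fields are smooth random surfaces (seeded) or constants.
#'
#' @param seed RNG seed for the surface fields.
#' @param extent Named vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param start POSIXct of the first synoptic time (UTC, snapped to 6 h).
#' @param n_steps Number of 6-hourly steps.
#' @param scenario Wind scenario.
#' @param u,v Wind components (m/s) for the constant/rotating scenarios.
#' @param rotation_deg Rotation per step for `"rotating_wind"`.
#' @param res_deg Grid spacing in degrees.
#' @param cloud_mean,precip_mean Means of the surface fields.
#' @return A `weather_grid` list with coordinate vectors `lon`, `lat`,
#'   `times`, `levels` and arrays `u`, `v`, `air_temp`, `vertical_flow`
#'   (lon x lat x time x level) and `surface_temp`, `precip`, `cloud`
#'   (lon x lat x time).
#' @export
generate_weather_grid <- function(seed = 1L,
                                  extent = c(-10, 30, 0, 60),
                                  start = as.POSIXct("2018-09-01 00:00:00",
                                                     tz = "UTC"),
                                  n_steps = 8L,
                                  scenario = c("zero_wind", "constant_wind",
                                               "rotating_wind"),
                                  u = 0, v = 0, rotation_deg = 45,
                                  res_deg = 2.5,
                                  cloud_mean = 0.4, precip_mean = 1) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  lon <- seq(extent[1], extent[2], by = res_deg)
  lat <- seq(extent[3], extent[4], by = res_deg)
  start <- as.POSIXct(floor(as.numeric(start) / 21600) * 21600,
                      tz = "UTC", origin = "1970-01-01")
  times <- start + (seq_len(n_steps) - 1) * 21600
  nl <- length(PRESSURE_LEVELS)
  dims4 <- c(length(lon), length(lat), n_steps, nl)
  dims3 <- dims4[1:3]

  uu <- array(0, dims4); vv <- array(0, dims4)
  if (scenario == "constant_wind") {
    uu[] <- u; vv[] <- v
  } else if (scenario == "rotating_wind") {
    y <- sqrt(u^2 + v^2)
    phi0 <- atan2(u, v)
    for (ti in seq_len(n_steps)) {
      ang <- phi0 + (ti - 1) * rotation_deg * DEG
      uu[, , ti, ] <- y * sin(ang)
      vv[, , ti, ] <- y * cos(ang)
    }
  }
  # ISA-like temperatures: level height from the barometric inversion
  lev_h <- 288.15 / 0.0065 * (1 - (PRESSURE_LEVELS / 1013.25)^(1 / 5.255))
  air_temp <- array(rep(288.15 - 0.0065 * lev_h, each = prod(dims3)), dims4)
  vertical_flow <- array(stats::rnorm(prod(dims4), 0, 0.05), dims4)
  surface_temp <- array(288 + stats::rnorm(prod(dims3), 0, 2), dims3)
  precip <- array(stats::rgamma(prod(dims3), shape = 1,
                                scale = precip_mean), dims3)
  cloud <- array(pmin(pmax(stats::rnorm(prod(dims3), cloud_mean, 0.2), 0), 1),
                 dims3)
  structure(list(lon = lon, lat = lat, times = times,
                 levels = PRESSURE_LEVELS,
                 u = uu, v = vv, air_temp = air_temp,
                 vertical_flow = vertical_flow,
                 surface_temp = surface_temp, precip = precip, cloud = cloud,
                 scenario = scenario),
            class = "weather_grid")
}

#' @exportS3Method base::print
print.weather_grid <- function(x, ...) {
  cat(sprintf(
    "<weather_grid> %d x %d nodes, %d six-hourly steps, %d levels (%s)\n",
    length(x$lon), length(x$lat), length(x$times), length(x$levels),
    x$scenario))
  invisible(x)
}

#' Write a weather grid as long-format CSV with a JSON header
#'
#' Plain-text serialisation: `<path>` holds one row per (lon, lat, time,
#' level) with all level variables, `<path>.surface.csv` the surface
#' variables, and `<path>.json` the coordinate vectors.
#'
#' @param grid A `weather_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(grid, path) {
  g <- expand.grid(lon = grid$lon, lat = grid$lat,
                   time = format(grid$times, "%Y-%m-%dT%H:%M:%SZ"),
                   level = grid$levels)
  g$u <- as.vector(grid$u); g$v <- as.vector(grid$v)
  g$air_temp <- as.vector(grid$air_temp)
  g$vertical_flow <- as.vector(grid$vertical_flow)
  utils::write.csv(g, path, row.names = FALSE)
  s <- expand.grid(lon = grid$lon, lat = grid$lat,
                   time = format(grid$times, "%Y-%m-%dT%H:%M:%SZ"))
  s$surface_temp <- as.vector(grid$surface_temp)
  s$precip <- as.vector(grid$precip)
  s$cloud <- as.vector(grid$cloud)
  utils::write.csv(s, paste0(path, ".surface.csv"), row.names = FALSE)
  jsonlite::write_json(list(lon = grid$lon, lat = grid$lat,
                            times = format(grid$times, "%Y-%m-%dT%H:%M:%SZ"),
                            levels = grid$levels, scenario = grid$scenario),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}
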