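# Synthetic GPS tracks with embedded stopovers and a known ground truth.
#
# The generator works on the natural 30-min interval grid of the downstream
# pipeline: per interval the bird either flies (advancing cruise_speed/2 km
# along a fixed heading) or is stationary. Scheduled stopover days are
# stationary throughout. Flight is scheduled either deterministically
# (daily_schedule: fixed UTC windows) or stochastically (per-interval
# Bernoulli draws with phase-specific probabilities). Isolated one-interval
# pauses inside flight bouts are merged into flight -- a 15-min landing
# would not register at the 30-min fix cadence -- which makes the
# both-endpoints speed rule recover the true flags exactly on noiseless
# tracks. Fixes can then be emitted at any (possibly irregular) cadence by
# interpolating within intervals.

#' Specification of a synthetic migratory track
#'
#' @param seed Integer RNG seed.
#' @param n_days Number of track days.
#' @param start Lon/lat of the first fix.
#' @param start_date Date of the first track day (UTC days throughout).
#' @param sampling_interval Fix cadence in minutes; a vector gives an
#'   irregular cadence (each gap drawn uniformly from the vector).
#' @param stopover_schedule List of `c(start_day, duration_days)` pairs;
#'   days are 1-based track days.
#' @param flight_prob_day,flight_prob_night Per-30-min-interval flight
#'   probabilities on travel days (by solar phase at the bird's position).
#' @param daily_schedule Optional deterministic schedule, a list with
#'   `day_hours`, `night_hours` and optionally `day_start_hour` (default 10)
#'   and `night_start_hour` (default 22), all UTC. Overrides the
#'   probabilities.
#' @param cruise_speed Flight speed in km/h; must exceed 10 so flight
#'   intervals classify as flight downstream.
#' @param heading Constant compass heading in degrees.
#' @param height_agl_mean,height_agl_sd Flight height above ground, metres.
#' @param water_effect_speed Ground-truth effect (km/day per unit water
#'   proportion in a 5-km disc) added to the realized daily distance.
#' @param random_intercept_sd SD (km/day) of an individual-level shift of
#'   daily distance, drawn once per track.
#' @param noise_km SD of isotropic position noise added to emitted fixes.
#' @param altitude_noise_sd SD (m) of GPS altitude noise (device error).
#' @param gross_error_rate Probability per fix of a gross altitude spike
#'   (+/- 5000-9000 m), to exercise the quality filter.
#' @param id,age,colony,year,season Metadata carried into the track table.
#' @return A `track_spec` list.
#' @export
track_spec <- function(seed = 1L, n_days = 10L, start = c(10, 55),
                       start_date = as.Date("2018-09-01"),
                       sampling_interval = 30,
                       stopover_schedule = list(),
                       flight_prob_day = 0.5, flight_prob_night = 0.25,
                       daily_schedule = NULL,
                       cruise_speed = 40, heading = 180,
                       height_agl_mean = 300, height_agl_sd = 50,
                       water_effect_speed = 0, random_intercept_sd = 0,
                       noise_km = 0, altitude_noise_sd = 15,
                       gross_error_rate = 0,
                       id = "bird01", age = "adult", colony = "colonyA",
                       year = 2018L, season = "autumn") {
  if (any(c(flight_prob_day, flight_prob_night) < 0) ||
      any(c(flight_prob_day, flight_prob_night) > 1)) {
    stop("flight probabilities must lie in [0, 1]")
  }
  if (cruise_speed <= 10) {
    stop("cruise_speed must exceed 10 km/h so traveling intervals classify as flight")
  }
  if (any(unlist(sampling_interval) < 5) || any(unlist(sampling_interval) > 120)) {
    stop("sampling_interval must lie in [5, 120] minutes")
  }
  structure(as.list(environment()), class = "track_spec")
}

# deterministic window membership for a UTC hour-of-day
in_window <- function(hour, start, len) {
  if (len <= 0) return(rep(FALSE, length(hour)))
  end <- (start + len) %% 24
  if (start + len <= 24) hour >= start & hour < start + len
  else hour >= start | hour < end
}

#' Generate a synthetic track and its ground truth
#'
#' @param tspec A [track_spec()].
#' @param landscape Optional `landscape_raster`; enables the water effect on
#'   daily distance and the extent check.
#' @param dem Optional `dem_raster` for GPS altitudes (sea level 0 without).
#' @return A list with `track` (tibble: id, timestamp, lon, lat,
#'   gps_altitude, inst_speed, age, colony, year, season) and `truth` (list:
#'   stopover_days, intervals tibble with per-interval flight flags and
#'   positions, daily tibble, beta_water, cruise_speed).
#' @export
generate_track <- function(tspec, landscape = NULL, dem = NULL) {
  stopifnot(inherits(tspec, "track_spec"))
  set.seed(tspec$seed)
  n_int <- tspec$n_days * 48L
  t0 <- as.POSIXct(paste(tspec$start_date, "00:00:00"), tz = "UTC")
  int_start <- t0 + (seq_len(n_int) - 1) * 1800
  day_of <- rep(seq_len(tspec$n_days), each = 48L)

  stop_days <- integer(0)
  for (s in tspec$stopover_schedule) {
    stop_days <- c(stop_days, seq.int(s[1], length.out = s[2]))
  }
  stop_days <- sort(unique(stop_days[stop_days >= 1 & stop_days <= tspec$n_days]))
  travel_int <- !(day_of %in% stop_days)

  # individual effect and water effect act on per-interval flight distance,
  # scaled by the expected daily flight hours so truth is in km/day units
  b_ind <- stats::rnorm(1, 0, tspec$random_intercept_sd)
  if (!is.null(tspec$daily_schedule)) {
    exp_hours <- tspec$daily_schedule$day_hours + tspec$daily_schedule$night_hours
  } else {
    exp_hours <- 12 * (tspec$flight_prob_day + tspec$flight_prob_night)
  }
  exp_hours <- max(exp_hours, 0.5)

  # flight scheduling
  if (!is.null(tspec$daily_schedule)) {
    ds <- tspec$daily_schedule
    dsh <- if (is.null(ds$day_start_hour)) 10 else ds$day_start_hour
    nsh <- if (is.null(ds$night_start_hour)) 22 else ds$night_start_hour
    hod <- as.numeric(difftime(int_start, t0, units = "hours")) %% 24
    fly <- travel_int & (in_window(hod, dsh, ds$day_hours) |
                           in_window(hod, nsh, ds$night_hours))
  } else {
    # phase from sun elevation at the start position: adequate because the
    # probabilities are phase-wise constants and tracks span few degrees/day
    mid <- int_start + 900
    day_phase <- sun_elevation(tspec$start[1], tspec$start[2], mid) > SUN_HORIZON_DEG
    p <- ifelse(day_phase, tspec$flight_prob_day, tspec$flight_prob_night)
    fly <- travel_int & (stats::runif(n_int) < p)
    # merge isolated one-interval pauses inside flight bouts
    iso <- which(!fly[-c(1, n_int)] & fly[-c(n_int - 1, n_int)] & fly[-c(1, 2)]) + 1L
    fly[iso] <- TRUE
  }

  # the last half-hour of the track ends at the emission boundary (there is
  # no later fix to observe movement against); keep it stationary so the
  # generative truth equals what a device could record
  fly[n_int] <- FALSE

  # movement loop
  lon <- numeric(n_int + 1); lat <- numeric(n_int + 1)
  lon[1] <- tspec$start[1]; lat[1] <- tspec$start[2]
  dist_km <- numeric(n_int)
  w_local <- numeric(n_int)
  for (k in seq_len(n_int)) {
    if (fly[k]) {
      v <- tspec$cruise_speed + b_ind / exp_hours
      if (!is.null(landscape) && tspec$water_effect_speed != 0) {
        w_local[k] <- water_proportion_at(landscape, lon[k], lat[k], 5)
        v <- v + tspec$water_effect_speed * w_local[k] / exp_hours
      }
      d <- max(v, 1) * 0.5
      p <- gc_destination(lon[k], lat[k], tspec$heading, d)
      lon[k + 1] <- p[1]; lat[k + 1] <- p[2]
      dist_km[k] <- d
    } else {
      lon[k + 1] <- lon[k]; lat[k + 1] <- lat[k]
    }
  }
  node_lon <- lon; node_lat <- lat
  node_time <- c(t0, int_start + 1800)
  if (!is.null(landscape)) {
    ext <- raster_extent_km(landscape)
    xy <- lonlat_to_xy(landscape, node_lon, node_lat)
    if (any(xy$x < 0 | xy$y < 0 | xy$x > ext["x"] | xy$y > ext["y"])) {
      stop("track leaves the landscape raster extent")
    }
  }

  # emit fixes at the requested cadence by interpolation within intervals
  if (identical(unlist(tspec$sampling_interval), 30)) {
    fix_time <- node_time
  } else {
    gaps <- sample(rep(unlist(tspec$sampling_interval), length.out = 1000),
                   ceiling(n_int * 30 / min(unlist(tspec$sampling_interval))) + 1,
                   replace = TRUE)
    fix_min <- cumsum(c(0, gaps))
    fix_min <- fix_min[fix_min <= n_int * 30]
    fix_time <- t0 + fix_min * 60
  }
  # the node at the final midnight belongs to the next calendar day; drop it
  fix_time <- fix_time[as.numeric(difftime(fix_time, t0, units = "mins")) <
                         n_int * 30]
  rel_min <- as.numeric(difftime(fix_time, t0, units = "mins"))
  k_int <- pmin(pmax(ceiling(rel_min / 30), 1L), n_int)  # interval containing the fix
  frac <- rel_min / 30 - (k_int - 1)
  fix_lon <- numeric(length(fix_time)); fix_lat <- numeric(length(fix_time))
  at_node <- frac %in% c(0, 1) | dist_km[k_int] == 0
  nd <- ifelse(frac >= 1 | dist_km[k_int] == 0, k_int + 1, k_int)
  nd[rel_min == 0] <- 1L
  fix_lon[at_node] <- node_lon[nd[at_node]]
  fix_lat[at_node] <- node_lat[nd[at_node]]
  if (any(!at_node)) {
    p <- gc_destination(node_lon[k_int[!at_node]], node_lat[k_int[!at_node]],
                        tspec$heading, frac[!at_node] * dist_km[k_int[!at_node]])
    fix_lon[!at_node] <- p[, 1]; fix_lat[!at_node] <- p[, 2]
  }

  # instantaneous speed as a GPS device would report it: the bird is moving
  # at a node if it flies in the interval on either side of it
  kmh <- dist_km / 0.5
  fix_speed <- numeric(length(fix_time))
  is_node <- frac %in% c(0, 1)
  k_before <- pmax(ifelse(frac >= 1, k_int, k_int - 1), 0)
  k_after <- pmin(ifelse(frac >= 1, k_int + 1, k_int), n_int + 1)
  sp_before <- ifelse(k_before >= 1, kmh[pmax(k_before, 1)], 0)
  sp_after <- ifelse(k_after <= n_int, kmh[pmin(k_after, n_int)], 0)
  fix_speed <- ifelse(is_node, pmax(sp_before, sp_after), kmh[k_int])

  # altitudes
  ground <- if (!is.null(dem)) elevation_at(dem, fix_lon, fix_lat) else 0
  flying_now <- fix_speed > 10
  agl <- ifelse(flying_now,
                stats::rnorm(length(fix_time), tspec$height_agl_mean,
                             tspec$height_agl_sd), 0)
  altitude <- ground + agl +
    stats::rnorm(length(fix_time), 0, tspec$altitude_noise_sd)
  if (tspec$gross_error_rate > 0) {
    spike <- stats::runif(length(fix_time)) < tspec$gross_error_rate
    altitude[spike] <- altitude[spike] +
      sample(c(-1, 1), sum(spike), TRUE) * stats::runif(sum(spike), 5000, 9000)
  }
  if (tspec$noise_km > 0) {
    th <- stats::runif(length(fix_time), 0, 360)
    r <- abs(stats::rnorm(length(fix_time), 0, tspec$noise_km))
    p <- gc_destination(fix_lon, fix_lat, th, r)
    fix_lon <- p[, 1]; fix_lat <- p[, 2]
  }

  track <- tibble::tibble(
    id = tspec$id, timestamp = fix_time, lon = fix_lon, lat = fix_lat,
    gps_altitude = altitude, inst_speed = fix_speed,
    age = tspec$age, colony = tspec$colony, year = tspec$year,
    season = tspec$season)

  daily <- tibble::tibble(
    day = seq_len(tspec$n_days),
    date = tspec$start_date + seq_len(tspec$n_days) - 1,
    stopover = seq_len(tspec$n_days) %in% stop_days,
    km = as.numeric(tapply(dist_km, day_of, sum)),
    flight_hours = as.numeric(tapply(fly, day_of, sum)) * 0.5)

  truth <- list(
    stopover_days = stop_days,
    stopover_dates = tspec$start_date + stop_days - 1,
    intervals = tibble::tibble(start = int_start, day = day_of, flight = fly,
                               km = dist_km),
    daily = daily,
    node_lon = node_lon, node_lat = node_lat,
    beta_water = tspec$water_effect_speed,
    cruise_speed = tspec$cruise_speed,
    b_individual = b_ind)
  list(track = track, truth = truth)
}

#' Write tracks as a Movebank-style CSV (plus ground-truth JSON sidecar)
#'
#' @param tracks A track tibble or list of them (rows are concatenated).
#' @param path Output CSV path.
#' @param truth Optional ground-truth list; written to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path, truth = NULL) {
  if (!is.data.frame(tracks)) tracks <- do.call(rbind, tracks)
  out <- data.frame(
    `individual-local-identifier` = tracks$id,
    timestamp = format(tracks$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    `location-long` = tracks$lon, `location-lat` = tracks$lat,
    `height-above-msl` = tracks$gps_altitude,
    `ground-speed` = tracks$inst_speed, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(truth)) {
    tr <- truth
    tr$intervals <- NULL  # keep the sidecar small; day-level truth suffices
    jsonlite::write_json(tr, paste0(path, ".truth.json"), auto_unbox = TRUE,
                         digits = NA, POSIXt = "ISO8601", Date = "ISO8601")
  }
  invisible(path)
}
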