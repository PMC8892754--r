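# Ingestion, quality filtering, 30-min resampling and flight classification.

#' Read Movebank-style relocation tables
#'
#' Parses a CSV of GPS relocations, maps columns, sorts by individual and
#' timestamp, drops duplicated timestamps and rows with impossible
#' coordinates or unparsable fields (with a message saying how many).
#'
#' @param path CSV file path.
#' @param column_map Named list mapping internal names (`id`, `timestamp`,
#'   `lon`, `lat`, `gps_altitude`, `inst_speed`) to file column names. The
#'   default is the Movebank dialect written by [write_tracks_csv()].
#'   `gps_altitude` and `inst_speed` are optional.
#' @param tz Timestamp time zone (default UTC).
#' @return A tibble of relocations (columns `id`, `timestamp`, `lon`, `lat`
#'   and, when present, `gps_altitude`, `inst_speed`), sorted within
#'   individual.
#' @export
read_tracks <- function(path,
                        column_map = list(id = "individual-local-identifier",
                                          timestamp = "timestamp",
                                          lon = "location-long",
                                          lat = "location-lat",
                                          gps_altitude = "height-above-msl",
                                          inst_speed = "ground-speed"),
                        tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  required <- c("id", "timestamp", "lon", "lat")
  missing <- setdiff(required, names(column_map))
  missing <- union(missing,
                   required[!unlist(column_map[required]) %in% names(raw)])
  if (length(missing)) {
    stop("required columns not mappable: ", paste(missing, collapse = ", "))
  }
  out <- tibble::tibble(
    id = as.character(raw[[column_map$id]]),
    timestamp = as.POSIXct(raw[[column_map$timestamp]], tz = tz),
    lon = as.numeric(raw[[column_map$lon]]),
    lat = as.numeric(raw[[column_map$lat]]))
  for (opt in c("gps_altitude", "inst_speed")) {
    if (!is.null(column_map[[opt]]) && column_map[[opt]] %in% names(raw)) {
      out[[opt]] <- as.numeric(raw[[column_map[[opt]]]])
    }
  }
  n0 <- nrow(out)
  bad <- is.na(out$timestamp) | is.na(out$lon) | is.na(out$lat) |
    out$lat < -90 | out$lat > 90 | out$lon < -180 | out$lon > 180
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped")
    out <- out[!bad, ]
  }
  out <- out[order(out$id, out$timestamp), ]
  dup <- duplicated(out[c("id", "timestamp")])
  if (any(dup)) {
    message(sum(dup), " duplicate-timestamp row(s) dropped")
    out <- out[!dup, ]
  }
  if (nrow(out) < n0) {
    message(n0 - nrow(out), " of ", n0, " rows removed during ingestion")
  }
  out
}

#' Remove low-quality fixes by implied speed and climb rate
#'
#' Iteratively drops fixes whose step from the previous retained fix implies
#' a ground speed above `max_speed` or an absolute climb rate above
#' `max_climb`, until no violation remains. Operates per individual. The
#' thresholds are configuration, not estimated.
#'
#' @param track Relocation tibble (sorted; see [read_tracks()]).
#' @param max_speed Maximum plausible ground speed, km/h.
#' @param max_climb Maximum plausible |climb rate|, m/s.
#' @return The filtered tibble.
#' @export
quality_filter <- function(track, max_speed = 150, max_climb = 20) {
  filter_one <- function(tr) {
    repeat {
      if (nrow(tr) < 2) return(tr)
      sp <- ground_speed(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                         tr$timestamp[-nrow(tr)],
                         tr$lon[-1], tr$lat[-1], tr$timestamp[-1])
      bad <- sp > max_speed
      if (!is.null(tr[["gps_altitude"]])) {
        dt_s <- as.numeric(diff(tr$timestamp), units = "secs")
        climb <- diff(tr[["gps_altitude"]]) / dt_s
        bad <- bad | abs(climb) > max_climb
      }
      bad[is.na(bad)] <- FALSE
      if (!any(bad)) return(tr)
      # drop the later fix of the first offending step, then re-evaluate
      tr <- tr[-(which(bad)[1] + 1), ]
    }
  }
  parts <- split(track, track$id)
  out <- do.call(rbind, lapply(parts, filter_one))
  tibble::as_tibble(out[order(out$id, out$timestamp), ])
}

#' Resample a track onto the 30-minute grid
#'
#' For every 30-min slot between the first and last fix, the observed fix
#' nearest the slot time is kept if it lies within `tolerance_min`; slots
#' with no such fix stay empty (no positional interpolation -- fabricated
#' positions would corrupt the speed-based flight classification).
#' Resampling an already-30-min track returns it unchanged.
#'
#' @param track Relocation tibble for one or more individuals.
#' @param tolerance_min Slot matching tolerance in minutes.
#' @return A tibble with `slot_time` plus the matched fix columns, class
#'   `resampled_track`.
#' @export
resample_30min <- function(track, tolerance_min = 5) {
  res_one <- function(tr) {
    t0 <- as.numeric(tr$timestamp[1])
    t0 <- floor(t0 / 1800) * 1800
    slots <- seq(t0, as.numeric(tr$timestamp[nrow(tr)]) + 899, by = 1800)
    ft <- as.numeric(tr$timestamp)
    i <- findInterval(slots, ft)
    cand_lo <- pmax(i, 1)
    cand_hi <- pmin(i + 1, nrow(tr))
    d_lo <- abs(slots - ft[cand_lo])
    d_hi <- abs(slots - ft[cand_hi])
    pick <- ifelse(d_hi < d_lo, cand_hi, cand_lo)
    dist <- pmin(d_lo, d_hi)
    keep <- dist <= tolerance_min * 60
    out <- tr[pick[keep], ]
    out$slot_time <- as.POSIXct(slots[keep], tz = "UTC",
                                origin = "1970-01-01")
    # a fix can serve only its nearest slot
    out[!duplicated(pick[keep]), ]
  }
  parts <- split(track, track$id)
  out <- tibble::as_tibble(do.call(rbind, lapply(parts, res_one)))
  rownames(out) <- NULL
  class(out) <- c("resampled_track", class(out))
  out
}

#' Classify 30-min intervals as flight or stationary
#'
#' An interval is flight iff the instantaneous ground speed exceeds
#' `threshold` (strictly) at both its start and end fix; 10.0 km/h exactly
#' is stationary. Fix speeds come from the `inst_speed` column when present
#' (device-reported), otherwise from the step ending at the fix. Intervals
#' whose endpoints are not 30 min apart (data gaps) get `NA`.
#'
#' @param rt A `resampled_track` (single individual or several; intervals
#'   never span individuals).
#' @param threshold Speed threshold in km/h.
#' @return `rt` with columns `fix_speed` and `flight` (flag for the interval
#'   starting at each fix; last fix of each individual is `NA`).
#' @export
classify_flight <- function(rt, threshold = 10) {
  one <- function(tr) {
    n <- nrow(tr)
    if (is.null(tr[["inst_speed"]])) {
      sp <- c(NA, ground_speed(tr$lon[-n], tr$lat[-n], tr$slot_time[-n],
                               tr$lon[-1], tr$lat[-1], tr$slot_time[-1]))
      sp[1] <- sp[2]
      tr$fix_speed <- sp
    } else {
      tr$fix_speed <- tr$inst_speed
    }
    gap_ok <- c(as.numeric(diff(tr$slot_time), units = "mins") == 30, NA)
    fl <- tr$fix_speed > threshold &
      c(tr$fix_speed[-1] > threshold, NA)
    fl[!gap_ok %in% TRUE] <- NA
    tr$flight <- fl
    tr
  }
  parts <- split(rt, rt$id)
  out <- tibble::as_tibble(do.call(rbind, lapply(parts, one)))
  rownames(out) <- NULL
  class(out) <- c("resampled_track", class(out))
  out
}

#' Annotate a resampled track with solar phase and day length
#'
#' @param rt A `resampled_track`.
#' @return `rt` with columns `phase`, `daylight_hours`, `dark_hours`.
#' @export
annotate_solar <- function(rt) {
  sp <- solar_phase(rt$lon, rt$lat, rt$slot_time)
  rt$phase <- sp$phase
  rt$daylight_hours <- sp$daylight_hours
  rt$dark_hours <- sp$dark_hours
  rt
}
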