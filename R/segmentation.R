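# Stopover detection by the daily net-displacement rule and extraction of
# traveling segments (the track between stopovers).

#' Daily net displacement of a track
#'
#' For each calendar day (UTC by default) the distance between the last
#' relocation of the previous day and the last relocation of that day; the
#' first day is measured from the first relocation of the track. Days
#' without fixes get `NA`.
#'
#' @param track Relocation tibble for a single individual (any cadence).
#' @param tz Time zone defining the calendar day.
#' @return A tibble with `date`, `displacement_km`, and the day's last-fix
#'   coordinates.
#' @export
daily_displacement <- function(track, tz = "UTC") {
  stopifnot(length(unique(track$id)) <= 1)
  if (nrow(track) < 2) stop("need at least two days of data")
  date <- as.Date(track[["timestamp"]] %||% track[["slot_time"]], tz = tz)
  last_idx <- tapply(seq_len(nrow(track)), date, max)
  days <- seq(min(date), max(date), by = "day")
  li <- last_idx[as.character(days)]
  lon_last <- track$lon[li]; lat_last <- track$lat[li]
  # origin for each day: previous day's last fix (first day: first fix);
  # for days after a gap, the most recent day with fixes
  prev_lon <- c(track$lon[1], lon_last[-length(days)])
  prev_lat <- c(track$lat[1], lat_last[-length(days)])
  for (k in seq_along(days)[-1]) {
    if (is.na(prev_lon[k])) {
      prev_lon[k] <- prev_lon[k - 1]
      prev_lat[k] <- prev_lat[k - 1]
    }
  }
  disp <- gc_dist_km(prev_lon, prev_lat, lon_last, lat_last)
  tibble::tibble(date = days, displacement_km = disp,
                 lon_last = lon_last, lat_last = lat_last)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect stopovers by the 35 km/day rule
#'
#' Maximal runs of consecutive days whose net daily displacement does not
#' exceed `threshold` (35 km exactly qualifies) become stopovers; single
#' qualifying days count. Days without fixes inherit the previous day's
#' classification, so data gaps do not split segments.
#'
#' @param track Relocation tibble for a single individual.
#' @param threshold Daily displacement threshold in km.
#' @param tz Calendar-day time zone.
#' @return A tibble of stopovers: `start_date`, `end_date` (inclusive),
#'   `duration_days`, centroid `lon`/`lat` of member-day fixes.
#' @export
detect_stopovers <- function(track, threshold = 35, tz = "UTC") {
  dd <- daily_displacement(track, tz = tz)
  is_stop <- dd$displacement_km <= threshold
  for (k in seq_along(is_stop)[-1]) {
    if (is.na(is_stop[k])) is_stop[k] <- is_stop[k - 1]
  }
  is_stop[is.na(is_stop)] <- FALSE
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  date_all <- as.Date(track[["timestamp"]] %||% track[["slot_time"]], tz = tz)
  out <- lapply(keep, function(i) {
    d0 <- dd$date[starts[i]]; d1 <- dd$date[ends[i]]
    member <- date_all >= d0 & date_all <= d1
    tibble::tibble(start_date = d0, end_date = d1,
                   duration_days = as.numeric(d1 - d0) + 1,
                   lon = mean(track$lon[member]),
                   lat = mean(track$lat[member]))
  })
  if (!length(out)) {
    return(tibble::tibble(start_date = as.Date(character()),
                          end_date = as.Date(character()),
                          duration_days = numeric(),
                          lon = numeric(), lat = numeric()))
  }
  do.call(rbind, out)
}

#' Extract traveling segments between stopovers
#'
#' Returns the runs of consecutive travel days, each carrying
#' `days_of_migration` (days elapsed since the first track day at segment
#' start, starting at 1) and `days_at_previous_stopover` (duration of the
#' immediately preceding stopover; for the first segment the pre-departure
#' staging duration supplied as `staging_days`, typically only meaningful in
#' autumn).
#'
#' @param track Relocation tibble for a single individual.
#' @param stopovers Output of [detect_stopovers()].
#' @param staging_days Pre-departure staging duration (days) for the first
#'   segment; `NA` when unknown (e.g. spring).
#' @param tz Calendar-day time zone.
#' @return A tibble with one row per segment: `segment` (index),
#'   `start_date`, `end_date`, `n_days`, `days_of_migration`,
#'   `days_at_previous_stopover`, and a list-column `fixes` holding the
#'   member relocations.
#' @export
extract_segments <- function(track, stopovers, staging_days = NA_real_,
                             tz = "UTC") {
  date_all <- as.Date(track[["timestamp"]] %||% track[["slot_time"]], tz = tz)
  days <- seq(min(date_all), max(date_all), by = "day")
  in_stop <- rep(FALSE, length(days))
  for (i in seq_len(nrow(stopovers))) {
    in_stop[days >= stopovers$start_date[i] & days <= stopovers$end_date[i]] <- TRUE
  }
  r <- rle(!in_stop)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- lapply(seq_along(keep), function(s) {
    i <- keep[s]
    d0 <- days[starts[i]]; d1 <- days[ends[i]]
    member <- date_all >= d0 & date_all <= d1
    prev <- stopovers$end_date == d0 - 1
    prev_days <- if (any(prev)) {
      stopovers$duration_days[which(prev)[1]]
    } else if (s == 1) staging_days else NA_real_
    tibble::tibble(
      segment = s, start_date = d0, end_date = d1,
      n_days = as.numeric(d1 - d0) + 1,
      days_of_migration = as.numeric(d0 - days[1]) + 1,
      days_at_previous_stopover = prev_days,
      fixes = list(track[member, ]))
  })
  if (!length(out)) stop("track contains no travel days")
  do.call(rbind, out)
}

#' Read region polygons from a GeoJSON configuration file
#'
#' Expects a FeatureCollection of Polygon features each with a `name` (or
#' `label`) property. Only the outer ring is used.
#'
#' @param path GeoJSON file path.
#' @return Named list of two-column coordinate matrices (lon, lat).
#' @export
read_regions <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- list()
  for (f in g$features) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("region features must be Polygons")
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    label <- f$properties$name %||% f$properties$label
    if (is.null(label)) stop("region feature lacks a name property")
    out[[label]] <- m
  }
  out
}

#' Assign a geographic region label to a segment
#'
#' The label of the polygon containing the majority of the segment's
#' relocations (ties broken by polygon order); `"unassigned"` when no
#' polygon contains a plurality of fixes.
#'
#' @param segment_fixes Relocation tibble of one segment.
#' @param regions Named list of polygon matrices (see [read_regions()]).
#' @return A single region label.
#' @export
assign_region <- function(segment_fixes, regions) {
  pts <- cbind(segment_fixes$lon, segment_fixes$lat)
  counts <- vapply(regions, function(poly) {
    sum(mgcv::in.out(rbind(poly, poly[1, ]), pts))
  }, numeric(1))
  if (all(counts == 0)) return("unassigned")
  names(regions)[which.max(counts)]
}
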