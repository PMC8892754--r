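# The five traveling-behavior response variables, computed per traveling
# segment from a flight-classified, solar-annotated 30-min track.

#' Travel speed of a segment
#'
#' Cumulative great-circle path length over consecutive fixes divided by the
#' number of segment days.
#'
#' @param seg Resampled relocation tibble of one segment (>= 2 fixes).
#' @param tz Calendar-day time zone.
#' @return Speed in km/day.
#' @export
travel_speed <- function(seg, tz = "UTC") {
  if (nrow(seg) < 2) stop("travel speed needs at least two relocations")
  n <- nrow(seg)
  path <- sum(gc_dist_km(seg$lon[-n], seg$lat[-n], seg$lon[-1], seg$lat[-1]))
  dates <- as.Date(seg[["slot_time"]] %||% seg[["timestamp"]], tz = tz)
  n_days <- as.numeric(max(dates) - min(dates)) + 1
  path / n_days
}

#' Flight heights above ground of a segment
#'
#' Height = GPS altitude minus DEM ground elevation, for fixes in flight
#' (a fix is in flight when an adjacent 30-min interval is flight).
#' Negative heights are retained -- discarding them would censor genuine
#' low-altitude flight. The segment summary is the median, which resists
#' the extreme values GPS altitudes are prone to.
#'
#' @param seg Flight-classified segment tibble with `gps_altitude`.
#' @param dem A `dem_raster`.
#' @return List with `heights_agl` (per flight fix, m) and `median_agl`.
#' @export
flight_heights <- function(seg, dem) {
  fl <- seg$flight %in% TRUE
  in_flight <- fl | c(FALSE, fl[-length(fl)])  # start or end fix of a flight interval
  sub <- seg[in_flight, ]
  if (!nrow(sub)) return(list(heights_agl = numeric(), median_agl = NA_real_))
  ground <- elevation_at(dem, sub$lon, sub$lat)
  keep <- !is.na(ground)
  if (any(!keep)) warning(sum(!keep), " flight fix(es) outside the DEM excluded")
  h <- sub$gps_altitude[keep] - ground[keep]
  list(heights_agl = h, median_agl = stats::median(h))
}

#' Daily hours of flight in a segment
#'
#' 0.5 h per flight-classified 30-min interval, summed per day; the segment
#' value is the mean over segment days.
#'
#' @param seg Flight-classified segment tibble.
#' @param tz Calendar-day time zone.
#' @return List with `per_day` (tibble date/hours) and `mean_hours`.
#' @export
daily_flight_hours <- function(seg, tz = "UTC") {
  dates <- as.Date(seg$slot_time, tz = tz)
  fl <- seg$flight %in% TRUE
  per <- tapply(fl, dates, sum) * 0.5
  per_day <- tibble::tibble(date = as.Date(names(per)), hours = as.numeric(per))
  list(per_day = per_day, mean_hours = mean(per_day$hours))
}

#' Photoperiod-corrected day-to-night flight ratio
#'
#' Per day: (day flight hours / daylight hours) divided by (night flight
#' hours / dark hours). Each 30-min interval's half hour is assigned to day
#' or night by the sun's side of the horizon at the interval midpoint (which
#' also apportions dawn/dusk intervals). Zero day- or night-flight hours are
#' replaced by `correction` hours (half an interval by default) so per-day
#' ratios stay finite. Days with no daylight or no darkness are excluded
#' with a message. The segment value is the mean over days.
#'
#' @param seg Flight-classified, solar-annotated segment tibble.
#' @param correction Continuity correction in hours.
#' @param tz Calendar-day time zone.
#' @return List with `per_day` (tibble) and `mean_ratio`.
#' @export
day_night_ratio <- function(seg, correction = 0.25, tz = "UTC") {
  n <- nrow(seg)
  fl <- seg$flight %in% TRUE
  mid <- seg$slot_time + 900
  is_day <- sun_elevation(seg$lon, seg$lat, mid) > SUN_HORIZON_DEG
  dates <- as.Date(seg$slot_time, tz = tz)
  agg <- function(x) as.numeric(tapply(x, dates, sum))
  day_h <- agg(fl & is_day) * 0.5
  night_h <- agg(fl & !is_day) * 0.5
  daylight <- as.numeric(tapply(seg$daylight_hours, dates, stats::median))
  dark <- as.numeric(tapply(seg$dark_hours, dates, stats::median))
  ok <- daylight > 0 & dark > 0
  if (any(!ok)) message(sum(!ok), " polar day(s) excluded from the flight ratio")
  day_h <- pmax(day_h, correction)
  night_h <- pmax(night_h, correction)
  ratio <- (day_h / daylight) / (night_h / dark)
  per_day <- tibble::tibble(date = unique(sort(dates)), day_hours = day_h,
                            night_hours = night_h, ratio = ratio)[ok, ]
  list(per_day = per_day, mean_ratio = mean(per_day$ratio))
}

#' Straightness index of a segment
#'
#' Beeline distance between the first and last fix divided by the cumulative
#' path length; 1 for perfectly straight motion, 0 for a closed loop.
#'
#' @param seg Segment tibble (>= 2 fixes).
#' @return Straightness in `[0, 1]`.
#' @export
straightness <- function(seg) {
  if (nrow(seg) < 2) stop("straightness undefined for a single fix")
  n <- nrow(seg)
  path <- sum(gc_dist_km(seg$lon[-n], seg$lat[-n], seg$lon[-1], seg$lat[-1]))
  beeline <- gc_dist_km(seg$lon[1], seg$lat[1], seg$lon[n], seg$lat[n])
  if (path == 0) return(NA_real_)
  min(beeline / path, 1)
}

#' All five behavior metrics for one segment
#'
#' @param seg Flight-classified, solar-annotated segment tibble.
#' @param dem A `dem_raster` (median flight height is `NA` without one).
#' @param correction Continuity correction for the flight ratio, hours.
#' @return One-row tibble with `travel_speed`, `median_flight_height`,
#'   `mean_daily_flight_hours`, `mean_day_night_ratio`, `straightness`.
#' @export
segment_behaviors <- function(seg, dem = NULL, correction = 0.25) {
  tibble::tibble(
    travel_speed = travel_speed(seg),
    median_flight_height = if (is.null(dem)) NA_real_ else
      flight_heights(seg, dem)$median_agl,
    mean_daily_flight_hours = daily_flight_hours(seg)$mean_hours,
    mean_day_night_ratio = day_night_ratio(seg, correction)$mean_ratio,
    straightness = straightness(seg))
}

#' Percentage change from the individual seasonal mean
#'
#' For each individual-season group, 100 * (value - group mean) / group
#' mean. Metrics bounded below by zero therefore have a -100% lower bound.
#'
#' @param data Tibble with one row per segment.
#' @param value Name of the metric column.
#' @param individual,season Grouping column names.
#' @return `data` with an added `pct_change` column; groups with zero mean
#'   get `NA` with a warning.
#' @export
percent_change <- function(data, value, individual = "id", season = "season") {
  g <- interaction(data[[individual]], data[[season]], drop = TRUE)
  mu <- stats::ave(data[[value]], g, FUN = mean)
  if (any(mu == 0, na.rm = TRUE)) {
    warning("zero individual-season mean; percentage change undefined there")
  }
  data$pct_change <- ifelse(mu == 0, NA_real_, 100 * (data[[value]] - mu) / mu)
  data
}
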