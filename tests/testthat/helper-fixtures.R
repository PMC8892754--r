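# Shared fixture builders: everything is generated in code at test time.

# a bare resampled track from vectors; slot times on the 30-min grid
make_rt <- function(lon, lat, start = "2018-09-10 00:00:00", id = "b1",
                    altitude = NULL, inst_speed = NULL) {
  n <- length(lon)
  out <- tibble::tibble(
    id = id,
    slot_time = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 1800,
    lon = lon, lat = lat)
  if (!is.null(altitude)) out$gps_altitude <- altitude
  if (!is.null(inst_speed)) out$inst_speed <- inst_speed
  class(out) <- c("resampled_track", class(out))
  out
}

# relocation CSV on disk, Movebank dialect
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

flat_dem <- function(base = 100, width = 300, height = 300, res = 500,
                     origin = c(0, 45)) {
  generate_dem(seed = 1, width = width, height = height, resolution = res,
               origin = origin, relief = "flat", base = base)
}

# a vertical-stripe landscape: left half water, right half land (exact)
stripe_landscape <- function(width = 200, height = 200, res = 500,
                             origin = c(0, 45)) {
  spec <- landscape_spec(seed = 1, width = width, height = height,
                         resolution = res, origin = origin,
                         pattern = "homogeneous_land")
  ls <- generate_landscape(spec)
  ls$values[, seq_len(width %/% 2)] <- 17L
  ls
}
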