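# Minimal in-memory rasters on a local metric grid.
#
# A grid_raster stores a matrix of cell values on a regular grid of square
# cells (res_m metres on a side) together with a geographic anchor: the
# lon/lat of the grid's lower-left corner. Geographic coordinates are mapped
# to grid kilometres through an equirectangular projection about the anchor
# latitude, which keeps all buffer/disc geometry metric and exact for the
# regional extents the pipeline works at. Rows index y (south -> north),
# columns x (west -> east); the centre of cell [i, j] sits at
# ((j - 0.5) res, (i - 0.5) res) km from the corner.

KM_PER_DEG_LAT <- 110.574

IGBP_WETLAND <- 11L
IGBP_WATER <- 17L

grid_raster <- function(values, res_m, origin = c(0, 45), class = "grid_raster") {
  stopifnot(is.matrix(values), res_m > 0, length(origin) == 2)
  structure(
    list(values = values, res_m = res_m,
         origin = c(lon = unname(origin[1]), lat = unname(origin[2]))),
    class = unique(c(class, "grid_raster")))
}

#' @exportS3Method base::print
print.grid_raster <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells @ %g m, lower-left corner (%.4f, %.4f)\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$res_m,
              x$origin["lon"], x$origin["lat"]))
  invisible(x)
}

raster_extent_km <- function(r) {
  c(x = ncol(r$values) * r$res_m / 1000, y = nrow(r$values) * r$res_m / 1000)
}

# km-per-degree of longitude at the raster's anchor latitude
km_per_deg_lon <- function(r) KM_PER_DEG_LAT * cos(r$origin["lat"] * pi / 180)

#' Convert lon/lat to a raster's local kilometre frame
#'
#' @param r A `grid_raster`.
#' @param lon,lat Coordinates in degrees.
#' @return A list with numeric vectors `x`, `y` (km from the lower-left corner).
#' @export
lonlat_to_xy <- function(r, lon, lat) {
  list(x = unname((lon - r$origin["lon"]) * km_per_deg_lon(r)),
       y = unname((lat - r$origin["lat"]) * KM_PER_DEG_LAT))
}

#' Convert local raster kilometres back to lon/lat
#'
#' @param r A `grid_raster`.
#' @param x,y Kilometres from the raster's lower-left corner.
#' @return A list with numeric vectors `lon`, `lat`.
#' @export
xy_to_lonlat <- function(r, x, y) {
  list(lon = unname(r$origin["lon"] + x / km_per_deg_lon(r)),
       lat = unname(r$origin["lat"] + y / KM_PER_DEG_LAT))
}

#' Bilinear elevation lookup on a DEM raster
#'
#' Interpolates between the four surrounding cell centres; points within half
#' a cell of the border use the edge value in that direction. Points outside
#' the raster return `NA` with a warning.
#'
#' @param dem A `dem_raster` (see [generate_dem()]).
#' @param lon,lat Query coordinates in degrees.
#' @return Elevation(s) in metres.
#' @export
elevation_at <- function(dem, lon, lat) {
  p <- lonlat_to_xy(dem, lon, lat)
  res_km <- dem$res_m / 1000
  nx <- ncol(dem$values); ny <- nrow(dem$values)
  # fractional cell-centre coordinates
  cx <- p$x / res_km + 0.5
  cy <- p$y / res_km + 0.5
  outside <- p$x < 0 | p$y < 0 | p$x > nx * res_km | p$y > ny * res_km
  if (any(outside, na.rm = TRUE)) {
    warning(sum(outside), " point(s) outside the DEM extent; elevation set to NA")
  }
  j0 <- pmin(pmax(floor(cx), 1), nx - 1)
  i0 <- pmin(pmax(floor(cy), 1), ny - 1)
  fx <- pmin(pmax(cx - j0, 0), 1)
  fy <- pmin(pmax(cy - i0, 0), 1)
  v <- dem$values
  z <- (1 - fx) * (1 - fy) * v[cbind(i0, j0)] +
    fx * (1 - fy) * v[cbind(i0, j0 + 1)] +
    (1 - fx) * fy * v[cbind(i0 + 1, j0)] +
    fx * fy * v[cbind(i0 + 1, j0 + 1)]
  z[outside] <- NA_real_
  z
}

# Row-wise cumulative sums of the water indicator, cached on the raster, so
# that any axis-aligned row segment of water pixels can be counted with two
# lookups. Used by disc and polyline-buffer counting.
water_cumsum <- function(landscape) {
  if (!is.null(landscape$.water_cs)) return(landscape$.water_cs)
  w <- landscape$values == IGBP_WATER | landscape$values == IGBP_WETLAND
  cs <- cbind(0, t(apply(w, 1, cumsum)))
  cs
}

#' Attach the cached water-count index to a landscape
#'
#' Precomputes row-wise cumulative sums of the water indicator so repeated
#' disc/buffer queries (e.g. the randomization test) are fast. Called
#' automatically by the query functions; calling it once up front avoids
#' recomputation.
#'
#' @param landscape A `landscape_raster`.
#' @return The landscape with the index attached.
#' @export
index_water <- function(landscape) {
  landscape$.water_cs <- water_cumsum(landscape)
  landscape
}

# Count (water, total) pixels whose centres lie within radius_km of each
# query point, given in local km. Returns a list of numeric vectors.
disc_counts_xy <- function(landscape, x, y, radius_km) {
  cs <- water_cumsum(landscape)
  res_km <- landscape$res_m / 1000
  nx <- ncol(landscape$values); ny <- nrow(landscape$values)
  n <- length(x)
  r_rows <- floor(radius_km / res_km) + 1L
  water <- numeric(n); total <- numeric(n)
  # process points in blocks; each block expands to (point x row-offset)
  block <- max(1L, floor(4e6 / (2 * r_rows + 1)))
  offs <- seq.int(-r_rows, r_rows)
  for (s in seq(1, n, by = block)) {
    idx <- s:min(s + block - 1, n)
    # nearest row of cell centres for each candidate row offset
    yc <- y[idx]
    i_center <- floor(yc / res_km - 0.5 + 0.5) + 1L  # row whose centre is nearest below/above handled via dy
    i_mat <- outer(rep(1L, length(idx)), offs) + i_center
    dy <- (i_mat - 0.5) * res_km - yc
    half <- radius_km^2 - dy^2
    ok <- half >= 0 & i_mat >= 1 & i_mat <= ny
    half_km <- sqrt(pmax(half, 0))
    xc <- x[idx]
    # column range with centres within +-half_km of x
    j_lo <- pmax(ceiling((xc - half_km) / res_km + 0.5), 1)
    j_hi <- pmin(floor((xc + half_km) / res_km + 0.5), nx)
    cnt <- pmax(j_hi - j_lo + 1, 0)
    cnt[!ok] <- 0
    j_lo <- pmin(pmax(j_lo, 1), nx)
    j_hi <- pmin(pmax(j_hi, 1), nx)
    i_flat <- pmin(pmax(i_mat, 1L), ny)
    wat <- cs[cbind(as.vector(i_flat), as.vector(j_hi) + 1L)] -
      cs[cbind(as.vector(i_flat), as.vector(j_lo))]
    wat <- matrix(wat, nrow = length(idx))
    wat[!ok | cnt == 0] <- 0
    water[idx] <- rowSums(wat)
    total[idx] <- rowSums(cnt)
  }
  list(water = water, total = total)
}

#' Proportion of water within a radius of points
#'
#' Counts raster cells whose centres fall within `radius_km` of each point
#' and returns the fraction classified as aquatic habitat (IGBP codes 11 or
#' 17). Discs that extend beyond the raster are evaluated on the
#' intersection, with a warning.
#'
#' @param landscape A `landscape_raster`.
#' @param lon,lat Point coordinates in degrees (vectorised).
#' @param radius_km Disc radius in km (default 5, the evaluation scale used
#'   around observed and random points).
#' @return Numeric vector of proportions in `[0, 1]`.
#' @export
water_proportion_at <- function(landscape, lon, lat, radius_km = 5) {
  p <- lonlat_to_xy(landscape, lon, lat)
  ext <- raster_extent_km(landscape)
  clipped <- p$x < radius_km | p$y < radius_km |
    p$x > ext["x"] - radius_km | p$y > ext["y"] - radius_km
  if (any(clipped, na.rm = TRUE)) {
    warning(sum(clipped), " disc(s) extend beyond the raster; ",
            "proportion computed on the intersection")
  }
  cnt <- disc_counts_xy(landscape, p$x, p$y, radius_km)
  ifelse(cnt$total > 0, cnt$water / cnt$total, NA_real_)
}

#' Realized water fraction of a landscape
#'
#' @param landscape A `landscape_raster`.
#' @return Fraction of cells coded as IGBP 11 or 17.
#' @export
water_fraction_realized <- function(landscape) {
  mean(landscape$values == IGBP_WATER | landscape$values == IGBP_WETLAND)
}

#' Write / read a raster as an ESRI ASCII grid with a JSON sidecar
#'
#' The `.asc` file holds the cell matrix in the local metre frame (plain
#' text, readable by GDAL); the `<path>.json` sidecar records the lon/lat of
#' the lower-left corner so the georeferencing round-trips.
#'
#' @param r A `grid_raster`.
#' @param path Output path (conventionally ending in `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster_asc <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %g", r$res_m),
    "NODATA_value -9999"), con)
  # ASCII grids are written north row first
  utils::write.table(r$values[rev(seq_len(nrow(r$values))), , drop = FALSE],
                     con, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(origin_lon = unname(r$origin["lon"]), origin_lat = unname(r$origin["lat"]),
         res_m = r$res_m, class = class(r)[1]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  vals <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  if (identical(meta$class, "landscape_raster")) {
    storage.mode(vals) <- "integer"
  }
  grid_raster(vals, res_m = meta$res_m,
              origin = c(meta$origin_lon, meta$origin_lat),
              class = meta$class)
}
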