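# Synthetic categorical landscapes and terrain with known ground truth.
#
# The landscapes emulate the structure of a MODIS IGBP land-cover product:
# integer class codes on a regular grid (default 500 m cells), with aquatic
# habitat as water bodies (17) and permanent wetlands (11) and everything
# else a single terrestrial code. Patterns are deliberately schematic --
# tests need controllable spatial structure, not realism.

IGBP_LAND_DEFAULT <- 16L  # barren, an arbitrary non-water background code

#' Specification of a synthetic land-cover raster
#'
#' @param seed Integer RNG seed; identical specs produce identical rasters.
#' @param width,height Raster dimensions in pixels.
#' @param resolution Cell size in metres (default 500, MODIS-like).
#' @param origin Lon/lat of the lower-left corner.
#' @param water_fraction Target fraction of aquatic cells in `[0, 1]`.
#' @param pattern One of `"uniform_random"`, `"corridor"`, `"patches"`,
#'   `"homogeneous_water"`, `"homogeneous_land"`.
#' @param wetland_share Share of aquatic cells coded as wetlands (11) rather
#'   than water bodies (17).
#' @param corridor_width_km Width of the water band for the corridor
#'   pattern. When `NULL` the band width is derived from `water_fraction`;
#'   when given and narrower than `water_fraction` requires, the remaining
#'   water is added as uniform background speckle so the realized fraction
#'   still matches the target.
#' @param patch_scale_km Correlation length of the smoothed-noise field used
#'   by the patches pattern.
#' @param land_code IGBP code used for non-aquatic cells.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(seed = 1L, width = 200L, height = 200L,
                           resolution = 500, origin = c(0, 45),
                           water_fraction = 0.3,
                           pattern = c("uniform_random", "corridor", "patches",
                                       "homogeneous_water", "homogeneous_land"),
                           wetland_share = 0.2, corridor_width_km = NULL,
                           patch_scale_km = 5, land_code = IGBP_LAND_DEFAULT) {
  pattern <- match.arg(pattern)
  if (width < 1 || height < 1) stop("raster dimensions must be positive")
  if (water_fraction < 0 || water_fraction > 1) {
    stop("water_fraction must lie in [0, 1]")
  }
  if (wetland_share < 0 || wetland_share > 1) {
    stop("wetland_share must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), width = as.integer(width),
                 height = as.integer(height), resolution = resolution,
                 origin = origin, water_fraction = water_fraction,
                 pattern = pattern, wetland_share = wetland_share,
                 corridor_width_km = corridor_width_km,
                 patch_scale_km = patch_scale_km,
                 land_code = as.integer(land_code)),
            class = "landscape_spec")
}

# Smooth random field: white noise convolved with a separable box kernel,
# applied twice for an approximately Gaussian kernel.
smooth_noise <- function(ny, nx, scale_px) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  k <- max(1L, as.integer(scale_px))
  box <- rep(1 / k, k)
  smooth1 <- function(m) {
    m <- apply(m, 2, function(col) stats::filter(col, box, circular = TRUE))
    t(apply(m, 1, function(row) stats::filter(row, box, circular = TRUE)))
  }
  smooth1(smooth1(z))
}

#' Generate a synthetic land-cover raster
#'
#' @param spec A [landscape_spec()].
#' @return A `landscape_raster` (a `grid_raster` of integer IGBP codes).
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  ny <- spec$height; nx <- spec$width
  res_km <- spec$resolution / 1000
  wf <- spec$water_fraction
  water <- switch(spec$pattern,
    homogeneous_water = matrix(TRUE, ny, nx),
    homogeneous_land = matrix(FALSE, ny, nx),
    uniform_random = matrix(stats::runif(ny * nx) < wf, ny, nx),
    corridor = {
      if (is.null(spec$corridor_width_km)) {
        band_px <- round(wf * ny)
        bg <- 0
      } else {
        band_px <- max(1L, round(spec$corridor_width_km / res_km))
        # background speckle tops the total up to the target fraction
        bg <- max(0, (wf - band_px / ny) / (1 - band_px / ny))
      }
      start <- floor((ny - band_px) / 2) + 1L
      rows <- start:(start + band_px - 1L)
      w <- matrix(stats::runif(ny * nx) < bg, ny, nx)
      w[rows[rows >= 1 & rows <= ny], ] <- TRUE
      attr(w, "rows") <- rows
      w
    },
    patches = {
      z <- smooth_noise(ny, nx, spec$patch_scale_km / res_km)
      thr <- stats::quantile(z, 1 - wf)
      z > thr
    })
  codes <- matrix(spec$land_code, ny, nx)
  nw <- sum(water)
  if (nw > 0) {
    cls <- rep(IGBP_WATER, nw)
    n_wet <- round(spec$wetland_share * nw)
    if (n_wet > 0) cls[sample.int(nw, n_wet)] <- IGBP_WETLAND
    codes[water] <- cls
  }
  out <- grid_raster(codes, res_m = spec$resolution, origin = spec$origin,
                     class = "landscape_raster")
  out$spec <- spec
  if (spec$pattern == "corridor") out$corridor_rows <- attr(water, "rows")
  out
}

#' Latitude of the mid-line of a corridor landscape's water band
#'
#' @param landscape A corridor-pattern `landscape_raster`.
#' @return Latitude in degrees of the corridor centreline.
#' @export
corridor_center_lat <- function(landscape) {
  if (is.null(landscape$corridor_rows)) stop("not a corridor landscape")
  y_km <- (mean(range(landscape$corridor_rows)) - 0.5) * landscape$res_m / 1000
  xy_to_lonlat(landscape, 0, y_km)$lat
}

#' Generate a synthetic digital elevation model
#'
#' @param seed RNG seed (used by the `"hills"` relief).
#' @param width,height Dimensions in pixels.
#' @param resolution Cell size in metres.
#' @param origin Lon/lat of the lower-left corner.
#' @param relief `"flat"` (constant `base`), `"ramp"` (planar west-east ramp
#'   from `base` to `base + amplitude`) or `"hills"` (smoothed noise scaled
#'   to `amplitude`).
#' @param base,amplitude Elevation parameters in metres.
#' @return A `dem_raster`.
#' @export
generate_dem <- function(seed = 1L, width = 200L, height = 200L,
                         resolution = 500, origin = c(0, 45),
                         relief = c("flat", "ramp", "hills"),
                         base = 100, amplitude = 400) {
  relief <- match.arg(relief)
  set.seed(seed)
  vals <- switch(relief,
    flat = matrix(base, height, width),
    ramp = matrix(base + amplitude * (col(matrix(0, height, width)) - 1) /
                    max(width - 1, 1), height, width),
    hills = {
      z <- smooth_noise(height, width, 10)
      base + amplitude * (z - min(z)) / diff(range(z))
    })
  grid_raster(vals, res_m = resolution, origin = origin, class = "dem_raster")
}
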