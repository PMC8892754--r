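# Pressure-level matching, weather interpolation, wind decomposition and
# water overlap along buffered segments.

test_that("ISA conversion matches the nearest reanalysis level", {
  expect_equal(round(altitude_to_pressure(0), 0), 1013)
  expect_equal(nearest_pressure_level(0), 1000)
  expect_equal(nearest_pressure_level(500), 925)   # ~955 hPa
  expect_equal(nearest_pressure_level(5500), 500)  # ~505 hPa
  expect_equal(nearest_pressure_level(c(0, 500, 5500)), c(1000, 925, 500))
  expect_warning(lv <- nearest_pressure_level(20000), "clamped")
  expect_equal(lv, 300)
})

test_that("field interpolation is exact on nodes and linear between", {
  g <- generate_weather_grid(seed = 1, scenario = "constant_wind", u = 7,
                             v = -3)
  t1 <- g$times[1]
  expect_equal(interpolate_field(g, "u", g$lon[3], g$lat[4], t1, 850), 7)
  # midpoint of equal-valued nodes
  expect_equal(interpolate_field(g, "u", mean(g$lon[3:4]), mean(g$lat[4:5]),
                                 t1, 700), 7)
  # non-wind variables exist only at synoptic hours
  expect_equal(interpolate_field(g, "surface_temp", g$lon[1], g$lat[1],
                                 t1 + 3600), NA_real_)
  expect_false(is.na(interpolate_field(g, "surface_temp", g$lon[1], g$lat[1],
                                       t1)))
  # outside the hull
  expect_true(is.na(interpolate_field(g, "u", min(g$lon) - 5, g$lat[1], t1,
                                      850)))
})

test_that("wind in time interpolates linearly between 6-h steps", {
  g <- generate_weather_grid(seed = 1, scenario = "rotating_wind", u = 0,
                             v = 10, rotation_deg = 60)
  # steps: v = 10cos(0), 10cos(60deg); midpoint is the vector mean
  tm <- g$times[1] + 10800
  expect_equal(interpolate_field(g, "v", 5, 30, tm, 500),
               (10 + 10 * cos(pi / 3)) / 2, tolerance = 1e-12)
  expect_equal(interpolate_field(g, "u", 5, 30, tm, 500),
               (0 + 10 * sin(pi / 3)) / 2, tolerance = 1e-12)
})

test_that("tailwind equation fa = y cos(theta) with compass conventions", {
  east <- tailwind_crosswind(90, 10, 0)
  expect_equal(east$tailwind, 10)
  expect_equal(east$crosswind, 0, tolerance = 1e-12)
  north <- tailwind_crosswind(0, 10, 0)
  expect_equal(north$tailwind, 0, tolerance = 1e-12)
  expect_equal(north$crosswind, 10)   # a westerly comes from a northbound bird's left
  west <- tailwind_crosswind(270, 10, 0)
  expect_equal(west$tailwind, -10)
  south <- tailwind_crosswind(180, 10, 0)
  expect_equal(south$crosswind, -10)  # same wind, from a southbound bird's right
})

test_that("decomposition identity holds at random bearings and winds", {
  set.seed(4)
  b <- runif(200, 0, 360); u <- rnorm(200, 0, 8); v <- rnorm(200, 0, 8)
  d <- tailwind_crosswind(b, u, v)
  expect_equal(d$tailwind^2 + d$crosswind^2, d$y^2, tolerance = 1e-9)
  # theta = 0 gives fa = y
  along <- tailwind_crosswind((atan2(u, v) * 180 / pi) %% 360, u, v)
  expect_equal(along$tailwind, along$y, tolerance = 1e-9)
})

test_that("annotated tracks on synthetic grids recover the scenario winds", {
  g <- generate_track(track_spec(seed = 23, n_days = 2, heading = 90,
                                 start = c(5, 40)))
  rt <- classify_flight(resample_30min(g$track))
  zero <- generate_weather_grid(seed = 1, scenario = "zero_wind",
                                extent = c(-10, 40, 20, 60), n_steps = 12)
  rt0 <- annotate_wind(rt, zero)
  expect_true(all(rt0$tailwind[!is.na(rt0$tailwind)] == 0))
  const <- generate_weather_grid(seed = 1, scenario = "constant_wind",
                                 u = 10, v = 0,
                                 extent = c(-10, 40, 20, 60), n_steps = 12)
  rtc <- annotate_wind(rt, const)
  ok <- !is.na(rtc$tailwind)
  expect_true(any(ok))
  expect_equal(rtc$tailwind[ok], rep(10, sum(ok)), tolerance = 1e-4)
  expect_equal(rtc$tailwind[ok]^2 + rtc$crosswind[ok]^2,
               rep(100, sum(ok)), tolerance = 1e-9)
})

test_that("water overlap is exact on degenerate and stripe landscapes", {
  lw <- generate_landscape(landscape_spec(seed = 1, width = 120, height = 120,
                                          pattern = "homogeneous_water"))
  seg <- tibble::tibble(lon = xy_to_lonlat(lw, c(10, 20), c(30, 30))$lon,
                        lat = xy_to_lonlat(lw, c(10, 20), c(30, 30))$lat)
  expect_equal(water_overlap_segment(seg, lw), 1)
  ll <- generate_landscape(landscape_spec(seed = 1, width = 120, height = 120,
                                          pattern = "homogeneous_land"))
  expect_equal(water_overlap_segment(seg, ll), 0)

  # stripe landscape: direct pixel enumeration oracle
  st <- stripe_landscape()
  p1 <- xy_to_lonlat(st, 40, 50); p2 <- xy_to_lonlat(st, 60, 50)
  seg2 <- tibble::tibble(lon = c(p1$lon, p2$lon), lat = c(p1$lat, p2$lat))
  got <- water_overlap_segment(seg2, st, buffer_km = 5)
  # oracle: enumerate cell centres within 5 km of the segment
  res <- 0.5
  xc <- ((1:200) - 0.5) * res
  yc <- ((1:200) - 0.5) * res
  X <- outer(rep(1, 200), xc); Y <- outer(yc, rep(1, 200))
  tpar <- pmin(pmax((X - 40) / 20, 0), 1)
  d2 <- (X - (40 + tpar * 20))^2 + (Y - 50)^2
  mask <- d2 <= 25
  expected <- mean((st$values == 17L)[mask])
  expect_equal(got, expected)
  expect_gt(got, 0.4); expect_lt(got, 0.6)
})

test_that("overlap is invariant to direction and stable across resolution", {
  ls <- generate_landscape(landscape_spec(seed = 31, width = 200, height = 200,
                                          water_fraction = 0.3,
                                          pattern = "patches"))
  mk <- function(x, y) {
    p <- xy_to_lonlat(ls, x, y)
    tibble::tibble(lon = p$lon, lat = p$lat)
  }
  seg <- mk(c(20, 40, 60), c(30, 45, 40))
  fwd <- water_overlap_segment(seg, ls)
  rev <- water_overlap_segment(seg[3:1, ], ls)
  expect_equal(fwd, rev)

  # same geography refined to 2x resolution by pixel replication
  fine <- ls
  fine$values <- ls$values[rep(1:200, each = 2), rep(1:200, each = 2)]
  fine$res_m <- ls$res_m / 2
  expect_lt(abs(water_overlap_segment(seg, fine) - fwd), 0.02)
})

test_that("bilinear elevation interpolates a planar ramp exactly", {
  dem <- generate_dem(seed = 1, width = 100, height = 100, resolution = 1000,
                      origin = c(0, 45), relief = "ramp", base = 0,
                      amplitude = 198)  # 2 m per column
  # on a cell centre
  p <- xy_to_lonlat(dem, 10.5, 20.5)
  expect_equal(elevation_at(dem, p$lon, p$lat), 20, tolerance = 1e-9)
  # midway between two centres: the mean of their values
  pm <- xy_to_lonlat(dem, 11.0, 20.5)
  expect_equal(elevation_at(dem, pm$lon, pm$lat), 21, tolerance = 1e-9)
  expect_warning(out <- elevation_at(dem, -10, 45), "outside")
  expect_true(is.na(out))
})
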