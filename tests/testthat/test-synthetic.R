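# The generators: landscapes, terrain, tracks and weather grids must honour
# their specifications exactly, since every downstream test leans on them.

test_that("degenerate landscape patterns are exact", {
  lw <- generate_landscape(landscape_spec(seed = 1, width = 60, height = 60,
                                          pattern = "homogeneous_water"))
  expect_true(all(lw$values %in% c(11L, 17L)))
  expect_equal(water_fraction_realized(lw), 1)

  ll <- generate_landscape(landscape_spec(seed = 1, width = 60, height = 60,
                                          pattern = "homogeneous_land"))
  expect_equal(water_fraction_realized(ll), 0)
  expect_equal(length(unique(as.vector(ll$values))), 1)
})

test_that("uniform-random landscapes hit the target water fraction", {
  ls <- generate_landscape(landscape_spec(seed = 7, width = 500, height = 500,
                                          water_fraction = 0.30))
  expect_gte(water_fraction_realized(ls), 0.28)
  expect_lte(water_fraction_realized(ls), 0.32)
  expect_true(all(ls$values %in% c(11L, 16L, 17L)))
})

test_that("realized water fraction converges with raster size", {
  err <- vapply(c(100, 300, 900), function(n) {
    ls <- generate_landscape(landscape_spec(seed = 3, width = n, height = n,
                                            water_fraction = 0.25))
    abs(water_fraction_realized(ls) - 0.25)
  }, numeric(1))
  expect_lt(err[2], 0.02)
  expect_lt(err[3], 0.02)
  expect_lt(err[3], err[1] + 1e-3)
})

test_that("landscape generation is seed-deterministic and validates input", {
  a <- generate_landscape(landscape_spec(seed = 42, width = 80, height = 80))
  b <- generate_landscape(landscape_spec(seed = 42, width = 80, height = 80))
  expect_identical(a$values, b$values)
  expect_error(landscape_spec(water_fraction = 1.2), "water_fraction")
  expect_error(landscape_spec(width = 0), "positive")
})

test_that("corridor pattern places a contiguous band of prescribed width", {
  spec <- landscape_spec(seed = 2, width = 100, height = 200,
                         water_fraction = 0.1, pattern = "corridor")
  ls <- generate_landscape(spec)
  w <- matrix(ls$values %in% c(11L, 17L), nrow(ls$values))
  rows_water <- which(apply(w, 1, all))
  expect_equal(length(rows_water), 20)  # 10% of 200 rows
  expect_equal(rows_water, seq(min(rows_water), max(rows_water)))
  # explicit width + background speckle still meets the target fraction
  spec2 <- landscape_spec(seed = 2, width = 400, height = 400,
                          resolution = 500, water_fraction = 0.1,
                          pattern = "corridor", corridor_width_km = 5)
  ls2 <- generate_landscape(spec2)
  expect_lt(abs(water_fraction_realized(ls2) - 0.1), 0.02)
})

test_that("patches pattern yields the target fraction with spatial structure", {
  ls <- generate_landscape(landscape_spec(seed = 5, width = 200, height = 200,
                                          water_fraction = 0.2,
                                          pattern = "patches"))
  expect_lt(abs(water_fraction_realized(ls) - 0.2), 0.02)
  # spatial autocorrelation: neighbour agreement far above the Bernoulli rate
  w <- ls$values %in% c(11L, 17L)
  dim(w) <- dim(ls$values)
  agree <- mean(w[-1, ] == w[-nrow(w), ])
  expect_gt(agree, 0.9)
})

test_that("scheduled stopovers are stationary days by construction", {
  g <- generate_track(track_spec(seed = 9, n_days = 7,
                                 stopover_schedule = list(c(3, 2))))
  expect_equal(g$truth$stopover_days, c(3, 4))
  expect_true(all(g$truth$daily$km[g$truth$daily$stopover] < 35))
  expect_true(all(g$truth$daily$km[!g$truth$daily$stopover] > 35))
})

test_that("flight scheduling follows the phase probabilities", {
  g <- generate_track(track_spec(seed = 4, n_days = 4, flight_prob_day = 1,
                                 flight_prob_night = 0))
  tr <- g$truth$intervals
  mid <- tr$start + 900
  is_day <- sun_elevation(10, 55, mid) > -0.833
  # all flight is diurnal; nearly all day intervals fly (the final track
  # interval is held stationary by design)
  expect_true(all(is_day[tr$flight]))
  expect_gt(mean(tr$flight[is_day]), 0.95)
})

test_that("track generation is reproducible and respects raster extents", {
  a <- generate_track(track_spec(seed = 11, n_days = 3))
  b <- generate_track(track_spec(seed = 11, n_days = 3))
  expect_identical(a$track, b$track)
  tiny <- generate_landscape(landscape_spec(seed = 1, width = 20, height = 20,
                                            origin = c(10, 55)))
  expect_error(generate_track(track_spec(seed = 1, n_days = 5), tiny),
               "extent")
})

test_that("irregular cadences emit fixes inside the sampling bounds", {
  g <- generate_track(track_spec(seed = 6, n_days = 2,
                                 sampling_interval = c(5, 15, 60)))
  gaps <- as.numeric(diff(g$track$timestamp), units = "mins")
  expect_true(all(gaps >= 5 & gaps <= 60))
  g2 <- generate_track(track_spec(seed = 6, n_days = 2))
  expect_true(all(as.numeric(diff(g2$track$timestamp), units = "mins") == 30))
})

test_that("zero and constant wind grids are exact; rotation interpolates linearly", {
  z <- generate_weather_grid(seed = 1, scenario = "zero_wind")
  expect_true(all(z$u == 0) && all(z$v == 0))
  cw <- generate_weather_grid(seed = 1, scenario = "constant_wind",
                              u = 10, v = 0)
  expect_true(all(cw$u == 10) && all(cw$v == 0))
  rw <- generate_weather_grid(seed = 1, scenario = "rotating_wind",
                              u = 10, v = 0, rotation_deg = 90)
  tmid <- rw$times[1] + 10800
  u_mid <- interpolate_field(rw, "u", 5, 30, tmid, 850)
  v_mid <- interpolate_field(rw, "v", 5, 30, tmid, 850)
  # vector midpoint of (10, 0) and (0, -10)
  expect_equal(u_mid, 5, tolerance = 1e-12)
  expect_equal(v_mid, -5, tolerance = 1e-12)
})

test_that("generated files round-trip through the plain-text writers", {
  ls <- generate_landscape(landscape_spec(seed = 8, width = 30, height = 20))
  p <- tempfile(fileext = ".asc")
  write_raster_asc(ls, p)
  back <- read_raster_asc(p)
  expect_identical(back$values, ls$values)
  expect_equal(back$origin, ls$origin)
  expect_s3_class(back, "landscape_raster")

  g <- generate_track(track_spec(seed = 2, n_days = 2))
  pc <- tempfile(fileext = ".csv")
  write_tracks_csv(g$track, pc, truth = g$truth)
  back_tr <- read_tracks(pc)
  expect_equal(nrow(back_tr), nrow(g$track))
  expect_equal(back_tr$lon, g$track$lon)
  expect_true(file.exists(paste0(pc, ".truth.json")))

  wg <- generate_weather_grid(seed = 1, n_steps = 2)
  pw <- tempfile(fileext = ".csv")
  write_weather_csv(wg, pw)
  expect_true(file.exists(pw) && file.exists(paste0(pw, ".json")))
})
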