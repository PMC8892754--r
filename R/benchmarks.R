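# Seeded end-to-end benchmark studies on synthetic data with known ground
# truth. These are the package's calibration experiments: each runs the
# full pipeline (generate -> process -> measure) and returns the summary
# statistics a validation report needs. Problem sizes are chosen so each
# study runs in seconds to a few minutes on one core; the methods vignette
# discusses the choices.

#' Day-level stopover recovery over seeded synthetic tracks
#'
#' Generates `n_tracks` 14-day tracks with randomly placed 2-4 day
#' stopovers, runs 30-min resampling and the 35 km/day segmentation, and
#' scores the fraction of track days whose stopover/travel classification
#' matches the generative truth.
#'
#' @param n_tracks Number of tracks.
#' @param noise_km SD of isotropic position noise applied to every fix.
#' @param seed Master seed.
#' @return List with `day_agreement` (fraction over all tracks and days)
#'   and `per_track` (numeric vector).
#' @export
benchmark_segmentation_recovery <- function(n_tracks = 50, noise_km = 0,
                                            seed = 1L) {
  per_track <- numeric(n_tracks)
  for (k in seq_len(n_tracks)) {
    set.seed(seed + 104729L * k)
    s1 <- sample(3:6, 1); d1 <- sample(2:4, 1)
    s2 <- s1 + d1 + sample(2:3, 1); d2 <- sample(2:3, 1)
    sched <- list(c(s1, d1))
    if (s2 + d2 <= 13) sched <- c(sched, list(c(s2, d2)))
    g <- generate_track(track_spec(
      seed = seed + 7L * k, n_days = 14L, stopover_schedule = sched,
      noise_km = noise_km))
    rt <- resample_30min(g$track)
    st <- detect_stopovers(rt)
    days <- g$truth$daily$date
    got <- rep(FALSE, length(days))
    for (i in seq_len(nrow(st))) {
      got[days >= st$start_date[i] & days <= st$end_date[i]] <- TRUE
    }
    per_track[k] <- mean(got == g$truth$daily$stopover)
  }
  list(day_agreement = mean(per_track), per_track = per_track)
}

#' Behavior-metric recovery on a deterministic equatorial schedule
#'
#' One noiseless track flying 6 h by day (of ~12 h daylight) and 3 h by
#' night (of ~12 h darkness) at the equator over a flat terrain, so every
#' metric has a closed-form truth: travel speed equals the generated daily
#' distance, flight hours are exactly 9, the photoperiod-corrected
#' day/night ratio is 2, and a constant-heading track is straight.
#'
#' @param seed Master seed.
#' @return List with `travel_speed`, `truth_speed`, `speed_err_pct`,
#'   `hours`, `truth_hours`, `ratio`, `straightness`, `median_agl`.
#' @export
benchmark_metric_recovery <- function(seed = 1L) {
  g <- generate_track(track_spec(
    seed = seed, n_days = 3, start = c(0, 0.5), heading = 90,
    daily_schedule = list(day_hours = 6, night_hours = 3,
                          day_start_hour = 10, night_start_hour = 2),
    altitude_noise_sd = 0, height_agl_sd = 0, height_agl_mean = 300))
  dem <- generate_dem(seed = seed, width = 700, height = 200,
                      resolution = 2000, origin = c(-1, -1), relief = "flat",
                      base = 0)
  rt <- annotate_solar(classify_flight(resample_30min(g$track)))
  b <- segment_behaviors(rt, dem)
  truth_speed <- sum(g$truth$daily$km) / nrow(g$truth$daily)
  list(travel_speed = b$travel_speed, truth_speed = truth_speed,
       speed_err_pct = 100 * abs(b$travel_speed - truth_speed) / truth_speed,
       hours = b$mean_daily_flight_hours,
       truth_hours = mean(g$truth$daily$flight_hours),
       ratio = b$mean_day_night_ratio,
       straightness = b$straightness,
       median_agl = b$median_flight_height)
}

#' Wind-decomposition checks on synthetic weather grids
#'
#' Annotates a due-east flight with a zero-wind grid and a constant 10 m/s
#' westerly (u = 10, v = 0), and reports the largest deviation from the
#' expected tailwinds and from the identity fa^2 + cross^2 = y^2.
#'
#' @param seed Master seed.
#' @return List with `max_abs_tailwind_zero`, `tailwind_east` (mean under
#'   the constant westerly), `max_identity_err`, `n_fixes`.
#' @export
benchmark_wind_decomposition <- function(seed = 1L) {
  g <- generate_track(track_spec(seed = seed, n_days = 2, heading = 90,
                                 start = c(5, 40)))
  rt <- classify_flight(resample_30min(g$track))
  ext <- c(-10, 40, 20, 60)
  zero <- generate_weather_grid(seed = seed, scenario = "zero_wind",
                                extent = ext, n_steps = 12)
  const <- generate_weather_grid(seed = seed, scenario = "constant_wind",
                                 u = 10, v = 0, extent = ext, n_steps = 12)
  r0 <- annotate_wind(rt, zero)
  rc <- annotate_wind(rt, const)
  ok <- !is.na(rc$tailwind)
  list(max_abs_tailwind_zero = max(abs(r0$tailwind[!is.na(r0$tailwind)])),
       tailwind_east = mean(rc$tailwind[ok]),
       max_identity_err = max(abs(rc$tailwind[ok]^2 + rc$crosswind[ok]^2 -
                                    (rc$u[ok]^2 + rc$v[ok]^2))),
       n_fixes = sum(ok))
}

#' Type-I calibration of the randomization test on a selection-free landscape
#'
#' Uniform-random relocations on a uniform-random 30%-water landscape carry
#' no selection signal, so the fraction of significant tests measures the
#' attained level of the add-one rank test (0.04 at 99 null points and
#' alpha = 0.05). A 100 m grid keeps the 5-km-disc proportions effectively
#' continuous so rank ties do not depress the level.
#'
#' @param n_relocations Number of tested relocations.
#' @param seed Master seed.
#' @return List with `significant_fraction`, `expected_level`, `n`.
#' @export
benchmark_selection_calibration <- function(n_relocations = 10000,
                                            seed = 1L) {
  ls <- generate_landscape(landscape_spec(
    seed = seed, width = 4000, height = 4000, resolution = 100,
    water_fraction = 0.30, pattern = "uniform_random"))
  ls <- index_water(ls)
  set.seed(seed + 1L)
  x <- stats::runif(n_relocations, 41, 359)
  y <- stats::runif(n_relocations, 41, 359)
  p <- xy_to_lonlat(ls, x, y)
  rt <- tibble::tibble(
    id = "cal", slot_time = as.POSIXct("2018-09-01", tz = "UTC") +
      seq_len(n_relocations) * 1800, lon = p$lon, lat = p$lat)
  tests <- selection_tests(rt, ls, buffers = 35, n = 99, seed = seed)
  list(significant_fraction = mean(tests$significant),
       expected_level = 0.04, n = n_relocations)
}

#' Power and buffer-monotonicity of the randomization test on a corridor
#'
#' A track pinned to the centreline of a water corridor exactly as wide as
#' the 5 km evaluation disc, on a landscape that is 10% water overall (the
#' rest as uniform speckle). Every observed disc is pure water while null
#' discs almost never are, so the test should flag nearly every relocation
#' at all three availability radii.
#'
#' @param n_relocations Relocations along the corridor.
#' @param seed Master seed.
#' @return List with `significant_fraction` (named by buffer),
#'   `buffers_km`, `n`.
#' @export
benchmark_corridor_selection <- function(n_relocations = 60, seed = 1L) {
  ls <- generate_landscape(landscape_spec(
    seed = seed, width = 2400, height = 2400, resolution = 100,
    water_fraction = 0.10, pattern = "corridor", corridor_width_km = 10.1))
  ls <- index_water(ls)
  lat_mid <- corridor_center_lat(ls)
  x <- 90 + (seq_len(n_relocations) - 1) * 1 + 0.05  # pixel centres, 1 km apart
  lon <- xy_to_lonlat(ls, x, rep(0, length(x)))$lon
  rt <- tibble::tibble(
    id = "cor", slot_time = as.POSIXct("2018-09-01", tz = "UTC") +
      seq_along(x) * 1800, lon = lon, lat = lat_mid)
  tests <- selection_tests(rt, ls, buffers = c(35, 50, 80), n = 99,
                           seed = seed)
  frac <- vapply(c(35, 50, 80), function(b)
    mean(tests$significant[tests$buffer_km == b]), numeric(1))
  names(frac) <- c("35", "50", "80")
  list(significant_fraction = frac, buffers_km = c(35, 50, 80),
       n = n_relocations)
}

#' Parameter recovery of the model-averaging pipeline over seeded replicates
#'
#' Each replicate simulates 20 individuals x 10 segments from a mixed model
#' with a strong water effect (-200 km/day per unit proportion) and two
#' zero-effect predictors, runs the all-subsets BIC averaging with
#' zero-method coefficients, and scores: does the averaged 95% CI cover the
#' true water effect; are the null predictors flagged indistinguishable
#' from zero; and does the zero-method shrinkage inequality hold for every
#' predictor.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param beta_water True water effect (km/day per unit proportion).
#' @return List with `coverage` (fraction of replicates covering the
#'   truth), `null_nondistinguishable_rate`, `shrinkage_ok` (all
#'   replicates), `n_reps`.
#' @export
benchmark_lmm_recovery <- function(n_reps = 100, seed = 1L,
                                   beta_water = -200) {
  cover <- logical(n_reps)
  null_flags <- integer(0)
  shrink_ok <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    d <- simulate_segment_data(
      seed = seed + 797L * r, n_individuals = 20, n_segments = 10,
      beta = c(water = beta_water, x1 = 0, x2 = 0),
      intercept = 400, sd_individual = 30, sd_residual = 50)
    av <- suppressWarnings(
      average_models(d, "response", c("water", "x1", "x2"), random = "id",
                     criterion = "BIC"))
    est <- av$estimates
    ew <- est[est$predictor == "water", ]
    cover[r] <- ew$ci_lower <= beta_water && beta_water <= ew$ci_upper
    null_flags <- c(null_flags,
                    !est$distinguishable[est$predictor %in% c("x1", "x2")])
    shrink_ok[r] <- all(abs(est$estimate) <=
                          abs(est$estimate_conditional) + 1e-12)
  }
  list(coverage = mean(cover), n_covered = sum(cover),
       null_nondistinguishable_rate = mean(null_flags),
       shrinkage_ok = all(shrink_ok), n_reps = n_reps)
}
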