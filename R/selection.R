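# Used-versus-available randomization test of aquatic-habitat selection:
# each observed relocation is compared against 99 random points drawn in a
# surrounding availability buffer, on the proportion of water within 5 km.

#' Theoretical visual range from flight height
#'
#' Horizon distance `sqrt(2 R h)` with R = 6371 km; the geometric upper
#' bound on how far an airborne bird could see the surface. A bird at 500 m
#' has a range of about 80 km.
#'
#' @param height_m Height(s) above the surface, metres (non-negative).
#' @return Range in km.
#' @export
visual_range <- function(height_m) {
  if (any(height_m < 0)) stop("height must be non-negative")
  sqrt(2 * EARTH_RADIUS_KM * height_m / 1000)
}

#' Random points uniform by area in a geodesic disc
#'
#' Radii drawn as `radius * sqrt(U)` and bearings uniform, so points are
#' uniform over the disc.
#'
#' @param lon,lat Disc centre, degrees.
#' @param radius_km Disc radius.
#' @param n Number of points.
#' @return Tibble with `lon`, `lat`, `dist_km`.
#' @export
sample_random_points <- function(lon, lat, radius_km, n = 99) {
  if (radius_km <= 0) stop("radius must be positive")
  r <- radius_km * sqrt(stats::runif(n))
  b <- stats::runif(n, 0, 360)
  p <- gc_destination(rep(lon, n), rep(lat, n), b, r)
  tibble::tibble(lon = p[, 1], lat = p[, 2], dist_km = r)
}

#' Randomization test of habitat selection at one relocation
#'
#' Compares the observed 5-km water proportion to those of `n` random
#' points uniform in a `buffer_km` availability disc. One-tailed add-one
#' rank p-value `p = (1 + #(null >= observed)) / (n + 1)`; ties count
#' against the observation (conservative). Significant iff `p < 0.05`.
#'
#' @param landscape A `landscape_raster`.
#' @param lon,lat Observed relocation.
#' @param buffer_km Availability radius (35, 50 or 80 km in practice).
#' @param n Number of random points.
#' @param radius_km Evaluation-disc radius around each point.
#' @return List: `observed`, `null` (length-n vector), `p_value`,
#'   `significant`, `homogeneous` (all nulls identical to the observation).
#' @export
selection_test <- function(landscape, lon, lat, buffer_km, n = 99,
                           radius_km = 5) {
  pts <- sample_random_points(lon, lat, buffer_km, n)
  obs <- water_proportion_at(landscape, lon, lat, radius_km)
  null <- water_proportion_at(landscape, pts$lon, pts$lat, radius_km)
  p <- (1 + sum(null >= obs)) / (n + 1)
  list(observed = obs, null = null, p_value = p,
       significant = p < 0.05,
       homogeneous = all(null == obs))
}

#' Run the randomization test over a track
#'
#' One test per relocation and buffer radius. Each relocation gets its own
#' RNG stream derived from `seed` and its index, so results are reproducible
#' regardless of evaluation order.
#'
#' @param rt Flight-classified, solar-annotated `resampled_track` (columns
#'   `phase` and `flight` are carried into the result when present).
#' @param landscape A `landscape_raster`.
#' @param buffers Availability radii in km.
#' @param n Random points per relocation.
#' @param seed Master seed.
#' @param radius_km Evaluation-disc radius.
#' @return Tibble with one row per relocation x buffer: `id`, `slot_time`,
#'   `buffer_km`, `observed`, `p_value`, `significant`, `homogeneous`, and
#'   `phase`/`activity` when available.
#' @export
selection_tests <- function(rt, landscape, buffers = c(35, 50, 80), n = 99,
                            seed = 1L, radius_km = 5) {
  landscape <- index_water(landscape)
  nr <- nrow(rt) * length(buffers)
  idx <- rep(seq_len(nrow(rt)), each = length(buffers))
  buf <- rep(buffers, nrow(rt))
  obs <- pval <- numeric(nr)
  sig <- hom <- logical(nr)
  for (k in seq_len(nr)) {
    i <- idx[k]
    set.seed((seed + 7919L * i + 13L * as.integer(buf[k])) %%
               .Machine$integer.max)
    st <- selection_test(landscape, rt$lon[i], rt$lat[i], buf[k], n,
                         radius_km)
    obs[k] <- st$observed; pval[k] <- st$p_value
    sig[k] <- st$significant; hom[k] <- st$homogeneous
  }
  tibble::tibble(
    id = rt$id[idx], slot_time = rt$slot_time[idx], buffer_km = buf,
    observed = obs, p_value = pval, significant = sig, homogeneous = hom,
    phase = if (is.null(rt[["phase"]])) NA_character_ else
      as.character(rt[["phase"]][idx]),
    activity = if (is.null(rt[["flight"]])) NA_character_ else
      ifelse(rt[["flight"]][idx] %in% TRUE, "flight", "stationary"))
}

#' Summarise selection tests per individual-day and stratum
#'
#' Relocations whose 99 null proportions are all identical to the observed
#' value (fully homogeneous surroundings, e.g. open sea or desert) are
#' excluded. Returns per individual x day x buffer x phase x activity the
#' number of tested and significant relocations, the proportion significant,
#' and hours in selected habitat (0.5 h per significant fix). The result
#' feeds the binomial GLMM of [fit_selection_glmm()].
#'
#' @param tests Output of [selection_tests()].
#' @param tz Calendar-day time zone.
#' @return Tibble of per-day strata.
#' @export
summarize_selection <- function(tests, tz = "UTC") {
  tests <- tests[!tests$homogeneous, ]
  if (!nrow(tests)) return(tibble::tibble())
  tests$date <- as.Date(tests$slot_time, tz = tz)
  g <- list(id = tests$id, date = tests$date, buffer_km = tests$buffer_km,
            phase = tests$phase, activity = tests$activity)
  agg_n <- stats::aggregate(tests$significant, g, length)
  agg_s <- stats::aggregate(tests$significant, g, sum)
  out <- tibble::as_tibble(agg_n)
  names(out)[names(out) == "x"] <- "n"
  out$n_significant <- agg_s$x
  out$prop_significant <- out$n_significant / out$n
  out$hours_selected <- out$n_significant * 0.5
  out
}

#' Binomial GLMM: does selection vary with time of day and activity?
#'
#' Fits `cbind(n_significant, n - n_significant) ~ phase * activity +
#' (1 | id)` with a binomial family, the inference stage attached to the
#' per-day selection summaries.
#'
#' @param summary_data Output of [summarize_selection()] for one buffer.
#' @return A fitted `glmerMod`.
#' @export
fit_selection_glmm <- function(summary_data) {
  lme4::glmer(
    cbind(n_significant, n - n_significant) ~ phase * activity + (1 | id),
    data = summary_data, family = stats::binomial())
}
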