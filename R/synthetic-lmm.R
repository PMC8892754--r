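# Segment-level simulator for the inference stage: draws segment behavior
# responses directly from the mixed model the pipeline fits, with known
# coefficients, so estimator calibration (CI coverage, false-positive
# rates, averaging shrinkage) can be measured without generating full
# trajectories.

#' Simulate per-segment behavior data from a known mixed model
#'
#' `y_ij = intercept + X_ij beta + b_i + e_ij` with `b_i ~ N(0,
#' sd_individual^2)` and `e_ij ~ N(0, sd_residual^2)`. The `water`
#' predictor is uniform on [0, 1] (a proportion); every other named
#' coefficient gets a standard-normal predictor.
#'
#' @param seed RNG seed.
#' @param n_individuals,n_segments Individuals and segments per individual.
#' @param beta Named coefficient vector, e.g. `c(water = -200, tailwind =
#'   0)`.
#' @param intercept Fixed intercept.
#' @param sd_individual SD of the individual random intercept.
#' @param sd_residual Residual SD.
#' @return Tibble with `id`, `segment`, the predictors, and `response`;
#'   the generating parameters are attached as attribute `truth`.
#' @export
simulate_segment_data <- function(seed = 1L, n_individuals = 20,
                                  n_segments = 10,
                                  beta = c(water = -200),
                                  intercept = 400,
                                  sd_individual = 30, sd_residual = 50) {
  set.seed(seed)
  n <- n_individuals * n_segments
  id <- factor(rep(sprintf("bird%02d", seq_len(n_individuals)),
                   each = n_segments))
  X <- sapply(names(beta), function(nm) {
    if (nm == "water") stats::runif(n) else stats::rnorm(n)
  })
  X <- matrix(X, nrow = n, dimnames = list(NULL, names(beta)))
  b <- stats::rnorm(n_individuals, 0, sd_individual)
  y <- intercept + drop(X %*% beta) + b[as.integer(id)] +
    stats::rnorm(n, 0, sd_residual)
  out <- tibble::tibble(id = id,
                        segment = rep(seq_len(n_segments), n_individuals))
  for (nm in colnames(X)) out[[nm]] <- X[, nm]
  out$response <- y
  attr(out, "truth") <- list(beta = beta, intercept = intercept,
                             sd_individual = sd_individual,
                             sd_residual = sd_residual)
  out
}
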