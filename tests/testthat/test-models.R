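# Predictor conditioning, collinearity screening, transforms, mixed-model
# contracts, information-criterion machinery and model averaging.

test_that("standardization centres and scales by one sample SD", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40), g = c("x", "y", "z"))
  s <- standardize(d, c("a", "b"))
  expect_equal(s$data$a, c(-1, 0, 1))
  expect_equal(mean(s$data$b), 0, tolerance = 1e-12)
  expect_equal(sd(s$data$b), 1, tolerance = 1e-12)
  expect_identical(s$data$g, d$g)
  # round-trip through the scaling record
  expect_equal(s$data$b * s$scaling$sd[2] + s$scaling$mean[2], d$b)
  # already standardized input is unchanged
  s2 <- standardize(s$data, c("a", "b"))
  expect_equal(s2$data$a, s$data$a, tolerance = 1e-12)
  expect_error(standardize(data.frame(a = c(1, 1, 1)), "a"), "zero-variance")
})

test_that("VIF screen drops collinear predictors at tolerance < 0.20", {
  set.seed(2)
  n <- 200
  x1 <- rnorm(n); x3 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n),
                  x3 = x3)
  ortho <- vif_screen(d, c("x1", "x3"))
  expect_equal(ortho$vif$vif, c(1, 1), tolerance = 0.05)
  expect_length(ortho$dropped, 0)

  # closed form: r = 0.9 between x1 and x2 gives VIF ~ 1/(1-0.81) ~ 5.26
  r <- cor(d$x1, d$x2)
  v <- vif_screen(d[c("x1", "x2")], c("x1", "x2"))
  expect_equal(1 / (1 - r^2), 5.26, tolerance = 0.5)
  if (1 / (1 - r^2) > 5) expect_length(v$dropped, 1)

  # independent route: car's VIF on an lm with the same predictors
  d$y <- rnorm(n)
  v_pkg <- vif_screen(d, c("x1", "x2", "x3"),
                      tolerance_threshold = 0)$vif  # no dropping, report only
  v_car <- car::vif(lm(y ~ x1 + x2 + x3, data = d))
  expect_equal(v_pkg$vif, unname(v_car[v_pkg$predictor]), tolerance = 1e-8)

  dup <- d; dup$x1b <- d$x1
  expect_warning(vd <- vif_screen(dup, c("x1", "x1b", "x3")), "collinearity")
  expect_length(vd$dropped, 1)
  # the user's preference decides which near-duplicate goes
  vp <- suppressWarnings(
    vif_screen(dup, c("x1", "x1b", "x3"), prefer_drop = "x1b"))
  expect_true("x1b" %in% vp$dropped)
  expect_true(all(vp$vif$tolerance >= 0.20))
})

test_that("Box-Cox lambda is recovered on known families", {
  set.seed(3)
  ln <- power_transform(exp(rnorm(500)))
  expect_lt(abs(ln$lambda), 0.15)
  gs <- power_transform(rnorm(2000, 10, 2))
  expect_equal(gs$lambda, 1, tolerance = 0.5)
  # lambda = 1 is the identity up to an affine shift
  y <- rnorm(50, 10)
  tr <- (y^1 - 1) / 1
  expect_equal(tr, y - 1)
  # shifted when non-positive values are present
  sh <- power_transform(c(0, 1, 2, 5, 10))
  expect_gt(sh$shift, 0)
  expect_warning(power_transform(rep(3, 10)), "constant")
})

test_that("candidate set enumerates all fixed-effect subsets", {
  expect_length(candidate_set(c("a", "b", "c")), 8)
  expect_length(candidate_set(character()), 1)
  expect_length(candidate_set(letters[1:11]), 2048)
  expect_error(candidate_set(letters[1:21]), "20")
})

test_that("Akaike weights follow exp(-delta/2) renormalization", {
  d <- simulate_segment_data(seed = 5, beta = c(water = -200, x1 = 0))
  fits <- fit_candidates(d, "response", c("water", "x1"), random = "id")
  ctab <- ic_weights(fits, "AICc")
  expect_equal(sum(ctab$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(ctab$cum_weight))
  # closed form at delta = 2: w = 1 / (1 + e^-1) = 0.7311
  w <- exp(-c(0, 2) / 2); w <- w / sum(w)
  expect_equal(w[1], 0.7311, tolerance = 1e-4)
  # equal criterion values split the weight evenly
  w2 <- exp(-c(0, 0) / 2); w2 <- w2 / sum(w2)
  expect_equal(w2, c(0.5, 0.5))
})

test_that("zero-method averaging multiplies by the containing weight", {
  d <- simulate_segment_data(seed = 8,
                             beta = c(water = -200, x1 = 0, x2 = 0))
  av <- average_models(d, "response", c("water", "x1", "x2"),
                       criterion = "BIC")
  est <- av$estimates
  # zero method: estimate = conditional estimate * weight of models
  # containing the predictor
  expect_equal(est$estimate,
               est$estimate_conditional * est$weight_containing,
               tolerance = 1e-9)
  # shrinkage: the zero-method magnitude never exceeds the conditional one
  expect_true(all(abs(est$estimate) <= abs(est$estimate_conditional) + 1e-12))
  # a dominant predictor is averaged over models that all contain it
  ew <- est[est$predictor == "water", ]
  expect_equal(ew$weight_containing, 1, tolerance = 1e-6)
  expect_true(ew$distinguishable)
  expect_true(ew$ci_lower < -200 & ew$ci_upper > -200)
  # weights of the confidence set are renormalized to 1
  expect_equal(sum(av$weights), 1, tolerance = 1e-12)
})

test_that("a single model above the confidence mass is returned as-is", {
  d <- simulate_segment_data(seed = 12, beta = c(water = -200))
  fits <- fit_candidates(d, "response", "water", random = "id")
  ctab <- ic_weights(fits, "BIC")
  expect_gt(ctab$weight[1], 0.95)
  av <- model_average(ctab)
  expect_equal(av$n_models, 1)
  expect_equal(av$estimates$estimate,
               unname(lme4::fixef(ctab$fit[[1]]$fit)["water"]),
               tolerance = 1e-9)
})

test_that("random-effect selection avoids singular structures", {
  # no colony effect: the colony variance collapses and is rejected
  d <- simulate_segment_data(seed = 21, n_individuals = 24,
                             beta = c(water = -200))
  d$colony <- factor(rep(sprintf("c%d", 1:4), length.out = nrow(d)))
  sel <- select_random_effects(d, "response", "water",
                               candidates = list("id", c("id", "colony")))
  expect_equal(sel$random, "id")
  # a real colony effect is kept
  d2 <- d
  d2$response <- d2$response +
    c(-120, 80, -60, 150)[as.integer(d2$colony)]
  sel2 <- select_random_effects(d2, "response", "water",
                                candidates = list("id", c("id", "colony")))
  expect_equal(sel2$random, c("id", "colony"))
  # single candidate comes straight back
  sel3 <- select_random_effects(d, "response", "water", candidates = list("id"))
  expect_equal(sel3$random, "id")
})

test_that("likelihood-ratio tests match the chi-square reference", {
  d <- simulate_segment_data(seed = 31, beta = c(water = -200, x1 = 0))
  m0 <- fit_lmm(d, "response", "x1", random = "id")
  m1 <- fit_lmm(d, "response", c("water", "x1"), random = "id")
  lrt <- likelihood_ratio_test(m0, m1)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p_value, 0.001)
  same <- likelihood_ratio_test(m1, m1)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)
  # df = 1, chi-square 3.84 sits at p ~ 0.05
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_error(likelihood_ratio_test(m1, m0), "not nested")
})

test_that("an intercept-only fit recovers the sample mean", {
  d <- simulate_segment_data(seed = 41, beta = c(water = 0))
  m <- fit_lmm(d, "response", character(), random = "id")
  expect_equal(unname(lme4::fixef(m$fit)[1]), mean(d$response),
               tolerance = 1)
})

test_that("BIC concentrates on the true sparse model as n grows", {
  hit <- function(n_ind) {
    d <- simulate_segment_data(seed = 51 + n_ind, n_individuals = n_ind,
                               n_segments = 10,
                               beta = c(water = -200, x1 = 0, x2 = 0))
    fits <- fit_candidates(d, "response", c("water", "x1", "x2"),
                           random = "id")
    ctab <- ic_weights(fits, "BIC")
    ctab$model[1] == "water"
  }
  expect_true(hit(100))  # n = 1000: true model dominates
})

test_that("spring predictor sets drop stopover fuelling, rain and age", {
  p <- c("water", "tailwind", "crosswind", "precip",
         "days_at_previous_stopover", "days_of_migration", "age")
  expect_identical(season_predictors(p, "autumn"), p)
  sp <- season_predictors(p, "spring")
  expect_false(any(c("precip", "days_at_previous_stopover", "age") %in% sp))
  expect_true(all(c("water", "tailwind") %in% sp))
})
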