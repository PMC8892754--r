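# Predictor conditioning, collinearity screening, response transforms,
# mixed-model fitting, information-criterion model averaging and
# likelihood-ratio tests.

#' Centre and scale predictors to unit standard deviation
#'
#' Each numeric predictor is centred on its mean and scaled by one sample
#' standard deviation; non-numeric columns pass through. The scaling record
#' allows coefficients to be mapped back to the raw scale.
#'
#' @param data Data frame of predictors (and possibly other columns).
#' @param cols Columns to standardize (default: all numeric among `cols`).
#' @return List with `data` (standardized) and `scaling` (tibble of column,
#'   mean, sd).
#' @export
standardize <- function(data, cols = names(data)) {
  cols <- cols[vapply(data[cols], is.numeric, logical(1))]
  mu <- vapply(data[cols], mean, numeric(1))
  sdev <- vapply(data[cols], stats::sd, numeric(1))
  zero <- sdev == 0 | is.na(sdev)
  if (any(zero)) {
    stop("zero-variance column(s): ", paste(cols[zero], collapse = ", "))
  }
  for (i in seq_along(cols)) {
    data[[cols[i]]] <- (data[[cols[i]]] - mu[i]) / sdev[i]
  }
  list(data = data, scaling = tibble::tibble(column = cols, mean = mu,
                                             sd = sdev))
}

#' Variance-inflation screening of predictors
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` from regressing each predictor on all
#' others and iteratively drops the worst offender until every tolerance
#' (`1 / VIF`) is at least `tolerance_threshold` (0.20, i.e. VIF <= 5).
#' When several variables are near-duplicates the `prefer_drop` argument
#' decides which goes first (e.g. dropping surface temperature in favour of
#' air temperature, the condition the bird actually experiences aloft).
#'
#' @param data Data frame containing the predictors.
#' @param cols Predictor column names (numeric).
#' @param tolerance_threshold Minimum acceptable tolerance.
#' @param prefer_drop Character vector of columns to drop first whenever
#'   they are among the offenders.
#' @return List with `retained`, `dropped`, and a `vif` tibble (final VIF
#'   and tolerance per retained predictor).
#' @export
vif_screen <- function(data, cols, tolerance_threshold = 0.20,
                       prefer_drop = NULL) {
  if (length(cols) < 2) stop("need at least two predictors")
  compute_vif <- function(cc) {
    vapply(cc, function(j) {
      fit <- stats::lm(stats::reformulate(setdiff(cc, j), response = j),
                       data = data)
      # a perfect fit is exactly what the screen must detect; silence lm's
      # numerical-reliability warning for that case
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  retained <- cols
  dropped <- character()
  repeat {
    if (length(retained) < 2) break
    v <- compute_vif(retained)
    offenders <- retained[1 / v < tolerance_threshold]
    if (!length(offenders)) break
    drop <- intersect(prefer_drop, offenders)
    drop <- if (length(drop)) drop[1] else retained[which.max(v)]
    if (is.infinite(max(v))) {
      warning("perfect collinearity; dropping ", drop)
    }
    dropped <- c(dropped, drop)
    retained <- setdiff(retained, drop)
  }
  v <- if (length(retained) >= 2) compute_vif(retained) else 1
  v <- unname(v)
  list(retained = retained, dropped = dropped,
       vif = tibble::tibble(predictor = retained, vif = v,
                            tolerance = 1 / v))
}

#' Box-Cox power transform of a response
#'
#' Chooses lambda by profile maximum likelihood over a grid. Responses
#' containing non-positive values are shifted so the minimum becomes one
#' hundredth of the data range (recorded for back-transformation).
#'
#' @param y Numeric response.
#' @param lambda_grid Grid of candidate lambda values.
#' @return List with `y_trans`, `lambda`, `shift`.
#' @export
power_transform <- function(y, lambda_grid = seq(-2, 2, 0.05)) {
  if (length(unique(y)) < 2) {
    warning("constant response; identity transform")
    return(list(y_trans = y, lambda = 1, shift = 0))
  }
  shift <- 0
  if (min(y) <= 0) {
    shift <- -min(y) + diff(range(y)) / 100
  }
  df <- data.frame(ys = y + shift)
  ys <- df$ys
  bc <- MASS::boxcox(ys ~ 1, data = df, lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  y_trans <- if (abs(lambda) < 1e-8) log(ys) else (ys^lambda - 1) / lambda
  list(y_trans = y_trans, lambda = lambda, shift = shift)
}

# ---- mixed-model plumbing -------------------------------------------------

random_formula_part <- function(random, nested = FALSE) {
  if (nested) return("(1 | id / segment)")
  paste(sprintf("(1 | %s)", random), collapse = " + ")
}

#' Fit a linear mixed model from a model specification
#'
#' Thin contract over [lme4::lmer()]: builds the formula from a response,
#' fixed-effect names and random-effect grouping factors, fits by ML or
#' REML, and attaches a singularity flag (any random-effect variance below
#' 1e-6 of the residual variance).
#'
#' @param data Model data.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (may be empty).
#' @param random Character vector of grouping factors, e.g. `c("id",
#'   "colony")`; `nested = TRUE` uses segment-within-individual nesting
#'   instead.
#' @param nested Use `(1 | id / segment)`.
#' @param reml Fit by REML (use `FALSE` whenever models are compared by
#'   information criteria or likelihood-ratio tests).
#' @return A `flyforage_lmm` list: `fit`, `singular`, `converged`,
#'   `response`, `fixed`, `random`.
#' @export
fit_lmm <- function(data, response, fixed, random = "id", nested = FALSE,
                    reml = FALSE) {
  rhs <- paste(c(if (length(fixed)) fixed else "1",
                 random_formula_part(random, nested)), collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- try(lme4::lmer(form, data = data, REML = reml), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(fit = NULL, singular = NA, converged = FALSE,
                          response = response, fixed = fixed,
                          random = random),
                     class = "flyforage_lmm"))
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
  structure(list(fit = fit, singular = is_singular_fit(fit),
                 converged = converged, response = response, fixed = fixed,
                 random = random),
            class = "flyforage_lmm")
}

#' Singularity check with an explicit variance-ratio threshold
#'
#' A fit is singular when any random-effect variance falls below `ratio`
#' times the residual variance.
#'
#' @param fit A `merMod`.
#' @param ratio Variance-ratio threshold.
#' @return Logical.
#' @export
is_singular_fit <- function(fit, ratio = 1e-6) {
  vc <- lme4::VarCorr(fit)
  resid_var <- attr(vc, "sc")^2
  re_vars <- unlist(lapply(vc, function(m) diag(m)))
  any(re_vars < ratio * resid_var)
}

#' Select random effects by AICc among non-singular fits
#'
#' Fits the full fixed-effect model under each candidate random-effect
#' structure (REML), ranks by AICc and returns the lowest-AICc structure
#' whose fit is not singular. Falls back to individual-only (with a
#' warning) when every candidate is singular, mirroring the common spring
#' situation of colony/year variances collapsing to zero.
#'
#' @param data Model data.
#' @param response Response column name.
#' @param fixed Fixed-effect terms of the full model.
#' @param candidates List of random-structure character vectors; the first
#'   entry containing only `"id"` is the fallback.
#' @return List with `random` (chosen structure) and `table` (tibble of
#'   structure, AICc, singular).
#' @export
select_random_effects <- function(data, response, fixed,
                                  candidates = list("id", c("id", "colony"),
                                                    c("id", "year"),
                                                    c("id", "colony", "year"))) {
  rows <- lapply(candidates, function(rand) {
    m <- fit_lmm(data, response, fixed, random = rand, reml = TRUE)
    tibble::tibble(structure = paste(rand, collapse = "+"),
                   aicc = if (is.null(m$fit)) NA_real_ else
                     aicc_of(stats::logLik(m$fit), nobs = nrow(data)),
                   singular = m$singular)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$aicc)
  ok <- ord[!tab$singular[ord] %in% c(TRUE, NA)]
  if (!length(ok)) {
    warning("all candidate random structures singular; using individual only")
    return(list(random = "id", table = tab))
  }
  list(random = candidates[[ok[1]]], table = tab)
}

aicc_of <- function(ll, nobs) {
  k <- attr(ll, "df")
  if (nobs <= k + 1) return(NA_real_)
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (nobs - k - 1)
}

#' All-subsets candidate set of fixed effects
#'
#' @param predictors Character vector of fixed-effect terms.
#' @return List of character vectors (including the empty, intercept-only
#'   model); errors above 20 predictors (2^20 models).
#' @export
candidate_set <- function(predictors) {
  p <- length(predictors)
  if (p > 20) stop("refusing all-subsets expansion beyond 20 predictors")
  if (p == 0) return(list(character()))
  unlist(lapply(0:p, function(k) {
    if (k == 0) return(list(character()))
    m <- utils::combn(predictors, k, simplify = FALSE)
    m
  }), recursive = FALSE)
}

#' Fit every candidate model
#'
#' ML fits of each fixed-effect subset under a common random structure.
#' Models that fail to converge are excluded with a warning.
#'
#' @param data Model data.
#' @param response Response column name.
#' @param predictors Full predictor set; all subsets are fitted.
#' @param random Random-effect grouping factors.
#' @return List of `flyforage_lmm` objects with a `subset` element each.
#' @export
fit_candidates <- function(data, response, predictors, random = "id") {
  subsets <- candidate_set(predictors)
  fits <- lapply(subsets, function(s) {
    m <- fit_lmm(data, response, s, random = random, reml = FALSE)
    m$subset <- s
    m
  })
  bad <- vapply(fits, function(m) is.null(m$fit) || !m$converged, logical(1))
  if (any(bad)) {
    warning(sum(bad), " candidate model(s) failed to converge and were excluded")
  }
  fits[!bad]
}

#' Information-criterion table and Akaike weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with Delta against
#' the criterion minimum; AICc applies the small-sample correction
#' `2k(k+1)/(n-k-1)` (models with `n <= k + 1` are excluded with a
#' warning).
#'
#' @param fits Output of [fit_candidates()].
#' @param criterion `"AICc"` or `"BIC"`.
#' @return Tibble sorted by weight: `model` (label), `subset`
#'   (list-column), `k`, `logLik`, `criterion`, `delta`, `weight`,
#'   `cum_weight`, plus a `fit` list-column.
#' @export
ic_weights <- function(fits, criterion = c("AICc", "BIC")) {
  criterion <- match.arg(criterion)
  n <- stats::nobs(fits[[1]]$fit)
  ll <- lapply(fits, function(m) stats::logLik(m$fit))
  k <- vapply(ll, attr, numeric(1), "df")
  crit <- switch(criterion,
    AICc = vapply(ll, aicc_of, numeric(1), nobs = n),
    BIC = vapply(fits, function(m) stats::BIC(m$fit), numeric(1)))
  undef <- is.na(crit)
  if (any(undef)) {
    warning(sum(undef), " model(s) with undefined ", criterion, " excluded")
    fits <- fits[!undef]; crit <- crit[!undef]
    k <- k[!undef]; ll <- ll[!undef]
  }
  delta <- crit - min(crit)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- tibble::tibble(
    model = vapply(fits, function(m)
      if (length(m$subset)) paste(m$subset, collapse = "+") else "(intercept)",
      character(1)),
    subset = lapply(fits, `[[`, "subset"),
    k = k, logLik = vapply(ll, as.numeric, numeric(1)),
    criterion = crit, delta = delta, weight = w)
  out <- out[order(-out$weight), ]
  out$cum_weight <- cumsum(out$weight)
  out$fit <- fits[order(-w)]
  out
}

#' Zero-method model averaging over the 95% confidence set
#'
#' Retains the smallest weight-ordered prefix of candidate models reaching
#' `cumulative_weight`, renormalizes the weights, and averages each
#' predictor's coefficient across the set with coefficient zero in models
#' that exclude it (the zero / full-average method). The unconditional
#' standard error combines within-model variance and between-model spread,
#' `SE_j = sqrt(sum_i w_i (var_ij + (b_ij - bbar_j)^2))`, with zero
#' variance contribution from excluding models. 95% CI = estimate +/-
#' 1.96 SE; a predictor is distinguishable from zero iff its CI excludes 0.
#'
#' @param ctab Output of [ic_weights()].
#' @param cumulative_weight Confidence-set mass (default 0.95).
#' @return List with `estimates` (tibble: predictor, estimate, se,
#'   ci_lower, ci_upper, distinguishable, weight_containing) and
#'   `n_models` retained.
#' @export
model_average <- function(ctab, cumulative_weight = 0.95) {
  if (!nrow(ctab)) stop("empty candidate table")
  m <- which(ctab$cum_weight >= cumulative_weight - 1e-12)[1]
  if (is.na(m)) m <- nrow(ctab)
  sel <- ctab[seq_len(m), ]
  w <- sel$weight / sum(sel$weight)
  predictors <- unique(unlist(sel$subset))
  # coefficient name lookup handles factors expanding to several terms
  rows <- lapply(predictors, function(pr) {
    b <- se2 <- numeric(nrow(sel))
    contain <- logical(nrow(sel))
    for (i in seq_len(nrow(sel))) {
      if (!pr %in% sel$subset[[i]]) next
      fit <- sel$fit[[i]]$fit
      cf <- lme4::fixef(fit)
      vc <- diag(as.matrix(stats::vcov(fit)))
      hits <- which(names(cf) == pr | startsWith(names(cf), pr))
      if (length(hits) != 1) {
        stop("predictor ", pr, " maps to ", length(hits),
             " coefficients; averaging expects single-column terms")
      }
      b[i] <- cf[hits]; se2[i] <- vc[hits]; contain[i] <- TRUE
    }
    est <- sum(w * b)
    se <- sqrt(sum(w * (se2 + (b - est)^2)))
    tibble::tibble(predictor = pr, estimate = est, se = se,
                   ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
                   distinguishable = (est - 1.96 * se) > 0 |
                     (est + 1.96 * se) < 0,
                   weight_containing = sum(w[contain]),
                   estimate_conditional = if (any(contain))
                     sum(w[contain] * b[contain]) / sum(w[contain]) else 0)
  })
  list(estimates = do.call(rbind, rows), n_models = m,
       weights = w, criterion_table = sel[setdiff(names(sel), "fit")])
}

#' One-call multimodel-averaged inference
#'
#' Fits all fixed-effect subsets by ML under the given random structure,
#' computes criterion weights and returns zero-method averaged estimates
#' over the 95% set.
#'
#' @inheritParams fit_candidates
#' @param criterion `"AICc"` or `"BIC"`.
#' @param cumulative_weight Confidence-set mass.
#' @return As [model_average()], plus the full candidate table.
#' @export
average_models <- function(data, response, predictors, random = "id",
                           criterion = "BIC", cumulative_weight = 0.95) {
  fits <- fit_candidates(data, response, predictors, random)
  ctab <- ic_weights(fits, criterion)
  out <- model_average(ctab, cumulative_weight)
  out$full_table <- ctab[setdiff(names(ctab), "fit")]
  out
}

#' Season-specific predictor sets
#'
#' Spring models drop days at previous stopover (first spring stopovers
#' happen inside the wintering grounds and cannot be measured from the
#' tracks), precipitation (collinearity with the temperature variables) and
#' age (only adults migrate back in spring).
#'
#' @param predictors Candidate predictor names.
#' @param season `"autumn"` or `"spring"`.
#' @return Filtered character vector.
#' @export
season_predictors <- function(predictors, season = c("autumn", "spring")) {
  season <- match.arg(season)
  if (season == "autumn") return(predictors)
  setdiff(predictors, c("days_at_previous_stopover", "precip", "age"))
}

#' Likelihood-ratio test between nested ML fits
#'
#' @param nested,full `flyforage_lmm` objects (or `merMod`s) fitted by ML
#'   on the same data, the nested model's fixed effects a subset of the
#'   full model's.
#' @return Tibble with `chisq`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  getfit <- function(m) if (inherits(m, "flyforage_lmm")) m$fit else m
  f0 <- getfit(nested); f1 <- getfit(full)
  if (inherits(nested, "flyforage_lmm") && inherits(full, "flyforage_lmm") &&
      !all(nested$fixed %in% full$fixed)) {
    stop("models are not nested")
  }
  ll0 <- stats::logLik(f0); ll1 <- stats::logLik(f1)
  if (stats::nobs(f0) != stats::nobs(f1)) stop("fits use different data")
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df < 0) stop("full model has fewer parameters than the nested model")
  chisq <- max(2 * (as.numeric(ll1) - as.numeric(ll0)), 0)
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  tibble::tibble(chisq = chisq, df = df, p_value = p)
}
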