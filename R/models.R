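# Stacked multilevel compositional inference.
#
# Residual variances are coordinate-specific: the three ILR coordinates live
# on different scales (the MVPA balance is far more variable than the SB/SPT
# balance), and pooling their residual variance misweights coordinate-level
# Wald tests. The default engine expresses this in lme4 by decomposing the
# coordinate-k residual variance as a common floor sigma^2 plus a
# non-negative coordinate excess tau_k^2, fitted as scalar random effects of
# the coordinate indicators grouped by subject-by-wave cell (one row per
# coordinate per cell, so the excess is residual variance, not structure).
# This is the same ML optimum as nlme::lme with a varIdent residual (the
# "nlme" engine, kept as a cross-check); plain lm ("fixed") serves the
# degenerate-case and rotation-invariance oracles.
#
# The composition is analysed by melting each subject-by-wave ILR vector into
# long format (one row per coordinate, identified by a 3-level `ilr_factor`)
# and fitting a linear mixed model with all fixed effects interacted with the
# coordinate factor, a subject random intercept shared across a subject's
# coordinate rows, and a school random intercept. The prospective design adds
# per-subject coordinate effects (a random "slope" for the ILR factor, with
# full covariance) to capture the persistence of a person's composition
# across waves. Composition-level inference is a type-III likelihood-ratio
# test on the ilr_factor x wave interaction; per-behaviour inference rotates
# the pivot coordinate.

#' Specify the stacked compositional model
#'
#' @param design `"cross_sectional"` or `"prospective"`.
#' @param covariates character vector of covariate columns entering the fixed
#'   effects (each interacted with the coordinate factor). Default
#'   age, sex, SES and family structure; use `character(0)` for an unadjusted
#'   model.
#' @param engine `"lmer"` (the default: lme4 with per-coordinate residual
#'   variances via the coordinate-excess decomposition), `"nlme"`
#'   (nlme::lme with a varIdent residual; same model, used as a
#'   cross-check), or `"fixed"` (fixed-effects only, via [stats::lm()]; used
#'   for degenerate oracles and rotation-invariance checks).
#' @param use_school include the school-level random intercept (default TRUE;
#'   dropped automatically, with a warning, when fewer than 2 schools are
#'   present).
#' @param random_slope per-subject coordinate effects `(0 + ilr_factor |
#'   subject)`; default TRUE for the prospective design, FALSE otherwise
#'   (not identifiable with one occasion per subject).
#' @return a `model_spec` list.
#' @export
model_spec <- function(design = c("cross_sectional", "prospective"),
                       covariates = c("age", "sex", "ses", "family"),
                       engine = c("lmer", "nlme", "fixed"),
                       use_school = TRUE,
                       random_slope = NULL) {
  design <- match.arg(design)
  engine <- match.arg(engine)
  if (is.null(random_slope)) random_slope <- design == "prospective"
  structure(list(design = design, covariates = covariates, engine = engine,
                 use_school = use_school, random_slope = random_slope),
            class = "model_spec")
}

#' Stack subject-level compositions into long ILR format
#'
#' Computes the ILR coordinates of every subject-by-wave composition under the
#' supplied contrast and reshapes to one row per coordinate, labelled by a
#' 3-level `ilr_factor`. A cross-sectional dataset therefore has exactly 3
#' rows per subject; a prospective dataset has 6 for completers and 3 for
#' dropouts (whose baseline rows are always retained). Rows with missing
#' covariates are excluded (complete-case) with a reported count.
#'
#' @param cohort tibble with `subject_id`, `school_id`, `wave`, the part
#'   columns `mvpa`, `lipa`, `sb`, `spt` (min/day), and covariates.
#' @param contrast ILR contrast matrix (default the MVPA-first pivot).
#' @param covariates covariate columns required complete (default the model
#'   covariates present in the cohort).
#' @return long tibble with `ilr_factor` and `ilr_value` plus ids, wave and
#'   covariates; the contrast is attached as an attribute.
#' @export
stack_data <- function(cohort, contrast = pivot_contrast(),
                       covariates = intersect(c("age", "sex", "ses", "family"),
                                              names(cohort))) {
  if (any(as.matrix(cohort[, MVB_PARTS]) <= 0)) {
    stop("compositions must be strictly positive before ILR stacking")
  }
  if (length(covariates)) {
    cc <- stats::complete.cases(cohort[, covariates])
    if (any(!cc)) message(sum(!cc), " row(s) dropped for missing covariates")
    cohort <- cohort[cc, ]
  }
  z <- ilr_transform(cohort[, MVB_PARTS], contrast)
  wide <- dplyr::bind_cols(
    cohort[, setdiff(names(cohort), MVB_PARTS)],
    tibble::as_tibble(z)
  )
  long <- tidyr::pivot_longer(wide, cols = dplyr::all_of(colnames(z)),
                              names_to = "ilr_factor", values_to = "ilr_value")
  long$ilr_factor <- factor(long$ilr_factor, levels = colnames(z))
  attr(long, "contrast") <- contrast
  long
}

fixed_rhs <- function(spec, with_wave = TRUE, moderator = NULL) {
  terms <- c(if (with_wave) "wave", spec$covariates)
  rhs <- "0 + ilr_factor"
  if (length(terms)) {
    rhs <- paste0(rhs, " + ilr_factor:(", paste(terms, collapse = " + "), ")")
  }
  if (!is.null(moderator)) {
    rhs <- paste0(rhs, " + ilr_factor:wave:", moderator)
  }
  rhs
}

#' Fit the stacked compositional mixed model
#'
#' Fits by maximum likelihood (so that likelihood-ratio comparisons between
#' nested fits are valid). On failure the model is refit along a documented
#' fallback chain: drop the random coordinate slope, then the school
#' intercept, then all random effects (fixed-effects fit); each step is
#' recorded in the result's `notes`.
#'
#' @param data a stacked dataset from [stack_data()].
#' @param spec a [model_spec()].
#' @param with_wave include the `ilr_factor:wave` interaction (FALSE gives the
#'   reduced model of the type-III composition test).
#' @param moderator optional covariate name added as an
#'   `ilr_factor:wave:covariate` three-way term.
#' @param reml fit by REML instead of ML (default FALSE). Any fit entering a
#'   likelihood-ratio comparison must use ML; Wald-based tests use REML so
#'   that variance components (and hence standard errors) are unbiased.
#' @return a `stacked_fit` list: `fit` (lmerMod or lm), `spec`, `formula`,
#'   `logLik`, `n_fixed`, `coef` (fixed effects), `vcov`, `n_rows`,
#'   `n_subjects`, `notes`, `singular`.
#' @export
fit_stacked_model <- function(data, spec = model_spec(), with_wave = TRUE,
                              moderator = NULL, reml = FALSE) {
  rhs <- fixed_rhs(spec, with_wave, moderator)
  fixed_f <- stats::as.formula(paste("ilr_value ~", rhs))
  notes <- character(0)
  n_schools <- length(unique(data$school_id))
  use_school <- spec$use_school && n_schools >= 2
  if (spec$use_school && !use_school && spec$engine != "fixed") {
    warning("fewer than 2 schools; school-level intercept dropped")
  }

  fit_nlme <- function(slope, school) {
    ran <- c(if (school) list(school_id = ~1),
             list(subject_id = if (slope) ~ilr_factor else ~1))
    nlme::lme(fixed_f, data = data, random = ran,
              weights = nlme::varIdent(form = ~1 | ilr_factor),
              method = if (reml) "REML" else "ML",
              control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                         niterEM = 5, returnObject = FALSE))
  }
  # coordinate indicators and the subject-by-wave cell, for the
  # coordinate-excess residual decomposition
  coords <- levels(data$ilr_factor)
  for (k in seq_along(coords)) {
    data[[paste0(".c", k)]] <- as.numeric(data$ilr_factor == coords[k])
  }
  data$.cell <- interaction(data$subject_id, data$wave, drop = TRUE)
  fit_lmer <- function(slope, school) {
    re <- c(if (school) "(1 | school_id)",
            if (slope) "(0 + ilr_factor | subject_id)" else "(1 | subject_id)",
            paste0("(0 + .c", seq_along(coords), " | .cell)"))
    f <- stats::as.formula(paste("ilr_value ~", rhs, "+", paste(re, collapse = " + ")))
    suppressMessages(lme4::lmer(
      f, data = data, REML = reml,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
  }

  if (spec$engine == "fixed") {
    fit <- stats::lm(fixed_f, data = data)
  } else {
    mk <- if (spec$engine == "nlme") fit_nlme else fit_lmer
    # fallback chain: drop the coordinate slope, then the school intercept,
    # then all random effects
    attempts <- list(c(spec$random_slope, use_school))
    if (spec$random_slope) attempts <- c(attempts, list(c(FALSE, use_school)))
    if (use_school) attempts <- c(attempts, list(c(FALSE, FALSE)))
    fit <- NULL
    for (a in seq_along(attempts)) {
      arg <- attempts[[a]]
      fit <- tryCatch(mk(arg[1], arg[2]), error = function(e) NULL)
      if (!is.null(fit)) {
        if (a > 1) notes <- c(notes, sprintf(
          "fallback step %d: random slope=%s, school=%s", a - 1, arg[1], arg[2]))
        break
      }
    }
    if (is.null(fit)) {
      fit <- stats::lm(fixed_f, data = data)
      notes <- c(notes, "fallback: fixed-effects-only fit")
    }
  }
  is_mer <- inherits(fit, "merMod")
  beta <- if (is_mer) lme4::fixef(fit)
          else if (inherits(fit, "lme")) nlme::fixef(fit)
          else stats::coef(fit)
  beta <- beta[!is.na(beta)]
  structure(list(
    fit = fit, spec = spec, formula = rhs,
    logLik = as.numeric(stats::logLik(fit)),
    n_fixed = length(beta),
    coef = beta,
    vcov = as.matrix(stats::vcov(fit)),
    n_rows = nrow(data),
    n_subjects = length(unique(data$subject_id)),
    contrast = attr(data, "contrast"),
    singular = if (is_mer) lme4::isSingular(fit) else FALSE,
    notes = notes
  ), class = "stacked_fit")
}

#' Type-III likelihood-ratio test of the composition-by-time interaction
#'
#' Compares nested ML fits with and without the `ilr_factor:wave` term. With
#' D = 4 parts the interaction spans 3 coefficients, so the statistic is
#' referred to a chi-square with 3 degrees of freedom. A significant result
#' means the whole 24-h composition differs between time points.
#'
#' @param fit_full,fit_reduced `stacked_fit` objects fit by ML on identical
#'   rows, the reduced one dropping exactly the `ilr_factor:wave` term.
#' @return list with `chi2`, `df`, `p`.
#' @export
test_composition_effect <- function(fit_full, fit_reduced) {
  if (fit_full$n_rows != fit_reduced$n_rows) {
    stop("full and reduced models must be fit on identical rows")
  }
  df <- fit_full$n_fixed - fit_reduced$n_fixed
  if (df <= 0) stop("reduced model is not nested in the full model")
  chi2 <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

wave_coef_info <- function(fit) {
  idx <- grep("^ilr_factorz[0-9]+:wave", names(fit$coef))
  list(idx = idx, beta = fit$coef[idx], vcov = fit$vcov[idx, idx, drop = FALSE])
}

#' Per-behaviour tests via pivot rotation
#'
#' For each behaviour placed first in the pivot order, the fixed-effect slope
#' of wave on the first pivot coordinate measures the change in that
#' behaviour relative to the geometric mean of the remaining three; its Wald
#' test gives the behaviour-specific p-value.
#'
#' @param cohort wide cohort (as taken by [stack_data()]).
#' @param spec a [model_spec()].
#' @return tibble with `part`, `estimate` (z1 wave slope), `se`, `z`, `p`.
#' @export
per_component_tests <- function(cohort, spec = model_spec()) {
  rows <- lapply(MVB_PARTS, function(b) {
    order_b <- c(b, setdiff(MVB_PARTS, b))
    V <- pivot_contrast(order_b, all_parts = MVB_PARTS)
    data <- stack_data(cohort, V, covariates = intersect(spec$covariates, names(cohort)))
    fit <- fit_stacked_model(data, spec, reml = TRUE)
    nm <- grep("^ilr_factorz1:wave", names(fit$coef), value = TRUE)
    est <- unname(fit$coef[nm])
    se <- sqrt(fit$vcov[nm, nm])
    tibble::tibble(part = b, estimate = est, se = se, z = est / se,
                   p = 2 * stats::pnorm(-abs(est / se)))
  })
  dplyr::bind_rows(rows)
}

#' Adjusted marginal-mean composition at a wave
#'
#' Predicts the ILR coordinate vector at the requested wave with continuous
#' covariates at their sample mean and factor covariates weighted by their
#' observed level proportions (implemented by averaging the fixed-effect
#' linear predictor over the observed covariate rows), then back-transforms
#' through the inverse ILR and closes to 1440 min/day.
#'
#' @param fit a `stacked_fit`.
#' @param data the stacked dataset the model was fit on.
#' @param wave `"2019"` or `"2022"`.
#' @param total closure total (default 1440).
#' @return named length-4 composition (min/day).
#' @export
marginal_means <- function(fit, data, wave, total = 1440) {
  contrast <- fit$contrast %||% attr(data, "contrast")
  coords <- levels(data$ilr_factor)
  ff <- stats::as.formula(paste("~", fit$formula))
  newdata <- as.data.frame(data)
  newdata$wave <- factor(wave, levels = levels(data$wave))
  z <- vapply(coords, function(k) {
    newdata$ilr_factor <- factor(k, levels = coords)
    X <- stats::model.matrix(ff, newdata)
    X <- X[, names(fit$coef), drop = FALSE]
    mean(X %*% fit$coef)
  }, numeric(1))
  ilr_inverse(z, contrast, total = total)
}

#' Per-part percent difference between two predicted compositions
#'
#' `100 * (t2 - t1) / t1`, the scale used in the comparison tables.
#'
#' @param pred_t1,pred_t2 compositions (min/day), strictly positive.
#' @return named numeric vector (unrounded; round to 1 decimal for display).
#' @export
percent_difference <- function(pred_t1, pred_t2) {
  if (any(pred_t1 <= 0)) stop("baseline parts must be positive")
  100 * (pred_t2 - pred_t1) / pred_t1
}

#' Wald tests of sociodemographic moderation
#'
#' For each covariate, refits the model with an `ilr_factor:wave:covariate`
#' three-way interaction and Wald-tests those coefficients jointly: 3 degrees
#' of freedom for continuous or binary covariates, 6 for the 3-level family
#' structure factor. Subgroup contrasts are only warranted when the
#' interaction is significant at 0.05.
#'
#' @param data a stacked dataset.
#' @param spec a [model_spec()].
#' @param covariates covariates to test (default the spec's).
#' @return tibble with `term`, `df`, `chi2`, `p`.
#' @export
moderation_tests <- function(data, spec = model_spec(),
                             covariates = spec$covariates) {
  rows <- lapply(covariates, function(cv) {
    fit <- fit_stacked_model(data, spec, moderator = cv, reml = TRUE)
    nm <- names(fit$coef)
    sel <- grepl("^ilr_factorz[0-9]+:wave", nm) &
      vapply(strsplit(nm, ":"), length, integer(1)) == 3 &
      grepl(paste0(":", cv), nm, fixed = TRUE)
    b <- fit$coef[sel]
    V <- fit$vcov[sel, sel, drop = FALSE]
    chi2 <- as.numeric(t(b) %*% solve(V, b))
    tibble::tibble(term = paste("ILR * wave *", cv), df = length(b), chi2 = chi2,
                   p = stats::pchisq(chi2, length(b), lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Full composition contrast between waves
#'
#' The main analysis for one cohort: stacks the data, fits the full and
#' reduced models (type-III LRT of the composition-by-time interaction),
#' derives adjusted marginal-mean compositions per wave with their percent
#' differences, and runs the per-behaviour pivot-rotation tests.
#'
#' @param cohort wide cohort tibble.
#' @param spec a [model_spec()].
#' @param contrast ILR contrast for the composition-level model (the LRT is
#'   invariant to this choice).
#' @return a `composition_contrast` list: `predictions` (2 x 4 matrix,
#'   min/day), `pct_diff`, `min_diff`, `lrt` (chi2/df/p), `per_part` tibble,
#'   `fit` (the full fit), `n_subjects`.
#' @export
composition_contrast <- function(cohort, spec = model_spec(),
                                 contrast = pivot_contrast()) {
  covs <- intersect(spec$covariates, names(cohort))
  data <- stack_data(cohort, contrast, covariates = covs)
  fit_full <- fit_stacked_model(data, spec, with_wave = TRUE)
  fit_red <- fit_stacked_model(data, spec, with_wave = FALSE)
  lrt <- test_composition_effect(fit_full, fit_red)
  pred <- rbind(`2019` = marginal_means(fit_full, data, "2019"),
                `2022` = marginal_means(fit_full, data, "2022"))
  per_part <- per_component_tests(cohort, spec)
  structure(list(
    predictions = pred,
    pct_diff = percent_difference(pred["2019", ], pred["2022", ]),
    min_diff = pred["2022", ] - pred["2019", ],
    lrt = lrt,
    per_part = per_part,
    fit = fit_full,
    n_subjects = fit_full$n_subjects
  ), class = "composition_contrast")
}

#' Sensitivity re-analyses
#'
#' Re-runs the full contrast pipeline under one of the pre-specified
#' sensitivity conditions: excluding compositional outliers (robust
#' Mahalanobis screen on the ILR coordinates), complete-case analysis
#' (prospective: subjects observed at both waves), or an alternative
#' composition table derived under adult cut-points.
#'
#' @param cohort wide cohort tibble.
#' @param spec a [model_spec()].
#' @param which `"outlier_excluded"`, `"complete_case"`, or
#'   `"adult_cutpoints"`.
#' @param alt_cohort replacement cohort (required for `"adult_cutpoints"`:
#'   compositions re-derived from epochs under the adult set).
#' @param quantile chi-square quantile of the outlier screen (default 0.975).
#' @return a `composition_contrast` with attribute `n_excluded`.
#' @export
run_sensitivity <- function(cohort, spec = model_spec(),
                            which = c("outlier_excluded", "complete_case",
                                      "adult_cutpoints"),
                            alt_cohort = NULL, quantile = 0.975) {
  which <- match.arg(which)
  n0 <- length(unique(cohort$subject_id))
  if (which == "outlier_excluded") {
    z <- ilr_transform(cohort[, MVB_PARTS], pivot_contrast())
    out <- mahalanobis_outliers(z, quantile = quantile)
    bad <- unique(cohort$subject_id[out$outlier])
    cohort <- cohort[!cohort$subject_id %in% bad, ]
  } else if (which == "complete_case") {
    counts <- table(cohort$subject_id)
    keep <- names(counts)[counts == length(unique(cohort$wave))]
    cohort <- cohort[cohort$subject_id %in% keep, ]
  } else {
    if (is.null(alt_cohort)) stop("adult_cutpoints sensitivity needs `alt_cohort`")
    cohort <- alt_cohort
  }
  if (nrow(cohort) == 0) stop("no data left after sensitivity filtering")
  res <- composition_contrast(cohort, spec)
  attr(res, "n_excluded") <- n0 - length(unique(cohort$subject_id))
  res
}
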