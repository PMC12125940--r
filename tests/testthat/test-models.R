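test_that("stacking yields 3 rows per subject-wave and keeps dropout baselines", {
  coh <- tiny_cohort(n = 10)
  cs <- coh[coh$wave == "2019", ]
  expect_equal(nrow(stack_data(cs)), 30)       # cross-sectional: 3 per subject
  expect_equal(nrow(stack_data(coh)), 60)      # both waves: 6 per subject
  ids <- sort(unique(coh$subject_id))
  dropped <- coh[!(coh$wave == "2022" & coh$subject_id %in% ids[1:4]), ]
  d <- stack_data(dropped)
  expect_equal(nrow(d), 48)                    # 6*6 + 4*3
  counts <- table(d$subject_id)
  expect_setequal(as.integer(counts), c(3L, 6L))
  expect_equal(sum(d$wave == "2019"), 30)      # baselines never reduced
  # missing covariates are dropped with a message
  cs$age[1] <- NA
  expect_message(d2 <- stack_data(cs), "dropped")
  expect_equal(nrow(d2), 27)
  # zero parts are rejected
  bad <- cs; bad$mvpa[2] <- 0
  expect_error(stack_data(bad), "strictly positive")
})

test_that("the degenerate (no random effects) fit matches coordinate-wise OLS", {
  # oracle for the stacked interaction parameterization: with the random
  # effects absent the stacked fit must decouple into three separate
  # per-coordinate regressions
  cc <- cohort_config("cross_sectional", n_subjects_per_wave = 60,
                      sd_school = 0, sd_subject = 0, seed = 23)
  d <- stack_data(generate_cohort(cc))
  fit <- fit_stacked_model(d, model_spec("cross_sectional", engine = "fixed"))
  for (k in 1:3) {
    dk <- d[d$ilr_factor == paste0("z", k), ]
    ols <- lm(ilr_value ~ wave + age + sex + ses + family, data = dk)
    expect_equal(unname(fit$coef[paste0("ilr_factorz", k, ":wave2022")]),
                 unname(coef(ols)["wave2022"]), tolerance = 1e-9)
    expect_equal(unname(fit$coef[paste0("ilr_factorz", k, ":age")]),
                 unname(coef(ols)["age"]), tolerance = 1e-9)
  }
})

test_that("the two heterogeneous-residual engines reach the same ML optimum", {
  cc <- cohort_config("cross_sectional", n_subjects_per_wave = 120, seed = 67)
  d <- stack_data(generate_cohort(cc))
  f_lmer <- fit_stacked_model(d, model_spec("cross_sectional", engine = "lmer"))
  f_nlme <- fit_stacked_model(d, model_spec("cross_sectional", engine = "nlme"))
  expect_equal(f_lmer$logLik, f_nlme$logLik, tolerance = 1e-6)
  nm <- grep("^ilr_factorz[0-9]:wave2022$", names(f_lmer$coef), value = TRUE)
  expect_equal(f_lmer$coef[nm], f_nlme$coef[nm], tolerance = 1e-4)
  expect_equal(sqrt(diag(f_lmer$vcov)[nm]), sqrt(diag(f_nlme$vcov)[nm]),
               tolerance = 1e-3)
})

test_that("refitting identical data reproduces the log-likelihood", {
  cc <- cohort_config("cross_sectional", n_subjects_per_wave = 80, seed = 29)
  d <- stack_data(generate_cohort(cc))
  spec <- model_spec("cross_sectional")
  expect_equal(fit_stacked_model(d, spec)$logLik,
               fit_stacked_model(d, spec)$logLik, tolerance = 1e-12)
})

test_that("the composition-level LRT is invariant to the SBP (fixed-effects fit)", {
  cc <- cohort_config("cross_sectional", n_subjects_per_wave = 120, seed = 31)
  coh <- generate_cohort(cc)
  spec <- model_spec("cross_sectional", engine = "fixed")
  lrt_for <- function(V) {
    d <- stack_data(coh, V)
    test_composition_effect(fit_stacked_model(d, spec),
                            fit_stacked_model(d, spec, with_wave = FALSE))
  }
  a <- lrt_for(pivot_contrast())
  b <- lrt_for(make_sbp_contrast(rbind(c(1, 1, -1, -1), c(1, -1, 0, 0),
                                       c(0, 0, 1, -1))))
  expect_equal(a$df, 3)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-8)
})

test_that("unadjusted marginal means are exactly the per-wave geometric means", {
  cc <- cohort_config("cross_sectional", n_subjects_per_wave = 50, seed = 37)
  coh <- generate_cohort(cc)
  spec <- model_spec("cross_sectional", engine = "fixed", covariates = character(0))
  d <- stack_data(coh)
  fit <- fit_stacked_model(d, spec)
  for (w in c("2019", "2022")) {
    mm <- marginal_means(fit, d, w)
    expect_equal(mm, geometric_mean_composition(coh[coh$wave == w, MVB_PARTS]),
                 tolerance = 1e-9)
    expect_lt(abs(sum(mm) - 1440), 1e-9)
  }
})

test_that("pivot-rotation slopes reassemble the marginal-mean contrast", {
  cc <- cohort_config("cross_sectional", n_subjects_per_wave = 60, seed = 41)
  coh <- generate_cohort(cc)
  spec <- model_spec("cross_sectional", engine = "fixed", covariates = character(0))
  d <- stack_data(coh)
  fit <- fit_stacked_model(d, spec)
  mm1 <- marginal_means(fit, d, "2019")
  mm2 <- marginal_means(fit, d, "2022")
  pp <- per_component_tests(coh, spec)
  # z1 slope relates to the clr difference by sqrt(3/4)
  clr_diff <- sqrt(3 / 4) * pp$estimate[match(MVB_PARTS, pp$part)]
  rebuilt <- close_composition(mm1 * exp(clr_diff), 1440)
  expect_equal(unname(rebuilt), unname(mm2), tolerance = 1e-6)
})

test_that("percent differences reproduce the published arithmetic", {
  expect_equal(round(percent_difference(29.9, 26.6), 1), -11.0)
  expect_equal(round(percent_difference(671.5, 705.5), 1), 5.1)
  expect_equal(percent_difference(c(a = 5, b = 10), c(a = 5, b = 10)),
               c(a = 0, b = 0))
  expect_error(percent_difference(0, 5), "positive")
})

test_that("moderation tests carry the design degrees of freedom", {
  cc <- cohort_config("cross_sectional", n_subjects_per_wave = 100, seed = 43)
  d <- stack_data(generate_cohort(cc))
  mod <- moderation_tests(d, model_spec("cross_sectional"))
  df <- setNames(mod$df, sub("ILR \\* wave \\* ", "", mod$term))
  expect_equal(df[["family"]], 6)
  expect_equal(df[["sex"]], 3)
  expect_equal(df[["age"]], 3)
  expect_equal(df[["ses"]], 3)
  expect_true(all(mod$p >= 0 & mod$p <= 1))
})

test_that("a strong simulated wave effect is detected with p < 0.001", {
  cc <- cohort_config("prospective", n_subjects_per_wave = 300, seed = 47)
  coh <- apply_dropout(generate_cohort(cc), 138 / 249, seed = 48)
  res <- composition_contrast(coh, model_spec("prospective"))
  expect_lt(res$lrt$p, 0.001)
  expect_equal(res$lrt$df, 3)
  expect_lt(abs(sum(res$predictions["2019", ]) - 1440), 1e-9)
  expect_lt(abs(sum(res$predictions["2022", ]) - 1440), 1e-9)
  # the dominant published signal: less MVPA, more SB at follow-up
  expect_lt(res$pct_diff[["mvpa"]], 0)
  expect_gt(res$pct_diff[["sb"]], 0)
})

test_that("sensitivity reruns reduce to the main analysis when nothing changes", {
  cc <- cohort_config("prospective", n_subjects_per_wave = 60, seed = 53)
  coh <- generate_cohort(cc)  # no dropout
  spec <- model_spec("prospective", engine = "fixed", covariates = character(0))
  main <- composition_contrast(coh, spec)
  cc_sens <- run_sensitivity(coh, spec, which = "complete_case")
  expect_equal(cc_sens$predictions, main$predictions, tolerance = 1e-9)
  expect_equal(attr(cc_sens, "n_excluded"), 0)
  # outlier screen on a clean cohort with a lenient cutoff changes nothing
  out_sens <- run_sensitivity(coh, spec, which = "outlier_excluded",
                              quantile = 1 - 1e-12)
  expect_equal(out_sens$predictions, main$predictions, tolerance = 1e-9)
  expect_error(run_sensitivity(coh, spec, which = "adult_cutpoints"), "alt_cohort")
})
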