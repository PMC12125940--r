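# Synthetic cohort and epoch-trace generation.
#
# The two-wave adolescent school cohort this pipeline targets (measured in
# 2019 and 2022) is not publicly available, so the pipeline carries its own
# generator. The
# generative model mirrors the assumptions of the fitted multilevel model:
# compositions are Gaussian on the ILR scale around wave-specific centres,
# with additive school, subject, and residual effects; covariates follow the
# published sample descriptives.

#' Default compositional targets per design (min/day)
#'
#' Wave-specific centres of the synthetic cohorts: the adjusted-prediction
#' columns of the published comparison tables for the repeated cross-sectional
#' samples and for the nested prospective cohort. Order: MVPA, LIPA, SB, SPT.
#'
#' @param design `"cross_sectional"` or `"prospective"`.
#' @return list with elements `t2019` and `t2022`, each a named length-4
#'   vector in min/day as printed (column sums 1440 within 0.1; the
#'   generator closes them exactly before use).
#' @export
default_targets <- function(design = c("cross_sectional", "prospective")) {
  design <- match.arg(design)
  if (design == "cross_sectional") {
    list(t2019 = c(mvpa = 29.9, lipa = 275.8, sb = 679.6, spt = 454.7),
         t2022 = c(mvpa = 26.6, lipa = 274.0, sb = 684.3, spt = 455.1))
  } else {
    list(t2019 = c(mvpa = 30.5, lipa = 277.4, sb = 671.5, spt = 460.6),
         t2022 = c(mvpa = 25.1, lipa = 261.1, sb = 705.5, spt = 448.4))
  }
}

#' Configuration for a synthetic cohort
#'
#' Bundles the generative parameters: wave-specific compositional targets,
#' ILR-scale variance components, covariate distributions, cohort size and
#' structure, and the retention probability of the prospective design.
#'
#' The variance components operate on the 3 ILR coordinates (pivot order
#' MVPA, LIPA, SB, SPT): `sd_school` and `sd_subject` are scalar random
#' intercepts shared across a unit's coordinates (inducing within-unit
#' cross-coordinate correlation, exactly as the fitted model assumes);
#' `sd_subject_coord` gives per-coordinate subject effects that persist across
#' waves (prospective design only); `sd_residual` gives per-coordinate
#' occasion-level noise.
#'
#' @param design `"cross_sectional"` (independent samples per wave) or
#'   `"prospective"` (the same subjects at both waves).
#' @param n_subjects_per_wave subjects per wave (cross-sectional) or cohort
#'   size at baseline (prospective).
#' @param n_schools number of school clusters (default 3).
#' @param target_2019,target_2022 length-4 compositional targets (min/day);
#'   defaults from [default_targets()].
#' @param sd_school,sd_subject scalar ILR-scale SDs of the shared school and
#'   subject intercepts (subject intercepts persist across waves in the
#'   prospective design). Prospective default for `sd_subject` is 0.05.
#' @param sd_subject_coord length-3 per-coordinate subject-effect SDs
#'   (prospective persistence; ignored for cross-sectional designs).
#'   Default (0.40, 0.12, 0.07).
#' @param sd_residual length-3 per-coordinate occasion SDs. In the
#'   cross-sectional design this is the between-person spread at one wave
#'   (default 0.50, 0.25, 0.20); in the prospective design it is the
#'   within-person between-wave fluctuation around the persistent level
#'   (default 0.30, 0.08, 0.05, implying 3-year tracking ICCs of roughly
#'   0.6-0.7 per coordinate).
#' @param prop_female,age_mean,age_sd,ses_mean,ses_sd covariate distribution
#'   parameters; defaults follow the published sample descriptives
#'   (53% female; age 16.4 (SD 1.1) cross-sectional, 15.6 (0.8) prospective;
#'   SES score 38.9 (SD 10.0) on the 0-100 scale).
#' @param parent_edu_probs probabilities of the four parental-education levels
#'   (`<8y`, `8-11y`, `>11y`, `dont_know`).
#' @param family_probs probabilities of the three family-structure levels
#'   (`both_parents`, `single_parent`, `no_parents`).
#' @param retention_prob probability that a baseline subject provides valid
#'   follow-up data (prospective design); default 138/249.
#' @param dropout_age_slope log-odds decrease in retention per year of
#'   baseline age (0 = missing completely at random; negative values make
#'   dropouts older, as observed in the cohort).
#' @param seed integer seed driving all cohort randomness.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(design = c("cross_sectional", "prospective"),
                          n_subjects_per_wave = 600,
                          n_schools = 3,
                          target_2019 = NULL,
                          target_2022 = NULL,
                          sd_school = 0.05,
                          sd_subject = NULL,
                          sd_subject_coord = c(0.40, 0.12, 0.07),
                          sd_residual = NULL,
                          prop_female = 0.53,
                          age_mean = NULL, age_sd = NULL,
                          ses_mean = 38.9, ses_sd = 10.0,
                          parent_edu_probs = c(0.057, 0.32, 0.59, 0.033),
                          family_probs = c(0.61, 0.34, 0.05),
                          retention_prob = 138 / 249,
                          dropout_age_slope = 0,
                          seed = 1L) {
  design <- match.arg(design)
  targets <- default_targets(design)
  if (is.null(target_2019)) target_2019 <- targets$t2019
  if (is.null(target_2022)) target_2022 <- targets$t2022
  if (any(target_2019 <= 0) || any(target_2022 <= 0)) {
    stop("compositional targets must be strictly positive")
  }
  if (retention_prob < 0 || retention_prob > 1) stop("retention_prob must be in [0, 1]")
  if (is.null(age_mean)) age_mean <- if (design == "prospective") 15.6 else 16.4
  if (is.null(age_sd)) age_sd <- if (design == "prospective") 0.8 else 1.1
  if (is.null(sd_subject)) sd_subject <- if (design == "prospective") 0.05 else 0.15
  if (is.null(sd_residual)) {
    sd_residual <- if (design == "prospective") c(0.30, 0.08, 0.05)
                   else c(0.50, 0.25, 0.20)
  }
  sds <- c(sd_school, sd_subject, sd_subject_coord, sd_residual)
  if (any(sds < 0)) stop("sd parameters must be non-negative")
  structure(list(
    design = design,
    n_subjects_per_wave = as.integer(n_subjects_per_wave),
    n_schools = as.integer(n_schools),
    target_2019 = close_composition(target_2019, 1440),
    target_2022 = close_composition(target_2022, 1440),
    sd_school = sd_school, sd_subject = sd_subject,
    sd_subject_coord = rep_len(sd_subject_coord, 3),
    sd_residual = rep_len(sd_residual, 3),
    prop_female = prop_female,
    age_mean = age_mean, age_sd = age_sd,
    ses_mean = ses_mean, ses_sd = ses_sd,
    parent_edu_probs = parent_edu_probs / sum(parent_edu_probs),
    family_probs = family_probs / sum(family_probs),
    retention_prob = retention_prob,
    dropout_age_slope = dropout_age_slope,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

sample_covariates <- function(n, config) {
  tibble::tibble(
    sex = factor(ifelse(stats::runif(n) < config$prop_female, "female", "male"),
                 levels = c("male", "female")),
    age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
    ses = pmin(100, pmax(0, round(stats::rnorm(n, config$ses_mean, config$ses_sd), 1))),
    parent_edu = factor(
      sample(c("lt8y", "8to11y", "gt11y", "dont_know"), n, replace = TRUE,
             prob = config$parent_edu_probs),
      levels = c("lt8y", "8to11y", "gt11y", "dont_know")),
    family = factor(
      sample(c("both_parents", "single_parent", "no_parents"), n, replace = TRUE,
             prob = config$family_probs),
      levels = c("both_parents", "single_parent", "no_parents"))
  )
}

#' Generate a synthetic cohort of daily compositions and covariates
#'
#' Draws per-subject compositions on the ILR scale around the wave-specific
#' target centres, with a shared school intercept, a shared subject intercept,
#' per-coordinate persistent subject effects (prospective only), and
#' per-coordinate residual noise, then back-transforms and closes to 1440
#' min/day. Covariates are sampled from the configured distributions and do
#' not affect the composition (their model coefficients are null), which makes
#' calibration simulations of covariate tests well-posed.
#'
#' @param config a [cohort_config()].
#' @return tibble with one row per subject x wave: `subject_id`, `school_id`,
#'   `wave` (factor 2019/2022), covariates, and `mvpa`, `lipa`, `sb`, `spt`
#'   (min/day, rows closed to 1440). Prospective cohorts carry both waves for
#'   every subject (apply [apply_dropout()] for attrition); cross-sectional
#'   cohorts have distinct subjects per wave.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  V <- pivot_contrast()
  mu <- rbind(`2019` = ilr_transform(config$target_2019, V),
              `2022` = ilr_transform(config$target_2022, V))
  school_eff <- stats::rnorm(config$n_schools, 0, config$sd_school)

  one_wave <- function(n, wave, subj_offset, persistent = NULL, school = NULL,
                       u = NULL) {
    if (is.null(school)) school <- sample.int(config$n_schools, n, replace = TRUE)
    if (is.null(u)) u <- stats::rnorm(n, 0, config$sd_subject)
    z <- matrix(rep(mu[wave, ], each = n), n, 3) +
      school_eff[school] + u +
      matrix(stats::rnorm(n * 3, 0, rep(config$sd_residual, each = n)), n, 3)
    if (!is.null(persistent)) z <- z + persistent
    comp <- ilr_inverse(z, V, total = 1440)
    tibble::tibble(
      subject_id = sprintf("S%04d", subj_offset + seq_len(n)),
      school_id = sprintf("school%d", school),
      wave = factor(wave, levels = c("2019", "2022")),
      tibble::as_tibble(comp)
    )
  }

  if (config$design == "cross_sectional") {
    n <- config$n_subjects_per_wave
    d1 <- one_wave(n, "2019", 0L)
    d2 <- one_wave(n, "2022", n)
    cov1 <- sample_covariates(n, config)
    cov2 <- sample_covariates(n, config)
    out <- dplyr::bind_rows(dplyr::bind_cols(d1, cov1), dplyr::bind_cols(d2, cov2))
  } else {
    n <- config$n_subjects_per_wave
    school <- sample.int(config$n_schools, n, replace = TRUE)
    persistent <- matrix(stats::rnorm(n * 3, 0, rep(config$sd_subject_coord, each = n)),
                         n, 3)
    u <- stats::rnorm(n, 0, config$sd_subject)  # persists across waves
    covs <- sample_covariates(n, config)
    d1 <- dplyr::bind_cols(one_wave(n, "2019", 0L, persistent, school, u), covs)
    d2 <- dplyr::bind_cols(one_wave(n, "2022", 0L, persistent, school, u), covs)
    out <- dplyr::bind_rows(d1, d2)
  }
  attr(out, "config") <- config
  out[order(out$subject_id, out$wave), ]
}

#' Apply follow-up attrition to a prospective cohort
#'
#' Removes the wave-2 rows of non-retained subjects; baseline rows are always
#' kept (dropouts stay in the analysis, as mixed models tolerate unbalanced
#' data). Retention is Bernoulli per subject; an optional age-dependent
#' mechanism tilts retention by baseline age on the log-odds scale while
#' keeping the marginal retention near `retention_prob`.
#'
#' @param cohort a two-wave cohort from [generate_cohort()].
#' @param retention_prob probability of providing valid follow-up data.
#' @param seed integer seed.
#' @param age_slope log-odds change in retention per year of (centred)
#'   baseline age; 0 = missing completely at random.
#' @return the cohort minus the dropped wave-2 rows, with a logical
#'   `retained` column on every row.
#' @export
apply_dropout <- function(cohort, retention_prob, seed = 1L, age_slope = 0) {
  if (retention_prob < 0 || retention_prob > 1) stop("retention_prob must be in [0, 1]")
  waves <- unique(as.character(cohort$wave))
  if (length(waves) < 2) stop("apply_dropout needs a two-wave cohort")
  set.seed(seed)
  base <- cohort[cohort$wave == "2019", ]
  p <- if (age_slope == 0) rep(retention_prob, nrow(base)) else {
    stats::plogis(stats::qlogis(retention_prob) +
                    age_slope * (base$age - mean(base$age)))
  }
  retained_ids <- base$subject_id[stats::runif(nrow(base)) < p]
  out <- cohort[cohort$wave == "2019" | cohort$subject_id %in% retained_ids, ]
  out$retained <- out$subject_id %in% retained_ids
  out
}

#' Specify a daily behaviour schedule for epoch-trace simulation
#'
#' Defines a deterministic day template — a sleep window plus physical-activity
#' bouts distributed through waking time, the remainder sedentary — together
#' with the emission model that turns behaviour labels into an accelerometer
#' signal: log-normal ENMO per behaviour with medians placed inside the
#' cut-point band each behaviour must trigger (and clipped to that band, so
#' classification is recoverable by construction), a near-constant z-angle
#' with small jitter during sleep, and frequent large posture changes while
#' awake.
#'
#' @param sleep_onset_min clock minute of sleep onset (default 23:00 = 1380).
#' @param sleep_dur_min sleep-window length in minutes (default 480).
#' @param n_mvpa,mvpa_len_min number and length of MVPA bouts per day.
#' @param n_lipa,lipa_len_min number and length of LIPA bouts per day.
#' @param enmo_median named medians (mg) of the log-normal ENMO emissions for
#'   sleep, sb, lipa, mvpa.
#' @param enmo_sigma log-scale SD of the ENMO emissions; 0 gives a noise-free
#'   trace.
#' @param z_sleep_deg,z_jitter_deg sleep-posture z-angle and its jitter SD.
#' @param posture_change_s seconds between waking posture changes.
#' @param nonwear data.frame with columns `day` (1-based), `start_min`,
#'   `dur_min` describing non-wear segments, or NULL.
#' @return a `schedule_spec` list; errors if scheduled behaviour exceeds 1440
#'   min/day.
#' @export
schedule_spec <- function(sleep_onset_min = 23 * 60, sleep_dur_min = 480,
                          n_mvpa = 3, mvpa_len_min = 10,
                          n_lipa = 14, lipa_len_min = 20,
                          enmo_median = c(sleep = 3, sb = 15, lipa = 85, mvpa = 300),
                          enmo_sigma = 0.25,
                          z_sleep_deg = -40, z_jitter_deg = 0.5,
                          posture_change_s = 60,
                          nonwear = NULL) {
  active <- sleep_dur_min + n_mvpa * mvpa_len_min + n_lipa * lipa_len_min
  if (active > 1440) stop("scheduled behaviour exceeds 1440 min/day")
  if (sleep_onset_min < 0 || sleep_onset_min >= 1440) stop("sleep onset must be a clock minute")
  structure(list(
    sleep_onset_min = sleep_onset_min, sleep_dur_min = sleep_dur_min,
    n_mvpa = n_mvpa, mvpa_len_min = mvpa_len_min,
    n_lipa = n_lipa, lipa_len_min = lipa_len_min,
    enmo_median = enmo_median, enmo_sigma = enmo_sigma,
    z_sleep_deg = z_sleep_deg, z_jitter_deg = z_jitter_deg,
    posture_change_s = posture_change_s,
    nonwear = nonwear
  ), class = "schedule_spec")
}

#' Scheduled composition of a daily template (min/day)
#'
#' The composition a perfect measurement pipeline should recover from a trace
#' generated under `schedule`: sleep, MVPA and LIPA as scheduled, SB as the
#' remainder of the 1440-min day.
#'
#' @param schedule a [schedule_spec()].
#' @return named length-4 vector (mvpa, lipa, sb, spt) summing to 1440.
#' @export
scheduled_composition <- function(schedule) {
  mvpa <- schedule$n_mvpa * schedule$mvpa_len_min
  lipa <- schedule$n_lipa * schedule$lipa_len_min
  spt <- schedule$sleep_dur_min
  c(mvpa = mvpa, lipa = lipa, sb = 1440 - mvpa - lipa - spt, spt = spt)
}

# Minute-level label template for one (periodic) day. Sleep minutes are the
# periodic window starting at sleep onset; activity bouts are laid out
# deterministically through the waking span, separated by equal sedentary
# gaps, so that the template is identical across days and bouts never straddle
# the sleep window.
day_label_template <- function(schedule) {
  lab <- rep("sb", 1440)
  sleep_min <- (schedule$sleep_onset_min + seq_len(schedule$sleep_dur_min) - 1) %% 1440
  lab[sleep_min + 1] <- "sleep"
  wake_start <- (schedule$sleep_onset_min + schedule$sleep_dur_min) %% 1440
  wake <- setdiff(((wake_start + 0:1439) %% 1440), sleep_min)  # circular order
  bouts <- c(rep("mvpa", schedule$n_mvpa), rep("lipa", schedule$n_lipa))
  lens <- c(rep(schedule$mvpa_len_min, schedule$n_mvpa),
            rep(schedule$lipa_len_min, schedule$n_lipa))
  if (length(bouts)) {
    # interleave MVPA bouts proportionally among the LIPA bouts
    frac <- c(if (schedule$n_mvpa) (seq_len(schedule$n_mvpa) - 0.5) / schedule$n_mvpa,
              if (schedule$n_lipa) (seq_len(schedule$n_lipa) - 0.5) / schedule$n_lipa)
    ord <- order(frac)
    bouts <- bouts[ord]; lens <- lens[ord]
    gap <- (length(wake) - sum(lens)) %/% (length(bouts) + 1)
    pos <- gap
    for (b in seq_along(bouts)) {
      lab[wake[pos + seq_len(lens[b])] + 1] <- bouts[b]
      pos <- pos + lens[b] + gap
    }
  }
  lab
}

#' Generate an epoch-level accelerometer trace for one subject
#'
#' Expands the daily schedule template to epoch resolution over `days`
#' consecutive days and emits a wrist-like signal: per-epoch ENMO drawn from
#' the behaviour's log-normal emission (clipped to its cut-point band),
#' z-angle near-constant during sleep and posture-switching while awake, and a
#' consistent triaxial decomposition so that recomputing ENMO and z-angle from
#' (ax, ay, az) reproduces the emitted values. Non-wear segments emit a
#' motionless device-on-table signal and are flagged `wear = FALSE`.
#'
#' @param schedule a [schedule_spec()].
#' @param days number of days (default 7).
#' @param epoch_s epoch length in seconds; must divide 60 (default 5).
#' @param start_date first calendar date (default a Monday, "2019-09-02").
#' @param subject_id id string stamped on every record.
#' @param seed integer seed.
#' @return tibble with `subject_id`, `timestamp` (POSIXct UTC), `ax`, `ay`,
#'   `az` (g), `enmo_mg`, `z_angle_deg`, `wear`; `86400 / epoch_s` rows per
#'   day.
#' @export
generate_epoch_trace <- function(schedule, days = 7, epoch_s = 5,
                                 start_date = "2019-09-02",
                                 subject_id = "S0001", seed = 1L) {
  stopifnot(inherits(schedule, "schedule_spec"))
  if (60 %% epoch_s != 0) stop("epoch_s must divide 60")
  set.seed(seed)
  per_min <- 60 %/% epoch_s
  n_day <- 1440L * per_min
  template <- day_label_template(schedule)
  labels <- rep(rep(template, each = per_min), days)
  # Sleep from the night before day 1: the template's periodic window already
  # covers it because sleep minutes are defined modulo 1440.
  n <- n_day * days
  wear <- rep(TRUE, n)
  if (!is.null(schedule$nonwear)) {
    for (k in seq_len(nrow(schedule$nonwear))) {
      s <- schedule$nonwear[k, ]
      idx <- ((s$day - 1) * 1440 + s$start_min) * per_min + seq_len(s$dur_min * per_min)
      wear[idx[idx >= 1 & idx <= n]] <- FALSE
    }
  }

  med <- schedule$enmo_median
  sig <- schedule$enmo_sigma
  enmo <- unname(med[labels]) * exp(if (sig > 0) stats::rnorm(n, 0, sig) else 0)
  # clip into the band each behaviour must trigger (child cut-points)
  enmo[labels == "sb"] <- pmin(enmo[labels == "sb"], 35.5)
  enmo[labels == "sleep"] <- pmin(enmo[labels == "sleep"], 35.5)
  enmo[labels == "lipa"] <- pmin(pmax(enmo[labels == "lipa"], 35.6), 201.3)
  enmo[labels == "mvpa"] <- pmax(enmo[labels == "mvpa"], 201.4)

  z <- numeric(n)
  asleep <- labels == "sleep"
  z[asleep] <- schedule$z_sleep_deg
  # waking posture: piecewise-constant, redrawn every posture_change_s
  per_posture <- max(1L, round(schedule$posture_change_s / epoch_s))
  n_post <- ceiling(n / per_posture)
  post <- stats::runif(n_post, -60, 60)
  # keep waking postures clearly away from the sleep angle so sleep-wake
  # transitions stay identifiable (calibration of the emission model)
  near <- abs(post - schedule$z_sleep_deg) < 10
  post[near] <- post[near] + ifelse(post[near] >= schedule$z_sleep_deg, 10, -10)
  z[!asleep] <- rep(post, each = per_posture)[seq_len(n)][!asleep]
  if (schedule$z_jitter_deg > 0 && sig > 0) {
    z <- z + stats::rnorm(n, 0, schedule$z_jitter_deg)
  }
  z <- pmin(89, pmax(-89, z))

  enmo[!wear] <- 0
  z[!wear] <- 89

  norm <- 1 + enmo / 1000
  az <- norm * sin(z * pi / 180)
  ax <- norm * cos(z * pi / 180)
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  tibble::tibble(
    subject_id = subject_id,
    timestamp = t0 + (seq_len(n) - 1) * epoch_s,
    ax = ax, ay = 0, az = az,
    enmo_mg = enmo, z_angle_deg = z,
    wear = wear
  )
}

#' Write / read epoch traces and subject tables as delimited text
#'
#' @param trace tibble from [generate_epoch_trace()].
#' @param path output file (comma-separated, ISO-8601 timestamps).
#' @export
write_epoch_trace <- function(trace, path) {
  out <- trace
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epoch_trace
#' @export
read_epoch_trace <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  x$wear <- as.logical(x$wear)
  tibble::as_tibble(x)
}
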