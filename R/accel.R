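# Epoch-level accelerometer processing: ENMO, non-wear, imputation, sleep
# window, cut-point classification, and weighted daily compositions.

#' Intensity cut-point sets (mg)
#'
#' Named wrist ENMO cut-points: the child set (SB < 35.6 mg, LIPA 35.6-201.4,
#' MVPA >= 201.4) used for the main analysis and the adult set
#' (44.8 / 100.6 mg) used for sensitivity re-processing. Intervals are
#' half-open: SB < `sb_upper`; LIPA >= `sb_upper` and < `mvpa_lower`;
#' MVPA >= `mvpa_lower`.
#'
#' @param name `"child"`, `"adult"`, or `"custom"` (then supply both bounds).
#' @param sb_upper,mvpa_lower custom bounds in mg.
#' @return a `cutpoint_set` list.
#' @export
cutpoint_set <- function(name = c("child", "adult", "custom"),
                         sb_upper = NULL, mvpa_lower = NULL) {
  name <- match.arg(name)
  if (name == "child") { sb_upper <- 35.6; mvpa_lower <- 201.4 }
  if (name == "adult") { sb_upper <- 44.8; mvpa_lower <- 100.6 }
  if (is.null(sb_upper) || is.null(mvpa_lower)) stop("custom cut-points need both bounds")
  if (!(0 < sb_upper && sb_upper < mvpa_lower)) stop("need 0 < sb_upper < mvpa_lower")
  structure(list(name = name, sb_upper = sb_upper, mvpa_lower = mvpa_lower),
            class = "cutpoint_set")
}

#' Day- and subject-level validity rules
#'
#' @param min_wear_h minimum pre-imputation wear per day (default 16 h).
#' @param min_weekdays,min_weekend_days minimum numbers of valid days
#'   (defaults 3 and 1).
#' @param weekday_weight,weekend_weight weights of the weekly average
#'   (default 5:2).
#' @export
validity_rules <- function(min_wear_h = 16, min_weekdays = 3, min_weekend_days = 1,
                           weekday_weight = 5, weekend_weight = 2) {
  if (min_wear_h <= 0 || min_wear_h > 24) stop("min_wear_h must be in (0, 24]")
  if (weekday_weight <= 0 || weekend_weight <= 0) stop("weights must be positive")
  structure(list(min_wear_h = min_wear_h, min_weekdays = min_weekdays,
                 min_weekend_days = min_weekend_days,
                 weekday_weight = weekday_weight, weekend_weight = weekend_weight),
            class = "validity_rules")
}

#' Parameters of the z-angle sleep heuristic
#'
#' The sleep window is the longest sustained period without posture changes in
#' a noon-to-noon interval. A posture change is an absolute change in
#' (optionally median-smoothed) z-angle exceeding `threshold_deg` between
#' consecutive epochs; change-free runs of at least `min_block_min` minutes
#' are candidate blocks, candidates separated by less than `max_gap_min` are
#' merged, and the longest merged block is the sleep window.
#'
#' @param threshold_deg posture-change threshold (default 5 degrees).
#' @param min_block_min minimum sustained-inactivity block (default 30 min).
#' @param max_gap_min maximum gap joined between blocks (default 60 min).
#' @param smooth_min width of an optional centred rolling-median pre-smoother
#'   (minutes; 0 = none, the default, which keeps transition localization
#'   exact on clean signals).
#' @export
sleep_params <- function(threshold_deg = 5, min_block_min = 30, max_gap_min = 60,
                         smooth_min = 0) {
  if (threshold_deg <= 0 || min_block_min <= 0 || max_gap_min <= 0) {
    stop("sleep parameters must be positive")
  }
  structure(list(threshold_deg = threshold_deg, min_block_min = min_block_min,
                 max_gap_min = max_gap_min, smooth_min = smooth_min),
            class = "sleep_params")
}

#' Euclidean norm minus one (ENMO), in milli-g
#'
#' `max(0, sqrt(ax^2 + ay^2 + az^2) - 1) * 1000`; negative values (norm below
#' 1 g) are truncated to zero, the standard ENMO convention.
#'
#' @param ax,ay,az triaxial acceleration in g.
#' @return ENMO in mg.
#' @export
compute_enmo <- function(ax, ay, az) {
  if (!all(is.finite(ax), is.finite(ay), is.finite(az))) stop("non-finite acceleration")
  pmax(0, sqrt(ax^2 + ay^2 + az^2) - 1) * 1000
}

#' z-angle of the wrist relative to the horizontal plane, in degrees
#'
#' `atan2(az, sqrt(ax^2 + ay^2))` in degrees; az-dominant postures map near
#' +/-90.
#'
#' @param ax,ay,az triaxial acceleration in g.
#' @export
compute_z_angle <- function(ax, ay, az) {
  if (any(ax == 0 & ay == 0 & az == 0)) stop("zero acceleration vector")
  atan2(az, sqrt(ax^2 + ay^2)) * 180 / pi
}

roll_sd <- function(x, w) {
  # sd over every window of w consecutive values (one per window start)
  n <- length(x)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  s <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  s2 <- cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]
  sqrt(pmax(0, (s2 - s^2 / w) / (w - 1)))
}

#' Flag non-wear epochs from triaxial variability
#'
#' Heuristic stand-in for validated non-wear detection: any rolling window of
#' `window_min` minutes in which at least two axes have a standard deviation
#' below `sd_threshold_mg` is flagged non-wear (every epoch the window covers).
#' If the input already carries a logical `wear` column it is returned
#' unchanged (passthrough), unless `use_existing = FALSE`.
#'
#' @param epochs tibble with `timestamp`, `ax`, `ay`, `az` (g), chronologically
#'   ordered without duplicates.
#' @param window_min window length (default 60 min).
#' @param sd_threshold_mg per-axis SD threshold (default 13 mg).
#' @param use_existing return an existing `wear` column untouched (default).
#' @return logical wear vector (TRUE = worn).
#' @export
detect_nonwear <- function(epochs, window_min = 60, sd_threshold_mg = 13,
                           use_existing = TRUE) {
  if (use_existing && "wear" %in% names(epochs)) return(epochs$wear)
  ts <- as.numeric(epochs$timestamp)
  if (is.unsorted(ts, strictly = TRUE)) stop("epochs must be ordered with unique timestamps")
  epoch_s <- ts[2] - ts[1]
  w <- as.integer(round(window_min * 60 / epoch_s))
  n <- nrow(epochs)
  if (n < w) return(rep(TRUE, n))
  thr <- sd_threshold_mg / 1000
  below <- (roll_sd(epochs$ax, w) < thr) + (roll_sd(epochs$ay, w) < thr) +
    (roll_sd(epochs$az, w) < thr)
  starts <- which(below >= 2)
  wear <- rep(TRUE, n)
  if (length(starts)) {
    # mark the union of flagged windows via a difference array
    d <- integer(n + 1)
    d[starts] <- d[starts] + 1L
    d[pmin(starts + w, n + 1)] <- d[pmin(starts + w, n + 1)] - 1L
    wear[cumsum(d)[seq_len(n)] > 0] <- FALSE
  }
  wear
}

#' Impute non-wear epochs from the same clock time on other valid days
#'
#' Each non-wear epoch on a valid day receives the mean of the wear-epoch
#' values (`enmo_mg` and `z_angle_deg`) observed at the same clock time on the
#' subject's other valid days, which normalizes every valid day to a full
#' 24 h. When a clock time has no wear observation on any other valid day,
#' the subject-level wear mean is used and a warning is raised.
#'
#' @param epochs one subject's epoch tibble (`timestamp`, `enmo_mg`,
#'   `z_angle_deg`, `wear`), complete days at a fixed epoch length.
#' @param valid_dates dates (as `Date`) whose days should be imputed; default
#'   all dates present.
#' @return the tibble with imputed `enmo_mg`/`z_angle_deg` and a logical
#'   `imputed` column.
#' @export
impute_nonwear <- function(epochs, valid_dates = NULL) {
  date <- as.Date(epochs$timestamp, tz = "UTC")
  if (is.null(valid_dates)) valid_dates <- unique(date)
  tod <- format(epochs$timestamp, "%H:%M:%S", tz = "UTC")
  epochs$imputed <- FALSE
  target <- !epochs$wear & date %in% valid_dates
  if (!any(target)) return(epochs)
  donor <- epochs$wear & date %in% valid_dates
  warned <- FALSE
  for (col in c("enmo_mg", "z_angle_deg")) {
    means <- tapply(epochs[[col]][donor], tod[donor], mean)
    vals <- means[tod[target]]
    if (anyNA(vals)) {
      if (!warned) {
        warning("clock time(s) unobserved on all other valid days; using subject wear mean")
        warned <- TRUE
      }
      vals[is.na(vals)] <- mean(epochs[[col]][donor])
    }
    epochs[[col]][target] <- as.numeric(vals)
  }
  epochs$imputed[target] <- TRUE
  epochs
}

rolling_median <- function(x, w) {
  if (w <= 1) return(x)
  stats::runmed(x, k = if (w %% 2 == 1) w else w + 1, endrule = "median")
}

#' Detect the sleep window in a z-angle series
#'
#' Implements the sustained-inactivity heuristic described in
#' [sleep_params()]: the longest run (after gap merging) without z-angle
#' posture changes is taken as the sleep window (sleep period time, SPT).
#'
#' @param z z-angle series (degrees) at a fixed epoch length, typically one
#'   noon-to-noon interval.
#' @param params a [sleep_params()].
#' @param epoch_s epoch length in seconds (default 5).
#' @return list with `onset`, `offset` (epoch indices into `z`, inclusive),
#'   `spt_min`, and `found` (FALSE when no qualifying block exists, in which
#'   case `spt_min` is 0).
#' @export
detect_sleep_window <- function(z, params = sleep_params(), epoch_s = 5) {
  n <- length(z)
  per_min <- 60 / epoch_s
  zs <- rolling_median(z, round(params$smooth_min * per_min))
  change <- c(TRUE, abs(diff(zs)) > params$threshold_deg)  # posture-change epochs
  r <- rle(!change)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= params$min_block_min * per_min
  if (!any(keep)) return(list(onset = NA, offset = NA, spt_min = 0, found = FALSE))
  bs <- starts[keep] - 1   # include the change epoch that opens the run
  bs[bs < 1] <- 1
  be <- ends[keep]
  # merge blocks separated by gaps shorter than max_gap_min
  merged_s <- bs[1]; merged_e <- be[1]
  if (length(bs) > 1) {
    for (k in 2:length(bs)) {
      if (bs[k] - merged_e[length(merged_e)] - 1 < params$max_gap_min * per_min) {
        merged_e[length(merged_e)] <- be[k]
      } else {
        merged_s <- c(merged_s, bs[k]); merged_e <- c(merged_e, be[k])
      }
    }
  }
  len <- merged_e - merged_s + 1
  j <- which.max(len)
  list(onset = merged_s[j], offset = merged_e[j],
       spt_min = len[j] / per_min, found = TRUE)
}

#' Classify epochs into SPT / SB / LIPA / MVPA
#'
#' Epochs inside the sleep window are SPT; the rest are labelled by half-open
#' ENMO intervals: SB below `sb_upper`, LIPA in [`sb_upper`, `mvpa_lower`),
#' MVPA at or above `mvpa_lower`.
#'
#' @param enmo ENMO series (mg), non-negative.
#' @param cutpoints a [cutpoint_set()].
#' @param sleep logical vector (TRUE = inside the sleep window), or NULL for
#'   none.
#' @return factor with levels mvpa, lipa, sb, spt.
#' @export
classify_epochs <- function(enmo, cutpoints = cutpoint_set("child"), sleep = NULL) {
  if (any(enmo < 0)) stop("negative ENMO")
  lab <- ifelse(enmo < cutpoints$sb_upper, "sb",
                ifelse(enmo < cutpoints$mvpa_lower, "lipa", "mvpa"))
  if (!is.null(sleep)) lab[sleep] <- "spt"
  factor(lab, levels = MVB_PARTS)
}

#' Aggregate one day of epoch labels into a daily composition
#'
#' @param labels factor from [classify_epochs()] covering a complete
#'   midnight-to-midnight day.
#' @param epoch_s epoch length in seconds.
#' @return named length-4 vector of minutes (mvpa, lipa, sb, spt) summing to
#'   exactly 1440.
#' @export
aggregate_day <- function(labels, epoch_s = 5) {
  if (length(labels) * epoch_s != 86400) stop("incomplete day: need 86400 s of epochs")
  counts <- table(factor(labels, levels = MVB_PARTS))
  out <- as.numeric(counts) * epoch_s / 60
  names(out) <- MVB_PARTS
  out
}

#' Weighted weekly composition for one subject
#'
#' A subject is valid with at least `min_weekdays` valid weekdays and
#' `min_weekend_days` valid weekend days; the weekly composition is the
#' weekday/weekend-weighted mean of the valid daily compositions
#' (default 5:2), re-closed to 1440.
#'
#' @param days tibble with columns `mvpa`, `lipa`, `sb`, `spt`, `is_weekend`,
#'   and `valid` (logical; pre-imputation wear criterion).
#' @param rules a [validity_rules()].
#' @return list with `valid`, `composition` (NULL when invalid),
#'   `n_weekdays`, `n_weekend_days`.
#' @export
summarize_subject <- function(days, rules = validity_rules()) {
  ok <- days[days$valid, , drop = FALSE]
  n_wd <- sum(!ok$is_weekend)
  n_we <- sum(ok$is_weekend)
  if (n_wd < rules$min_weekdays || n_we < rules$min_weekend_days) {
    return(list(valid = FALSE, composition = NULL, n_weekdays = n_wd,
                n_weekend_days = n_we))
  }
  wd <- colMeans(ok[!ok$is_weekend, MVB_PARTS, drop = FALSE])
  we <- colMeans(ok[ok$is_weekend, MVB_PARTS, drop = FALSE])
  w <- c(rules$weekday_weight, rules$weekend_weight)
  m <- (w[1] * wd + w[2] * we) / sum(w)
  comp <- m / sum(m) * 1440  # re-close; zero parts are legitimate here
  list(valid = TRUE, composition = comp, n_weekdays = n_wd, n_weekend_days = n_we)
}

#' Process one subject's epoch trace into daily and weekly compositions
#'
#' The full measurement pipeline: (1) derive ENMO and z-angle from the
#' triaxial signal where not already present; (2) flag non-wear; (3) assess
#' day validity on pre-imputation wear time (>= 16 h by default); (4) impute
#' non-wear epochs on valid days from the same clock time across the other
#' valid days, normalizing them to 24 h; (5) detect the sleep window in
#' noon-to-noon intervals (plus the leading/trailing half-days) and map SPT
#' epochs back to calendar days; (6) classify the remaining epochs by
#' cut-points; (7) aggregate midnight-to-midnight days and (8) combine valid
#' days with 5:2 weekday/weekend weighting.
#'
#' @param epochs epoch tibble for one subject: `timestamp` plus either
#'   `ax`/`ay`/`az` or `enmo_mg` and `z_angle_deg`; optional `wear`.
#' @param cutpoints a [cutpoint_set()].
#' @param rules a [validity_rules()].
#' @param sleep a [sleep_params()].
#' @return list with `days` (per-day tibble: date, is_weekend, wear_h, valid,
#'   minutes per behaviour) and `subject` (output of [summarize_subject()]).
#' @export
process_trace <- function(epochs, cutpoints = cutpoint_set("child"),
                          rules = validity_rules(), sleep = sleep_params()) {
  ts <- as.numeric(epochs$timestamp)
  if (is.unsorted(ts, strictly = TRUE)) stop("epochs must be ordered with unique timestamps")
  epoch_s <- ts[2] - ts[1]
  if (is.null(epochs$enmo_mg)) epochs$enmo_mg <- compute_enmo(epochs$ax, epochs$ay, epochs$az)
  if (is.null(epochs$z_angle_deg)) epochs$z_angle_deg <- compute_z_angle(epochs$ax, epochs$ay, epochs$az)
  epochs$wear <- detect_nonwear(epochs)

  date <- as.Date(epochs$timestamp, tz = "UTC")
  wear_h <- tapply(epochs$wear, date, sum) * epoch_s / 3600
  valid_dates <- as.Date(names(wear_h)[wear_h >= rules$min_wear_h])
  epochs <- impute_nonwear(epochs, valid_dates)

  # sleep detection on noon-split intervals; SPT mapped back per epoch
  n <- nrow(epochs)
  secs_of_day <- as.numeric(epochs$timestamp) %% 86400
  noon_idx <- which(diff(secs_of_day >= 43200) == 1) + 1
  bounds <- unique(c(1, noon_idx, n + 1))
  is_sleep <- rep(FALSE, n)
  for (b in seq_len(length(bounds) - 1)) {
    idx <- bounds[b]:(bounds[b + 1] - 1)
    win <- detect_sleep_window(epochs$z_angle_deg[idx], sleep, epoch_s)
    if (win$found) is_sleep[idx[win$onset:win$offset]] <- TRUE
  }

  labels <- classify_epochs(epochs$enmo_mg, cutpoints, is_sleep)

  day_rows <- lapply(as.character(unique(date)), function(d) {
    sel <- date == as.Date(d)
    if (sum(sel) * epoch_s != 86400) return(NULL)  # incomplete calendar day
    comp <- aggregate_day(labels[sel], epoch_s)
    tibble::tibble(date = as.Date(d),
                   is_weekend = format(as.Date(d), "%u") %in% c("6", "7"),
                   wear_h = as.numeric(wear_h[d]),
                   valid = as.Date(d) %in% valid_dates,
                   !!!as.list(comp))
  })
  days <- dplyr::bind_rows(day_rows)
  list(days = days, subject = summarize_subject(days, rules))
}

#' Process many subjects' epoch traces into a composition table
#'
#' @param traces named list of epoch tibbles (or one tibble with a
#'   `subject_id` column).
#' @inheritParams process_trace
#' @return tibble of weighted weekly compositions, one row per valid subject,
#'   plus validity bookkeeping for the invalid ones.
#' @export
process_traces <- function(traces, cutpoints = cutpoint_set("child"),
                           rules = validity_rules(), sleep = sleep_params()) {
  if (is.data.frame(traces)) traces <- split(traces, traces$subject_id)
  rows <- lapply(names(traces), function(id) {
    res <- process_trace(traces[[id]], cutpoints, rules, sleep)
    s <- res$subject
    if (s$valid) {
      tibble::tibble(subject_id = id, valid = TRUE,
                     n_weekdays = s$n_weekdays, n_weekend_days = s$n_weekend_days,
                     !!!as.list(s$composition))
    } else {
      tibble::tibble(subject_id = id, valid = FALSE,
                     n_weekdays = s$n_weekdays, n_weekend_days = s$n_weekend_days,
                     mvpa = NA_real_, lipa = NA_real_, sb = NA_real_, spt = NA_real_)
    }
  })
  dplyr::bind_rows(rows)
}
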