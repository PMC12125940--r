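test_that("ENMO is the truncated euclidean norm minus one in mg", {
  expect_equal(compute_enmo(0, 0, 1), 0)
  expect_equal(compute_enmo(0, 0, 1.2), 200, tolerance = 1e-12)
  expect_equal(compute_enmo(0, 0, 0.5), 0)  # negatives truncate to zero
  expect_error(compute_enmo(NA, 0, 1), "non-finite")
})

test_that("z-angle maps postures as expected", {
  expect_equal(compute_z_angle(1, 0, 0), 0)
  expect_equal(compute_z_angle(0, 0, 1), 90)
  expect_equal(compute_z_angle(0, 1, 1), 45)
  expect_equal(compute_z_angle(0, 0, -1), -90)
  expect_error(compute_z_angle(0, 0, 0), "zero acceleration")
})

test_that("non-wear stand-in flags motionless windows and spares active signal", {
  set.seed(31)
  n <- 12 * 720  # 12 h at 5-s epochs
  ts <- as.POSIXct("2019-09-02", tz = "UTC") + (0:(n - 1)) * 5
  noise <- function(m) m + rnorm(n, 0, 0.05)  # sd 50 mg
  epochs <- tibble::tibble(timestamp = ts, ax = noise(0), ay = noise(0), az = noise(1))
  still <- 3601:(3600 + 1080)  # 90 motionless minutes
  epochs$ax[still] <- 0.01; epochs$ay[still] <- 0.02; epochs$az[still] <- 0.99
  wear <- detect_nonwear(epochs, window_min = 60, sd_threshold_mg = 13)
  expect_true(all(!wear[still]))
  # windows straddling the still segment can also fall under the threshold,
  # so assert wear only for epochs a full window away from it
  active <- setdiff(seq_len(n), (still[1] - 720):(still[length(still)] + 720))
  expect_true(all(wear[active]))
  # passthrough of an existing flag column
  epochs$wear <- rep(TRUE, n)
  expect_identical(detect_nonwear(epochs), epochs$wear)
  # unordered input is rejected
  expect_error(detect_nonwear(epochs[c(2, 1, 3:n), 1:4], use_existing = FALSE), "ordered")
})

test_that("imputation fills non-wear epochs from the same clock time on other days", {
  ts <- as.POSIXct("2019-09-02", tz = "UTC") + seq(0, 3 * 86400 - 60, by = 60)
  n <- length(ts)
  epochs <- tibble::tibble(timestamp = ts, enmo_mg = rep(50, n),
                           z_angle_deg = rep(10, n), wear = TRUE)
  at10 <- format(ts, "%H:%M:%S", tz = "UTC") == "10:00:00"
  epochs$enmo_mg[at10] <- c(100, 300, 200)  # days 1-3
  epochs$wear[which(at10)[2]] <- FALSE      # day 2, 10:00 missing
  imp <- impute_nonwear(epochs)
  expect_equal(imp$enmo_mg[which(at10)[2]], 150)  # mean of 100 and 200
  expect_true(imp$imputed[which(at10)[2]])
  # no non-wear -> identity
  imp2 <- impute_nonwear(dplyr::mutate(epochs, wear = TRUE))
  expect_equal(imp2$enmo_mg, epochs$enmo_mg)
  # clock time missing everywhere -> subject wear mean with warning
  epochs$wear[at10] <- FALSE
  expect_warning(imp3 <- impute_nonwear(epochs), "subject wear mean")
  expect_equal(imp3$enmo_mg[which(at10)[1]], 50)
})

test_that("high-compliance traces need under 1% imputation", {
  # 12 min of non-wear per day (23.8 h wear), staggered so every clock time
  # has donors on other days
  nw <- data.frame(day = 1:7, start_min = 540 + 30 * (1:7), dur_min = 12)
  tr <- generate_epoch_trace(schedule_spec(nonwear = nw), days = 7, seed = 41)
  date <- as.Date(tr$timestamp, tz = "UTC")
  wear_h <- tapply(tr$wear, date, sum) * 5 / 3600
  expect_equal(unname(round(mean(wear_h), 1)), 23.8)
  imp <- impute_nonwear(tr)
  expect_lt(mean(imp$imputed), 0.01)
})

test_that("sleep window detection finds, selects and merges inactivity blocks", {
  p <- sleep_params()
  # constant angle 23:00-07:00 inside a noon-to-noon window (starts at 12:00)
  z <- make_z_series(data.frame(start_min = 660, dur_min = 480))
  w <- detect_sleep_window(z, p)
  expect_lt(abs(w$spt_min - 480), 0.25)
  expect_true(w$found)
  # two separated blocks: the longest wins
  z2 <- make_z_series(data.frame(start_min = c(60, 540), dur_min = c(300, 400)))
  w2 <- detect_sleep_window(z2, p)
  expect_lt(abs(w2$spt_min - 400), 0.25)
  expect_lt(abs(w2$onset / 12 - 540), 1)
  # blocks 200 + 250 min with a 30-min gap merge under the 60-min allowance
  z3 <- make_z_series(data.frame(start_min = c(500, 730), dur_min = c(200, 250)))
  w3 <- detect_sleep_window(z3, p)
  expect_lt(abs(w3$spt_min - 480), 0.25)
  # featureless waking signal -> no window
  w4 <- detect_sleep_window(make_z_series(), p)
  expect_false(w4$found)
  expect_equal(w4$spt_min, 0)
})

test_that("cut-point boundaries classify exactly as half-open intervals", {
  child <- cutpoint_set("child")
  expect_equal(as.character(classify_epochs(c(35.5, 35.6, 201.3, 201.4), child)),
               c("sb", "lipa", "lipa", "mvpa"))
  adult <- cutpoint_set("adult")
  expect_equal(as.character(classify_epochs(c(44.7, 44.8, 100.5, 100.6, 150), adult)),
               c("sb", "lipa", "lipa", "mvpa", "mvpa"))
  sleepmask <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(as.character(classify_epochs(c(300, 10, 50, 250), child, sleepmask)),
               c("spt", "sb", "lipa", "mvpa"))
  expect_error(classify_epochs(-1, child), "negative")
  expect_error(cutpoint_set("custom", 100, 50), "sb_upper < mvpa_lower")
})

test_that("raising the MVPA threshold never increases MVPA minutes", {
  set.seed(51)
  enmo <- rlnorm(17280, log(40), 1)
  prev <- Inf
  for (ml in c(100.6, 150, 201.4, 300)) {
    lab <- classify_epochs(enmo, cutpoint_set("custom", 35.6, ml))
    m <- sum(lab == "mvpa") / 12
    expect_lte(m, prev)
    prev <- m
  }
})

test_that("daily aggregation closes to exactly 1440 minutes", {
  all_sb <- factor(rep("sb", 17280), levels = MVB_PARTS)
  expect_equal(aggregate_day(all_sb), c(mvpa = 0, lipa = 0, sb = 1440, spt = 0))
  set.seed(61)
  lab <- factor(sample(MVB_PARTS, 17280, TRUE), levels = MVB_PARTS)
  expect_equal(sum(aggregate_day(lab)), 1440)
  expect_error(aggregate_day(lab[1:100]), "incomplete day")
})

test_that("weekly summaries apply 5:2 weighting and the validity rules", {
  day <- function(mvpa, weekend, valid = TRUE) {
    tibble::tibble(mvpa = mvpa, lipa = 300 - mvpa + 100, sb = 600, spt = 440,
                   is_weekend = weekend, valid = valid)
  }
  days <- dplyr::bind_rows(day(100, FALSE), day(100, FALSE), day(100, FALSE),
                           day(100, FALSE), day(100, FALSE),
                           day(30, TRUE), day(30, TRUE))
  s <- summarize_subject(days)
  expect_true(s$valid)
  expect_equal(s$composition[["mvpa"]], 80)  # (5*100 + 2*30) / 7
  expect_equal(sum(s$composition), 1440)
  # 2 valid weekdays + 2 weekend days -> invalid
  s2 <- summarize_subject(dplyr::bind_rows(day(100, FALSE), day(100, FALSE),
                                           day(30, TRUE), day(30, TRUE)))
  expect_false(s2$valid)
  # a 15.9-h wear day is excluded from averaging
  days3 <- dplyr::bind_rows(days, day(1000, TRUE, valid = FALSE))
  expect_equal(summarize_subject(days3)$composition, s$composition)
})

test_that("noise-free traces are recovered end-to-end within one epoch per boundary", {
  sch <- schedule_spec(enmo_sigma = 0)
  res <- process_trace(generate_epoch_trace(sch, days = 7, seed = 71))
  sched <- scheduled_composition(sch)
  expect_lt(max(abs(as.matrix(res$days[, MVB_PARTS]) -
                      matrix(sched, 7, 4, byrow = TRUE))), 2 / 12 + 1e-9)
  expect_true(res$subject$valid)
  expect_equal(res$subject$n_weekdays, 5)
  expect_equal(res$subject$n_weekend_days, 2)
  expect_lt(max(abs(rowSums(res$days[, MVB_PARTS]) - 1440)), 1e-9)
})

test_that("adult cut-points reclassify the same trace with less MVPA", {
  tr <- generate_epoch_trace(schedule_spec(enmo_sigma = 0.25), days = 7, seed = 81)
  child <- process_trace(tr, cutpoint_set("child"))
  adult <- process_trace(tr, cutpoint_set("adult"))
  # LIPA emissions (median 85 mg) straddle the adult MVPA bound of 100.6 mg
  expect_gt(adult$subject$composition[["mvpa"]], child$subject$composition[["mvpa"]])
  expect_equal(sum(adult$subject$composition), 1440)
})
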