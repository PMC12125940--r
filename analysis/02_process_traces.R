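#!/usr/bin/env Rscript
# Demonstrate the measurement pipeline on simulated wrist-accelerometer
# traces: schedule -> 5-s epochs -> non-wear imputation -> sleep window ->
# cut-point classification -> weighted weekly compositions. Uses a small
# subject panel so the whole script runs in seconds.

suppressMessages(library(coda24h))

out <- "results/02_process"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20220801
set.seed(seed)

schedules <- list(
  active    = schedule_spec(n_mvpa = 5, mvpa_len_min = 12, n_lipa = 16),
  typical   = schedule_spec(),
  sedentary = schedule_spec(n_mvpa = 1, n_lipa = 10, sleep_dur_min = 450)
)

rows <- list()
for (i in seq_along(schedules)) {
  for (r in 1:3) {
    id <- sprintf("%s_%d", names(schedules)[i], r)
    nw <- data.frame(day = sample(1:7, 2), start_min = c(540, 840), dur_min = 45)
    sch <- schedules[[i]]
    sch$nonwear <- nw
    tr <- generate_epoch_trace(sch, days = 7, subject_id = id,
                               seed = seed + 10 * i + r)
    res <- process_trace(tr)
    sched <- scheduled_composition(schedules[[i]])
    rec <- res$subject$composition
    rows[[id]] <- data.frame(subject_id = id, t(rec),
                             max_day_err = max(abs(as.matrix(res$days[, MVB_PARTS]) -
                                                     matrix(sched, 7, 4, byrow = TRUE))))
    cat(sprintf("%-12s scheduled %s | recovered %s\n", id,
                paste(sprintf("%.0f", sched), collapse = "/"),
                paste(sprintf("%.1f", rec), collapse = "/")))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "trace_recovery.csv"), row.names = FALSE)
cat(sprintf("Max per-day recovery error across %d subject-weeks: %.2f min\n",
            nrow(tab), max(tab$max_day_err)))
cat("(noisy emissions + 2x45 min non-wear per week; errors reflect epoch-grid",
    "boundaries and imputation, not classification.)\n")
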