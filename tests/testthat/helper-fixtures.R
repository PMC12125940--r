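# Shared fixture builders (all data generated in code).

# n random strictly positive 4-part compositions closed to 1440
rand_comp <- function(n, seed = 1) {
  set.seed(seed)
  close_composition(matrix(stats::rlnorm(n * 4, c(3, 5.5, 6.5, 6), 0.4),
                           n, 4, byrow = FALSE,
                           dimnames = list(NULL, MVB_PARTS)))
}

# z-angle series for one 24-h window at 5-s epochs: waking signal alternates
# +/-amp every minute (guaranteed posture changes); `blocks` is a data.frame
# with start_min / dur_min rows set to a constant sleep-like angle
make_z_series <- function(blocks = NULL, total_min = 1440, epoch_s = 5,
                          amp = 50, sleep_angle = -40) {
  per_min <- 60 / epoch_s
  n <- total_min * per_min
  z <- rep(rep(c(amp, -amp), length.out = total_min), each = per_min)
  if (!is.null(blocks)) {
    for (k in seq_len(nrow(blocks))) {
      idx <- blocks$start_min[k] * per_min + seq_len(blocks$dur_min[k] * per_min)
      z[idx] <- sleep_angle
    }
  }
  z
}

# tiny wide cohort for bookkeeping tests: n subjects, both waves
tiny_cohort <- function(n = 10, seed = 3) {
  cc <- cohort_config("prospective", n_subjects_per_wave = n, seed = seed)
  generate_cohort(cc)
}
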