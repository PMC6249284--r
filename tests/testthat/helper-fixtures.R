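# Shared fixture builders. Everything is generated in code at test time.

# small BOLD spec that keeps per-subject work around a second
tiny_bold_spec <- function(seed = 1L, n_volumes_per_run = 120, n_runs = 2,
                           ...) {
  bold_spec(grid_shape = c(14, 16, 14), n_volumes_per_run = n_volumes_per_run,
            n_runs = n_runs, seed = seed, ...)
}

# cohort with carrier status already called from the genotype table
called_cohort <- function(n = 1000, seed = 1L, missing_rate = 0.015) {
  sim <- generate_cohort(cohort_spec(n_subjects = n, seed = seed,
                                     missing_rate = missing_rate))
  sim$cohort$carrier_called <- carrier_status_table(sim$genotypes)
  sim
}

# brute-force survival curve: explicit double loop over voxel pairs
brute_survival <- function(ts, tau_grid) {
  v <- nrow(ts)
  out <- matrix(NA_real_, v, length(tau_grid))
  for (a in seq_len(v)) {
    rs <- numeric(0)
    for (b in seq_len(v)) {
      if (a == b) next
      rs <- c(rs, stats::cor(ts[a, ], ts[b, ]))
    }
    for (j in seq_along(tau_grid)) out[a, j] <- mean(rs > tau_grid[j])
  }
  out
}

# textbook Pearson chi-square: explicit expected-count double loop
brute_chisq <- function(counts) {
  n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  }
  stat
}

# Table-4-style predictor set used across association tests
assoc_predictors <- c("age", "sex", "vocabulary", "ses", "spanish_home",
                      "bilingual", "maternal_education", "carrier_ru2short")
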