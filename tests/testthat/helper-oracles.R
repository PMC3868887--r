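# Independent brute-force oracle for the plug-in estimator: an explicit
# double loop over every (odor, state) cell with empirical marginals.
brute_force_mi <- function(counts, base = 2) {
  total <- sum(counts)
  mi <- 0
  for (k in seq_len(nrow(counts))) {
    for (n in seq_len(ncol(counts))) {
      pnk <- counts[k, n] / total
      if (pnk > 0) {
        pk <- sum(counts[k, ]) / total
        pn <- sum(counts[, n]) / total
        mi <- mi + pnk * log(pnk / (pk * pn), base = base)
      }
    }
  }
  mi
}

# Random contingency table with equal per-odor trial counts.
random_counts_table <- function(n_odors, n_states, trials_per_odor) {
  t(vapply(
    seq_len(n_odors),
    function(k) tabulate(sample.int(n_states, trials_per_odor, replace = TRUE), n_states),
    integer(n_states)
  ))
}

# Small, fast experiment configuration for structural tests.
tiny_config <- function(...) {
  experiment_config(
    n_odors = 3, n_trials = 16, n_flies = 2, theta = c(2, 4), seed = 7, ...
  )
}
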