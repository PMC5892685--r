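# shared fixtures: all built in code, cached per session so several test
# files can reuse the same simulated cohorts

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(n, seed, ...) {
  key <- paste0("n", n, "_s", seed, "_",
                paste(deparse(substitute(list(...))), collapse = ""))
  if (!exists(key, .cohort_cache))
    assign(key, simulateCohort(simulationConfig(n_subjects = n, seed = seed,
                                                ...)),
           .cohort_cache)
  get(key, .cohort_cache)
}

# beta matrix with every score CpG set to a single value per subject
flat_betas <- function(values, ids = paste0("P", seq_along(values))) {
  m <- matrix(rep(values, each = 10), nrow = 10,
              dimnames = list(mortalityWeights()$cpg_id, ids))
  m
}

# independent all-pairs concordance oracle (O(n^2) double loop)
oracle_harrell_c <- function(time, event, risk) {
  conc <- ties <- pairs <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || event[i] != 1) next
    if (time[i] < time[j] || (time[i] == time[j] && event[j] == 0)) {
      pairs <- pairs + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) ties <- ties + 1
    }
  }
  if (pairs == 0) return(NA_real_)
  (conc + 0.5 * ties) / pairs
}
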