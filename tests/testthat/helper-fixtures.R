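# Small cohorts shared across tests. Generation is fast and seeded, so
# fixtures are built in code rather than stored.

tiny_cohort <- function(n = 4, duration = 300, fps = 0.5, seed = 42, ...) {
  generate_cohort(n, duration = duration, fps = fps, seed = seed, ...)
}

# A procedure with no out-of-body intervals (deterministic frame grid).
clean_procedure <- function(duration = 600, fps = 0.5, seed = 42) {
  generate_cohort(1, duration = duration, fps = fps, outside_rate = 0, seed = seed)[[1]]
}

# Noise-free annotator group: tags always equal ground truth.
perfect_raters <- function(n = 3) {
  lapply(seq_len(n), function(i) {
    rater_profile(sprintf("rater_%d", i),
      binary_flip_prob = 0,
      ordinal_noise = c("0" = 1)
    )
  })
}

# Frames plus ground-truth labels sampled from a cohort, for model fixtures.
labelled_frames <- function(cohort, n, seed = 1) {
  truth <- purrr::list_rbind(lapply(cohort, function(p) p$truth))
  truth <- truth[!truth$outside_body, ]
  idx <- withr::with_seed(seed, sample(nrow(truth), n))
  truth[idx, ]
}
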