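# Small fixtures shared across test files; everything is built in code.

# A minimal noise-free design for fast deterministic cohorts.
quiet_design <- function(...) {
  cohort_design(noise_sd = 0, baseline_scale = 0, scatter_sd = 0,
                bio_sdlog = 0, ...)
}

# One-spectrum set from a vector.
one_spectrum <- function(axis, y, passage = 5, id = "s1") {
  spectra_set(axis, matrix(y, nrow = 1),
              tibble::tibble(sample_id = id, passage = passage))
}

# Random multi-spectrum set.
random_set <- function(n = 5, axis = seq(2000, 1000, by = -10), seed = 1) {
  m <- withr::with_seed(seed, matrix(runif(n * length(axis), 0.1, 1),
                                     nrow = n))
  spectra_set(axis, m, tibble::tibble(sample_id = paste0("s", seq_len(n)),
                                      passage = seq_len(n)))
}

single_gaussian <- function(center = 1650, width = 12, amp = 0.8,
                            axis = seq(1800, 1500, by = -2)) {
  amp * exp(-log(2) * ((axis - center) / width)^2)
}
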