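# Shared fixtures and independent oracles for the test suite.

# Brute-force sample entropy by direct template-pair enumeration (pure R,
# O(N^2)), written independently of the package implementation.
brute_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in seq.int(i + 1, nt)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Distance (s) from each labelled event to the nearest ground-truth event
# with the same label.
event_errors <- function(events, truth_events) {
  vapply(seq_len(nrow(events)), function(i) {
    tt <- truth_events$time_s[truth_events$label == events$label[i]]
    min(abs(events$time_s[i] - tt))
  }, 0)
}

# Simulate, preprocess and label one walk; returns everything a test needs.
walk_through_pipeline <- function(params, seed, task = "normal") {
  w <- simulate_walk(params, task = task, seed = seed)
  clean <- preprocess_recording(w$recording)
  events <- detect_gait_events(clean)
  list(walk = w, clean = clean, events = events)
}

noise_free_params <- function(stride_jitter_cov = 0, ...) {
  stride_params(noise_sd = 0, stride_jitter_cov = stride_jitter_cov, ...)
}

# Small cohort joined wide for model tests.
small_model_cohort <- function(seed = 5, n_control = 44, n_t2dm = 94) {
  ch <- simulate_cohort(cohort_config(n_control = n_control, n_t2dm = n_t2dm),
                        seed = seed)
  dplyr::inner_join(widen_gait(ch$gait), ch$cohort, by = "subject")
}

velocity_inputs <- function(data) grep("^velocity_mps_", names(data), value = TRUE)
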