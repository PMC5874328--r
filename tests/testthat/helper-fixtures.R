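# Shared fixtures.  Heavy objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small training configuration for shape/determinism tests; the patience
# is widened because small smooth problems plateau briefly long before
# convergence
tiny_config <- function(seed = 1, maxit = 40) {
  train_config(hidden_sizes = c(24, 12), max_iterations = maxit, seed = seed,
               patience = 30)
}

# a noise-free subject (exact channels, for oracle comparisons)
quiet_subject <- function(seed = 2) {
  make_subject(seed, overrides = list(
    noise_scales = list(orientation_deg = 0, accel = 0, force_n = 0),
    stride_jitter_sd = 0
  ))
}

# short two-subject dataset at reduced duration for evaluation tests
small_dataset <- function() {
  cached("small_dataset", build_dataset(n_subjects = 2, speeds = c(10, 12, 14),
                                        duration = 20, subject_seed_base = 0L,
                                        trial_seed_base = 40L))
}

# one preprocessed 20 s trial with defaults
default_trial <- function() {
  cached("default_trial",
         preprocess_trial(simulate_trial(make_subject(1), 12, duration = 20,
                                         seed = 3)))
}

# the full-scale validation study shared by the acceptance tests
headline <- function() {
  cached("headline", headline_study(seed = 1))
}
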