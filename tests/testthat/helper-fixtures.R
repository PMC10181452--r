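# Shared fixtures. Small cohorts keep the suite fast; the acceptance tests
# use the full study-sized conditions where a criterion calls for them.

`%||%` <- function(a, b) if (is.null(a)) b else a

quick_config <- function(n_subjects = 1, n_targets = 4,
                         n_train_trials_per_target = 5,
                         n_validation_movements = 6, sampling_rate = 60,
                         movement_duration = 1.2, rest_duration = 0.4,
                         noise_sd = 0.5, seed = 42, ...) {
  cohort_config(n_subjects = n_subjects, n_targets = n_targets,
                n_train_trials_per_target = n_train_trials_per_target,
                n_validation_movements = n_validation_movements,
                sampling_rate = sampling_rate,
                movement_duration = movement_duration,
                rest_duration = rest_duration,
                noise_sd = noise_sd, seed = seed, ...)
}

quick_scenario <- function(methodology = "two_synergy", ...,
                           n_hidden_layers = 1L, input_combo = 6L) {
  scenario_spec(methodology, n_hidden_layers, input_combo,
                hidden_units = 8L, epochs = 3L, batch_size = 64L,
                learning_rate = 0.01, val_fraction = 0, seed = 5L, ...)
}

# One prepared subject shared across test files (built lazily, cached).
.fixture_cache <- new.env(parent = emptyenv())

shared_subject <- function() {
  if (is.null(.fixture_cache$subject)) {
    coh <- generate_cohort(quick_config())
    .fixture_cache$cohort <- coh
    .fixture_cache$subject <- prepare_subject(coh[[1]]$training,
                                              coh[[1]]$validation)
  }
  .fixture_cache$subject
}

shared_truth <- function() {
  shared_subject()
  .fixture_cache$cohort[[1]]$subject
}

# Noise-free single subject for exactness-style checks.
shared_clean_subject <- function() {
  if (is.null(.fixture_cache$clean)) {
    coh <- generate_cohort(quick_config(noise_sd = 0, seed = 7))
    .fixture_cache$clean_cohort <- coh
    .fixture_cache$clean <- prepare_subject(coh[[1]]$training,
                                            coh[[1]]$validation)
  }
  .fixture_cache$clean
}

shared_clean_truth <- function() {
  shared_clean_subject()
  .fixture_cache$clean_cohort[[1]]$subject
}
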