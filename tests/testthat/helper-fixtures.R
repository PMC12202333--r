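# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small moderate-effect cohort: 4 subjects x 2 states x 20 s at 200 Hz.
small_params <- function(...) {
  signal_model_params(fs = 200, duration_s = 20, seed = 4242L, ...)
}

small_cohort <- function() {
  cached("small_cohort", generate_cohort(4, small_params()))
}

small_epochs <- function() {
  cached("small_epochs",
         suppressMessages(preprocess_pipeline(small_cohort(), verbose = FALSE)))
}

small_features <- function() {
  cached("small_features", extract_feature_table(small_epochs()))
}
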