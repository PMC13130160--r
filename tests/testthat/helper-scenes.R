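# Shared fixtures, all generated in code. Small scenes keep unit tests fast;
# the acceptance tests use the package defaults.

# a compact TWP-in-paraffin scene whose particles fit a small grid
small_twp_config <- function(n_rows = 40, n_cols = 40, n_particles = 6) {
  scene_config("twp_in_paraffin", n_rows = n_rows, n_cols = n_cols,
               n_particles = n_particles, diameter_mean_um = 45,
               diameter_sd_um = 12, diameter_range_um = c(14, 90))
}

small_gut_config <- function(n_rows = 50, n_cols = 50) {
  scene_config("blank_gut", n_rows = n_rows, n_cols = n_cols,
               n_confounders = 2)
}

noise_off <- function() {
  default_noise(poisson = FALSE, washout = FALSE)
}

# one default-config trained classifier, computed once per test run
cached <- local({
  env <- new.env()
  function(key, fn) {
    if (is.null(env[[key]])) env[[key]] <- fn()
    env[[key]]
  }
})

default_training <- function() {
  cached("training", function() train_twp_classifier(seed = 1))
}
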