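# Small, fast generator configurations used across the suite. All fixtures
# are built in code at test time.

# Three-angle, noise-controlled config for structural checks.
tiny_config <- function(seed = 7, ...) {
  generator_config(n_subjects = 2, n_trials = 3,
                   angles = c(30, 90, 150), seed = seed, ...)
}

# Zero-tuning config: features carry no direction information.
null_config <- function(seed = 1, n_subjects = 4, n_trials = 5,
                        angles = c(60, 90, 120)) {
  generator_config(n_subjects = n_subjects, n_trials = n_trials,
                   angles = angles,
                   negativity_depth_gain = 0, negativity_base_depth = 0,
                   negativity_duration_gain = 0, gravity_tuning_gain = 0,
                   antigravity_burst_gain = 0, updown_asymmetry = 1,
                   seed = seed)
}

# The scaled-down study layout: 6 subjects, 9 angles, 5 trials.
study_config <- function(seed = 11, ...) {
  generator_config(n_subjects = 6, n_trials = 5,
                   angles = c(0, 30, 60, 75, 90, 105, 120, 150, 180),
                   seed = seed, ...)
}

# A small Z-scored phasic set, memoised so several test files can share it.
get_study_pset <- local({
  cache <- new.env()
  function(seed = 11) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_dataset(study_config(seed), level = "phasic")
    }
    cache[[key]]
  }
})

# Deterministic two-class gaussian data for classifier tests.
make_gaussian_task <- function(n_per_class = 20, p = 4, shift = 1,
                               seed = 1) {
  phasictune:::with_seed(seed, {
    x <- matrix(stats::rnorm(2 * n_per_class * p), ncol = p)
    y <- rep(0:1, each = n_per_class)
    x[y == 1, ] <- x[y == 1, ] + shift
    list(x = x, y = y)
  })
}

# Wrap a plain matrix as a feature_matrix for feature-op tests.
fm_from_matrix <- function(x, y, muscles = "m1") {
  npts <- ncol(x) / length(muscles)
  map <- data.frame(muscle = rep(muscles, each = npts),
                    time = rep(seq_len(npts), times = length(muscles)))
  phasictune:::new_feature_matrix(
    x, y, map,
    meta = data.frame(subject = seq_len(nrow(x)),
                      angle = ifelse(y == 1, 150, 90),
                      trial = 1L),
    angles = c(90, 150))
}
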