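# Shared fixtures built in code.

# A circular CoP trajectory: radius cm, rotation frequency Hz.
make_circle_trial <- function(radius = 1, freq = 0.5, fs = 23,
                              duration = 30, condition = NA_character_) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  cop_trial(t, radius * cos(2 * pi * freq * t),
            radius * sin(2 * pi * freq * t), fs = fs,
            condition = condition)
}

make_sine_trial <- function(freq, amp = 1, fs = 23, duration = 30,
                            axis = "x") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  s <- amp * sin(2 * pi * freq * t)
  if (axis == "x") cop_trial(t, s, 0 * t, fs = fs)
  else cop_trial(t, 0 * t, s, fs = fs)
}

# Random-feature training table with a planted linear target.
make_linear_table <- function(n = 40, beta = c(2, -1), bias = 3,
                              noise_sd = 0, seed = 42,
                              condition = "EO-firm") {
  set.seed(seed)
  fn <- sway_feature_names()
  X <- matrix(stats::runif(n * 10, 0.5, 2), n, 10,
              dimnames = list(NULL, fn))
  y <- bias + X[, 1] * beta[1] + X[, 2] * beta[2] +
    stats::rnorm(n, 0, noise_sd)
  cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                   condition = condition, stringsAsFactors = FALSE),
        as.data.frame(X), si_reference = pmax(y, 0))
}

# Small BO budget for unit tests.
fast_bo <- function(seed = 1) bo_config(n_iterations = 6, n_initial = 5,
                                        n_candidates = 200, seed = seed)

# One calibrated generator config shared across the whole test run
# (calibration is deterministic, so caching is safe).
.test_env <- new.env(parent = emptyenv())
test_gen_config <- function() {
  if (is.null(.test_env$cfg))
    .test_env$cfg <- suppressWarnings(calibrate_generator(generator_config()))
  .test_env$cfg
}
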