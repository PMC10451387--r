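#' Bandpass filter specification
#'
#' Specification of the Butterworth bandpass used to condition CoP
#' signals before feature extraction: 4th order, 0.1-4 Hz passband,
#' applied forward-backward (zero phase) by default.
#'
#' @param order Butterworth design order (per skirt; the bandpass
#'   polynomial order is twice this).
#' @param f_low,f_high Passband edges in Hz.
#' @param zero_phase Apply forward-backward for zero phase distortion?
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, f_low = 0.1, f_high = 4,
                        zero_phase = TRUE) {
  stopifnot(order >= 1, f_low > 0, f_high > f_low)
  structure(list(order = as.integer(order), f_low = f_low, f_high = f_high,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Digital Butterworth bandpass coefficients for a given sampling rate.
design_bandpass <- function(spec, fs) {
  if (spec$f_high >= fs / 2)
    stop("bandpass design: f_high (", spec$f_high,
         " Hz) must be below the Nyquist frequency ", fs / 2, " Hz",
         call. = FALSE)
  signal::butter(spec$order, c(spec$f_low, spec$f_high) / (fs / 2),
                 type = "pass")
}

# Zero-phase (forward-backward) filtering with odd-reflection padding of
# 3 filter lengths at each end, to suppress edge transients.
filtfilt_odd <- function(b, a, x) {
  n <- length(x)
  p <- min(3L * max(length(a), length(b)), n - 1L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(p + 1):(p + n)]
}

#' Remove a linear trend from a CoP trial
#'
#' Fits and subtracts a least-squares straight line independently from
#' the x and y coordinates. Slow drift (weight shifts, sensor creep) is
#' removed before bandpass filtering.
#'
#' @param trial A [cop_trial()] with at least 3 samples.
#' @return A detrended [cop_trial()] with per-axis mean zero.
#' @export
detrend_cop <- function(trial) {
  stopifnot(inherits(trial, "cop_trial"))
  n <- length(trial$time)
  if (n < 3L)
    stop("detrend_cop: need at least 3 samples", call. = FALSE)
  X <- cbind(1, trial$time)
  trial$x <- stats::lm.fit(X, trial$x)$residuals
  trial$y <- stats::lm.fit(X, trial$y)$residuals
  trial
}

#' Bandpass-filter a CoP trial
#'
#' Applies the designed digital Butterworth bandpass to each axis. In
#' zero-phase mode the filter runs forward then backward (no phase
#' distortion, so velocity- and acceleration-type features are not
#' skewed), with odd-reflection edge padding; note the two passes deepen
#' the edge attenuation from -3 dB to about -6 dB. Output length equals
#' input length.
#'
#' @param trial A [cop_trial()].
#' @param spec A [filter_spec()].
#' @return The filtered [cop_trial()].
#' @export
bandpass_cop <- function(trial, spec = filter_spec()) {
  stopifnot(inherits(trial, "cop_trial"), inherits(spec, "filter_spec"))
  ba <- design_bandpass(spec, trial$fs)
  if (spec$zero_phase) {
    trial$x <- filtfilt_odd(ba$b, ba$a, trial$x)
    trial$y <- filtfilt_odd(ba$b, ba$a, trial$y)
  } else {
    trial$x <- as.numeric(signal::filter(ba$b, ba$a, trial$x))
    trial$y <- as.numeric(signal::filter(ba$b, ba$a, trial$y))
  }
  trial
}

#' Single-pass gain of the designed bandpass at a frequency
#'
#' Evaluates the magnitude response of the digital filter that
#' [bandpass_cop()] would apply (one pass, regardless of the zero-phase
#' setting), in dB. By the Butterworth design the response is -3 dB at
#' both band edges.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param f Frequency (or vector of frequencies) in Hz, in `(0, fs/2)`.
#' @return Gain(s) in dB.
#' @export
filter_gain <- function(spec, fs, f) {
  if (any(f <= 0) || any(f >= fs / 2))
    stop("filter_gain: f must lie strictly between 0 and fs/2",
         call. = FALSE)
  ba <- design_bandpass(spec, fs)
  z <- exp(-1i * 2 * pi * f / fs)
  num <- outer(z, seq_along(ba$b) - 1, `^`) %*% ba$b
  den <- outer(z, seq_along(ba$a) - 1, `^`) %*% ba$a
  20 * log10(Mod(num / den))[, 1]
}
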