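#' Names of the ten sway features
#'
#' Order and naming used for model matrices, feature tables and exported
#' linear formulas.
#'
#' @return Character vector of length 10.
#' @export
sway_feature_names <- function() {
  c("mean_cm", "mean_path_cm_s", "mean_velocity_cm_s", "mean_distance_cm",
    "mean_acc_cm_s2", "ellipse_area_cm2", "freq_high5_hz", "freq_center_hz",
    "freq_low5_hz", "freq_median_hz")
}

#' Time-domain sway features
#'
#' Computes the five time-domain CoP magnitudes from a (preprocessed)
#' trial. Definitions adopted here, with `r(t)` the resultant distance of
#' the CoP from the trial centroid and `d_i` the planar chord length
#' between consecutive samples:
#'
#' * `mean_cm`: mean of `r(t)` (mean CoP movement about the centroid);
#' * `mean_path_cm_s`: total path length divided by the trial duration;
#' * `mean_velocity_cm_s`: mean per-sample speed, `mean(d_i) * fs`;
#' * `mean_distance_cm`: mean inter-sample chord length `mean(d_i)`;
#' * `mean_acc_cm_s2`: signed mean of the second difference of `r(t)`
#'   times `fs^2` (signed, so slowing drifts can be negative).
#'
#' `mean_path_cm_s` and `mean_velocity_cm_s` coincide numerically under
#' these definitions (duration is `(n-1)/fs`); both are retained because
#' downstream models expect the full ten-variable vector.
#'
#' @param trial A [cop_trial()] with at least 3 samples, normally already
#'   detrended and bandpass filtered.
#' @return Named numeric vector with the five time-domain features.
#' @export
time_domain_features <- function(trial) {
  stopifnot(inherits(trial, "cop_trial"))
  n <- length(trial$time)
  if (n < 3L)
    stop("time_domain_features: need at least 3 samples", call. = FALSE)
  mx <- mean(trial$x); my <- mean(trial$y)
  r <- sqrt((trial$x - mx)^2 + (trial$y - my)^2)
  d <- sqrt(diff(trial$x)^2 + diff(trial$y)^2)
  duration <- trial$time[n] - trial$time[1]
  c(mean_cm = mean(r),
    mean_path_cm_s = sum(d) / duration,
    mean_velocity_cm_s = mean(d) * trial$fs,
    mean_distance_cm = mean(d),
    mean_acc_cm_s2 = mean(diff(r, differences = 2)) * trial$fs^2)
}

#' 95% confidence sway ellipse area
#'
#' Area of the 95% confidence ellipse of the CoP scatter under a
#' bivariate Gaussian model: `pi * chi2 * sqrt(lambda1 * lambda2)` with
#' `lambda_i` the eigenvalues of the x-y sample covariance and
#' `chi2 = 5.991` the 95% quantile of the chi-squared distribution with
#' 2 degrees of freedom. The ellipse is aligned with the principal axes
#' of the scatter.
#'
#' @param trial A [cop_trial()] with at least 3 samples.
#' @param chi2 Coverage constant (default `qchisq(0.95, 2) = 5.991`).
#' @return Area in cm^2. A rank-deficient (collinear) trajectory returns
#'   0 with a warning.
#' @export
ellipse_area_95 <- function(trial, chi2 = 5.991) {
  stopifnot(inherits(trial, "cop_trial"))
  if (length(trial$time) < 3L)
    stop("ellipse_area_95: need at least 3 samples", call. = FALSE)
  S <- stats::cov(cbind(trial$x, trial$y))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12 * max(ev[1], 1e-300)) {
    warning("ellipse_area_95: degenerate (collinear) trajectory; area 0")
    return(0)
  }
  pi * chi2 * sqrt(ev[1] * ev[2])
}

#' Welch power spectrum of a CoP trial
#'
#' Welch-averaged periodogram per axis, with a Hann window, 50% segment
#' overlap and per-segment mean removal. The resultant spectrum is the
#' sum of the two axis spectra. Output is restricted to the analysis band
#' `[band[1], band[2]]`.
#'
#' @param trial A [cop_trial()] with at least 64 samples.
#' @param band Analysis band in Hz (default the filter passband 0.1-4).
#' @param seg_seconds Welch segment length in seconds (default 8 s, which
#'   resolves the 0.1 Hz band edge within a 30 s trial).
#' @param overlap Segment overlap fraction.
#' @return An object of class `power_spectrum`: list with `freqs` (Hz),
#'   `power` (matrix with columns `x`, `y`, `resultant`; density in
#'   cm^2/Hz) and `method` metadata.
#' @export
power_spectrum <- function(trial, band = c(0.1, 4), seg_seconds = 8,
                           overlap = 0.5) {
  stopifnot(inherits(trial, "cop_trial"))
  n <- length(trial$time)
  if (n < 64L)
    stop("power_spectrum: need at least 64 samples", call. = FALSE)
  fs <- trial$fs
  L <- min(n, round(seg_seconds * fs))
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  nb <- L %/% 2 + 1L
  pwelch1 <- function(s) {
    acc <- numeric(nb)
    for (st in starts) {
      seg <- s[st:(st + L - 1L)]
      seg <- (seg - mean(seg)) * w
      sp <- Mod(stats::fft(seg))^2 / (fs * sum(w^2))
      acc <- acc + sp[seq_len(nb)]
    }
    acc <- acc / length(starts)
    acc[2:(nb - 1L)] <- 2 * acc[2:(nb - 1L)]  # fold negative frequencies
    acc
  }
  px <- pwelch1(trial$x)
  py <- pwelch1(trial$y)
  freqs <- (seq_len(nb) - 1L) * fs / L
  keep <- freqs >= band[1] & freqs <= band[2]
  if (sum(keep) < 2L)
    stop("power_spectrum: analysis band contains fewer than 2 frequency bins",
         call. = FALSE)
  power <- cbind(x = px[keep], y = py[keep],
                 resultant = px[keep] + py[keep])
  structure(list(freqs = freqs[keep], power = power,
                 method = list(window = "hann", segment_samples = L,
                               overlap = overlap, fs = fs, band = band)),
            class = "power_spectrum")
}

#' Spectral percentile and centroid features
#'
#' From the resultant band spectrum: the frequencies at which the
#' cumulative band power reaches 5%, 50% and 95% (trapezoidal
#' integration, linear interpolation between bins), and the power-
#' weighted mean frequency (spectral centroid) over the band.
#'
#' @param spectrum A [power_spectrum()].
#' @return Named numeric vector `freq_high5_hz`, `freq_center_hz`,
#'   `freq_low5_hz`, `freq_median_hz`.
#' @export
frequency_features <- function(spectrum) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  f <- spectrum$freqs
  p <- spectrum$power[, "resultant"]
  m <- length(f)
  cum <- c(0, cumsum((p[-1] + p[-m]) / 2 * diff(f)))
  total <- cum[m]
  # 1e-18 cm^2/Hz-scale guard: treats pure floating-point residue from a
  # constant trajectory as zero power
  if (!is.finite(total) || total <= 1e-18)
    stop("frequency_features: zero total band power (undefined spectrum)",
         call. = FALSE)
  qf <- function(q) stats::approx(cum / total, f, q, ties = "ordered")$y
  centroid <- sum(diff(f) * (f[-1] * p[-1] + f[-m] * p[-m]) / 2) / total
  c(freq_high5_hz = qf(0.95), freq_center_hz = centroid,
    freq_low5_hz = qf(0.05), freq_median_hz = qf(0.5))
}

#' Compute the full ten-variable sway feature vector
#'
#' Runs the complete preprocessing and feature pipeline on a raw trial:
#' linear detrend, zero-phase Butterworth bandpass, then the five
#' time-domain magnitudes, the 95% sway ellipse area, and the four Welch
#' spectral features.
#'
#' For degenerate inputs (a constant trajectory), the magnitude features
#' are 0 and the spectral features are returned as `NA` with attribute
#' `flagged_missing` listing them, rather than erroring, so batch
#' pipelines can surface the problem.
#'
#' @param trial A raw [cop_trial()].
#' @param spec A [filter_spec()].
#' @param ... Passed to [power_spectrum()] (e.g. `seg_seconds`).
#' @return Named numeric vector of the ten features (class
#'   `sway_features`), in [sway_feature_names()] order.
#' @export
compute_sway_features <- function(trial, spec = filter_spec(), ...) {
  filt <- bandpass_cop(detrend_cop(trial), spec)
  td <- time_domain_features(filt)
  area <- withCallingHandlers(
    ellipse_area_95(filt),
    warning = function(w) invokeRestart("muffleWarning"))
  ff <- tryCatch({
    sp <- power_spectrum(filt, band = c(spec$f_low, spec$f_high), ...)
    frequency_features(sp)
  }, error = function(e) {
    stats::setNames(rep(NA_real_, 4),
                    c("freq_high5_hz", "freq_center_hz",
                      "freq_low5_hz", "freq_median_hz"))
  })
  out <- c(td, ellipse_area_cm2 = area, ff)[sway_feature_names()]
  flagged <- names(out)[is.na(out)]
  structure(out, class = "sway_features",
            flagged_missing = if (length(flagged)) flagged else NULL)
}

#' @export
print.sway_features <- function(x, ...) {
  cat("Sway features:\n")
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, 4))
  fm <- attr(x, "flagged_missing")
  if (!is.null(fm))
    cat("flagged missing:", paste(fm, collapse = ", "), "\n")
  invisible(x)
}
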