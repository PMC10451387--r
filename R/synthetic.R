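#' Default per-condition calibration targets
#'
#' Condition-wise calibration targets for the synthetic sway generator:
#' mean velocity (cm/s), 95% ellipse area (cm^2) and median frequency
#' (Hz) typical of elderly i-CTSIB cohorts measured on a consumer force
#' plate, together with the between-subject standard deviations used to
#' size cohort heterogeneity. Difficulty rises with eyes closed and foam
#' surfaces.
#'
#' @return Data frame with one row per condition.
#' @export
default_condition_targets <- function() {
  data.frame(
    condition = ctsib_conditions(),
    target_mean_velocity = c(1.20, 1.69, 1.59, 2.04, 1.64, 2.26, 2.94),
    target_ellipse_area  = c(1.49, 3.27, 2.13, 3.58, 1.71, 3.16, 6.28),
    target_freq_median   = c(1.44, 1.44, 1.44, 1.46, 1.48, 1.49, 1.46),
    sd_mean_velocity     = c(0.54, 0.97, 0.56, 0.65, 0.94, 1.05, 1.02),
    sd_ellipse_area      = c(1.67, 5.73, 1.50, 2.24, 1.79, 3.00, 4.07),
    sd_freq_median       = c(0.40, 0.38, 0.33, 0.37, 0.35, 0.34, 0.33),
    stringsAsFactors = FALSE)
}

#' Default stability-index link
#'
#' The linear link tying sway features to the synthetic ground-truth SI.
#' Weights load on magnitude features that grow with sway severity; the
#' noise level is expressed as a target R-squared, converted to a noise
#' standard deviation from the realized spread of the linear predictor
#' across the generated cohort.
#'
#' @param weights Named numeric vector of feature weights (missing
#'   features get weight 0).
#' @param intercept Link intercept.
#' @param r_squared Target R-squared of the linear predictor against the
#'   noisy SI; ignored when `noise_sd` is given.
#' @param noise_sd Fixed Gaussian noise SD, or `NULL` to derive it from
#'   `r_squared`.
#' @return List describing the link.
#' @export
si_link <- function(weights = c(mean_cm = 3, ellipse_area_cm2 = 0.3,
                                freq_median_hz = 0.5),
                    intercept = 0.2, r_squared = 0.95, noise_sd = NULL) {
  full <- stats::setNames(rep(0, 10), sway_feature_names())
  bad <- setdiff(names(weights), names(full))
  if (length(bad))
    stop("si_link: unknown feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  full[names(weights)] <- weights
  list(weights = full, intercept = intercept,
       r_squared = r_squared, noise_sd = noise_sd)
}

#' Synthetic sway generator configuration
#'
#' The generator models each CoP axis as a band-limited Gaussian process
#' with a power-law spectrum `S(f) ~ f^-alpha` inside the analysis band,
#' synthesized in the frequency domain on the trial's own Fourier grid.
#' Per condition, the exponent `alpha` and the amplitude are calibrated
#' so that the expected mean velocity and 95% ellipse area produced by
#' the full analysis pipeline (detrend, zero-phase bandpass, feature
#' extraction) hit the condition's targets. The median-frequency target
#' is checked for consistency and a conflict is recorded when it cannot
#' be reached jointly with the velocity and area targets (see the
#' methods vignette for the feasibility analysis).
#'
#' @param targets Per-condition target table, see
#'   [default_condition_targets()].
#' @param duration_s Trial length in seconds.
#' @param fs Sampling rate in Hz.
#' @param band Spectral band (Hz) of the sway model; defaults to the
#'   analysis band of `filter`.
#' @param anisotropy Ratio of AP to ML RMS amplitude (1 = isotropic).
#' @param severity_sd Log-scale SD of the per-subject sway severity
#'   multiplier (lognormal, mean 1) used by [generate_cohort()].
#' @param link An [si_link()].
#' @param filter The [filter_spec()] the analysis pipeline will use.
#' @param refine Rounds of internal Monte-Carlo refinement of the
#'   calibration (corrects small finite-trial biases; deterministic).
#' @param n_refine Trials per refinement round.
#' @return Object of class `generator_config` (calibration computed
#'   lazily, see [calibrate_generator()]).
#' @export
generator_config <- function(targets = default_condition_targets(),
                             duration_s = 30, fs = 23, band = NULL,
                             anisotropy = 1, severity_sd = 0.4,
                             link = si_link(), filter = filter_spec(),
                             refine = 2, n_refine = 150) {
  if (is.null(band)) band <- c(filter$f_low, filter$f_high)
  stopifnot(band[1] > 0, band[2] > band[1], band[2] < fs / 2,
            anisotropy > 0, severity_sd >= 0, duration_s > 0, fs > 0)
  structure(list(targets = targets, duration_s = duration_s, fs = fs,
                 band = band, anisotropy = anisotropy,
                 severity_sd = severity_sd, link = link, filter = filter,
                 refine = refine, n_refine = n_refine,
                 calibration = NULL),
            class = "generator_config")
}

# Frequency grid (positive, excluding DC and Nyquist) for an n-sample
# trial, and the squared power gain of the zero-phase filter on it.
synth_grid <- function(config) {
  n <- round(config$duration_s * config$fs)
  kmax <- ceiling(n / 2) - 1L
  f <- (1:kmax) / config$duration_s
  ba <- design_bandpass(config$filter, config$fs)
  z <- exp(-1i * 2 * pi * f / config$fs)
  num <- outer(z, seq_along(ba$b) - 1, `^`) %*% ba$b
  den <- outer(z, seq_along(ba$a) - 1, `^`) %*% ba$a
  h2 <- Mod(num / den)[, 1]^2          # single-pass power gain
  passes <- if (config$filter$zero_phase) 2 else 1
  list(n = n, f = f, h_pow = h2^passes)
}

# Gaussian series with independent Fourier modes: bin k gets variance
# v[k]; E[var(x)] = sum(v). Uses the ambient RNG stream.
synth_gauss <- function(n, v) {
  kmax <- length(v)
  X <- complex(real = stats::rnorm(kmax), imaginary = stats::rnorm(kmax)) *
    sqrt(v) / 2
  full <- complex(real = numeric(n))
  full[1 + (1:kmax)] <- X
  full[n + 1 - (1:kmax)] <- Conj(X)
  Re(stats::fft(full, inverse = TRUE))
}

# Closed-form calibration of (alpha, sigma_x, sigma_y) for one condition.
cal_closed_form <- function(V, A, med_target, config, grid) {
  chi2 <- 5.991
  f <- grid$f
  inband <- f >= config$band[1] & f <= config$band[2]
  wincr <- 4 * sin(pi * f / config$fs)^2
  shape <- function(alpha) {
    s <- ifelse(inband, f^(-alpha), 0)
    s * grid$h_pow
  }
  kD2 <- function(alpha) {
    w <- shape(alpha)
    sum(w * wincr) / sum(w)
  }
  med_of <- function(alpha) {
    w <- shape(alpha)
    cs <- cumsum(w) / sum(w)
    stats::approx(cs, f, 0.5, ties = "ordered")$y
  }
  sig_g <- sqrt(A / (pi * chi2))
  sx <- sig_g * sqrt(config$anisotropy)
  sy <- sig_g / sqrt(config$anisotropy)
  theta <- (seq_len(256) - 0.5) * 2 * pi / 256
  ang <- mean(sqrt(sx^2 * cos(theta)^2 + sy^2 * sin(theta)^2))
  kD_need <- V / (config$fs * sqrt(pi / 2) * ang)
  lim <- c(-3, 8)
  k_lo <- sqrt(kD2(lim[2])); k_hi <- sqrt(kD2(lim[1]))
  if (kD_need < k_lo || kD_need > k_hi)
    stop("generator calibration: target_mean_velocity = ", V,
         " is inconsistent with target_ellipse_area = ", A,
         " and the band [", config$band[1], ", ", config$band[2],
         "] Hz (achievable velocity range ",
         signif(config$fs * sqrt(pi / 2) * ang * k_lo, 3), " to ",
         signif(config$fs * sqrt(pi / 2) * ang * k_hi, 3), " cm/s)",
         call. = FALSE)
  alpha <- stats::uniroot(function(a) kD2(a) - kD_need^2, lim,
                          tol = 1e-10)$root
  med_real <- med_of(alpha)
  conflict <- NULL
  if (is.finite(med_target) &&
      abs(med_real - med_target) > pmax(0.05, 0.05 * med_target))
    conflict <- sprintf(
      paste0("target_freq_median = %.3g Hz cannot be met jointly with ",
             "target_mean_velocity = %.3g and target_ellipse_area = %.3g ",
             "(achievable median at these targets: %.3g Hz)"),
      med_target, V, A, med_real)
  list(alpha = alpha, sigma_x = sx, sigma_y = sy,
       med_realized = med_real, conflict = conflict)
}

# Raw per-bin variance vectors for one condition's calibrated process.
cal_bin_variance <- function(cal, config, grid) {
  f <- grid$f
  s <- ifelse(f >= config$band[1] & f <= config$band[2], f^(-cal$alpha), 0)
  denom <- sum(s * grid$h_pow)
  list(vx = s * cal$sigma_x^2 / denom, vy = s * cal$sigma_y^2 / denom)
}

gen_trial_internal <- function(cal, config, grid, condition,
                               severity = 1, subject_id = NA_character_) {
  v <- cal_bin_variance(cal, config, grid)
  x <- synth_gauss(grid$n, v$vx * severity^2)
  y <- synth_gauss(grid$n, v$vy * severity^2)
  cop_trial((seq_len(grid$n) - 1) / config$fs, x, y, fs = config$fs,
            condition = condition, subject_id = subject_id)
}

#' Calibrate the generator
#'
#' Solves the closed-form spectral calibration for every condition and
#' then applies `config$refine` rounds of deterministic Monte-Carlo
#' refinement: a fixed-seed batch of trials is pushed through the actual
#' feature pipeline and the working targets are corrected
#' multiplicatively, absorbing small finite-trial biases (sample-
#' covariance shrinkage of the ellipse area, detrend and filter edge
#' effects).
#'
#' @param config A [generator_config()].
#' @param quiet Suppress the per-condition conflict warnings?
#' @return The config with `$calibration` filled (list per condition:
#'   `alpha`, `sigma_x`, `sigma_y`, `med_realized`, `conflict`).
#' @export
calibrate_generator <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$calibration)) return(config)
  grid <- synth_grid(config)
  cal_list <- list()
  for (i in seq_len(nrow(config$targets))) {
    tg <- config$targets[i, ]
    V <- tg$target_mean_velocity; A <- tg$target_ellipse_area
    Vadj <- V; Aadj <- A
    cal <- cal_closed_form(Vadj, Aadj, tg$target_freq_median, config, grid)
    if (config$refine > 0) {
      for (round in seq_len(config$refine)) {
        mb <- with_seed(20260930L + round, {
          vals <- vapply(seq_len(config$n_refine), function(j) {
            tr <- gen_trial_internal(cal, config, grid, tg$condition)
            ft <- compute_sway_features(tr, config$filter)
            c(ft[["mean_velocity_cm_s"]], ft[["ellipse_area_cm2"]])
          }, numeric(2))
          rowMeans(vals)
        })
        Vadj <- Vadj * V / mb[1]
        Aadj <- Aadj * A / mb[2]
        cal <- cal_closed_form(Vadj, Aadj, tg$target_freq_median, config,
                               grid)
      }
      # conflict reporting should quote the nominal targets, not the
      # internally adjusted ones
      if (!is.null(cal$conflict))
        cal$conflict <- sprintf(
          paste0("target_freq_median = %.3g Hz cannot be met jointly with ",
                 "target_mean_velocity = %.3g and target_ellipse_area = ",
                 "%.3g (achievable median at these targets: %.3g Hz)"),
          tg$target_freq_median, V, A, cal$med_realized)
    }
    if (!is.null(cal$conflict) && !quiet)
      warning("condition ", tg$condition, ": ", cal$conflict, call. = FALSE)
    cal_list[[tg$condition]] <- cal
  }
  config$calibration <- cal_list
  config
}

#' Generate one synthetic CoP trial
#'
#' Synthesizes a calibrated band-limited Gaussian sway trial for the
#' given condition. Deterministic for a given seed.
#'
#' @param config A [generator_config()] (calibrated on first use).
#' @param condition One of [ctsib_conditions()].
#' @param seed Integer seed.
#' @param severity Sway-severity multiplier scaling both axis amplitudes.
#' @param subject_id Identifier attached to the trial.
#' @return A [cop_trial()].
#' @export
generate_cop_trial <- function(config, condition, seed = 1, severity = 1,
                               subject_id = NA_character_) {
  condition <- match.arg(condition, ctsib_conditions())
  config <- calibrate_generator(config, quiet = TRUE)
  grid <- synth_grid(config)
  with_seed(seed,
    gen_trial_internal(config$calibration[[condition]], config, grid,
                       condition, severity, subject_id))
}

#' Generate a synthetic cohort with ground-truth SI
#'
#' Per subject, a latent sway-severity multiplier (lognormal, mean 1,
#' log-SD `config$severity_sd`) scales the condition-calibrated sway
#' amplitudes, inducing between-subject feature variance. Every trial is
#' run through the real preprocessing and feature pipeline, and the
#' reference SI is the linear link applied to the features plus Gaussian
#' noise. When the link specifies a target R-squared instead of a fixed
#' noise SD, the noise SD is derived per condition from the realized
#' spread of the linear predictor.
#'
#' @param config A [generator_config()].
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param keep_trials Keep the raw trials in the result?
#' @return Object of class `synthetic_cohort`: list with `table` (a
#'   training table, one row per subject x condition, plus `noise` and
#'   `severity` columns), `link` (with the realized `noise_sd` per
#'   condition), `severity`, and optionally `trials`.
#' @export
generate_cohort <- function(config, n_subjects, seed = 1,
                            keep_trials = FALSE) {
  if (n_subjects < 2L)
    stop("generate_cohort: need at least 2 subjects", call. = FALSE)
  config <- calibrate_generator(config, quiet = TRUE)
  grid <- synth_grid(config)
  conds <- config$targets$condition
  fn <- sway_feature_names()
  with_seed(seed, {
    sev <- exp(stats::rnorm(n_subjects, -config$severity_sd^2 / 2,
                            config$severity_sd))
    ids <- sprintf("S%03d", seq_len(n_subjects))
    names(sev) <- ids
    rows <- vector("list", n_subjects * length(conds))
    trials <- if (keep_trials) vector("list", length(rows)) else NULL
    k <- 0L
    for (i in seq_len(n_subjects)) {
      for (cond in conds) {
        k <- k + 1L
        tr <- gen_trial_internal(config$calibration[[cond]], config, grid,
                                 cond, sev[i], ids[i])
        ft <- compute_sway_features(tr, config$filter)
        rows[[k]] <- data.frame(subject_id = ids[i], condition = cond,
                                as.list(unclass(ft)[fn]),
                                stringsAsFactors = FALSE)
        if (keep_trials) trials[[k]] <- tr
      }
    }
    tab <- do.call(rbind, rows)
    lin <- as.matrix(tab[fn]) %*% config$link$weights +
      config$link$intercept
    lin <- as.numeric(lin)
    link_out <- config$link
    if (is.null(config$link$noise_sd)) {
      # noise calibrated per condition so the within-condition R^2 (the
      # scale on which per-condition models are fitted) hits the target
      r2 <- config$link$r_squared
      sd_cond <- tapply(lin, tab$condition, stats::sd)
      noise_sd <- stats::setNames(sd_cond[tab$condition] *
                                    sqrt((1 - r2) / r2), NULL)
      link_out$noise_sd <- sd_cond * sqrt((1 - r2) / r2)
    } else {
      noise_sd <- rep(config$link$noise_sd, nrow(tab))
    }
    noise <- stats::rnorm(nrow(tab), 0, noise_sd)
    tab$si_reference <- pmax(lin + noise, 0)
    tab$noise <- tab$si_reference - lin  # recorded draw; respects SI >= 0
    tab$severity <- sev[tab$subject_id]
    if (keep_trials)
      names(trials) <- paste(tab$subject_id, tab$condition, sep = ":")
    structure(list(table = tab, link = link_out, severity = sev,
                   trials = trials),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic i-CTSIB cohort: %d subjects x %d conditions\n",
              length(x$severity),
              length(unique(x$table$condition))))
  cat(sprintf("  SI range [%.2f, %.2f], link noise SD %.3f\n",
              min(x$table$si_reference), max(x$table$si_reference),
              mean(x$link$noise_sd)))
  invisible(x)
}
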