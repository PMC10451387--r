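test_that("time-domain features match analytic oracles on canonical paths", {
  # constant CoP: all magnitudes zero
  t <- seq(0, 2 - 1 / 23, by = 1 / 23)
  const <- cop_trial(t, rep(0.5, length(t)), rep(-0.2, length(t)))
  td0 <- time_domain_features(const)
  expect_equal(unname(td0[c("mean_cm", "mean_path_cm_s",
                            "mean_velocity_cm_s")]), c(0, 0, 0))

  # circle of radius 1 cm at 0.5 Hz: mean distance from centroid is the
  # radius; speed is the chord length x fs (chord-corrected 2*pi*f*R)
  circ <- make_circle_trial(radius = 1, freq = 0.5, fs = 23, duration = 30)
  td <- time_domain_features(circ)
  expect_equal(td[["mean_cm"]], 1, tolerance = 1e-3)
  chord_speed <- 2 * sin(pi * 0.5 / 23) * 23
  expect_equal(td[["mean_velocity_cm_s"]], chord_speed, tolerance = 1e-6)
  expect_equal(td[["mean_velocity_cm_s"]], 2 * pi * 0.5, tolerance = 0.01)

  # straight traverse 0 -> 1 cm in 1 s
  n <- 24
  tt <- (0:(n - 1)) / 23
  line <- cop_trial(tt, seq(0, 1, length.out = n), rep(0, n))
  tdl <- time_domain_features(line)
  expect_equal(tdl[["mean_path_cm_s"]], 1 / (tt[n] - tt[1]),
               tolerance = 1e-9)
  expect_equal(tdl[["mean_distance_cm"]], 1 / (n - 1), tolerance = 1e-12)

  expect_error(time_domain_features(cop_trial(c(0, 1 / 23), 0:1, c(0, 0))),
               "3 samples")
})

test_that("95% ellipse area matches the bivariate-Gaussian closed form", {
  # all points identical -> 0 with a warning
  t3 <- c(0, 1, 2)
  expect_warning(a0 <- ellipse_area_95(cop_trial(t3, rep(1, 3), rep(2, 3))),
                 "degenerate")
  expect_equal(a0, 0)
  # collinear trajectory -> 0 with a warning
  expect_warning(ac <- ellipse_area_95(cop_trial(1:5, 1:5, 2 * (1:5))),
                 "degenerate")
  expect_equal(ac, 0)

  # large-n Gaussian scatter: area -> pi * 5.991 * sx * sy
  set.seed(123)
  n <- 1e5
  iso <- cop_trial((0:(n - 1)) / 23, stats::rnorm(n), stats::rnorm(n))
  expect_equal(ellipse_area_95(iso), pi * 5.991, tolerance = 0.02)
  aniso <- cop_trial((0:(n - 1)) / 23, stats::rnorm(n, 0, 2),
                     stats::rnorm(n, 0, 1))
  expect_equal(ellipse_area_95(aniso), pi * 5.991 * 2, tolerance = 0.02)
})

test_that("Welch spectrum localizes tones and has no power for silence", {
  tone <- make_sine_trial(1.5, amp = 1)
  sp <- power_spectrum(tone)
  expect_true(all(sp$power >= 0))
  expect_true(!is.unsorted(sp$freqs))
  expect_lte(max(sp$freqs), 23 / 2)
  near <- abs(sp$freqs - 1.5) <= 23 / sp$method$segment_samples * 1.5
  expect_gt(sum(sp$power[near, "resultant"]),
            0.95 * sum(sp$power[, "resultant"]))

  t <- seq(0, 30 - 1 / 23, by = 1 / 23)
  silent <- cop_trial(t, 0 * t, 0 * t)
  sps <- power_spectrum(silent)
  expect_equal(max(sps$power), 0)
  expect_error(frequency_features(sps), "zero total band power")
  expect_error(power_spectrum(cop_trial((0:9) / 23, 0:9, 0:9)),
               "64 samples")
})

test_that("white noise has approximately flat band power", {
  # simulation oracle for the flatness bound: per-bin Welch estimates on
  # white noise are ~chi-squared with 2K dof (K segments), so the CV
  # across bins is about 1/sqrt(K); allow 3x.
  set.seed(5)
  t <- seq(0, 30 - 1 / 23, by = 1 / 23)
  wn <- cop_trial(t, stats::rnorm(length(t)), stats::rnorm(length(t)))
  sp <- power_spectrum(wn)
  k_seg <- floor((length(t) - sp$method$segment_samples) /
                   (sp$method$segment_samples / 2)) + 1
  cv <- stats::sd(sp$power[, "resultant"]) / mean(sp$power[, "resultant"])
  expect_lt(cv, 3 / sqrt(k_seg))
})

test_that("spectral percentile features match distribution oracles", {
  # flat band spectrum on [0.1, 4]: uniform-distribution quantiles
  f <- seq(0.1, 4, by = 0.025)
  flat <- structure(list(freqs = f,
                         power = cbind(x = rep(1, length(f)),
                                       y = rep(1, length(f)),
                                       resultant = rep(2, length(f))),
                         method = list()), class = "power_spectrum")
  ff <- frequency_features(flat)
  expect_equal(ff[["freq_median_hz"]], 2.05, tolerance = 1e-9)
  expect_equal(ff[["freq_low5_hz"]], 0.295, tolerance = 1e-9)
  expect_equal(ff[["freq_high5_hz"]], 3.805, tolerance = 1e-9)
  expect_equal(ff[["freq_center_hz"]], 2.05, tolerance = 1e-9)

  # pure tone: all percentile features inside the tone's bin
  tone <- make_sine_trial(1.5)
  ft <- frequency_features(power_spectrum(tone))
  bw <- 23 / 184
  expect_true(all(abs(ft - 1.5) <= 1.5 * bw))

  # two equal-power tones at 0.5 and 2.5 Hz: centroid at the midpoint,
  # median strictly between the tones (two-atom distribution)
  t <- seq(0, 30 - 1 / 23, by = 1 / 23)
  two <- cop_trial(t, sin(2 * pi * 0.5 * t), sin(2 * pi * 2.5 * t))
  f2 <- frequency_features(power_spectrum(two))
  expect_equal(f2[["freq_center_hz"]], 1.5, tolerance = 0.1)
  expect_gt(f2[["freq_median_hz"]], 0.5)
  expect_lt(f2[["freq_median_hz"]], 2.5)
})

test_that("the assembled feature vector is consistent and invariant", {
  cfg <- test_gen_config()
  tr <- generate_cop_trial(cfg, "EO-firm", seed = 31)
  ft <- compute_sway_features(tr)
  expect_s3_class(ft, "sway_features")
  expect_length(ft, 10L)
  expect_true(all(is.finite(ft)))
  expect_identical(names(ft), sway_feature_names())
  expect_lte(ft[["freq_low5_hz"]], ft[["freq_median_hz"]])
  expect_lte(ft[["freq_median_hz"]], ft[["freq_high5_hz"]])

  # pipeline self-consistency: ellipse area equals the direct call on
  # the preprocessed trajectory
  pre <- bandpass_cop(detrend_cop(tr))
  expect_equal(ft[["ellipse_area_cm2"]], ellipse_area_95(pre),
               tolerance = 1e-12)

  # constant raw input: magnitudes ~0, spectral features flagged missing
  t <- seq(0, 30 - 1 / 23, by = 1 / 23)
  flatft <- compute_sway_features(cop_trial(t, 0 * t + 1, 0 * t + 2))
  expect_lt(max(abs(flatft[1:6]), na.rm = TRUE), 1e-9)
  expect_true(all(is.na(flatft[7:10])))
  expect_setequal(attr(flatft, "flagged_missing"),
                  c("freq_high5_hz", "freq_center_hz", "freq_low5_hz",
                    "freq_median_hz"))
})

test_that("features transform correctly under translation, rotation and
           scaling", {
  cfg <- test_gen_config()
  tr <- generate_cop_trial(cfg, "EC-foam1", seed = 77)
  base <- compute_sway_features(tr)

  shift <- tr; shift$x <- tr$x + 3.1; shift$y <- tr$y - 1.4
  expect_equal(unclass(compute_sway_features(shift)), unclass(base),
               tolerance = 1e-9)

  th <- 0.6
  rot <- tr
  rot$x <- cos(th) * tr$x - sin(th) * tr$y
  rot$y <- sin(th) * tr$x + cos(th) * tr$y
  rf <- compute_sway_features(rot)
  inv <- c("mean_cm", "mean_path_cm_s", "mean_velocity_cm_s",
           "mean_distance_cm", "ellipse_area_cm2")
  expect_equal(unclass(rf)[inv], unclass(base)[inv], tolerance = 1e-6)
  # the resultant spectrum is exactly rotation invariant (the trace of
  # the per-bin cross-spectral matrix), so these are tight
  expect_equal(unclass(rf)[7:10], unclass(base)[7:10], tolerance = 1e-9)

  k <- 2.5
  sc <- tr; sc$x <- k * tr$x; sc$y <- k * tr$y
  sf <- compute_sway_features(sc)
  lin <- c("mean_cm", "mean_path_cm_s", "mean_velocity_cm_s",
           "mean_distance_cm")
  expect_equal(unclass(sf)[lin], k * unclass(base)[lin], tolerance = 1e-9)
  expect_equal(sf[["ellipse_area_cm2"]], k^2 * base[["ellipse_area_cm2"]],
               tolerance = 1e-9)
  expect_equal(unclass(sf)[7:10], unclass(base)[7:10], tolerance = 1e-9)
})
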