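#' Run a full i-CTSIB session
#'
#' For each supplied condition: read the trial (when given as a path),
#' preprocess, extract the ten sway features, and predict the stability
#' index with the matching per-condition model. The overall SI is the
#' mean of the per-condition estimates that could be computed; conditions
#' not supplied are listed in the report. Trials whose spectral features
#' are undefined (e.g. a flat trajectory) get `NA` SI and are flagged
#' rather than crashing the session.
#'
#' @param trials Named list (by condition) of [cop_trial()] objects or
#'   file paths readable by [read_cop_trial()].
#' @param models An `si_model_set` (or named list of `si_model`s)
#'   covering at least the supplied conditions.
#' @param spec A [filter_spec()].
#' @param subject_id Reported subject identifier; defaults to the first
#'   trial's.
#' @return A [session_report()].
#' @export
run_ictsib_session <- function(trials, models, spec = filter_spec(),
                               subject_id = NULL) {
  if (length(trials) == 0L)
    stop("run_ictsib_session: no conditions supplied (empty session)",
         call. = FALSE)
  conds <- names(trials)
  if (is.null(conds) || any(!conds %in% ctsib_conditions()))
    stop("run_ictsib_session: trials must be named by CTSIB condition",
         call. = FALSE)
  no_model <- setdiff(conds, names(models))
  if (length(no_model))
    stop("run_ictsib_session: no model for condition(s): ",
         paste(no_model, collapse = ", "), call. = FALSE)
  si <- stats::setNames(rep(NA_real_, length(conds)), conds)
  feats <- list()
  for (cond in conds) {
    tr <- trials[[cond]]
    if (is.character(tr)) tr <- read_cop_trial(tr, condition = cond)
    if (is.null(subject_id)) subject_id <- tr$subject_id
    ft <- compute_sway_features(tr, spec)
    feats[[cond]] <- ft
    if (is.null(attr(ft, "flagged_missing")))
      si[cond] <- max(predict(models[[cond]], ft), 0)
  }
  session_report(
    subject_id = if (is.null(subject_id)) NA_character_ else subject_id,
    per_condition_si = si, feature_table = feats,
    missing_conditions = setdiff(ctsib_conditions(), conds))
}

#' Device agreement: Pearson correlation of paired SI values
#'
#' Pearson's r between per-subject stability indices measured by two
#' devices, with the two-sided p-value of the test of zero correlation.
#'
#' @param si_a,si_b Equal-length numeric vectors (>= 3) of per-subject
#'   SIs from the two devices.
#' @param alpha Significance level reported alongside.
#' @return List with `r`, `p_value`, `n`, `alpha`, `significant`.
#' @export
device_agreement <- function(si_a, si_b, alpha = 0.05) {
  n <- length(si_a)
  if (n < 3L || length(si_b) != n)
    stop("device_agreement: need equal-length vectors of at least 3",
         call. = FALSE)
  if (stats::sd(si_a) == 0 || stats::sd(si_b) == 0)
    stop("device_agreement: constant vector (correlation undefined)",
         call. = FALSE)
  ct <- stats::cor.test(si_a, si_b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n,
       alpha = alpha, significant = ct$p.value < alpha)
}

#' Minimum sample size for a finite population
#'
#' Cochran's formula with finite-population correction:
#' `n0 = z^2 p (1 - p) / margin^2`, then
#' `n = ceil(n0 / (1 + (n0 - 1) / N))`. The ceiling is used because the
#' result is a minimum number of measurements.
#'
#' @param population Population size `N` (>= 1).
#' @param confidence Confidence level, e.g. 0.95.
#' @param margin Margin of error as a proportion, e.g. 0.05.
#' @param p Anticipated proportion (0.5 is the conservative default).
#' @return Required sample size (integer).
#' @export
#' @examples
#' sample_size_finite_population(108, 0.95, 0.05)  # 85
sample_size_finite_population <- function(population, confidence = 0.95,
                                          margin = 0.05, p = 0.5) {
  if (margin <= 0 || margin >= 1)
    stop("sample_size_finite_population: margin must be in (0, 1)",
         call. = FALSE)
  if (confidence <= 0 || confidence >= 1)
    stop("sample_size_finite_population: confidence must be in (0, 1)",
         call. = FALSE)
  if (population < 1)
    stop("sample_size_finite_population: population must be >= 1",
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n0 <- z^2 * p * (1 - p) / margin^2
  if (is.infinite(population)) return(as.integer(ceiling(n0)))
  n <- ceiling(n0 / (1 + (n0 - 1) / population))
  as.integer(min(n, population))
}
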