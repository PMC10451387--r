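#' CTSIB condition labels
#'
#' The seven conditions of the instrumented Clinical Test of Sensory
#' Interaction with Balance: vision open or closed, crossed with support
#' surface (firm, one foam pad, two foam pads), plus the eyes-open
#' backwards-counting dual task on the firm surface.
#'
#' @return Character vector of the seven condition labels.
#' @export
#' @examples
#' ctsib_conditions()
ctsib_conditions <- function() {
  c("EO-firm", "EO-firm-DC", "EO-foam1", "EO-foam2",
    "EC-firm", "EC-foam1", "EC-foam2")
}

#' Construct a center-of-pressure trial
#'
#' A `cop_trial` holds one uniformly sampled planar CoP trajectory.
#' Coordinate convention used throughout the package: `x` is the
#' anterior-posterior (AP) displacement and `y` the medio-lateral (ML)
#' displacement, in centimetres, with the origin at the device centre.
#'
#' @param time Sample times in seconds, strictly increasing with uniform
#'   step.
#' @param x,y CoP coordinates in cm (AP, ML).
#' @param fs Sampling rate in Hz. If `NULL` it is inferred as the
#'   reciprocal of the median time step.
#' @param condition One of [ctsib_conditions()], or `NA`.
#' @param subject_id Opaque subject identifier string.
#'
#' @details Uniform sampling is enforced: every time step must agree with
#'   `1/fs` within 1% of the step (and at least 1e-6 s). Trials need at
#'   least 2 samples.
#'
#' @return An object of class `cop_trial`: a list with elements `time`,
#'   `x`, `y`, `fs`, `condition`, `subject_id`.
#' @export
cop_trial <- function(time, x, y, fs = NULL, condition = NA_character_,
                      subject_id = NA_character_) {
  time <- as.numeric(time); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(time)
  if (n < 2L || length(x) != n || length(y) != n)
    stop("cop_trial: need time, x, y of equal length >= 2", call. = FALSE)
  if (anyNA(time) || anyNA(x) || anyNA(y))
    stop("cop_trial: missing values in trial data", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0))
    stop("cop_trial: time must be strictly increasing", call. = FALSE)
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0)
    stop("cop_trial: fs must be positive", call. = FALSE)
  tol <- max(0.01 / fs, 1e-6)
  if (any(abs(dt - 1 / fs) > tol))
    stop("cop_trial: non-uniform sampling (time steps deviate from 1/fs ",
         "beyond tolerance)", call. = FALSE)
  if (!is.na(condition)) condition <- match.arg(condition, ctsib_conditions())
  structure(
    list(time = time, x = x, y = y, fs = fs,
         condition = condition, subject_id = as.character(subject_id)),
    class = "cop_trial")
}

#' @export
print.cop_trial <- function(x, ...) {
  dur <- x$time[length(x$time)] - x$time[1]
  cat(sprintf("CoP trial: %d samples, %.1f s at %.3g Hz\n",
              length(x$time), dur, x$fs))
  cat(sprintf("  condition: %s   subject: %s\n",
              ifelse(is.na(x$condition), "<none>", x$condition),
              ifelse(is.na(x$subject_id), "<none>", x$subject_id)))
  cat(sprintf("  AP range [%.3f, %.3f] cm, ML range [%.3f, %.3f] cm\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
length.cop_trial <- function(x) length(x$time)

#' Read a CoP trial from a delimited text file
#'
#' The file dialect is comma-separated, `.` decimal, UTF-8, with a header
#' row containing at least the columns `time_s`, `cop_x_cm`, `cop_y_cm`.
#' Optional `condition` and `subject_id` columns (as written by
#' [write_cop_trial()]) are picked up when the corresponding arguments are
#' not supplied.
#'
#' @param path Path to the file.
#' @param condition Condition label to attach; overrides any label stored
#'   in the file.
#' @param fs Sampling rate override in Hz; if `NULL`, inferred from the
#'   time stamps.
#' @return A [cop_trial()].
#' @export
read_cop_trial <- function(path, condition = NULL, fs = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "cop_x_cm", "cop_y_cm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_cop_trial: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d) < 2L)
    stop("read_cop_trial: empty trial (fewer than 2 samples)", call. = FALSE)
  if (is.null(condition) && "condition" %in% names(d))
    condition <- d$condition[1]
  if (is.null(condition)) condition <- NA_character_
  subject_id <- if ("subject_id" %in% names(d)) as.character(d$subject_id[1])
                else NA_character_
  cop_trial(d$time_s, d$cop_x_cm, d$cop_y_cm, fs = fs,
            condition = condition, subject_id = subject_id)
}

#' Write a CoP trial to a delimited text file
#'
#' Writes columns `time_s`, `cop_x_cm`, `cop_y_cm`, plus `condition` and
#' `subject_id` when present, in a format readable by [read_cop_trial()].
#' The round trip preserves coordinates to better than 1e-9 cm.
#'
#' @param trial A [cop_trial()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cop_trial <- function(trial, path) {
  stopifnot(inherits(trial, "cop_trial"))
  d <- data.frame(time_s = trial$time, cop_x_cm = trial$x,
                  cop_y_cm = trial$y)
  if (!is.na(trial$condition)) d$condition <- trial$condition
  if (!is.na(trial$subject_id)) d$subject_id <- trial$subject_id
  ok <- tryCatch({
    utils::write.table(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                       file = path, sep = ",", dec = ".", qmethod = "double",
                       row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("write_cop_trial: cannot write to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Construct an i-CTSIB session report
#'
#' Bundles per-condition stability-index estimates for one subject. The
#' overall SI is the arithmetic mean of the per-condition values that are
#' present (non-missing).
#'
#' @param subject_id Subject identifier.
#' @param per_condition_si Named numeric vector, names from
#'   [ctsib_conditions()]. `NA` entries mark conditions where prediction
#'   was not possible (they are excluded from the overall mean).
#' @param feature_table Optional named list of per-condition sway feature
#'   vectors (as returned by [compute_sway_features()]).
#' @param missing_conditions Character vector of conditions not supplied.
#' @return An object of class `session_report`.
#' @export
session_report <- function(subject_id, per_condition_si,
                           feature_table = NULL,
                           missing_conditions = character()) {
  if (length(per_condition_si) == 0L)
    stop("session_report: empty per-condition SI map", call. = FALSE)
  if (is.null(names(per_condition_si)) || any(names(per_condition_si) == ""))
    stop("session_report: per_condition_si must be named by condition",
         call. = FALSE)
  bad <- setdiff(names(per_condition_si), ctsib_conditions())
  if (length(bad))
    stop("session_report: unknown condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  vals <- per_condition_si[!is.na(per_condition_si)]
  if (any(vals < 0))
    stop("session_report: SI values must be >= 0", call. = FALSE)
  overall <- if (length(vals)) mean(vals) else NA_real_
  structure(
    list(subject_id = as.character(subject_id),
         per_condition_si = per_condition_si,
         overall_si = overall,
         feature_table = feature_table,
         missing_conditions = missing_conditions,
         schema_version = "1.0"),
    class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat("i-CTSIB session report for subject", x$subject_id, "\n")
  for (cond in names(x$per_condition_si)) {
    v <- x$per_condition_si[[cond]]
    cat(sprintf("  %-10s SI = %s\n", cond,
                ifelse(is.na(v), "NA (not estimable)", sprintf("%.3f", v))))
  }
  cat(sprintf("  overall SI (mean of %d conditions) = %.3f\n",
              sum(!is.na(x$per_condition_si)), x$overall_si))
  if (length(x$missing_conditions))
    cat("  missing conditions:",
        paste(x$missing_conditions, collapse = ", "), "\n")
  invisible(x)
}

#' Write a session report as JSON
#'
#' @param report A [session_report()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_session_report <- function(report, path) {
  stopifnot(inherits(report, "session_report"))
  if (length(report$per_condition_si) == 0L)
    stop("write_session_report: empty report", call. = FALSE)
  conds <- lapply(names(report$per_condition_si), function(cond) {
    entry <- list(condition = cond,
                  si = report$per_condition_si[[cond]])
    ft <- report$feature_table[[cond]]
    if (!is.null(ft)) entry$features <- as.list(ft)
    entry
  })
  obj <- list(schema_version = report$schema_version,
              subject_id = report$subject_id,
              conditions = conds,
              overall_si = report$overall_si,
              missing_conditions = I(report$missing_conditions))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a session report written by [write_session_report()]
#'
#' @param path Path to the JSON report.
#' @return A [session_report()].
#' @export
read_session_report <- function(path) {
  obj <- jsonlite::read_json(path)
  si <- vapply(obj$conditions, function(e)
    ifelse(is.null(e$si), NA_real_, as.numeric(e$si)), numeric(1))
  names(si) <- vapply(obj$conditions, function(e) e$condition, character(1))
  ft <- lapply(obj$conditions, function(e)
    if (is.null(e$features)) NULL else unlist(e$features))
  names(ft) <- names(si)
  session_report(obj$subject_id, si, feature_table = ft,
                 missing_conditions = unlist(obj$missing_conditions))
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring
# the caller's RNG state afterwards. Keeps package functions reproducible
# without clobbering the user's random stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
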