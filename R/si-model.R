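#' Validate a training table
#'
#' A training table is a data frame with columns `subject_id`,
#' `condition`, the ten [sway_feature_names()], and `si_reference` (the
#' reference stability index measured by a commercial balance system).
#'
#' @param table Data frame to validate.
#' @param require_features Require all feature values non-missing?
#' @return The table, invisibly, after checks.
#' @export
validate_training_table <- function(table, require_features = TRUE) {
  need <- c("subject_id", "condition", sway_feature_names(), "si_reference")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("training table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(table[c("subject_id", "condition")]))
    stop("training table: duplicated (subject, condition) rows",
         call. = FALSE)
  if (any(table$si_reference < 0, na.rm = TRUE))
    stop("training table: si_reference must be >= 0", call. = FALSE)
  if (require_features && anyNA(table[sway_feature_names()]))
    stop("training table: missing feature values", call. = FALSE)
  invisible(table)
}

#' Read / write a training table as delimited text
#'
#' Comma-separated with a header; columns as described in
#' [validate_training_table()].
#'
#' @param path File path.
#' @return `read_training_table()` returns the validated data frame.
#' @export
read_training_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_training_table(d)
  d
}

#' @rdname read_training_table
#' @param table Training table to write.
#' @export
write_training_table <- function(table, path) {
  validate_training_table(table, require_features = FALSE)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a training table by subject
#'
#' Subjects are shuffled deterministically by `seed` and the first
#' `floor(train_fraction * n_subjects)` form the training set; all rows
#' (conditions) of a subject land on the same side, so the test set
#' contains only unseen subjects.
#'
#' @param table Training table (see [validate_training_table()]).
#' @param train_fraction Fraction of subjects assigned to training.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(table, train_fraction = 0.7, seed = 1) {
  validate_training_table(table, require_features = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("split_dataset: train_fraction must lie in (0, 1)", call. = FALSE)
  subjects <- sort(unique(table$subject_id))
  if (length(subjects) < 2L)
    stop("split_dataset: need at least 2 distinct subjects", call. = FALSE)
  shuffled <- with_seed(seed, sample(subjects))
  n_train <- floor(train_fraction * length(subjects))
  tr_sub <- shuffled[seq_len(n_train)]
  list(train = table[table$subject_id %in% tr_sub, , drop = FALSE],
       test = table[!table$subject_id %in% tr_sub, , drop = FALSE])
}

# Closed-form ridge on a standardized design: minimizes
# ||y - ybar - Z beta||^2 + lambda ||beta||^2.
ridge_solve <- function(Z, yc, lambda) {
  p <- ncol(Z)
  A <- crossprod(Z) + diag(lambda, p)
  solve(A, crossprod(Z, yc))[, 1]
}

#' Default hyperparameter search spaces
#'
#' Search spaces used by [fit_condition_model()] for each model family,
#' in the format of [bayesian_optimize()]. All are overridable.
#'
#' @param model_type One of `"linear"`, `"svm"`, `"gam"`, `"tree"`.
#' @return Named list of parameter definitions.
#' @export
default_search_space <- function(model_type) {
  switch(model_type,
    linear = list(
      lambda = list(type = "loguniform", lower = 1e-6, upper = 1e3)),
    svm = list(
      cost = list(type = "loguniform", lower = 1e-2, upper = 1e3),
      gamma = list(type = "loguniform", lower = 1e-3, upper = 10),
      epsilon = list(type = "uniform", lower = 0.01, upper = 1)),
    gam = {
      sp <- lapply(sway_feature_names(), function(f)
        list(type = "loguniform", lower = 1e-4, upper = 1e4))
      names(sp) <- paste0("sp_", sway_feature_names())
      c(sp, list(k = list(type = "integer", lower = 5, upper = 20)))
    },
    tree = list(
      maxdepth = list(type = "integer", lower = 2, upper = 12),
      minbucket = list(type = "integer", lower = 2, upper = 20)),
    stop("unknown model_type: ", model_type, call. = FALSE))
}

# Fit one model family on standardized features; returns a closure-free
# object with everything predict needs.
fit_engine <- function(model_type, Z, y, params, feature_names) {
  df <- as.data.frame(Z)
  names(df) <- feature_names
  df$.y <- y
  switch(model_type,
    linear = {
      # centre within the fitting rows so the intercept is exact even on
      # cross-validation subsets of the standardized design
      mu <- colMeans(Z)
      beta <- ridge_solve(sweep(Z, 2, mu), y - mean(y), params$lambda)
      list(kind = "linear", beta = beta,
           bias = mean(y) - sum(mu * beta))
    },
    svm = list(kind = "svm",
               fit = e1071::svm(Z, y, type = "eps-regression",
                                kernel = "radial", cost = params$cost,
                                gamma = params$gamma,
                                epsilon = params$epsilon, scale = FALSE)),
    gam = {
      k <- max(3L, min(params$k, nrow(Z) - 1L))
      terms <- paste0("s(", feature_names, ", k=", k, ")")
      fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      sp <- unlist(params[paste0("sp_", feature_names)])
      list(kind = "gam",
           fit = mgcv::gam(fml, data = df, sp = sp, method = "GCV.Cp"))
    },
    tree = list(kind = "tree",
                fit = rpart::rpart(
                  .y ~ ., data = df, method = "anova",
                  control = rpart::rpart.control(
                    maxdepth = params$maxdepth, minbucket = params$minbucket,
                    minsplit = max(2L, 2L * params$minbucket),
                    cp = 0, xval = 0))))
}

predict_engine <- function(engine, Z, feature_names) {
  df <- as.data.frame(Z)
  names(df) <- feature_names
  switch(engine$kind,
    linear = engine$bias + as.numeric(Z %*% engine$beta),
    svm = as.numeric(stats::predict(engine$fit, Z)),
    gam = as.numeric(mgcv::predict.gam(engine$fit, newdata = df)),
    tree = as.numeric(stats::predict(engine$fit, newdata = df)))
}

#' Fit a per-condition stability-index regression model
#'
#' The central fitting function. Features are standardized on training
#' statistics; hyperparameters are chosen by [bayesian_optimize()]
#' minimizing 5-fold cross-validated RMSE; the final model is refitted on
#' all training rows with the selected hyperparameters. For the linear
#' family (ridge regression, the model family selected for deployment)
#' the coefficients are also folded back to the raw feature scale so the
#' fitted SI formula can be exported and applied without the package.
#'
#' @param train Training table rows for a single condition (at least 10).
#' @param model_type `"linear"` (ridge), `"svm"`, `"gam"` or `"tree"`.
#' @param bo A [bo_config()] controlling the hyperparameter search.
#' @param search_space Optional override of [default_search_space()].
#' @param cv_folds Number of cross-validation folds for the search
#'   objective.
#' @return An object of class `si_model` with `print`, `summary`,
#'   `coef`, `predict`, `residuals` and `plot` methods.
#' @export
fit_condition_model <- function(train, model_type = c("linear", "svm",
                                                      "gam", "tree"),
                                bo = bo_config(), search_space = NULL,
                                cv_folds = 5) {
  model_type <- match.arg(model_type)
  validate_training_table(train)
  cond <- unique(train$condition)
  if (length(cond) != 1L)
    stop("fit_condition_model: train must contain exactly one condition ",
         "(got ", length(cond), ")", call. = FALSE)
  n <- nrow(train)
  if (n < 10L)
    stop("fit_condition_model: need at least 10 training rows, got ", n,
         call. = FALSE)
  fn <- sway_feature_names()
  X <- as.matrix(train[fn])
  y <- train$si_reference
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")
  base <- list(condition = cond, model_type = model_type,
               feature_names = fn, center = center, scale = scale_,
               n_train = n, y_train = y)
  if (stats::sd(y) == 0) {
    warning("fit_condition_model: constant target; returning intercept-only ",
            "model")
    out <- c(base, list(
      engine = list(kind = "linear", beta = rep(0, length(fn)),
                    bias = y[1]),
      hyperparams = list(), cv_rmse = 0, fitted = rep(y[1], n)))
    out$beta <- stats::setNames(rep(0, length(fn)), fn)
    out$bias <- y[1]
    out <- c(out, linear_raw_form(out))
    return(structure(out, class = "si_model"))
  }
  if (is.null(search_space)) search_space <- default_search_space(model_type)
  folds <- with_seed(bo$seed, sample(rep_len(seq_len(cv_folds), n)))
  objective <- function(params) {
    pred <- numeric(n)
    for (fo in seq_len(cv_folds)) {
      idx <- folds == fo
      if (all(idx) || !any(idx)) next
      eng <- fit_engine(model_type, Z[!idx, , drop = FALSE], y[!idx],
                        params, fn)
      pred[idx] <- predict_engine(eng, Z[idx, , drop = FALSE], fn)
    }
    sqrt(mean((pred - y)^2))
  }
  bo_res <- bayesian_optimize(objective, search_space, bo)
  engine <- fit_engine(model_type, Z, y, bo_res$best_params, fn)
  out <- c(base, list(engine = engine, hyperparams = bo_res$best_params,
                      cv_rmse = bo_res$best_value, bo_trace = bo_res$trace))
  if (model_type == "linear") {
    out$beta <- stats::setNames(engine$beta, fn)
    out$bias <- engine$bias
    out <- c(out, linear_raw_form(out))
  }
  out$fitted <- predict_engine(engine, Z, fn)
  structure(out, class = "si_model")
}

# Fold standardized linear coefficients back to the raw feature scale:
# si = bias_raw + sum(beta_raw * feature).
linear_raw_form <- function(m) {
  beta_raw <- m$beta / m$scale
  list(beta_raw = beta_raw,
       bias_raw = m$bias - sum(beta_raw * m$center))
}

#' @export
print.si_model <- function(x, ...) {
  cat(sprintf("SI model (%s) for condition %s, fitted on %d rows\n",
              x$model_type, x$condition, x$n_train))
  if (length(x$hyperparams))
    cat("  hyperparameters:",
        paste(sprintf("%s=%.4g", names(x$hyperparams),
                      unlist(x$hyperparams)), collapse = ", "), "\n")
  if (!is.null(x$cv_rmse))
    cat(sprintf("  CV RMSE: %.4f\n", x$cv_rmse))
  invisible(x)
}

#' @export
summary.si_model <- function(object, ...) {
  print(object)
  res <- stats::residuals(object)
  cat(sprintf("  training RMSE: %.4f, residual range [%.3f, %.3f]\n",
              sqrt(mean(res^2)), min(res), max(res)))
  if (object$model_type == "linear") {
    cat("  raw-scale formula coefficients:\n")
    print(round(c(bias = object$bias_raw, object$beta_raw), 5))
  }
  invisible(object)
}

#' @export
coef.si_model <- function(object, raw = TRUE, ...) {
  if (object$model_type != "linear")
    stop("coef: only linear SI models expose coefficients", call. = FALSE)
  if (raw) c(bias = object$bias_raw, object$beta_raw)
  else c(bias = object$bias, object$beta)
}

#' @export
residuals.si_model <- function(object, ...) object$y_train - object$fitted

#' Predict the stability index for new feature vectors
#'
#' @param object An `si_model`.
#' @param newdata A data frame with the ten feature columns, a named
#'   numeric vector, or a `sway_features` vector.
#' @param ... Unused.
#' @return Numeric vector of SI predictions.
#' @export
predict.si_model <- function(object, newdata, ...) {
  fn <- object$feature_names
  if (inherits(newdata, "sway_features") || (is.numeric(newdata) &&
      !is.null(names(newdata))))
    newdata <- as.data.frame(as.list(unclass(newdata)))
  miss <- setdiff(fn, names(newdata))
  if (length(miss))
    stop("predict: missing feature(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(newdata[fn])
  if (anyNA(X) || any(!is.finite(X)))
    stop("predict: missing or non-finite feature values", call. = FALSE)
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  predict_engine(object$engine, Z, fn)
}

#' @rdname predict.si_model
#' @param model An `si_model`.
#' @param features Feature input as in `newdata`.
#' @export
predict_si <- function(model, features) predict(model, features)

#' @export
plot.si_model <- function(x, ...) {
  graphics::plot(x$y_train, x$fitted,
                 xlab = "reference SI", ylab = "fitted SI",
                 main = sprintf("%s model, %s", x$model_type, x$condition),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Evaluate a fitted model on held-out rows
#'
#' Pearson correlation between reference and predicted SI on the test
#' rows (the headline accuracy metric), with RMSE as a secondary metric.
#'
#' @param model An `si_model`.
#' @param test Test rows of a training table (same condition).
#' @return List with `r`, `rmse`, `n`.
#' @export
evaluate_model <- function(model, test) {
  validate_training_table(test)
  if (nrow(test) < 3L)
    stop("evaluate_model: need at least 3 test rows", call. = FALSE)
  pred <- predict(model, test)
  obs <- test$si_reference
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    stop("evaluate_model: zero variance in observed or predicted values ",
         "(correlation undefined)", call. = FALSE)
  list(r = stats::cor(obs, pred),
       rmse = sqrt(mean((obs - pred)^2)),
       n = nrow(test))
}

#' Fit SI models for every condition in a table
#'
#' @param table Full training table.
#' @param model_type Model family, as in [fit_condition_model()].
#' @param bo A [bo_config()]; the seed is offset per condition so each
#'   condition gets an independent reproducible search.
#' @param ... Passed to [fit_condition_model()].
#' @return Named list of `si_model` objects (class `si_model_set`).
#' @export
train_si_models <- function(table, model_type = "linear", bo = bo_config(),
                            ...) {
  conds <- intersect(ctsib_conditions(), unique(table$condition))
  models <- lapply(seq_along(conds), function(i) {
    boi <- bo
    boi$seed <- bo$seed + i - 1L
    fit_condition_model(table[table$condition == conds[i], , drop = FALSE],
                        model_type = model_type, bo = boi, ...)
  })
  names(models) <- conds
  structure(models, class = "si_model_set")
}

#' @export
print.si_model_set <- function(x, ...) {
  cat("SI model set:", length(x), "conditions\n")
  for (m in x)
    cat(sprintf("  %-10s %s, CV RMSE %.4f\n", m$condition, m$model_type,
                m$cv_rmse))
  invisible(x)
}

#' Export per-condition linear SI formulas as JSON
#'
#' Writes the raw-feature-scale coefficients (`beta`, named by feature)
#' and bias for each condition, so the fitted SI formula can be
#' re-implemented anywhere. Loading the file with
#' [read_linear_formula()] reconstitutes models whose predictions match
#' the originals to within 1e-9.
#'
#' @param models An `si_model_set` or named list of linear `si_model`s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_linear_formula <- function(models, path) {
  bad <- names(models)[vapply(models, function(m)
    m$model_type != "linear", logical(1))]
  if (length(bad))
    stop("export_linear_formula: non-linear model for condition(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  obj <- list(schema_version = "1.0",
              conditions = lapply(unname(models), function(m)
                list(condition = m$condition,
                     beta = as.list(m$beta_raw),
                     bias = m$bias_raw)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load linear SI formulas exported by [export_linear_formula()]
#'
#' @param path Path to the JSON file.
#' @return An `si_model_set` of linear models that predict identically to
#'   the exported ones.
#' @export
read_linear_formula <- function(path) {
  obj <- jsonlite::read_json(path)
  fn <- sway_feature_names()
  models <- lapply(obj$conditions, function(e) {
    beta_raw <- unlist(e$beta)[fn]
    structure(list(condition = e$condition, model_type = "linear",
                   feature_names = fn,
                   center = stats::setNames(rep(0, length(fn)), fn),
                   scale = stats::setNames(rep(1, length(fn)), fn),
                   engine = list(kind = "linear", beta = unname(beta_raw),
                                 bias = e$bias),
                   beta = stats::setNames(beta_raw, fn), bias = e$bias,
                   beta_raw = stats::setNames(beta_raw, fn),
                   bias_raw = e$bias,
                   hyperparams = list(), n_train = NA_integer_),
              class = "si_model")
  })
  names(models) <- vapply(models, function(m) m$condition, character(1))
  structure(models, class = "si_model_set")
}
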