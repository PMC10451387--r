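#' Bayesian-optimization configuration
#'
#' Settings for hyperparameter search: a Gaussian-process surrogate with
#' a probability-of-improvement (POI) acquisition, 30 optimization
#' iterations after a 10-point Latin-hypercube initial design.
#'
#' @param n_iterations Number of acquisition-driven evaluations after the
#'   initial design.
#' @param n_initial Size of the Latin-hypercube initial design.
#' @param acquisition Acquisition function; only `"POI"` is implemented.
#' @param xi Improvement margin subtracted from the incumbent best before
#'   computing the probability of improvement.
#' @param n_candidates Random candidate points scored per iteration.
#' @param seed Integer seed making the whole search reproducible.
#' @return An object of class `bo_config`.
#' @export
bo_config <- function(n_iterations = 30, n_initial = 10,
                      acquisition = "POI", xi = 0.01,
                      n_candidates = 500, seed = 1) {
  stopifnot(n_iterations >= 1, n_initial >= 1)
  acquisition <- match.arg(acquisition, "POI")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_initial = as.integer(n_initial),
                 acquisition = acquisition, xi = xi,
                 n_candidates = as.integer(n_candidates),
                 seed = as.integer(seed)),
            class = "bo_config")
}

# Map unit-cube coordinates to parameter values per the space definition.
bo_decode <- function(z, space) {
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (j in seq_along(space)) {
    p <- space[[j]]
    out[[j]] <- switch(p$type,
      uniform = p$lower + z[j] * (p$upper - p$lower),
      loguniform = exp(log(p$lower) + z[j] * (log(p$upper) - log(p$lower))),
      integer = as.integer(round(p$lower + z[j] * (p$upper - p$lower))),
      stop("unknown parameter type: ", p$type))
  }
  out
}

# Gaussian-process regression on the unit cube with a squared-exponential
# kernel; length-scale picked from a small grid by marginal likelihood.
bo_gp_fit <- function(Z, y) {
  ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yn <- (y - mean(y)) / ys
  n <- nrow(Z)
  D2 <- as.matrix(stats::dist(Z))^2
  best <- NULL
  for (ell in c(0.1, 0.2, 0.35, 0.6, 1)) {
    K <- exp(-D2 / (2 * ell^2)) + diag(1e-6, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), yn))
    ll <- -0.5 * sum(yn * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, ell = ell, ch = ch, alpha = alpha)
  }
  if (is.null(best))
    stop("bayesian_optimize: surrogate fit failed", call. = FALSE)
  best$Z <- Z; best$ymean <- mean(y); best$ysd <- ys
  best
}

bo_gp_predict <- function(gp, Znew) {
  Ks <- exp(-(outer(rowSums(Znew^2), rowSums(gp$Z^2), `+`) -
                2 * Znew %*% t(gp$Z)) / (2 * gp$ell^2))
  mu <- as.numeric(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$ch), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mu = gp$ymean + gp$ysd * mu, sd = gp$ysd * sqrt(s2))
}

#' Minimize an objective by Bayesian optimization
#'
#' Runs a Latin-hypercube initial design followed by
#' `config$n_iterations` evaluations chosen by maximizing the probability
#' of improvement under a Gaussian-process surrogate. Returns the best
#' point over all evaluations. The whole trace is deterministic given
#' `config$seed`.
#'
#' @param objective Function taking a named list of parameter values and
#'   returning a scalar loss to minimize.
#' @param search_space Named list of parameter definitions, each a list
#'   with `type` (`"uniform"`, `"loguniform"` or `"integer"`), `lower`
#'   and `upper`. A parameter with `lower == upper` is held fixed.
#' @param config A [bo_config()].
#' @return A list of class `bo_result` with `best_params`, `best_value`
#'   and the evaluation `trace` (data frame of parameters and losses).
#' @export
bayesian_optimize <- function(objective, search_space, config = bo_config()) {
  stopifnot(length(search_space) >= 1)
  d <- length(search_space)
  fixed <- vapply(search_space, function(p) p$lower >= p$upper, logical(1))
  eval_point <- function(z) {
    params <- bo_decode(z, search_space)
    val <- tryCatch(objective(params), error = function(e)
      stop("bayesian_optimize: objective failed at (",
           paste(sprintf("%s=%.4g", names(params), unlist(params)),
                 collapse = ", "), "): ", conditionMessage(e), call. = FALSE))
    if (!is.finite(val)) val <- Inf
    val
  }
  if (all(fixed)) {
    z <- rep(0, d)
    val <- eval_point(z)
    params <- bo_decode(z, search_space)
    tr <- cbind(as.data.frame(params), loss = val)
    return(structure(list(best_params = params, best_value = val, trace = tr),
                     class = "bo_result"))
  }
  with_seed(config$seed, {
    Z0 <- lhs::randomLHS(config$n_initial, d)
    Z0[, fixed] <- 0
    Z <- Z0
    y <- apply(Z, 1, eval_point)
    for (it in seq_len(config$n_iterations)) {
      Zc <- matrix(stats::runif(config$n_candidates * d),
                   ncol = d)
      Zc[, fixed] <- 0
      gp <- bo_gp_fit(Z, y)
      pr <- bo_gp_predict(gp, Zc)
      target <- min(y) - config$xi * max(stats::sd(y), 1e-12)
      poi <- stats::pnorm((target - pr$mu) / pr$sd)
      znext <- Zc[which.max(poi), , drop = TRUE]
      Z <- rbind(Z, znext)
      y <- c(y, eval_point(znext))
    }
    best <- which.min(y)
    params_tr <- do.call(rbind, lapply(seq_len(nrow(Z)), function(i)
      as.data.frame(bo_decode(Z[i, ], search_space))))
    tr <- cbind(params_tr, loss = y)
    structure(list(best_params = bo_decode(Z[best, ], search_space),
                   best_value = y[best], trace = tr),
              class = "bo_result")
  })
}

#' @export
print.bo_result <- function(x, ...) {
  cat("Bayesian optimization:", nrow(x$trace), "evaluations\n")
  cat("  best loss:", format(x$best_value, digits = 6), "at\n")
  for (nm in names(x$best_params))
    cat("   ", nm, "=", format(x$best_params[[nm]], digits = 5), "\n")
  invisible(x)
}
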