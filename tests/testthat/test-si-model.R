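test_that("subject-level split has the right sizes and is deterministic", {
  tab <- do.call(rbind, lapply(ctsib_conditions(), function(cond) {
    d <- make_linear_table(103, condition = cond)
    d
  }))
  sp <- split_dataset(tab, 0.7, seed = 5)
  tr_sub <- unique(sp$train$subject_id)
  te_sub <- unique(sp$test$subject_id)
  expect_length(tr_sub, 72L)   # floor(0.7 * 103)
  expect_length(te_sub, 31L)
  expect_length(intersect(tr_sub, te_sub), 0L)
  # all conditions of a subject stay on one side
  expect_equal(nrow(sp$train), 72L * 7L)

  sp2 <- split_dataset(tab, 0.7, seed = 5)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)

  two <- make_linear_table(2)
  s2 <- split_dataset(two, 0.5, seed = 1)
  expect_equal(nrow(s2$train), 1L)
  expect_equal(nrow(s2$test), 1L)

  expect_error(split_dataset(tab, 1.2), "train_fraction")
  expect_error(split_dataset(make_linear_table(1), 0.5), "2 distinct")
})

test_that("ridge with a small optimized penalty recovers planted
           coefficients on noiseless data", {
  tab <- make_linear_table(n = 60, beta = c(2, -1), bias = 3)
  m <- fit_condition_model(tab, "linear",
                           bo = bo_config(n_iterations = 10, n_initial = 6,
                                          seed = 2))
  co <- coef(m)
  expect_equal(unname(co["bias"]), 3, tolerance = 1e-3)
  expect_equal(unname(co[paste0(sway_feature_names()[1])]), 2,
               tolerance = 1e-3)
  expect_equal(unname(co[paste0(sway_feature_names()[2])]), -1,
               tolerance = 1e-3)
  expect_lt(max(abs(co[sway_feature_names()[3:10]])), 1e-3)
  # predictions on new points follow the exact formula
  new <- make_linear_table(n = 12, beta = c(2, -1), bias = 3, seed = 9)
  expect_equal(predict(m, new),
               3 + 2 * new$mean_cm - new$mean_path_cm_s, tolerance = 1e-3)
})

test_that("ridge agrees with an independent penalized-regression solver", {
  tab <- make_linear_table(n = 50, beta = c(1.5, -0.8), bias = 1,
                           noise_sd = 0.3, seed = 12)
  X <- as.matrix(tab[sway_feature_names()])
  y <- tab$si_reference
  Z <- scale(X)
  lam_glmnet <- 0.05
  g <- glmnet::glmnet(Z, y, alpha = 0, lambda = lam_glmnet,
                      standardize = FALSE, intercept = TRUE,
                      thresh = 1e-14)
  # glmnet standardizes the response internally, so its penalty acts on
  # the y/sd_n(y) scale; translate to the plain ridge parameterization
  n <- nrow(Z)
  sdn_y <- stats::sd(y) * sqrt((n - 1) / n)
  mine <- ictsib:::ridge_solve(Z, y - mean(y), n * lam_glmnet / sdn_y)
  expect_equal(unname(mine), unname(as.numeric(g$beta)), tolerance = 1e-6)
})

test_that("the ridge coefficient norm shrinks monotonically in the
           penalty", {
  tab <- make_linear_table(n = 40, noise_sd = 0.2, seed = 3)
  Z <- scale(as.matrix(tab[sway_feature_names()]))
  yc <- tab$si_reference - mean(tab$si_reference)
  norms <- vapply(10^seq(-4, 4), function(l)
    sqrt(sum(ictsib:::ridge_solve(Z, yc, l)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], norms[1] / 100)
})

test_that("constant targets yield an intercept-only model", {
  tab <- make_linear_table(n = 20)
  tab$si_reference <- 5
  expect_warning(m <- fit_condition_model(tab, "linear", bo = fast_bo()),
                 "constant target")
  expect_equal(unname(coef(m)["bias"]), 5)
  expect_equal(max(abs(coef(m)[-1])), 0)
  expect_equal(unname(predict(m, tab[1, ])), 5)
})

test_that("a regression tree on a step function predicts the leaf means", {
  tab <- make_linear_table(n = 60, seed = 21)
  tab$si_reference <- ifelse(tab$mean_cm < 1.2, 1, 5)
  space <- list(maxdepth = list(type = "integer", lower = 2, upper = 2),
                minbucket = list(type = "integer", lower = 5, upper = 5))
  m <- fit_condition_model(tab, "tree", bo = fast_bo(),
                           search_space = space)
  pred <- predict(m, tab)
  lo <- tab$mean_cm < 1.2
  # piecewise-mean oracle: each side predicted by its own group mean
  expect_equal(unique(round(pred[lo], 10)),
               mean(tab$si_reference[lo]), tolerance = 1e-9)
  expect_equal(unique(round(pred[!lo], 10)),
               mean(tab$si_reference[!lo]), tolerance = 1e-9)
})

test_that("svm and gam engines fit and predict finite values", {
  tab <- make_linear_table(n = 40, noise_sd = 0.2, seed = 8)
  svm_space <- list(cost = list(type = "loguniform", lower = 1, upper = 10),
                    gamma = list(type = "loguniform", lower = 0.01,
                                 upper = 0.1),
                    epsilon = list(type = "uniform", lower = 0.1,
                                   upper = 0.1))
  ms <- fit_condition_model(tab, "svm", bo = fast_bo(),
                            search_space = svm_space)
  expect_true(all(is.finite(predict(ms, tab))))
  gam_space <- default_search_space("gam")
  for (nm in names(gam_space))
    gam_space[[nm]]$lower <- gam_space[[nm]]$upper <-
      if (nm == "k") 3 else 1
  mg <- fit_condition_model(tab, "gam", bo = bo_config(n_iterations = 1,
                                                       n_initial = 1),
                            search_space = gam_space)
  expect_true(all(is.finite(predict(mg, tab))))
  expect_error(fit_condition_model(tab, "boost"), "arg")
})

test_that("predictions are reproducible from the exported formula alone", {
  tab <- make_linear_table(n = 30, beta = c(1, 0.5), bias = 2,
                           noise_sd = 0.1, seed = 4)
  m <- fit_condition_model(tab, "linear", bo = fast_bo())
  # centering identity: predicting at the training means gives the
  # standardized-form bias
  mu <- as.data.frame(as.list(colMeans(tab[sway_feature_names()])))
  expect_equal(unname(predict(m, mu)), m$bias, tolerance = 1e-9)
  # manual raw-formula evaluation equals the model prediction
  manual <- m$bias_raw +
    as.numeric(as.matrix(tab[sway_feature_names()]) %*% m$beta_raw)
  expect_equal(predict(m, tab), manual, tolerance = 1e-9)
  expect_error(predict(m, tab[, -3]), "missing feature")
})

test_that("linear formula export round-trips predictions exactly", {
  tabs <- lapply(ctsib_conditions()[1:3], function(cond)
    make_linear_table(n = 25, noise_sd = 0.1, condition = cond,
                      seed = match(cond, ctsib_conditions())))
  models <- lapply(tabs, fit_condition_model, model_type = "linear",
                   bo = fast_bo())
  names(models) <- ctsib_conditions()[1:3]
  path <- withr::local_tempfile(fileext = ".json")
  export_linear_formula(models, path)
  obj <- jsonlite::read_json(path)
  expect_length(obj$conditions, 3L)
  expect_length(obj$conditions[[1]]$beta, 10L)
  back <- read_linear_formula(path)
  for (cond in names(models))
    expect_equal(predict(back[[cond]], tabs[[match(cond, names(models))]]),
                 predict(models[[cond]], tabs[[match(cond, names(models))]]),
                 tolerance = 1e-9)
  # a non-linear model in the map is rejected
  tree_space <- list(maxdepth = list(type = "integer", lower = 3, upper = 3),
                     minbucket = list(type = "integer", lower = 5,
                                      upper = 5))
  mt <- fit_condition_model(tabs[[1]], "tree", bo = fast_bo(),
                            search_space = tree_space)
  expect_error(export_linear_formula(c(models[1], list("EO-foam2" = mt)),
                                     path), "non-linear")
})

test_that("evaluate_model computes Pearson r with RMSE", {
  tab <- make_linear_table(n = 40, beta = c(2, -1), bias = 3, seed = 6)
  m <- fit_condition_model(tab, "linear", bo = fast_bo())
  te <- make_linear_table(n = 10, beta = c(2, -1), bias = 3, seed = 60)
  ev <- evaluate_model(m, te)
  expect_equal(ev$r, 1, tolerance = 1e-6)
  expect_lt(ev$rmse, 1e-3)
  expect_equal(ev$n, 10L)
  # anti-correlated predictions
  te2 <- te
  te2$si_reference <- pmax(max(te$si_reference) + 1 -
                             (3 + 2 * te$mean_cm - te$mean_path_cm_s), 0)
  expect_equal(evaluate_model(m, te2)$r, -1, tolerance = 1e-6)
  te3 <- te
  te3$si_reference <- rep(2, 10)
  expect_error(evaluate_model(m, te3), "zero variance")
  expect_error(evaluate_model(m, te[1:2, ]), "3 test rows")
})
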