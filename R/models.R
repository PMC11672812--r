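ALGORITHMS <- c("random_forest", "extra_trees", "adaboost", "gbdt", "xgboost")

#' A model specification
#'
#' @param algorithm One of `"random_forest"`, `"extra_trees"`, `"adaboost"`,
#'   `"gbdt"`, `"xgboost"`.
#' @param ... Hyperparameters overriding the engine defaults. For `gbdt`:
#'   `loss` (`"ls"`, `"lad"`, `"huber"`), `learning_rate`, `n_estimators`,
#'   `max_depth`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(algorithm, ...) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  structure(list(algorithm = algorithm, params = list(...)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  p <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "engine defaults"
  cat(sprintf("<model_spec> %s (%s)\n", x$algorithm, p))
  invisible(x)
}

#' The five candidate tree-ensemble regressors with engine defaults
#' @return A named list of [model_spec()]s.
#' @export
default_model_specs <- function() {
  specs <- lapply(ALGORITHMS, model_spec)
  names(specs) <- ALGORITHMS
  specs
}

spec_param <- function(spec, name, default) {
  if (!is.null(spec$params[[name]])) spec$params[[name]] else default
}

gbdt_objective <- function(loss) {
  switch(loss,
         ls = "reg:squarederror",
         lad = "reg:absoluteerror",
         huber = "reg:pseudohubererror",
         stop("unknown gbdt loss: ", loss, call. = FALSE))
}

feature_matrix <- function(rs) {
  cbind(sex_male = as.integer(as.character(rs$sex) == "male"),
        age_days = as.numeric(rs$age_days))
}

# AdaBoost.R2 (Drucker 1997) for regression on rpart base learners: no
# installed R package provides boosted regression of this form.
adaboost_r2 <- function(x, y, n_estimators = 50, max_depth = 3,
                        learning_rate = 1, loss = "linear") {
  n <- length(y)
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  df <- data.frame(y = y, x)
  for (m in seq_len(n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE, prob = w)
    tree <- rpart::rpart(y ~ ., data = df[idx, , drop = FALSE],
                         control = rpart::rpart.control(
                           maxdepth = max_depth, cp = 0, minsplit = 2,
                           minbucket = 1, xval = 0))
    pred <- predict(tree, df)
    abs_err <- abs(pred - y)
    emax <- max(abs_err)
    if (emax == 0) { trees[[m]] <- tree; betas[m] <- 1e-10; break }
    err <- switch(loss,
                  linear = abs_err / emax,
                  square = (abs_err / emax)^2,
                  exponential = 1 - exp(-abs_err / emax))
    errbar <- sum(w * err)
    if (errbar >= 0.5) { if (length(trees) == 0) { trees[[1]] <- tree; betas[1] <- 0.5 }; break }
    beta <- errbar / (1 - errbar)
    trees[[m]] <- tree; betas[m] <- beta
    w <- w * beta^(learning_rate * (1 - err))
    w <- w / sum(w)
  }
  list(trees = trees, weights = log(1 / betas))
}

predict_adaboost_r2 <- function(fit, x) {
  preds <- vapply(fit$trees, function(t) predict(t, data.frame(x)),
                  numeric(nrow(x)))
  preds <- matrix(preds, nrow = nrow(x))
  wts <- fit$weights
  apply(preds, 1, function(p) {
    o <- order(p)
    cw <- cumsum(wts[o])
    p[o][which(cw >= 0.5 * sum(wts))[1]]  # weighted median
  })
}

#' Fit one growth model
#'
#' Trains a regressor of weight (kg) on `(sex, age_days)`. The `gbdt` spec
#' is classic unregularised gradient tree boosting (exact greedy splits, no
#' shrinkage of leaf weights beyond the learning rate, full-sample trees);
#' `xgboost` uses the xgboost library defaults; `random_forest`,
#' `extra_trees` and `adaboost` use their usual engine defaults.
#'
#' @param spec A [model_spec()].
#' @param rs Training records (`sex`, `age_days`, `weight_kg`).
#' @param seed Seed controlling any training randomness.
#' @return An object of class `growth_model`.
#' @export
fit_growth_model <- function(spec, rs, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), nrow(rs) > 0)
  x <- feature_matrix(rs)
  y <- rs$weight_kg
  set.seed(seed)
  fit <- switch(spec$algorithm,
    gbdt = {
      params <- list(
        objective = gbdt_objective(spec_param(spec, "loss", "ls")),
        eta = spec_param(spec, "learning_rate", 0.1),
        max_depth = spec_param(spec, "max_depth", 3),
        lambda = 0, alpha = 0, subsample = 1, colsample_bytree = 1,
        min_child_weight = 1, tree_method = "exact", nthread = 1,
        seed = seed)
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(x, label = y),
                         nrounds = spec_param(spec, "n_estimators", 100),
                         verbose = 0)
    },
    xgboost = {
      params <- list(
        objective = "reg:squarederror",
        eta = spec_param(spec, "learning_rate", 0.3),
        max_depth = spec_param(spec, "max_depth", 6),
        nthread = 1, seed = seed)
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(x, label = y),
                         nrounds = spec_param(spec, "n_estimators", 100),
                         verbose = 0)
    },
    random_forest = randomForest::randomForest(
      x = x, y = y, ntree = spec_param(spec, "n_estimators", 500),
      mtry = ncol(x)),  # all features per split, as sklearn regression RFs
    extra_trees = ranger::ranger(
      y = y, x = as.data.frame(x),
      num.trees = spec_param(spec, "n_estimators", 500),
      splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1, mtry = 2,
      min.node.size = 5, seed = seed, num.threads = 1),
    adaboost = adaboost_r2(
      x, y,
      n_estimators = spec_param(spec, "n_estimators", 50),
      max_depth = spec_param(spec, "max_depth", 3)))
  structure(list(spec = spec, fit = fit), class = "growth_model")
}

#' Predict weights from a fitted growth model
#'
#' @param object A `growth_model`.
#' @param newdata Records with `sex` and `age_days`.
#' @param ... Unused.
#' @return Numeric vector of predicted weights, kg.
#' @export
predict.growth_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  switch(object$spec$algorithm,
    gbdt = ,
    xgboost = predict(object$fit, xgboost::xgb.DMatrix(x)),
    random_forest = unname(predict(object$fit, x)),
    extra_trees = predict(object$fit, as.data.frame(x),
                          num.threads = 1)$predictions,
    adaboost = predict_adaboost_r2(object$fit, x))
}

#' Regression metrics
#'
#' Coefficient of determination, mean absolute error and mean squared
#' error. When the truth is constant (zero total sum of squares) R^2 is
#' degenerate and reported as 0.
#'
#' @param predicted,actual Numeric vectors of equal positive length.
#' @return A `weight_metrics` list: `r2`, `mae` (kg), `mse` (kg^2), `n`.
#' @export
weight_metrics <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) > 0)
  ss_res <- sum((actual - predicted)^2)
  ss_tot <- sum((actual - mean(actual))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(r2 = r2, mae = mean(abs(actual - predicted)),
                 mse = mean((actual - predicted)^2), n = length(actual)),
            class = "weight_metrics")
}

#' Evaluate a fitted model on held-out records
#'
#' @param model A `growth_model`.
#' @param test Held-out records.
#' @return A [weight_metrics()] object.
#' @export
evaluate_model <- function(model, test) {
  stopifnot(nrow(test) > 0)
  weight_metrics(predict(model, test), test$weight_kg)
}

#' Random train/test split stratified by sex
#'
#' @param rs Records to split.
#' @param ratio Train:test ratio (default 3, i.e. a 3:1 split).
#' @param seed Seed for the partition.
#' @return A list with disjoint, exhaustive `train` and `test` record sets.
#' @export
split_train_test <- function(rs, ratio = 3, seed = 1L) {
  if (nrow(rs) == 0) stop("cannot split an empty record set", call. = FALSE)
  set.seed(seed)
  test_idx <- integer(0)
  for (s in levels(factor(rs$sex))) {
    idx <- which(as.character(rs$sex) == s)
    n_test <- round(length(idx) / (ratio + 1))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = as_panda_records(rs[-test_idx, , drop = FALSE]),
       test = as_panda_records(rs[sort(test_idx), , drop = FALSE]))
}

fold_assignment <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(folds), n))
}

cv_one_spec <- function(spec, rs, fold_id, seed) {
  folds <- max(fold_id)
  r2_test <- r2_train <- numeric(folds)
  for (j in seq_len(folds)) {
    tr <- rs[fold_id != j, , drop = FALSE]
    te <- rs[fold_id == j, , drop = FALSE]
    if (nrow(te) < 2 || nrow(tr) < 2) {
      stop("cross-validation fold with fewer than 2 samples", call. = FALSE)
    }
    m <- fit_growth_model(spec, tr, seed = seed + j)
    r2_test[j] <- weight_metrics(predict(m, te), te$weight_kg)$r2
    r2_train[j] <- weight_metrics(predict(m, tr), tr$weight_kg)$r2
  }
  c(mean_r2 = mean(r2_test), sd_r2 = stats::sd(r2_test),
    mean_train_r2 = mean(r2_train))
}

#' K-fold cross-validated comparison of model specs
#'
#' @param train Training records.
#' @param specs A list of [model_spec()]s (default: the five candidates).
#' @param folds Number of folds.
#' @param seed Seed fixing the fold assignment and any engine randomness.
#' @return A `cv_result` data frame: one row per spec with mean and SD of
#'   held-out R^2 and mean training R^2.
#' @export
cross_validate_models <- function(train, specs = default_model_specs(),
                                  folds = 5, seed = 1L) {
  stopifnot(nrow(train) > 0, length(specs) > 0)
  fold_id <- fold_assignment(nrow(train), folds, seed)
  res <- t(vapply(specs, cv_one_spec, numeric(3),
                  rs = train, fold_id = fold_id, seed = seed))
  out <- data.frame(algorithm = vapply(specs, `[[`, "", "algorithm"),
                    res, folds = folds, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("cv_result", "data.frame")
  out
}
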