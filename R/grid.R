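#' Hyperparameter grid for gradient tree boosting
#'
#' The default grid spans 3 loss functions (`ls`, `lad`, `huber`), 25
#' learning rates (0.05 to 0.29 in steps of 0.01), 1000 estimator counts
#' (90 to 1089) and 4 depths (2--5): 300,000 combinations in total.
#'
#' @param loss,learning_rate,n_estimators,max_depth Option vectors, one per
#'   hyperparameter dimension.
#' @return An object of class `hyper_grid`.
#' @export
hyper_grid <- function(loss = c("ls", "lad", "huber"),
                       learning_rate = seq(0.05, 0.29, by = 0.01),
                       n_estimators = 90:1089,
                       max_depth = 2:5) {
  g <- list(loss = loss, learning_rate = learning_rate,
            n_estimators = n_estimators, max_depth = max_depth)
  if (any(lengths(g) == 0)) {
    stop("every hyperparameter dimension needs at least one option",
         call. = FALSE)
  }
  structure(g, class = "hyper_grid")
}

#' Number of hyperparameter combinations in a grid
#'
#' @param g A [hyper_grid()].
#' @return The product of the option-list lengths.
#' @export
grid_cardinality <- function(g) {
  stopifnot(inherits(g, "hyper_grid"))
  prod(lengths(g))
}

# decode 1-based linear index into one combination (mixed radix, first
# dimension varying slowest)
grid_combo <- function(g, index) {
  dims <- lengths(g)
  idx <- index - 1
  combo <- vector("list", length(dims))
  for (d in rev(seq_along(dims))) {
    combo[[d]] <- g[[d]][idx %% dims[d] + 1]
    idx <- idx %/% dims[d]
  }
  names(combo) <- names(g)
  combo
}

#' Cross-validated grid search for the boosted growth model
#'
#' Evaluates `budget` hyperparameter combinations (the full grid when
#' `budget >= grid_cardinality(g)`, otherwise a uniform random subsample
#' drawn without replacement) by k-fold cross-validation of the `gbdt`
#' model, and returns the best by mean held-out R^2. Ties are broken in
#' favour of fewer estimators, then shallower trees, then a lower learning
#' rate.
#'
#' @param train Training records.
#' @param g A [hyper_grid()].
#' @param folds CV folds.
#' @param budget Number of combinations to evaluate.
#' @param seed Seed for the subsample and the CV folds.
#' @return A list with `best_spec` (a [model_spec()]), `mean_r2`, `sd_r2`
#'   and `results` (one row per evaluated combination).
#' @export
grid_search_gbdt <- function(train, g = hyper_grid(), folds = 5,
                             budget = 2000, seed = 1L) {
  if (budget <= 0) stop("grid-search budget must be positive", call. = FALSE)
  card <- grid_cardinality(g)
  set.seed(seed)
  indices <- if (budget >= card) seq_len(card) else sample.int(card, budget)
  fold_id <- fold_assignment(nrow(train), folds, seed)
  rows <- vector("list", length(indices))
  for (i in seq_along(indices)) {
    combo <- grid_combo(g, indices[i])
    spec <- do.call(model_spec, c(list(algorithm = "gbdt"), combo))
    cv <- cv_one_spec(spec, train, fold_id, seed)
    rows[[i]] <- data.frame(loss = combo$loss,
                            learning_rate = combo$learning_rate,
                            n_estimators = combo$n_estimators,
                            max_depth = combo$max_depth,
                            mean_r2 = cv[["mean_r2"]], sd_r2 = cv[["sd_r2"]],
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  ord <- order(-results$mean_r2, results$n_estimators, results$max_depth,
               results$learning_rate, match(results$loss, g$loss))
  best <- results[ord[1], ]
  list(best_spec = model_spec("gbdt", loss = best$loss,
                              learning_rate = best$learning_rate,
                              n_estimators = best$n_estimators,
                              max_depth = best$max_depth),
       mean_r2 = best$mean_r2, sd_r2 = best$sd_r2, results = results)
}
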