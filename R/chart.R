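#' Bootstrap replicate models for one age group
#'
#' Trains `B` replicates of the given model spec, each on a subset of
#' `ceiling(subset_fraction * N)` records drawn with replacement from the
#' group's records. Records never drawn into a replicate form its
#' out-of-bag (OOB) set, on which the replicate is scored; replicates with
#' an empty OOB set are skipped in the score aggregation and counted.
#'
#' @param rs Records of one age group (both sexes).
#' @param spec The tuned [model_spec()] for this group.
#' @param B Number of bootstrap replicates.
#' @param subset_fraction Fraction of the dataset drawn per replicate.
#' @param seed Seed for the resampling.
#' @return A list with `models` (length `B`), `oob` (mean and SD of OOB
#'   R^2/MAE/MSE over scored replicates), `n_oob_skipped` and `draw_sizes`.
#' @export
bootstrap_models <- function(rs, spec, B = 1000, subset_fraction = 0.2,
                             seed = 1L) {
  stopifnot(nrow(rs) > 0, B >= 2,
            subset_fraction > 0, subset_fraction <= 1)
  n <- nrow(rs)
  m <- ceiling(subset_fraction * n)
  set.seed(seed)
  draws <- lapply(seq_len(B), function(b) sample.int(n, m, replace = TRUE))
  models <- vector("list", B)
  scores <- matrix(NA_real_, nrow = B, ncol = 3,
                   dimnames = list(NULL, c("r2", "mae", "mse")))
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- draws[[b]]
    models[[b]] <- fit_growth_model(spec, rs[idx, , drop = FALSE],
                                    seed = seed + b)
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) == 0) { skipped <- skipped + 1L; next }
    met <- evaluate_model(models[[b]], rs[oob, , drop = FALSE])
    scores[b, ] <- c(met$r2, met$mae, met$mse)
  }
  oob <- list(
    mean = colMeans(scores, na.rm = TRUE),
    sd = apply(scores, 2, stats::sd, na.rm = TRUE),
    n_scored = sum(!is.na(scores[, 1])))
  list(models = models, oob = oob, n_oob_skipped = skipped,
       draw_sizes = rep(m, B), draws = draws)
}

#' Bootstrap ensembles for every age group
#'
#' Resamples and retrains within each age group separately, so that each
#' day of age is later predicted by the replicate models of its own group.
#'
#' @param rs Calibrated records (both sexes, all ages).
#' @param specs Named list of [model_spec()]s, one per age group
#'   (`newborn`, `cub`, `subadult_adult`); groups absent from the data are
#'   skipped.
#' @inheritParams bootstrap_models
#' @return An object of class `bootstrap_ensemble`: per-group model lists
#'   and OOB metrics.
#' @export
bootstrap_ensemble <- function(rs, specs, B = 1000, subset_fraction = 0.2,
                               seed = 1L) {
  grp <- assign_age_group(rs$age_days)
  out <- list()
  for (g in levels(grp)) {
    sub <- rs[grp == g, , drop = FALSE]
    if (nrow(sub) == 0) next
    spec <- if (inherits(specs, "model_spec")) specs else specs[[g]]
    out[[g]] <- bootstrap_models(sub, spec, B = B,
                                 subset_fraction = subset_fraction,
                                 seed = seed + match(g, levels(grp)))
  }
  structure(list(groups = out, B = B), class = "bootstrap_ensemble")
}

#' Out-of-bag metrics of a bootstrap ensemble
#'
#' @param ensemble A [bootstrap_ensemble()].
#' @return Data frame of mean and SD of OOB R^2, MAE and MSE per age group.
#' @export
oob_metrics <- function(ensemble) {
  do.call(rbind, lapply(names(ensemble$groups), function(g) {
    o <- ensemble$groups[[g]]$oob
    data.frame(age_group = g,
               r2_mean = o$mean[["r2"]], r2_sd = o$sd[["r2"]],
               mae_mean = o$mean[["mae"]], mae_sd = o$sd[["mae"]],
               mse_mean = o$mean[["mse"]], mse_sd = o$sd[["mse"]],
               n_scored = o$n_scored, stringsAsFactors = FALSE)
  }))
}

#' Replicate predictions for every day of age
#'
#' Predicts weight at each day in `0:max_age_days` for one sex from all
#' `B` replicates, routing each day to the replicate models of its age
#' group.
#'
#' @param ensemble A [bootstrap_ensemble()].
#' @param sex `"female"` or `"male"`.
#' @param max_age_days Last day of age to predict.
#' @return A list with `days` and `pred`, a `B x (max_age_days + 1)` matrix.
#' @export
predict_daily <- function(ensemble, sex, max_age_days) {
  days <- 0:max_age_days
  grp <- assign_age_group(days)
  pred <- matrix(NA_real_, nrow = ensemble$B, ncol = length(days))
  for (g in names(ensemble$groups)) {
    cols <- which(as.character(grp) == g)
    if (length(cols) == 0) next
    nd <- data.frame(sex = factor(rep(sex, length(cols)),
                                  levels = c("female", "male")),
                     age_days = days[cols])
    models <- ensemble$groups[[g]]$models
    for (b in seq_along(models)) {
      pred[b, cols] <- predict(models[[b]], nd)
    }
  }
  list(sex = sex, days = days, pred = pred)
}

#' Summarise daily replicate predictions into chart rows
#'
#' Per day of age: mean and median predicted weight, percentile-bootstrap
#' 95% interval (2.5th and 97.5th percentiles across replicates) and SD.
#'
#' @param daily A [predict_daily()] result.
#' @return A data frame with one row per day: `sex`, `age_day`, `mean_kg`,
#'   `median_kg`, `ci_low_kg`, `ci_high_kg`, `sd_kg`, `n_replicates`.
#' @export
build_chart <- function(daily) {
  stopifnot(nrow(daily$pred) >= 2)
  q <- apply(daily$pred, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  data.frame(
    sex = daily$sex, age_day = daily$days,
    mean_kg = colMeans(daily$pred),
    median_kg = q[2, ], ci_low_kg = q[1, ], ci_high_kg = q[3, ],
    sd_kg = apply(daily$pred, 2, stats::sd),
    n_replicates = nrow(daily$pred),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a full weight-for-age chart
#'
#' Bootstrap-retrains the per-age-group models and emits, for each sex and
#' each day of age up to the sex's maximum, the median predicted weight
#' with its bootstrap 95% confidence band and SD.
#'
#' @param rs Calibrated records.
#' @param specs Per-age-group [model_spec()]s (or one spec for all groups).
#' @param B Bootstrap replicates (1000 reproduces the reference analysis;
#'   smaller values are adequate for exploration).
#' @param subset_fraction Fraction of each group drawn per replicate.
#' @param max_age_days Named vector of last chart day per sex.
#' @param seed Seed.
#' @return An object of class `weight_chart` (a data frame of chart rows
#'   for both sexes) with the ensemble's OOB metrics in attribute
#'   `"oob_metrics"`.
#' @export
weight_chart <- function(rs, specs, B = 1000, subset_fraction = 0.2,
                         max_age_days = c(female = 13717, male = 11984),
                         seed = 1L) {
  ens <- bootstrap_ensemble(rs, specs, B = B,
                            subset_fraction = subset_fraction, seed = seed)
  rows <- lapply(intersect(c("female", "male"), unique(as.character(rs$sex))),
                 function(s) build_chart(predict_daily(ens, s, max_age_days[[s]])))
  chart <- do.call(rbind, rows)
  attr(chart, "oob_metrics") <- oob_metrics(ens)
  class(chart) <- c("weight_chart", "data.frame")
  chart
}
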