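#' Fit a sub-adult growth curve for one sex
#'
#' Least-squares Gompertz fit `w(t) = A * exp(-b * exp(-k t))` to the
#' sub-adult records (ages 501--2007 days by default) of one sex, via
#' Levenberg-Marquardt. Starting values come from a log-log linearisation.
#'
#' @param rs A `panda_records` data frame.
#' @param sex `"female"` or `"male"`.
#' @param age_range Two integers bounding the fit range in days.
#' @return An object of class `growth_curve_fit` with elements `sex`,
#'   `family`, `params` (`A`, `b`, `k`), `age_range`, `n` and `predict`
#'   (an age-to-kg evaluator).
#' @export
fit_subadult_curve <- function(rs, sex, age_range = c(501, 2007)) {
  sex <- match.arg(sex, c("female", "male"))
  sub <- rs[as.character(rs$sex) == sex &
              rs$age_days >= age_range[1] & rs$age_days <= age_range[2], ]
  if (nrow(sub) < 10) {
    stop("need at least 10 sub-adult ", sex, " records to fit a curve (have ",
         nrow(sub), ")", call. = FALSE)
  }
  a0 <- 1.05 * max(sub$weight_kg)
  ok <- sub$weight_kg < a0
  lin <- stats::lm(log(log(a0 / sub$weight_kg[ok])) ~ sub$age_days[ok])
  start <- list(A = a0,
                b = exp(unname(stats::coef(lin)[1])),
                k = max(1e-5, -unname(stats::coef(lin)[2])))
  fit <- tryCatch(
    minpack.lm::nlsLM(weight_kg ~ A * exp(-b * exp(-k * age_days)),
                      data = sub, start = start,
                      lower = c(A = 1, b = 1e-3, k = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("sub-adult curve fit failed to converge for ",
                             sex, ": ", conditionMessage(e), call. = FALSE))
  p <- stats::coef(fit)
  structure(list(
    sex = sex, family = "gompertz", params = p, age_range = age_range,
    n = nrow(sub),
    predict = function(age_days) {
      unname(p["A"] * exp(-p["b"] * exp(-p["k"] * age_days)))
    }), class = "growth_curve_fit")
}

#' @export
print.growth_curve_fit <- function(x, ...) {
  cat(sprintf("Gompertz growth curve (%s, ages %d-%d days, n = %d)\n",
              x$sex, x$age_range[1], x$age_range[2], x$n))
  cat(sprintf("  A = %.2f kg, b = %.3f, k = %.5f /day\n",
              x$params["A"], x$params["b"], x$params["k"]))
  invisible(x)
}

#' Adjust sub-adult weights to the month's mean record day
#'
#' Within each (animal, calendar month) group of records in the curve's sex
#' and age range, weights are moved along the fitted curve to the group's
#' mean record day: a record at age `d` becomes
#' `weight - (f(d) - f(d_bar))` where `d_bar` is the mean age of the
#' group's records. This removes the within-month growth trend so that the
#' subsequent per-age-month clustering compares like with like. Records
#' outside the curve's sex or age range are left unadjusted and counted in
#' attribute `"n_unadjusted"`.
#'
#' @param rs A `panda_records` data frame.
#' @param fit A [fit_subadult_curve()] result.
#' @return `rs` with adjusted weights and the `adjusted` flag set on the
#'   records the adjustment touched.
#' @export
adjust_within_month <- function(rs, fit) {
  stopifnot(inherits(fit, "growth_curve_fit"))
  in_scope <- as.character(rs$sex) == fit$sex &
    rs$age_days >= fit$age_range[1] & rs$age_days <= fit$age_range[2]
  idx <- which(in_scope)
  if (length(idx)) {
    key <- paste(rs$animal_id[idx], format(rs$measure_date[idx], "%Y-%m"))
    for (grp in split(idx, key)) {
      dbar <- mean(rs$age_days[grp])
      delta <- fit$predict(rs$age_days[grp]) - fit$predict(dbar)
      rs$weight_kg[grp] <- rs$weight_kg[grp] - delta
      rs$adjusted[grp] <- TRUE
    }
  }
  attr(rs, "n_unadjusted") <- sum(as.character(rs$sex) == fit$sex) - length(idx)
  rs
}

#' Two-cluster split of one age-month's weights
#'
#' 2-means clustering of the weights recorded in a single month of age for
#' one sex, separating the empty-stomach (low) and fed (high) states.
#' Months with fewer than `min_samples` weights are skipped (`NULL`).
#'
#' @param weights Numeric weights, kg.
#' @param min_samples Minimum count required to cluster.
#' @param nstart Random restarts for k-means.
#' @return `NULL` (skip), or a list with `center_low`, `center_high`,
#'   `distance` and `assign` (factor `"low"`/`"high"` per weight). When all
#'   weights are identical both centers equal that value and every member
#'   is assigned `"low"`.
#' @export
split_feeding_clusters <- function(weights, min_samples = 4, nstart = 10) {
  stopifnot(all(is.finite(weights)))
  if (length(weights) < min_samples) return(NULL)
  if (length(unique(weights)) < 2) {
    return(list(center_low = weights[1], center_high = weights[1],
                distance = 0,
                assign = factor(rep("low", length(weights)),
                                levels = c("low", "high"))))
  }
  km <- stats::kmeans(weights, centers = 2, nstart = nstart,
                      iter.max = 100, algorithm = "Hartigan-Wong")
  lo <- which.min(km$centers)
  list(center_low = min(km$centers), center_high = max(km$centers),
       distance = max(km$centers) - min(km$centers),
       assign = factor(ifelse(km$cluster == lo, "low", "high"),
                       levels = c("low", "high")))
}

#' Remove fed-state weighings by per-age-month clustering
#'
#' For each sex, the sub-adult/adult records (ages >= `cluster_min_age`)
#' are grouped by month of age and each month is split by
#' [split_feeding_clusters()]; every record assigned to the higher cluster
#' center is removed. Younger records (newborns and cubs) are never
#' touched. Degenerate months (cluster distance 0) remove nothing.
#'
#' @param rs A `panda_records` data frame (sub-adult weights should already
#'   be month-adjusted, see [adjust_within_month()]).
#' @param cluster_min_age Youngest age (days) entering the clustering.
#' @param min_samples Minimum weights per age-month to cluster.
#' @param month_length_days Days per month of age.
#' @param seed Seed for the k-means restarts.
#' @return A list with `records` (the kept records) and `report` (a
#'   `calibration_report`).
#' @export
remove_fed_samples <- function(rs, cluster_min_age = 501, min_samples = 4,
                               month_length_days = 30.4375, seed = 1L) {
  set.seed(seed)
  in_scope <- rs$age_days >= cluster_min_age
  drop <- logical(nrow(rs))
  per_sex <- list()
  for (sex in c("female", "male")) {
    idx <- which(in_scope & as.character(rs$sex) == sex)
    month <- age_in_months(rs$age_days[idx], month_length_days)
    distances <- numeric(0)
    skipped <- 0L; clustered <- 0L
    for (grp in split(idx, month)) {
      cl <- split_feeding_clusters(rs$weight_kg[grp], min_samples = min_samples)
      if (is.null(cl)) { skipped <- skipped + 1L; next }
      clustered <- clustered + length(grp)
      distances <- c(distances, cl$distance)
      if (cl$distance > 0) drop[grp[cl$assign == "high"]] <- TRUE
    }
    per_sex[[sex]] <- list(
      distances = distances,
      mean_distance = if (length(distances)) mean(distances) else NA_real_,
      sd_distance = if (length(distances) > 1) stats::sd(distances) else NA_real_,
      n_months = length(distances), n_months_skipped = skipped,
      n_clustered = clustered,
      n_removed = sum(drop[in_scope & as.character(rs$sex) == sex]),
      n_kept = clustered - sum(drop[in_scope & as.character(rs$sex) == sex]))
  }
  report <- structure(list(
    per_sex = per_sex,
    n_input = nrow(rs), n_removed = sum(drop), n_kept = nrow(rs) - sum(drop),
    cluster_min_age = cluster_min_age, min_samples = min_samples),
    class = "calibration_report")
  list(records = as_panda_records(rs[!drop, , drop = FALSE]), report = report)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Feeding-status calibration report\n")
  for (sex in names(x$per_sex)) {
    s <- x$per_sex[[sex]]
    cat(sprintf(
      "  %s: cluster distance %.1f +/- %.1f kg over %d age-months; removed %d / kept %d (%d months skipped)\n",
      sex, s$mean_distance, s$sd_distance, s$n_months, s$n_removed, s$n_kept,
      s$n_months_skipped))
  }
  cat(sprintf("  total: %d records in, %d removed, %d kept\n",
              x$n_input, x$n_removed, x$n_kept))
  invisible(x)
}

#' Full feeding-status calibration pipeline
#'
#' Fits a sub-adult curve per sex, adjusts sub-adult weights to each
#' month's mean record day, then removes the fed-state cluster from every
#' sub-adult/adult month of age. Newborn and cub records pass through
#' untouched.
#'
#' @inheritParams remove_fed_samples
#' @param subadult_range Age range (days) of the per-sex curve fit.
#' @return A list with `records`, `report` and `fits` (per-sex
#'   `growth_curve_fit`s).
#' @export
calibrate_records <- function(rs, subadult_range = c(501, 2007),
                              cluster_min_age = 501, min_samples = 4,
                              month_length_days = 30.4375, seed = 1L) {
  fits <- list()
  for (sex in c("female", "male")) {
    if (sum(as.character(rs$sex) == sex &
              rs$age_days >= subadult_range[1] &
              rs$age_days <= subadult_range[2]) >= 10) {
      fits[[sex]] <- fit_subadult_curve(rs, sex, subadult_range)
      rs <- adjust_within_month(rs, fits[[sex]])
    }
  }
  out <- remove_fed_samples(rs, cluster_min_age = cluster_min_age,
                            min_samples = min_samples,
                            month_length_days = month_length_days, seed = seed)
  out$report$fits <- lapply(fits, function(f) f$params)
  out$fits <- fits
  out
}
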