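# exhaustive 1-D 2-means oracle: the optimal 2-partition of sorted points
# is a split point; enumerate all splits and minimize within-cluster SSE
best_split_2means <- function(x) {
  x <- sort(x)
  best <- NULL
  for (i in seq_len(length(x) - 1)) {
    lo <- x[1:i]; hi <- x[(i + 1):length(x)]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(sse = sse, center_low = mean(lo), center_high = mean(hi),
                   n_low = i)
    }
  }
  best
}

test_that("two-cluster split matches the exhaustive 2-means oracle", {
  x <- c(100, 101, 102, 118, 119, 120)
  cl <- split_feeding_clusters(x)
  oracle <- best_split_2means(x)
  expect_equal(cl$center_low, oracle$center_low)   # 101
  expect_equal(cl$center_high, oracle$center_high) # 119
  expect_equal(cl$distance, 18)
  expect_equal(as.character(cl$assign),
               c("low", "low", "low", "high", "high", "high"))

  # random instances agree with the oracle
  set.seed(5)
  for (i in 1:10) {
    x <- c(rnorm(8, 50, 2), rnorm(8, 50 + runif(1, 8, 25), 2))
    cl <- split_feeding_clusters(x)
    oracle <- best_split_2means(x)
    expect_equal(cl$center_low, oracle$center_low, tolerance = 1e-8)
    expect_equal(cl$center_high, oracle$center_high, tolerance = 1e-8)
  }
})

test_that("degenerate and undersized months are handled", {
  cl <- split_feeding_clusters(c(100, 100, 100, 100))
  expect_equal(cl$center_low, 100)
  expect_equal(cl$center_high, 100)
  expect_equal(cl$distance, 0)
  expect_null(split_feeding_clusters(c(1, 2, 3), min_samples = 4))
})

test_that("noiseless Gompertz data recovers generating parameters within 1%", {
  cfg <- clean_cfg()
  rs <- simulate_cohort(cfg)$records
  for (s in c("female", "male")) {
    cv <- if (s == "female") cfg$curve_female else cfg$curve_male
    fit <- fit_subadult_curve(rs, s)
    expect_equal(unname(fit$params["A"]), cv$asymptote, tolerance = 0.01)
    expect_equal(unname(fit$params["b"]),
                 log(cv$asymptote / cv$birth_weight), tolerance = 0.01)
    expect_equal(unname(fit$params["k"]), cv$rate, tolerance = 0.01)
    # evaluator nondecreasing over the fit range, residual mean ~ 0
    w <- fit$predict(501:2007)
    expect_true(all(diff(w) >= 0))
    sub <- rs[as.character(rs$sex) == s & rs$age_days >= 501 &
                rs$age_days <= 2007, ]
    expect_lt(abs(mean(sub$weight_kg - fit$predict(sub$age_days))), 0.05)
  }
  expect_error(fit_subadult_curve(rs[1:5, ], "female"), "at least 10")
})

test_that("within-month adjustment moves weights along the curve", {
  # flat curve: nothing changes
  rs <- simulate_cohort(small_cfg())$records
  flat <- structure(list(sex = "female", family = "gompertz",
                         params = c(A = 50, b = 1, k = 0),
                         age_range = c(501, 2007),
                         predict = function(age) rep(50, length(age))),
                    class = "growth_curve_fit")
  adj <- adjust_within_month(rs, flat)
  expect_equal(adj$weight_kg, rs$weight_kg)

  # a single-record month sits on its own mean day: unchanged
  one <- rs[1, ]; one$age_days <- 600L
  one$sex <- factor("female", c("female", "male"))
  one$birth_date <- as.Date("2021-06-05") - 600L
  one$measure_date <- as.Date("2021-06-05")
  fit <- fit_subadult_curve(simulate_cohort(clean_cfg())$records, "female")
  adj1 <- adjust_within_month(one, fit)
  expect_equal(adj1$weight_kg, one$weight_kg)
  expect_true(adj1$adjusted)

  # forced arithmetic: curve increment of delta is subtracted (both
  # records fall in the same calendar month, 20 days apart)
  two <- rbind(one, one)
  two$measure_date <- two$birth_date + c(600L, 620L)
  two$age_days <- c(600L, 620L)
  two$weight_kg <- c(50, 50)
  adj2 <- adjust_within_month(two, fit)
  f <- fit$predict
  expect_equal(adj2$weight_kg,
               c(50 - (f(600) - f(610)), 50 - (f(620) - f(610))))
})

test_that("fed-cluster removal conserves records and targets fed weighings", {
  cfg <- sim_config(n_female = 40, n_male = 40, offset_mean_female = 18,
                    offset_mean_male = 18, fed_fraction = 0.5,
                    min_followup_days = 2000, seed = 11)
  rs <- simulate_cohort(cfg)$records
  cal <- calibrate_records(rs, seed = 11)
  rep <- cal$report
  for (s in c("female", "male")) {
    ps <- rep$per_sex[[s]]
    expect_equal(ps$n_removed + ps$n_kept, ps$n_clustered)
  }
  # cubs and newborns are never touched
  young_in <- rs[rs$age_days <= 500, ]
  young_out <- cal$records[cal$records$age_days <= 500, ]
  expect_equal(young_out$weight_kg, young_in$weight_kg)
  # removed records are overwhelmingly the truly fed ones
  kept_key <- paste(cal$records$animal_id, cal$records$measure_date)
  removed <- rs[rs$age_days >= 501 &
                  !(paste(rs$animal_id, rs$measure_date) %in% kept_key), ]
  expect_gt(mean(removed$fed_truth), 0.9)
  # and the recovered cluster distance is near the configured offset
  expect_equal(rep$per_sex$female$mean_distance, 18, tolerance = 0.15 * 18)
})

test_that("unimodal (unfed) months lose at most half their records", {
  cfg <- sim_config(n_female = 25, n_male = 25, fed_fraction = 0,
                    seasonal_amplitude = 0, min_followup_days = 2000,
                    seed = 17)
  rs <- simulate_cohort(cfg)$records
  cal <- calibrate_records(rs, seed = 17)
  n_elig <- sum(rs$age_days >= 501)
  expect_lte(cal$report$n_removed, n_elig / 2)
  # distances are on the noise scale, nowhere near a feeding offset
  expect_lt(cal$report$per_sex$female$mean_distance, 10)
})
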