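# exact two-sided Mann-Whitney p by exhaustive rank enumeration (no ties)
exact_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  combos <- combn(n, length(a))
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - length(idx) * (length(idx) + 1) / 2
  }
  u_obs <- u_of(seq_along(a))
  mu <- length(a) * length(b) / 2
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

test_that("Mann-Whitney matches symmetry and the exhaustive enumeration oracle", {
  cmp <- mann_whitney(1:5, 1:5)
  expect_equal(cmp$U, 12.5)           # n^2 / 2
  expect_equal(cmp$p, 1, tolerance = 0.01)

  a <- c(1, 2, 3); b <- c(10, 11, 12)
  cmp <- mann_whitney(a, b)
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p, exact_mw_p(a, b))  # minimum attainable for (3,3): 0.1
  expect_equal(cmp$direction, "<")

  set.seed(2)
  a <- rnorm(6); b <- rnorm(7, 0.5)
  expect_equal(mann_whitney(a, b)$p, exact_mw_p(a, b))

  deg <- mann_whitney(c(5, 5, 5), c(5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("a shifted winter group is detected among adult weights", {
  set.seed(33)
  winter <- rnorm(200, 98, 8)
  summer <- rnorm(200, 103, 8)
  expect_lt(mann_whitney(winter, summer)$p, 0.05)
})

test_that("period comparisons enumerate all unordered label pairs", {
  rs <- adult_period_records(n_per_season = 40, seed = 3)
  cmp <- compare_periods(rs, period_scheme("natural_season"))
  expect_equal(nrow(cmp), choose(4, 2))
  cmp <- compare_periods(rs, period_scheme("reproductive"))
  expect_equal(nrow(cmp), choose(5, 2))
  # optional Holm correction never lowers a p value
  cmp_h <- compare_periods(rs, period_scheme("natural_season"),
                           p_adjust = "holm")
  expect_true(all(cmp_h$p_adj >= cmp_h$p))
})

test_that("record velocities are midpoint finite differences, order-invariant", {
  rs <- data.frame(
    animal_id = c("a", "a", "b"),
    sex = factor(c("female", "female", "male"), c("female", "male")),
    birth_date = as.Date("2020-01-01"),
    measure_date = as.Date("2020-01-01") + c(100, 110, 50),
    weight_kg = c(10, 12, 5), age_days = c(100L, 110L, 50L),
    adjusted = FALSE)
  v <- velocity_from_records(rs)
  expect_equal(nrow(v), 1)  # single-record animals contribute nothing
  expect_equal(v$age_mid_days, 105)
  expect_equal(v$velocity_kg_per_day, 0.2)
  # shuffled input gives the same points
  v2 <- velocity_from_records(rs[c(3, 2, 1), ])
  expect_equal(v2, v, ignore_attr = TRUE)
  # decreases stay negative; zero-gap pairs are skipped
  rs$weight_kg <- c(10, 8, 5)
  expect_equal(velocity_from_records(rs)$velocity_kg_per_day, -0.2)
  rs2 <- rs; rs2$measure_date[2] <- rs2$measure_date[1]
  rs2$age_days[2] <- rs2$age_days[1]
  expect_equal(nrow(velocity_from_records(rs2)), 0)
  expect_equal(attr(velocity_from_records(rs2), "n_skipped"), 1L)
})

test_that("chart velocities telescope exactly and match a finite-difference oracle", {
  set.seed(12)
  chart <- data.frame(sex = "female", age_day = 0:50,
                      mean_kg = cumsum(runif(51, 0, 0.3)))
  v <- velocity_from_chart(chart)
  expect_equal(v$velocity_kg_per_day, diff(chart$mean_kg))
  # telescoping over any interval (a, b]
  for (ab in list(c(0, 50), c(3, 17), c(20, 21))) {
    s <- sum(v$velocity_kg_per_day[v$age_mid_days > ab[1] &
                                     v$age_mid_days <= ab[2]])
    expect_equal(s, chart$mean_kg[ab[2] + 1] - chart$mean_kg[ab[1] + 1])
  }
  # constant chart: all-zero velocities
  chart$mean_kg <- 100
  expect_true(all(velocity_from_chart(chart)$velocity_kg_per_day == 0))
  # gaps are an error
  expect_error(velocity_from_chart(chart[-5, ]), "gaps")
})

test_that("yearly bins put day 1096 in year 4 and cap at the growing range", {
  bins <- yearly_age_bins()
  y4 <- bins[bins$label == "year4", ]
  expect_equal(c(y4$start_day, y4$end_day), c(1096, 1460))
  expect_equal(bins$end_day[nrow(bins)], 2008)
})

test_that("sexual dimorphism shows up in default synthetic adults", {
  rs <- simulate_cohort(sim_config(n_female = 20, n_male = 20,
                                   fed_fraction = 0, seed = 19))$records
  adults <- filter_adults(rs)
  cmp <- mann_whitney(adults$weight_kg[adults$sex == "male"],
                      adults$weight_kg[adults$sex == "female"],
                      "male", "female")
  expect_lt(cmp$p, 0.05)
  expect_equal(cmp$direction, ">")
})
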