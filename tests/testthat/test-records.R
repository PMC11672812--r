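test_that("age_in_days does whole-day calendar arithmetic", {
  expect_identical(age_in_days(as.Date("2020-01-01"), as.Date("2020-01-01")), 0L)
  expect_identical(age_in_days(as.Date("2020-01-01"), as.Date("2020-01-31")), 30L)
  # leap year: oracle is base Date arithmetic through Feb 29
  expect_identical(age_in_days(as.Date("2019-12-31"), as.Date("2020-12-31")), 366L)
  expect_error(age_in_days(as.Date("2020-01-02"), as.Date("2020-01-01")),
               "precedes")
})

test_that("age groups partition the nonnegative integers with the stated bounds", {
  expect_equal(as.character(assign_age_group(c(0, 30, 31, 500, 501))),
               c("newborn", "newborn", "cub", "cub", "subadult_adult"))
  grp <- assign_age_group(0:20000)
  expect_false(anyNA(grp))           # every age gets exactly one label
  expect_error(assign_age_group(-1), "non-negative")
})

test_that("period schemes label dates per the calendar definitions", {
  ns <- period_scheme("natural_season")
  rep_ <- period_scheme("reproductive")
  expect_equal(as.character(label_period(as.Date("2021-01-15"), ns)), "winter")
  expect_equal(as.character(label_period(as.Date("2021-03-22"), rep_)),
               "peak_breeding")
  expect_equal(as.character(label_period(as.Date("2021-06-01"), rep_)),
               "nonbreeding")
  # Feb 29 takes Feb 28's label
  expect_equal(as.character(label_period(as.Date("2020-02-29"), ns)), "winter")
  expect_equal(as.character(label_period(as.Date("2020-02-29"), rep_)),
               "early_breeding")
})

test_that("both schemes cover a 365-day year exactly once with the stated lengths", {
  days <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  for (name in c("natural_season", "reproductive")) {
    lab <- label_period(days, period_scheme(name))
    expect_false(anyNA(lab))
  }
  counts <- table(label_period(days, period_scheme("reproductive")))
  expect_equal(as.integer(counts[c("pre_breeding", "early_breeding",
                                   "peak_breeding", "late_breeding",
                                   "nonbreeding")]),
               c(123L, 49L, 25L, 46L, 122L))
  expect_equal(sum(counts), 365L)
})

test_that("adult filter keeps exactly 66-246 completed months", {
  mk <- function(months) {
    days <- as.integer(ceiling(months * 30.4375))
    data.frame(animal_id = "a", sex = factor("female", c("female", "male")),
               birth_date = as.Date("2000-01-01"),
               measure_date = as.Date("2000-01-01") + days,
               weight_kg = 100, age_days = days, adjusted = FALSE)
  }
  rs <- do.call(rbind, lapply(c(65, 66, 246, 247), mk))
  kept <- filter_adults(rs)
  expect_equal(age_in_months(kept$age_days), c(66, 246))
})

test_that("CSV loading validates rows and round-trips valid records", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("animal_id,sex,birth_date,measure_date,weight_kg",
               "p1,female,2020-01-01,2020-02-01,5.5",
               "p2,male,2020-01-01,2020-03-01,7.25",
               "p3,female,2020-01-01,2020-04-01,9.125"), csv)
  rs <- load_records(csv)
  expect_equal(nrow(rs), 3)
  expect_equal(rs$age_days, c(31L, 60L, 91L))

  # bad rows rejected with a per-row report
  writeLines(c("animal_id,sex,birth_date,measure_date,weight_kg",
               "p1,female,2020-01-01,2020-02-01,5.5",
               "p2,male,2020-01-01,2020-03-01,-1",
               "p3,female,2020-01-01,not-a-date,9"), csv)
  rs <- load_records(csv)
  expect_equal(nrow(rs), 1)
  expect_length(attr(rs, "row_errors"), 2)

  # schema and duplicate errors
  writeLines(c("animal_id,sex,birth_date,weight_kg",
               "p1,female,2020-01-01,5.5"), csv)
  expect_error(load_records(csv), "measure_date")
  writeLines(c("animal_id,sex,birth_date,measure_date,weight_kg",
               "p1,female,2020-01-01,2020-02-01,5.5",
               "p1,female,2020-01-01,2020-02-01,6.5"), csv)
  expect_error(load_records(csv), "p1")

  # write -> load identity on a simulated set
  rs <- simulate_cohort(small_cfg())$records
  rs$fed_truth <- NULL
  out <- tempfile(fileext = ".csv")
  write_records(rs, out)
  back <- load_records(out)
  expect_equal(back$animal_id, rs$animal_id)
  expect_equal(back$age_days, rs$age_days)
  expect_equal(back$weight_kg, rs$weight_kg, tolerance = 1e-8)
})
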