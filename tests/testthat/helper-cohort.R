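# Small cohort configurations reused across tests. Sizes are chosen so the
# whole suite runs in minutes on one core while keeping enough records for
# the stochastic checks to be stable.

small_cfg <- function(...) {
  sim_config(n_female = 15, n_male = 15, min_followup_days = 600, seed = 7, ...)
}

# noiseless, unfed, season-free cohort: weights equal the generative curve
clean_cfg <- function(...) {
  sim_config(n_female = 12, n_male = 12, noise_cv = 0, seasonal_amplitude = 0,
             fed_fraction = 0, min_followup_days = 2500, seed = 3, ...)
}

# identical growth curves for both sexes (null for sex comparisons)
same_sex_curves_cfg <- function(seed, n_female = 15, n_male = 15, ...) {
  fem <- list(asymptote = 103, birth_weight = 0.15, rate = 0.0050)
  sim_config(n_female = n_female, n_male = n_male,
             curve_female = fem, curve_male = fem,
             fed_fraction = 0, seasonal_amplitude = 0, noise_cv = 0.02,
             min_followup_days = 2008, max_age_female = 2008,
             max_age_male = 2008, gap_adult = 30, seed = seed, ...)
}

# adult records spread over calendar periods, with an optional square
# winter weight dip; one row per independent weighing
adult_period_records <- function(n_per_season = 200, dip_kg = 0,
                                 median_kg = 103, sd_kg = 8, seed = 1) {
  set.seed(seed)
  seasons <- list(spring = c("2021-03-01", "2021-05-31"),
                  summer = c("2021-06-01", "2021-08-31"),
                  autumn = c("2021-09-01", "2021-11-30"),
                  winter = c("2021-12-01", "2022-02-28"))
  rows <- lapply(names(seasons), function(s) {
    rng <- as.Date(seasons[[s]])
    dates <- rng[1] + sample.int(as.integer(rng[2] - rng[1]) + 1,
                                 n_per_season, replace = TRUE) - 1
    w <- rnorm(n_per_season, median_kg, sd_kg) - dip_kg * (s == "winter")
    data.frame(animal_id = sprintf("%s%03d", s, seq_len(n_per_season)),
               sex = factor("female", levels = c("female", "male")),
               birth_date = dates - 3000, measure_date = dates,
               weight_kg = w, age_days = 3000L, adjusted = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_records_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
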