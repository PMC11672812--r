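#' Configuration for the synthetic panda cohort simulator
#'
#' Defaults emulate the composition of a large captive breeding colony:
#' 108 females and 98 males born 1984--2020, sex-specific Gompertz growth
#' from ~0.15 kg at birth to adult medians of 103 kg (female) and 115 kg
#' (male), a winter-trough seasonal modulation of the mature weight, a
#' bimodal feeding-status offset (16.5 kg female / 19.9 kg male) applied to
#' a fraction of weighings past one year of age, and multiplicative
#' measurement noise. Measurement cadence is age-dependent (newborns are
#' weighed much more often than adults).
#'
#' @param n_female,n_male Animals per sex.
#' @param birth_window Two dates bounding uniformly sampled birth dates.
#' @param curve_female,curve_male Named lists with `asymptote` (kg),
#'   `birth_weight` (kg) and `rate` (1/day) of the Gompertz curve.
#' @param gap_newborn,gap_cub,gap_adult Mean days between weighings in the
#'   0--30, 31--500 and 501+ day age ranges.
#' @param gap_jitter Relative SD of each inter-measurement gap.
#' @param seasonal_amplitude Peak-to-trough fractional dip of the mature
#'   weight (0 disables seasonality).
#' @param seasonal_trough_doy Day-of-year of minimum weight (mid-January).
#' @param offset_mean_female,offset_mean_male Mean fed-state weight offset, kg.
#' @param offset_sd SD of the per-weighing fed offset draw, kg.
#' @param fed_fraction Probability that an eligible weighing is in the fed
#'   state; eligibility requires `age_days >= feeding_min_age_days`.
#' @param feeding_min_age_days Youngest age at which the fed offset applies.
#' @param noise_cv Measurement noise SD as a fraction of true weight.
#' @param noise_floor_kg Lower bound on the noise SD.
#' @param max_age_female,max_age_male Maximum simulated age, days.
#' @param min_followup_days Minimum per-animal observation span, days.
#' @param velocity_boost Optional `list(sex, start_day, end_day, kg_per_day)`
#'   adding a linear-in-age weight gain for one sex inside an age window
#'   (used to construct cohorts with a known growth-velocity difference).
#' @param seed Integer seed; the whole simulation is reproducible given the
#'   config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_female = 108, n_male = 98,
                       birth_window = as.Date(c("1984-01-01", "2020-12-31")),
                       curve_female = list(asymptote = 103, birth_weight = 0.15,
                                           rate = 0.0050),
                       curve_male = list(asymptote = 115, birth_weight = 0.16,
                                         rate = 0.0045),
                       gap_newborn = 3, gap_cub = 12, gap_adult = 75,
                       gap_jitter = 0.3,
                       seasonal_amplitude = 0.03, seasonal_trough_doy = 15,
                       offset_mean_female = 16.5, offset_mean_male = 19.9,
                       offset_sd = 2, fed_fraction = 0.5,
                       feeding_min_age_days = 365,
                       noise_cv = 0.025, noise_floor_kg = 0.01,
                       max_age_female = 13717, max_age_male = 11984,
                       min_followup_days = 1000,
                       velocity_boost = NULL,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$fed_fraction >= 0, cfg$fed_fraction <= 1,
            cfg$noise_cv >= 0, cfg$seasonal_amplitude >= 0)
  for (cv in list(curve_female, curve_male)) {
    stopifnot(cv$asymptote > cv$birth_weight, cv$birth_weight > 0, cv$rate > 0)
  }
  if (gap_newborn <= 0 || gap_cub <= 0 || gap_adult <= 0) {
    stop("measurement gaps must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

gompertz <- function(age_days, asymptote, birth_weight, rate) {
  b <- log(asymptote / birth_weight)
  asymptote * exp(-b * exp(-rate * age_days))
}

boost_component <- function(sex, age_days, boost) {
  if (is.null(boost)) return(0)
  amount <- boost$kg_per_day *
    pmax(0, pmin(age_days, boost$end_day) - boost$start_day)
  amount * (as.character(sex) == boost$sex)
}

#' Noise-free weight under the generative model
#'
#' Sex-specific Gompertz growth, an optional windowed growth boost, and a
#' cosine seasonal modulation whose amplitude scales with maturity so that
#' cubs are essentially unaffected. With `seasonal_amplitude = 0` the value
#' is independent of the date and nondecreasing in age.
#'
#' @param sex `"female"` or `"male"` (vectorised).
#' @param age_days Non-negative ages, days.
#' @param date Measurement dates (only used when seasonality is on).
#' @param cfg A [sim_config()].
#' @return Weight in kg.
#' @export
true_weight <- function(sex, age_days, date = NULL, cfg = sim_config()) {
  stopifnot(all(age_days >= 0))
  sex <- as.character(sex)
  n <- max(length(sex), length(age_days))
  sex <- rep_len(sex, n); age_days <- rep_len(age_days, n)
  w <- numeric(n)
  for (s in c("female", "male")) {
    idx <- sex == s
    if (!any(idx)) next
    cv <- if (s == "female") cfg$curve_female else cfg$curve_male
    w[idx] <- gompertz(age_days[idx], cv$asymptote, cv$birth_weight, cv$rate)
  }
  w <- w + boost_component(sex, age_days, cfg$velocity_boost)
  if (cfg$seasonal_amplitude > 0 && !is.null(date)) {
    doy <- as.integer(format(as.Date(date), "%j"))
    asym <- ifelse(sex == "female", cfg$curve_female$asymptote,
                   cfg$curve_male$asymptote)
    phase <- 2 * pi * (doy - cfg$seasonal_trough_doy) / 365.25
    dip <- cfg$seasonal_amplitude * (w / asym) * (1 + cos(phase)) / 2
    w <- w * (1 - dip)
  }
  w
}

sample_gap <- function(age, cfg) {
  mean_gap <- if (age <= 30) cfg$gap_newborn
              else if (age <= 500) cfg$gap_cub else cfg$gap_adult
  max(1, round(stats::rnorm(1, mean_gap, cfg$gap_jitter * mean_gap)))
}

#' Simulate a longitudinal panda weighing cohort
#'
#' Each animal gets a birth date, an observation span, and an irregular
#' age-dependent weighing schedule. Each weighing evaluates [true_weight()],
#' adds a fed-state offset with probability `fed_fraction` (at eligible
#' ages), and adds Gaussian measurement noise. The ground-truth feeding
#' label of every record is retained for validation.
#'
#' @param cfg A [sim_config()].
#' @return A list with `records` (a `panda_records` data frame including a
#'   `fed_truth` column) and `truth` (the config plus a noiseless per-sex
#'   curve evaluator, `curve(sex, age_days)`).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  animals <- data.frame(
    animal_id = c(sprintf("F%03d", seq_len(cfg$n_female)),
                  sprintf("M%03d", seq_len(cfg$n_male))),
    sex = rep(c("female", "male"), c(cfg$n_female, cfg$n_male)),
    stringsAsFactors = FALSE)
  span <- as.integer(cfg$birth_window[2] - cfg$birth_window[1])
  rows <- vector("list", nrow(animals))
  for (i in seq_len(nrow(animals))) {
    sex <- animals$sex[i]
    birth <- cfg$birth_window[1] + sample.int(span + 1L, 1L) - 1L
    max_age <- if (sex == "female") cfg$max_age_female else cfg$max_age_male
    last_age <- round(stats::runif(1, cfg$min_followup_days, max_age))
    ages <- 0L
    repeat {
      nxt <- ages[length(ages)] + sample_gap(ages[length(ages)], cfg)
      if (nxt > last_age) break
      ages <- c(ages, nxt)
    }
    dates <- birth + ages
    tw <- true_weight(sex, ages, dates, cfg)
    eligible <- ages >= cfg$feeding_min_age_days
    fed <- eligible & stats::runif(length(ages)) < cfg$fed_fraction
    off_mean <- if (sex == "female") cfg$offset_mean_female else cfg$offset_mean_male
    offset <- ifelse(fed, stats::rnorm(length(ages), off_mean, cfg$offset_sd), 0)
    noise_sd <- if (cfg$noise_cv > 0) {
      pmax(cfg$noise_floor_kg, cfg$noise_cv * tw)
    } else 0
    w <- pmax(0.01, tw + offset + stats::rnorm(length(ages), 0, noise_sd))
    rows[[i]] <- data.frame(
      animal_id = animals$animal_id[i], sex = sex,
      birth_date = birth, measure_date = dates,
      weight_kg = w, age_days = as.integer(ages),
      adjusted = FALSE, fed_truth = fed,
      stringsAsFactors = FALSE)
  }
  rs <- do.call(rbind, rows)
  rs$sex <- factor(rs$sex, levels = c("female", "male"))
  rownames(rs) <- NULL
  rs <- as_panda_records(rs, provenance = sprintf("simulated (seed %d)", cfg$seed))
  truth <- list(
    config = cfg,
    curve = function(sex, age_days) {
      w <- true_weight(sex, age_days, date = NULL, cfg = cfg)
      w
    },
    offset_means = c(female = cfg$offset_mean_female,
                     male = cfg$offset_mean_male))
  list(records = rs, truth = truth)
}
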