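#' Age in whole days
#'
#' @param birth,measure `Date` vectors (recycled to a common length).
#' @return Integer vector of whole days from `birth` to `measure`.
#' @examples
#' age_in_days(as.Date("2020-01-01"), as.Date("2020-01-31"))
#' @export
age_in_days <- function(birth, measure) {
  birth <- as.Date(birth)
  measure <- as.Date(measure)
  days <- as.integer(measure - birth)
  if (any(days < 0, na.rm = TRUE)) {
    stop("measure_date precedes birth_date for ", sum(days < 0, na.rm = TRUE),
         " record(s)", call. = FALSE)
  }
  days
}

#' Developmental age group of a panda
#'
#' Three physiological stages partition age in days: newborn (0--30),
#' cub to sub-adult (31--500), and sub-adult/adult (501 and up).
#'
#' @param age_days Non-negative integer vector of ages in days.
#' @return Factor with levels `newborn`, `cub`, `subadult_adult`.
#' @export
assign_age_group <- function(age_days) {
  if (any(is.na(age_days)) || any(age_days < 0)) {
    stop("age_days must be non-negative and non-missing", call. = FALSE)
  }
  cut(age_days, breaks = c(-0.5, 30.5, 500.5, Inf),
      labels = c("newborn", "cub", "subadult_adult"))
}

#' Age in completed months
#'
#' Converts age in days to months using the mean Gregorian month length
#' (30.4375 days), truncated to completed months.
#'
#' @param age_days Non-negative numeric vector.
#' @param month_length_days Days per month; default mean Gregorian month.
#' @export
age_in_months <- function(age_days, month_length_days = 30.4375) {
  floor(age_days / month_length_days)
}

# Period schemes are tables of (label, start, end) month-day codes, where a
# month-day is encoded as month * 100 + day; intervals wrapping the year end
# have start > end.
scheme_table <- function(name) {
  switch(name,
    natural_season = data.frame(
      label = c("spring", "summer", "autumn", "winter"),
      start = c(301, 601, 901, 1201),
      end   = c(531, 831, 1130, 228),
      stringsAsFactors = FALSE),
    reproductive = data.frame(
      label = c("pre_breeding", "early_breeding", "peak_breeding",
                "late_breeding", "nonbreeding"),
      start = c(1001, 201, 322, 416, 601),
      end   = c(131, 321, 415, 531, 930),
      stringsAsFactors = FALSE),
    stop("unknown period scheme: ", name, call. = FALSE)
  )
}

#' A calendar period scheme
#'
#' Two schemes are available. `natural_season` divides the year into the
#' four natural seasons of Chengdu: spring (Mar--May), summer (Jun--Aug),
#' autumn (Sep--Nov) and winter (Dec--Feb). `reproductive` divides it into
#' five windows anchored on the female reproductive cycle: pre-breeding
#' (Oct 1--Jan 31), early breeding (Feb 1--Mar 21), peak breeding
#' (Mar 22--Apr 15), late breeding (Apr 16--May 31) and nonbreeding
#' (Jun 1--Sep 30).
#'
#' @param name `"natural_season"` or `"reproductive"`.
#' @return An object of class `period_scheme`: a data frame of labelled
#'   month-day intervals covering every day of a 365-day year exactly once.
#' @export
period_scheme <- function(name = c("natural_season", "reproductive")) {
  name <- match.arg(name)
  tab <- scheme_table(name)
  structure(tab, name = name, class = c("period_scheme", "data.frame"))
}

# month-day code for a date; Feb 29 is mapped to Feb 28 because schemes are
# defined on the month-day grid of a 365-day year
month_day_code <- function(d) {
  d <- as.Date(d)
  md <- as.integer(format(d, "%m")) * 100L + as.integer(format(d, "%d"))
  md[md == 229L] <- 228L
  md
}

#' Label dates by calendar period
#'
#' @param dates `Date` vector.
#' @param scheme A [period_scheme()].
#' @return Factor of period labels, one per date (Feb 29 takes the label of
#'   Feb 28).
#' @export
label_period <- function(dates, scheme = period_scheme("natural_season")) {
  stopifnot(inherits(scheme, "period_scheme"))
  md <- month_day_code(dates)
  out <- rep(NA_character_, length(md))
  for (i in seq_len(nrow(scheme))) {
    s <- scheme$start[i]; e <- scheme$end[i]
    hit <- if (s <= e) md >= s & md <= e else md >= s | md <= e
    out[hit] <- scheme$label[i]
  }
  factor(out, levels = scheme$label)
}

#' Load longitudinal weight records from CSV
#'
#' Expects columns `animal_id, sex, birth_date, measure_date, weight_kg`
#' with ISO-8601 dates. Rows with unparseable dates, non-positive weight or
#' a measurement before birth are rejected and collected into a per-row
#' report attached as attribute `"row_errors"`; duplicated
#' `(animal_id, measure_date)` pairs are a validation error.
#'
#' @param path Path to a CSV file.
#' @param provenance Free-text label stored on the result.
#' @return A `panda_records` data frame with computed `age_days` and an
#'   `adjusted` flag (all `FALSE` on load).
#' @export
load_records <- function(path, provenance = path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("animal_id", "sex", "birth_date", "measure_date", "weight_kg")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  errs <- character(0); err_rows <- integer(0)
  note <- function(rows, msg) {
    err_rows <<- c(err_rows, rows)
    errs <<- c(errs, paste0("row ", rows, ": ", msg))
  }

  birth <- as.Date(raw$birth_date, format = "%Y-%m-%d")
  meas <- as.Date(raw$measure_date, format = "%Y-%m-%d")
  w <- suppressWarnings(as.numeric(raw$weight_kg))
  bad_date <- which(is.na(birth) | is.na(meas))
  if (length(bad_date)) note(bad_date, "unparseable date")
  bad_w <- setdiff(which(is.na(w) | w <= 0), bad_date)
  if (length(bad_w)) note(bad_w, "non-positive or missing weight_kg")
  bad_order <- setdiff(which(!is.na(birth) & !is.na(meas) & meas < birth),
                       c(bad_date, bad_w))
  if (length(bad_order)) note(bad_order, "measure_date before birth_date")
  bad_sex <- setdiff(which(!raw$sex %in% c("female", "male")),
                     c(bad_date, bad_w, bad_order))
  if (length(bad_sex)) note(bad_sex, "sex must be 'female' or 'male'")

  keep <- setdiff(seq_len(n), unique(err_rows))
  rs <- data.frame(
    animal_id = raw$animal_id[keep],
    sex = factor(raw$sex[keep], levels = c("female", "male")),
    birth_date = birth[keep],
    measure_date = meas[keep],
    weight_kg = w[keep],
    stringsAsFactors = FALSE)
  rs$age_days <- age_in_days(rs$birth_date, rs$measure_date)
  rs$adjusted <- FALSE

  dup <- duplicated(rs[c("animal_id", "measure_date")])
  if (any(dup)) {
    pair <- rs[which(dup)[1], ]
    stop("duplicate (animal_id, measure_date) pair: ", pair$animal_id, ", ",
         format(pair$measure_date), call. = FALSE)
  }
  as_panda_records(rs, provenance = provenance, row_errors = errs)
}

as_panda_records <- function(df, provenance = NULL, row_errors = NULL) {
  class(df) <- unique(c("panda_records", class(df)))
  if (!is.null(provenance)) attr(df, "provenance") <- provenance
  if (!is.null(row_errors)) attr(df, "row_errors") <- row_errors
  df
}

#' Write weight records to CSV
#'
#' Emits the input schema plus derived columns `age_days`, `age_group`,
#' `season`, `reproductive_period` and `adjusted`.
#'
#' @param rs A `panda_records` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(rs, path) {
  out <- data.frame(
    animal_id = rs$animal_id,
    sex = as.character(rs$sex),
    birth_date = format(rs$birth_date, "%Y-%m-%d"),
    measure_date = format(rs$measure_date, "%Y-%m-%d"),
    weight_kg = rs$weight_kg,
    age_days = rs$age_days,
    age_group = as.character(assign_age_group(rs$age_days)),
    season = as.character(label_period(rs$measure_date,
                                       period_scheme("natural_season"))),
    reproductive_period = as.character(label_period(rs$measure_date,
                                                    period_scheme("reproductive"))),
    adjusted = rs$adjusted,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict records to the adult age window
#'
#' Adults are pandas aged 66--246 completed months (inclusive bounds), with
#' months computed by [age_in_months()].
#'
#' @param rs A `panda_records` data frame.
#' @param min_age_months,max_age_months Window bounds in completed months.
#' @param month_length_days Days per month used in the conversion.
#' @export
filter_adults <- function(rs, min_age_months = 66, max_age_months = 246,
                          month_length_days = 30.4375) {
  stopifnot(min_age_months < max_age_months)
  m <- age_in_months(rs$age_days, month_length_days)
  as_panda_records(rs[m >= min_age_months & m <= max_age_months, , drop = FALSE])
}
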