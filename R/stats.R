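#' Two-sided Mann-Whitney U comparison
#'
#' Wraps [stats::wilcox.test()] (exact for small tie-free samples, normal
#' approximation with tie and continuity correction otherwise) and reports
#' the U statistic, the p value and the direction of the median difference.
#' When every value in both groups is identical the comparison is
#' degenerate: p is reported as 1 with `degenerate = TRUE`.
#'
#' @param a,b Numeric weight (or velocity) samples.
#' @param label_a,label_b Group labels carried into the result.
#' @return A one-row data frame of class `comparison_result`.
#' @export
mann_whitney <- function(a, b, label_a = "a", label_b = "b") {
  stopifnot(length(a) >= 1, length(b) >= 1)
  degenerate <- length(unique(c(a, b))) == 1
  if (degenerate) {
    u <- length(a) * length(b) / 2
    p <- 1
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    u <- unname(ht$statistic)
    p <- ht$p.value
  }
  md <- stats::median(a) - stats::median(b)
  out <- data.frame(
    group_a = label_a, n_a = length(a), group_b = label_b, n_b = length(b),
    U = u, p = p,
    direction = if (md > 0) ">" else if (md < 0) "<" else "=",
    degenerate = degenerate, stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Pairwise weight comparisons across calendar periods
#'
#' Labels each record's measurement date by the scheme and runs a
#' Mann-Whitney comparison for every unordered pair of period labels
#' (6 pairs for the four natural seasons, 10 for the five reproductive
#' periods). Pairs with an empty group are skipped and listed in
#' attribute `"skipped"`.
#'
#' @param rs Records of one sex, already restricted to the adult window
#'   (see [filter_adults()]).
#' @param scheme A [period_scheme()].
#' @param p_adjust Multiplicity correction applied across the pairs
#'   (`"none"`, the default, or any [stats::p.adjust()] method such as
#'   `"holm"`); adjusted p values are added as column `p_adj`.
#' @return A `comparison_result` data frame, one row per compared pair.
#' @export
compare_periods <- function(rs, scheme = period_scheme("natural_season"),
                            p_adjust = "none") {
  lab <- label_period(rs$measure_date, scheme)
  groups <- split(rs$weight_kg, lab)
  pairs <- utils::combn(scheme$label, 2)
  rows <- list(); skipped <- character(0)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (length(groups[[a]]) == 0 || length(groups[[b]]) == 0) {
      skipped <- c(skipped, paste(a, "vs", b))
      next
    }
    rows[[length(rows) + 1]] <- mann_whitney(groups[[a]], groups[[b]], a, b)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  attr(out, "skipped") <- skipped
  out
}

#' Weight velocity from adjacent records (method A)
#'
#' For each animal, sorted by measurement date, the velocity between two
#' adjacent records is the weight difference divided by the day gap,
#' assigned to the midpoint age of the pair. Pairs sharing a date (zero
#' gap) are skipped and counted in attribute `"n_skipped"`; decreases give
#' negative velocities.
#'
#' @param rs A `panda_records` data frame (any row order).
#' @param max_gap_days Optional cap on the day gap of a usable pair.
#' @return Data frame of `VelocityPoint`s: `animal_id`, `sex`,
#'   `age_mid_days`, `velocity_kg_per_day`, `method = "records"`.
#' @export
velocity_from_records <- function(rs, max_gap_days = Inf) {
  rs <- rs[order(rs$animal_id, rs$measure_date), , drop = FALSE]
  n_skipped <- 0L
  rows <- lapply(split(seq_len(nrow(rs)), rs$animal_id), function(idx) {
    if (length(idx) < 2) return(NULL)
    dd <- diff(rs$age_days[idx])
    dw <- diff(rs$weight_kg[idx])
    mid <- (rs$age_days[idx][-1] + rs$age_days[idx][-length(idx)]) / 2
    ok <- dd > 0 & dd <= max_gap_days
    n_skipped <<- n_skipped + sum(dd == 0)
    if (!any(ok)) return(NULL)
    data.frame(animal_id = rs$animal_id[idx][1],
               sex = as.character(rs$sex[idx][1]),
               age_mid_days = mid[ok],
               velocity_kg_per_day = dw[ok] / dd[ok],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out)) {
    out <- data.frame(animal_id = character(0), sex = character(0),
                      age_mid_days = numeric(0),
                      velocity_kg_per_day = numeric(0))
  }
  out$method <- rep("records", nrow(out))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Weight velocity from the daily chart (method B)
#'
#' The velocity for day `d` is the mean predicted weight at `d` minus the
#' mean predicted weight at `d - 1`; the chart must be dense (consecutive
#' days) per sex. Velocities therefore telescope: summed over `(a, b]`
#' they equal the mean-prediction difference between days `b` and `a`.
#'
#' @param chart A [weight_chart()] (or any data frame with `sex`,
#'   `age_day`, `mean_kg`).
#' @return Data frame of `VelocityPoint`s with `method = "chart"`;
#'   `age_mid_days` is the day the velocity is assigned to.
#' @export
velocity_from_chart <- function(chart) {
  rows <- lapply(split(chart, chart$sex), function(ch) {
    if (nrow(ch) == 0) return(NULL)
    ch <- ch[order(ch$age_day), , drop = FALSE]
    if (any(diff(ch$age_day) != 1)) {
      stop("chart has gaps in age_day; velocities need a dense chart",
           call. = FALSE)
    }
    if (nrow(ch) < 2) return(NULL)
    data.frame(animal_id = NA_character_, sex = as.character(ch$sex[-1]),
               age_mid_days = ch$age_day[-1],
               velocity_kg_per_day = diff(ch$mean_kg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  out$method <- rep("chart", nrow(out))
  rownames(out) <- NULL
  out
}

#' Yearly age bins for velocity analysis
#'
#' Year `y` covers days `365 (y - 1) + 1` to `365 y` (year 1 starts at day
#' 0 so newborn midpoints are binned); the last bin is truncated at
#' `max_day`. Year 4 is days 1096--1460, the window in which growing male
#' and female pandas are compared.
#'
#' @param max_day Upper end of the analysed age range, days (the growing
#'   period runs to 2008 days).
#' @return Data frame with `label`, `start_day`, `end_day`.
#' @export
yearly_age_bins <- function(max_day = 2008) {
  years <- seq_len(ceiling(max_day / 365))
  data.frame(label = paste0("year", years),
             start_day = ifelse(years == 1, 0, 365 * (years - 1) + 1),
             end_day = pmin(365 * years, max_day),
             stringsAsFactors = FALSE)
}

#' Compare weight velocity between sexes within age bins
#'
#' Runs a Mann-Whitney comparison of male vs female velocities inside each
#' age bin; bins missing a sex are skipped and listed in attribute
#' `"skipped"`.
#'
#' @param points Velocity points from [velocity_from_records()] or
#'   [velocity_from_chart()].
#' @param bins Age bins, see [yearly_age_bins()].
#' @return A `comparison_result` data frame with a `bin` column.
#' @export
compare_velocity_by_sex <- function(points, bins = yearly_age_bins()) {
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(bins))) {
    inbin <- points$age_mid_days >= bins$start_day[i] &
      points$age_mid_days <= bins$end_day[i]
    m <- points$velocity_kg_per_day[inbin & points$sex == "male"]
    f <- points$velocity_kg_per_day[inbin & points$sex == "female"]
    if (length(m) == 0 || length(f) == 0) {
      skipped <- c(skipped, bins$label[i])
      next
    }
    cmp <- mann_whitney(m, f, "male", "female")
    cmp$bin <- bins$label[i]
    rows[[length(rows) + 1]] <- cmp
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
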