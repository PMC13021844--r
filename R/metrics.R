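# Drug utilization outcomes: DDD per 1000 inhabitants per day (DDD/TID),
# incident recipients per 100,000, and relative change versus the 2019 base
# year. Periods are sets of study month indices (a single month or a quarter).

#' Month indices of a calendar quarter
#'
#' @param year Year in 2018..2022.
#' @param quarter Quarter in 1..4.
#' @return Integer vector of the quarter's three month indices.
#' @export
quarter_months <- function(year, quarter) {
  quarter <- as.integer(quarter)
  if (length(quarter) != 1L || is.na(quarter) || quarter < 1L || quarter > 4L) {
    stop("quarter_months(): quarter must be in 1..4", call. = FALSE)
  }
  month_index(rep(as.integer(year), 3L), (quarter - 1L) * 3L + 1:3)
}

#' Dispensed volume of a period in DDD/TID
#'
#' Computes the internationally comparable utilization metric
#' \deqn{v_p = \frac{\sum_m u_m}{d_p \, n_p} \cdot 1000}
#' where \eqn{u_m} is the dispensed DDD total of month \eqn{m}, \eqn{d_p} the
#' number of days in the period and \eqn{n_p} its population size. For a
#' multi-month period \eqn{d_p} is the exact sum of calendar days and
#' \eqn{n_p} the mean of the monthly populations, which reduces to the
#' single-population formula whenever the population is constant.
#'
#' @param series A [monthly_series].
#' @param months Integer vector of study month indices forming the period
#'   (e.g. a single index, or [quarter_months()]).
#' @return A one-row tibble with `v` (DDD/TID), `numerator_ddd`,
#'   `person_days` (\eqn{d_p n_p}), `n_months`, `days`, `population`.
#' @examples
#' # 93,000 DDD over a 31-day month in a population of 100,000 -> 30 DDD/TID
#' @export
compute_dddtid <- function(series, months) {
  rows <- period_rows(series, months)
  n_p <- mean(rows$population)
  d_p <- sum(rows$days)
  if (n_p <= 0) {
    stop("compute_dddtid(): population is zero; DDD/TID undefined",
         call. = FALSE)
  }
  tibble::tibble(
    v = sum(rows$ddd) / (d_p * n_p) * 1000,
    numerator_ddd = sum(rows$ddd),
    person_days = d_p * n_p,
    n_months = nrow(rows),
    days = d_p,
    population = n_p
  )
}

#' Treatment incidence of a period per 100,000 persons
#'
#' \deqn{incidence_p = \frac{\sum k_p}{\sum n_p} \cdot 100{,}000}
#' where \eqn{k_p} are monthly incident recipient counts and \eqn{n_p} the
#' monthly populations; both are summed over the months of the period.
#'
#' @inheritParams compute_dddtid
#' @return A one-row tibble with `incidence` (per 100,000), `incident_count`
#'   and `population` (the summed monthly populations).
#' @export
compute_incidence <- function(series, months) {
  rows <- period_rows(series, months)
  if (any(is.na(rows$incident_count))) {
    stop(sprintf(
      "compute_incidence(): incident counts absent for series %s in the requested period",
      series_label(series)), call. = FALSE)
  }
  tibble::tibble(
    incidence = sum(rows$incident_count) / sum(rows$population) * 1e5,
    incident_count = sum(rows$incident_count),
    population = sum(rows$population)
  )
}

period_rows <- function(series, months) {
  months <- as.integer(months)
  if (!length(months) || any(is.na(months)) || any(months < 1L | months > 60L)) {
    stop("period months must be study month indices in 1..60", call. = FALSE)
  }
  rows <- series[match(months, series$month_index), , drop = FALSE]
  if (anyNA(rows$month_index)) {
    stop("period months missing from series", call. = FALSE)
  }
  rows
}

#' Quarterly metric table for one series
#'
#' Convenience wrapper evaluating [compute_dddtid()] or [compute_incidence()]
#' on all 20 quarters of the study window.
#'
#' @param series A [monthly_series].
#' @param metric `"dddtid"` or `"incidence"`.
#' @return A tibble with columns `region`, `age_group`, `sex`, `year`,
#'   `quarter`, `metric`, `value`.
#' @export
quarterly_metric <- function(series, metric = c("dddtid", "incidence")) {
  metric <- match.arg(metric)
  grid <- expand.grid(quarter = 1:4, year = 2018:2022)
  vals <- mapply(function(y, q) {
    m <- quarter_months(y, q)
    if (metric == "dddtid") compute_dddtid(series, m)$v
    else compute_incidence(series, m)$incidence
  }, grid$year, grid$quarter)
  tibble::tibble(
    region = attr(series, "region"), age_group = attr(series, "age_group"),
    sex = attr(series, "sex"), year = as.integer(grid$year),
    quarter = as.integer(grid$quarter), metric = metric, value = vals
  )
}

#' Relative change of a quarterly metric versus the 2019 base year
#'
#' \deqn{\Delta_{q,y} = (v_{q,y} / v_{q,2019} - 1) \cdot 100}
#' with 2019, the last full pre-pandemic year, as the base. By construction
#' every quarter of 2019 maps to exactly 0 percent.
#'
#' @param metric_by_quarter A tibble with columns `year`, `quarter`, `value`
#'   (e.g. from [quarterly_metric()]).
#' @param quarter Quarter 1..4.
#' @param year Year 2018..2022.
#' @return A one-row tibble with `quarter`, `year`, `delta_pct`.
#' @export
relative_change <- function(metric_by_quarter, quarter, year) {
  pick <- function(y, q) {
    v <- metric_by_quarter$value[metric_by_quarter$year == y &
                                   metric_by_quarter$quarter == q]
    if (length(v) != 1L) {
      stop(sprintf("relative_change(): no unique value for Q%d %d", q, y),
           call. = FALSE)
    }
    v
  }
  base <- pick(2019L, quarter)
  if (!is.finite(base) || base == 0) {
    stop(sprintf("relative_change(): base value for Q%d 2019 is zero; ratio undefined",
                 quarter), call. = FALSE)
  }
  tibble::tibble(quarter = as.integer(quarter), year = as.integer(year),
                 delta_pct = (pick(year, quarter) / base - 1) * 100)
}

#' Monthly incident recipient counts under the 12-month washout rule
#'
#' A person is an incident recipient in month \eqn{m} if they have at least
#' one antidepressant (ATC `N06A`) dispensing in \eqn{m} and none in the 12
#' preceding calendar months \eqn{m-12, \ldots, m-1}. Multiple dispensings
#' inside the incident month count once. The washout operates at calendar
#' month resolution.
#'
#' @param events A person-level event table accepted by
#'   [person_event_table()]. Stratum columns (`region`, `age_group`, `sex`),
#'   if present, are carried through and counts are computed per stratum.
#' @param months Study month indices for which counts are requested
#'   (default all 60).
#' @param history_from First month index (possibly `<= 0`) from which the
#'   event data are complete; defaults to the earliest event month. Every
#'   requested month must have a full 12-month lookback at or after this
#'   point, otherwise an insufficient-history error is raised.
#' @return A tibble with any stratum columns, `month_index`, and
#'   `incident_count` (a row for every requested month, including zeros).
#' @export
derive_incident_counts <- function(events, months = 1:60,
                                   history_from = NULL) {
  events <- person_event_table(events)
  months <- sort(unique(as.integer(months)))
  if (any(months < 1L | months > 60L)) {
    stop("derive_incident_counts(): requested months must lie in 1..60",
         call. = FALSE)
  }
  if (!nrow(events)) {
    stop("derive_incident_counts(): no N06A events in the table", call. = FALSE)
  }
  if (is.null(history_from)) history_from <- min(events$month_index)
  if (min(months) - 12L < history_from) {
    stop(sprintf(
      "derive_incident_counts(): month index %d lacks a full 12-month lookback (history starts at %d)",
      min(months), history_from), call. = FALSE)
  }

  strata_cols <- intersect(c("region", "age_group", "sex"), names(events))
  key_cols <- c(strata_cols, "person_id")
  pm <- dplyr::distinct(events[, c(key_cols, "month_index")])
  pm <- dplyr::arrange(pm, dplyr::across(dplyr::all_of(c(key_cols, "month_index"))))
  pm <- dplyr::group_by(pm, dplyr::across(dplyr::all_of(key_cols)))
  pm <- dplyr::mutate(pm, gap = month_index - dplyr::lag(month_index))
  pm <- dplyr::ungroup(pm)
  inc <- pm[(is.na(pm$gap) | pm$gap > 12L) & pm$month_index %in% months, ]

  counts <- dplyr::count(inc,
                         dplyr::across(dplyr::all_of(c(strata_cols, "month_index"))),
                         name = "incident_count")
  # fill zero months per stratum
  strata <- if (length(strata_cols)) {
    dplyr::distinct(events[, strata_cols, drop = FALSE])
  } else {
    tibble::tibble(.rows = 1L)
  }
  grid <- tidyr::crossing(strata, month_index = months)
  out <- dplyr::left_join(grid, counts, by = c(strata_cols, "month_index"))
  out$incident_count <- ifelse(is.na(out$incident_count), 0L,
                               as.integer(out$incident_count))
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(strata_cols, "month_index"))))
}
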