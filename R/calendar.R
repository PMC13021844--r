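#' The 60-month study calendar (January 2018 to December 2022)
#'
#' The whole package works on a fixed observation window of 60 calendar
#' months, indexed 1..60 with January 2018 = 1. The pre-pandemic period is
#' January 2018 to February 2020 (indices 1..26) and the pandemic period is
#' March 2020 to December 2022 (indices 27..60).
#'
#' @return A tibble with one row per month and columns `month_index` (1..60),
#'   `year`, `month` (1..12), `days_in_month` (calendar days, 29 for February
#'   2020), `quarter` (1..4), `period` (`"pre_covid"` or `"covid"`).
#' @examples
#' cal <- study_calendar()
#' cal[cal$year == 2020 & cal$month == 3, ]  # March 2020, index 27
#' @export
study_calendar <- function() {
  years <- rep(2018:2022, each = 12L)
  months <- rep(1:12, times = 5L)
  tibble::tibble(
    month_index = seq_len(60L),
    year = years,
    month = months,
    days_in_month = days_in_month(years, months),
    quarter = (months - 1L) %/% 3L + 1L,
    period = ifelse(seq_len(60L) <= 26L, "pre_covid", "covid")
  )
}

#' Number of days in a calendar month
#'
#' @param year,month Integer vectors (recycled to common length).
#' @return Integer vector of month lengths; February of a leap year is 29.
#' @keywords internal
days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | (year %% 400L == 0L)
  out <- base[month]
  out[month == 2L & leap] <- 29L
  out
}

#' Convert a calendar month to its 1-based study index
#'
#' @param year,month Integer vectors identifying calendar months. Both are
#'   recycled to a common length.
#' @param strict If `TRUE` (default), months outside January 2018 to
#'   December 2022 raise an error; if `FALSE`, out-of-window months get an
#'   index on the same scale (e.g. December 2017 = 0), which is what the
#'   incident-user washout needs for its lookback.
#' @return Integer vector: January 2018 = 1, March 2020 = 27, December 2022 = 60.
#' @examples
#' month_index(2020, 3)   # 27
#' month_index(2022, 12)  # 60
#' @export
month_index <- function(year, month, strict = TRUE) {
  n <- max(length(year), length(month))
  year <- rep_len(as.integer(year), n)
  month <- rep_len(as.integer(month), n)
  if (any(is.na(year) | is.na(month)) || any(month < 1L | month > 12L)) {
    stop("month_index(): `year`/`month` must be complete, with month in 1..12",
         call. = FALSE)
  }
  idx <- (year - 2018L) * 12L + month
  if (strict && any(idx < 1L | idx > 60L)) {
    bad <- which(idx < 1L | idx > 60L)[1L]
    stop(sprintf(
      "month_index(): %d-%02d is outside the study window Jan 2018 - Dec 2022",
      year[bad], month[bad]), call. = FALSE)
  }
  idx
}

#' Convert a study month index back to (year, month)
#'
#' Inverse of [month_index()].
#'
#' @param index Integer vector in 1..60.
#' @return A tibble with columns `month_index`, `year`, `month`.
#' @export
month_from_index <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L | index > 60L)) {
    stop("month_from_index(): index must lie in 1..60", call. = FALSE)
  }
  tibble::tibble(
    month_index = index,
    year = 2018L + (index - 1L) %/% 12L,
    month = (index - 1L) %% 12L + 1L
  )
}

#' Calendar quarter label of a study month index
#'
#' @param index Integer vector in 1..60.
#' @return A tibble with columns `year` and `quarter` (1..4).
#' @export
quarter_of <- function(index) {
  ym <- month_from_index(index)
  tibble::tibble(year = ym$year, quarter = (ym$month - 1L) %/% 3L + 1L)
}

# Named anchor indices used throughout: pandemic onset, ramp onset,
# plateau start, end of window.
.calendar_anchors <- list(
  pandemic_onset = 27L,  # March 2020
  ramp_onset = 30L,      # June 2020
  plateau_from = 49L,    # January 2022 (plateau holds the Dec 2021 level)
  end_of_window = 60L    # December 2022
)

#' Study period month-index ranges
#'
#' @return A list with integer vectors `pre_covid` (1..26, Jan 2018-Feb 2020)
#'   and `covid` (27..60, Mar 2020-Dec 2022).
#' @export
study_periods <- function() {
  list(pre_covid = 1:26, covid = 27:60)
}
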