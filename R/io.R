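# Canonical long-format schema for registry extracts:
#   region, age_group, sex, year, month, ddd, population, days, incident_count
# One row per (region, stratum, calendar month); incident_count may be empty.

.age_levels <- c("0-17", "18-44", "45-64", "65-74", "75+", "all")
.sex_levels <- c("female", "male", "all")

#' Construct and validate a monthly dispensing series
#'
#' A `monthly_series` is one region/stratum's aligned 60-month series of
#' dispensed DDD totals, population, calendar days and (optionally) incident
#' recipient counts. All downstream metrics and model fits consume this type.
#'
#' @param data A data frame with columns `month_index` (or `year` + `month`),
#'   `ddd`, `population`, `days`, and optionally `incident_count`.
#' @param region Region identifier (non-empty string).
#' @param age_group One of `"0-17"`, `"18-44"`, `"45-64"`, `"65-74"`, `"75+"`,
#'   `"all"`. An en-dash in the label is normalised to `-`.
#' @param sex One of `"female"`, `"male"`, `"all"`.
#' @return A tibble of 60 rows (classed `monthly_series`) with columns
#'   `month_index`, `year`, `month`, `ddd`, `population`, `days`,
#'   `incident_count`, and attributes `region`, `age_group`, `sex`.
#' @export
monthly_series <- function(data, region, age_group = "all", sex = "all") {
  region <- as.character(region)
  if (length(region) != 1L || is.na(region) || !nzchar(region)) {
    stop("monthly_series(): `region` must be a non-empty string", call. = FALSE)
  }
  age_group <- normalise_age_group(age_group)
  sex <- match_level(sex, .sex_levels, "sex")

  data <- tibble::as_tibble(data)
  if (!"month_index" %in% names(data)) {
    if (!all(c("year", "month") %in% names(data))) {
      stop("monthly_series(): need `month_index` or `year` + `month` columns",
           call. = FALSE)
    }
    data$month_index <- month_index(data$year, data$month)
  }
  ym <- month_from_index(data$month_index)
  data$year <- ym$year
  data$month <- ym$month
  if (!"incident_count" %in% names(data)) data$incident_count <- NA_integer_

  needed <- c("ddd", "population", "days")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("monthly_series(): missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[order(data$month_index),
               c("month_index", "year", "month", "ddd", "population", "days",
                 "incident_count")]
  out <- structure(data,
                   class = c("monthly_series", class(tibble::tibble())),
                   region = region, age_group = age_group, sex = sex)
  validate_monthly_series(out)
}

#' @rdname monthly_series
#' @param x A `monthly_series` object.
#' @export
validate_monthly_series <- function(x) {
  lab <- series_label(x)
  idx <- x$month_index
  if (anyDuplicated(idx)) {
    stop(sprintf("series %s: duplicated month indices", lab), call. = FALSE)
  }
  gaps <- setdiff(1:60, idx)
  if (length(gaps)) {
    ym <- month_from_index(gaps[1L])
    stop(sprintf("series %s: missing month %s %d (index %d)", lab,
                 month.name[ym$month], ym$year, gaps[1L]), call. = FALSE)
  }
  if (any(!is.finite(x$ddd)) || any(x$ddd < 0)) {
    stop(sprintf("series %s: dispensed DDD must be finite and non-negative", lab),
         call. = FALSE)
  }
  if (any(!is.finite(x$population)) || any(x$population <= 0)) {
    stop(sprintf("series %s: population must be positive for every month", lab),
         call. = FALSE)
  }
  if (any(!is.finite(x$days)) || any(x$days < 28 | x$days > 31)) {
    stop(sprintf("series %s: days per month must lie in 28..31", lab),
         call. = FALSE)
  }
  expected_days <- days_in_month(x$year, x$month)
  if (any(x$days != expected_days)) {
    warning(sprintf(
      "series %s: stored days disagree with the calendar in %d month(s)",
      lab, sum(x$days != expected_days)), call. = FALSE)
  }
  kc <- x$incident_count
  if (any(!is.na(kc) & (kc < 0 | kc != round(kc)))) {
    stop(sprintf("series %s: incident_count must be a non-negative integer", lab),
         call. = FALSE)
  }
  invisible(x)
}

series_label <- function(x) {
  sprintf("%s/%s/%s", attr(x, "region"), attr(x, "age_group"), attr(x, "sex"))
}

normalise_age_group <- function(age_group) {
  age_group <- gsub("–", "-", as.character(age_group))
  match_level(age_group, .age_levels, "age_group")
}

match_level <- function(value, levels, what) {
  value <- as.character(value)
  if (length(value) != 1L || is.na(value) || !value %in% levels) {
    stop(sprintf("unknown %s label %s; expected one of: %s", what,
                 deparse(value), paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  value
}

#' Read a canonical long-format dispensing CSV
#'
#' Reads the on-disk exchange format (UTF-8 CSV, `.` decimal separator) with
#' header `region, age_group, sex, year, month, ddd, population, days,
#' incident_count` and splits it into validated [monthly_series] objects,
#' one per (region, age group, sex) stratum. Every stratum must cover the
#' full study window with no gaps or duplicates.
#'
#' @param path Path to the CSV file.
#' @return A named list of `monthly_series`, keyed `region|age_group|sex`.
#' @seealso [write_monthly_series()] for the inverse operation.
#' @export
read_monthly_series <- function(path) {
  if (!file.exists(path)) {
    stop("read_monthly_series(): file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(region = "character",
                                        age_group = "character",
                                        sex = "character"))
  needed <- c("region", "age_group", "sex", "year", "month", "ddd",
              "population", "days")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("read_monthly_series(): missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"incident_count" %in% names(raw)) raw$incident_count <- NA_integer_
  key <- paste(raw$region, raw$age_group, raw$sex, sep = "|")
  out <- lapply(split(raw, key), function(chunk) {
    monthly_series(chunk[, c("year", "month", "ddd", "population", "days",
                             "incident_count")],
                   region = chunk$region[1L],
                   age_group = chunk$age_group[1L],
                   sex = chunk$sex[1L])
  })
  out[order(names(out))]
}

#' Write monthly series to the canonical long-format CSV
#'
#' @param series A `monthly_series` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_monthly_series <- function(series, path) {
  if (inherits(series, "monthly_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    validate_monthly_series(s)
    tibble::tibble(
      region = attr(s, "region"), age_group = attr(s, "age_group"),
      sex = attr(s, "sex"), year = s$year, month = s$month, ddd = s$ddd,
      population = s$population, days = s$days,
      incident_count = s$incident_count
    )
  })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a person-level dispensing event table
#'
#' Person-level tables carry one row per dispensing event: `person_id`,
#' `year`, `month` (the dispensing month; events before January 2018 provide
#' the washout lookback), `atc_code`, and optionally stratum columns
#' (`region`, `age_group`, `sex`). Only antidepressant events (ATC prefix
#' `N06A`) are retained.
#'
#' @param events A data frame of dispensing events.
#' @return A tibble with the `N06A` rows and an added absolute `month_index`
#'   column (values `<= 0` for pre-window lookback months).
#' @export
person_event_table <- function(events) {
  events <- tibble::as_tibble(events)
  needed <- c("person_id", "year", "month", "atc_code")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols)) {
    stop("person_event_table(): missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  idx <- month_index(events$year, events$month, strict = FALSE)
  if (any(idx > 60L)) {
    stop("person_event_table(): dispensing dates after December 2022",
         call. = FALSE)
  }
  events$month_index <- idx
  events[startsWith(as.character(events$atc_code), "N06A"), , drop = FALSE]
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("<monthly_series> %s: 60 months Jan 2018 - Dec 2022\n",
              series_label(x)))
  NextMethod()
}
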