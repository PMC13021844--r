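test_that("DDD/TID matches the hand-computed single-month value", {
  # 93,000 DDD over 31 days in a population of 100,000 -> 30 DDD/TID
  s <- monthly_series(make_series_df(), region = "x")
  jan18 <- compute_dddtid(s, 1)
  expect_equal(jan18$v, 93000 / (31 * 1e5) * 1000)
  expect_equal(jan18$v, 30)
  zero <- monthly_series(make_series_df(ddd = rep(0, 60)), region = "x")
  expect_equal(compute_dddtid(zero, 1:60)$v, 0)
})

test_that("DDD/TID is invariant under joint scaling of DDD and population", {
  set.seed(31)
  ddd <- runif(60, 1e3, 1e5)
  s1 <- monthly_series(make_series_df(ddd = ddd, population = 5e4),
                       region = "x")
  s2 <- monthly_series(make_series_df(ddd = ddd * 7, population = 5e4 * 7),
                       region = "x")
  for (months in list(3, 27, quarter_months(2020, 2), 1:60)) {
    expect_equal(compute_dddtid(s2, months)$v, compute_dddtid(s1, months)$v)
  }
})

test_that("a quarter's DDD/TID combines its months' numerators and denominators", {
  set.seed(32)
  s <- monthly_series(make_series_df(ddd = runif(60, 1e3, 1e5),
                                     population = 8e4), region = "x")
  for (y in 2018:2022) for (q in 1:4) {
    months <- quarter_months(y, q)
    monthly <- lapply(months, function(m) compute_dddtid(s, m))
    num <- sum(vapply(monthly, function(p) p$numerator_ddd, numeric(1)))
    d_p <- sum(vapply(monthly, function(p) p$days, numeric(1)))
    n_p <- mean(vapply(monthly, function(p) p$population, numeric(1)))
    expect_equal(compute_dddtid(s, months)$v, num / (d_p * n_p) * 1000)
  }
})

test_that("incidence per 100,000 follows the summed-count formula", {
  df <- make_series_df()
  df$incident_count <- 0L
  df$incident_count[1] <- 50L
  # quarter with (k, n) = (10, 50k), (20, 50k), (30, 50k) -> 40 per 100,000
  df$incident_count[4:6] <- c(10L, 20L, 30L)
  df$population <- c(rep(1e5, 3), rep(5e4, 3), rep(1e5, 54))
  s <- monthly_series(df, region = "x")
  expect_equal(compute_incidence(s, 1)$incidence, 50)
  expect_equal(compute_incidence(s, 2)$incidence, 0)
  expect_equal(compute_incidence(s, quarter_months(2018, 2))$incidence, 40)
  s_na <- monthly_series(make_series_df(), region = "x")
  expect_error(compute_incidence(s_na, 1), "incident counts absent")
})

test_that("relative change versus 2019 behaves as a percentage ratio", {
  base <- tibble::tibble(
    year = rep(2018:2022, each = 4), quarter = rep(1:4, 5),
    value = rep(80, 20)
  )
  tbl <- base
  tbl$value[tbl$year == 2020 & tbl$quarter == 2] <- 80 * 0.61
  tbl$value[tbl$year == 2021 & tbl$quarter == 3] <- 80 * 1.5
  expect_equal(relative_change(tbl, 2, 2020)$delta_pct, -39)
  expect_equal(relative_change(tbl, 3, 2021)$delta_pct, 50)
  for (q in 1:4) expect_equal(relative_change(tbl, q, 2019)$delta_pct, 0)
  tbl$value[tbl$year == 2019 & tbl$quarter == 1] <- 0
  expect_error(relative_change(tbl, 1, 2020), "zero")
})

test_that("quarterly_metric tabulates all 20 quarters per series", {
  s <- monthly_series(make_series_df(), region = "x")
  tab <- quarterly_metric(s, "dddtid")
  expect_equal(nrow(tab), 20L)
  expect_true(all(tab$value > 0))
  q1_2018 <- tab$value[tab$year == 2018 & tab$quarter == 1]
  expect_equal(q1_2018, compute_dddtid(s, quarter_months(2018, 1))$v)
})

test_that("washout: prior dispensing 13 months back is incident, 1 month back is not", {
  ev <- tibble::tibble(
    person_id = c(1L, 1L, 2L, 2L),
    year = c(2018, 2019, 2019, 2019),
    month = c(1, 2, 1, 2),
    atc_code = "N06AB06"
  )
  # person 1: months 1 and 14 (gap 13 > 12 -> incident again)
  # person 2: months 13 and 14 (gap 1 -> not incident in 14)
  counts <- derive_incident_counts(ev, months = 13:14, history_from = 1L)
  expect_equal(counts$incident_count[counts$month_index == 14L], 1L)
  # person 2 incident at 13 needs lookback to month 1 -> covered
  expect_equal(counts$incident_count[counts$month_index == 13L], 1L)
})

test_that("washout counts a person once per month despite repeat dispensings", {
  ev <- tibble::tibble(
    person_id = 1L, year = 2019, month = c(6, 6, 6), atc_code = "N06AB06"
  )
  counts <- derive_incident_counts(ev, months = 18, history_from = 1L)
  expect_equal(counts$incident_count, 1L)
})

test_that("washout requires a full 12-month lookback", {
  ev <- tibble::tibble(person_id = 1L, year = 2018, month = 5,
                       atc_code = "N06AB06")
  expect_error(derive_incident_counts(ev, months = 6),
               "lacks a full 12-month lookback")
  expect_no_error(derive_incident_counts(ev, months = 6, history_from = -7L))
})

test_that("washout agrees with the brute-force per-person oracle", {
  set.seed(41)
  months <- 13:42
  for (rep in 1:30) {
    ev <- random_event_table(n_persons = 20, month_range = 1:42)
    got <- derive_incident_counts(ev, months = months, history_from = 1L)
    want <- brute_force_incident_counts(ev, months)
    expect_identical(got$incident_count, as.integer(want))
  }
})

test_that("washout respects stratum columns when present", {
  ev <- tibble::tibble(
    person_id = c(1L, 2L), year = 2019, month = 6,
    atc_code = "N06AB06", sex = c("female", "male")
  )
  counts <- derive_incident_counts(ev, months = 18, history_from = 1L)
  expect_equal(nrow(counts), 2L)
  expect_setequal(counts$sex, c("female", "male"))
  expect_true(all(counts$incident_count == 1L))
})
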