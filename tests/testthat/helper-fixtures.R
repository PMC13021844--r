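# Shared fixtures and independent oracles, built in code at test time.

# A well-formed 60-month series data frame (one region/stratum).
make_series_df <- function(ddd = rep(93000, 60), population = 1e5) {
  cal <- study_calendar()
  tibble::tibble(
    month_index = cal$month_index, ddd = ddd,
    population = population, days = cal$days_in_month
  )
}

# Random person-level event table over months `month_range` (absolute study
# indices, <= 0 allowed for lookback history). Mixes in non-N06A rows.
random_event_table <- function(n_persons = 20, month_range = -11:48,
                               mean_events = 4) {
  rows <- lapply(seq_len(n_persons), function(pid) {
    k <- stats::rpois(1, mean_events)
    if (k == 0) return(NULL)
    m <- sample(month_range, k, replace = TRUE)
    tibble::tibble(person_id = pid, idx = m)
  })
  tbl <- dplyr::bind_rows(rows)
  if (is.null(tbl) || !nrow(tbl)) {
    tbl <- tibble::tibble(person_id = 1L, idx = min(month_range))
  }
  out <- tibble::tibble(
    person_id = tbl$person_id,
    year = 2018L + (tbl$idx - 1L) %/% 12L,
    month = (tbl$idx - 1L) %% 12L + 1L,
    atc_code = sample(c("N06AB06", "N06AX16", "N06AA09"), nrow(tbl),
                      replace = TRUE)
  )
  # decoy rows outside N06A that must be ignored
  decoy <- out[sample(nrow(out), min(3, nrow(out))), ]
  decoy$atc_code <- "C07AB02"
  dplyr::bind_rows(out, decoy)
}

# Independent brute-force washout oracle: person is incident in month m iff
# they have an N06A event in m and none in m-12..m-1.
brute_force_incident_counts <- function(events, months) {
  events <- events[startsWith(as.character(events$atc_code), "N06A"), ]
  idx <- (events$year - 2018L) * 12L + events$month
  out <- integer(length(months))
  for (j in seq_along(months)) {
    m <- months[j]
    n_inc <- 0L
    for (pid in unique(events$person_id)) {
      pm <- idx[events$person_id == pid]
      if (any(pm == m) && !any(pm >= m - 12L & pm <= m - 1L)) {
        n_inc <- n_inc + 1L
      }
    }
    out[j] <- n_inc
  }
  out
}

# One-stratum volume simulation config used across model tests.
recovery_config <- function(seed, ramp_slope = 0.2, ar = 0.5,
                            innovation_sd = 1.5) {
  simulation_config(
    regions = "r1", age_groups = "all", sexes = "all",
    region_baselines = c(r1 = 50), trend_slope = 0.1,
    seasonal_amplitude = 0, ar = ar, ma = numeric(),
    innovation_sd = innovation_sd, pulse_effect = 8,
    ramp_slope = ramp_slope, seed = seed
  )
}

volume_regressors <- function(variant = "standard") {
  cbind(volume_pulse = build_volume_pulse(variant),
        volume_ramp = build_volume_ramp())
}
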