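# Synthetic registry generator: stratified monthly dispensing volumes,
# incident-recipient counts, and person-level dispensing histories with the
# statistical structure the ITS analysis assumes (linear trend, annual
# seasonality, ARMA noise, a 3-month onset pulse and post-June-2020 ramps).
# It exists so every pipeline stage can be exercised without registry access;
# it makes no claim to reproduce any real country's series.

#' Configuration for the synthetic dispensing cohort
#'
#' Default values sketch a "paper-like" scenario: region baselines spanning
#' the range observed across European registries (about 27 to 210 DDD/TID),
#' a gentle upward trend, one annual seasonal harmonic, AR(1) noise, a
#' zero-sum stockpiling pulse at pandemic onset, and a post-June-2020 change
#' in slope. Incidence defaults put the youngest age group lowest, rising
#' with age.
#'
#' @param regions Character vector of region labels.
#' @param age_groups,sexes Stratum labels (closed vocabularies of
#'   [monthly_series()]).
#' @param region_baselines Named numeric, baseline outcome level per region
#'   (DDD/TID for volumes, per 100,000 per month for incidence). Defaults
#'   spread evenly on a log scale over 27..210 (volumes).
#' @param age_multipliers,sex_multipliers Named multiplicative factors
#'   applied to the baseline per stratum.
#' @param trend_slope Deterministic trend, outcome units per month.
#' @param seasonal_amplitude Amplitude of the annual sinusoid (outcome units).
#' @param seasonal_phase Phase shift in months.
#' @param ar,ma ARMA noise coefficients (possibly empty).
#' @param innovation_sd Innovation standard deviation (>= 0).
#' @param pulse_effect Coefficient on the volume pulse column (DDD/TID per
#'   unit of the pulse shape), or on the incidence pulse indicator (per
#'   100,000; typically negative for incidence).
#' @param pulse_variant `"standard"` or `"slovenia"`.
#' @param ramp_slope Post-June-2020 change in slope, outcome units/month
#'   (volume ramp).
#' @param plateau_slope,slope_2022 Incidence ramp slopes (units/month) for
#'   the June 2020-December 2021 ramp-plateau and the 2022 ramp.
#' @param population Stratum population: a scalar, or named per age group.
#' @param new_starters_per_month Expected number of treatment initiators per
#'   month in the person-level generator.
#' @param persistence Monthly probability that a current user redispenses in
#'   the next month (consecutive-month refills; a user who stops does not
#'   return).
#' @param burn_in_months Months of person-level history generated before
#'   January 2018 (>= 12 so the washout is exercisable from month 1).
#' @param seed Integer seed; every generator call is deterministic in it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(regions = paste0("region_", letters[1:6]),
                              age_groups = "all",
                              sexes = "all",
                              region_baselines = NULL,
                              age_multipliers = NULL,
                              sex_multipliers = NULL,
                              trend_slope = 0.3,
                              seasonal_amplitude = 3,
                              seasonal_phase = 0,
                              ar = 0.5,
                              ma = numeric(),
                              innovation_sd = 1.5,
                              pulse_effect = 8,
                              pulse_variant = c("standard", "slovenia"),
                              ramp_slope = 0.2,
                              plateau_slope = 0.2,
                              slope_2022 = 0,
                              population = 1e5,
                              new_starters_per_month = 30,
                              persistence = 0.6,
                              burn_in_months = 12L,
                              seed = 20180101L) {
  pulse_variant <- match.arg(pulse_variant)
  age_groups <- vapply(age_groups, normalise_age_group, character(1),
                       USE.NAMES = FALSE)
  sexes <- vapply(sexes, function(s) match_level(s, .sex_levels, "sex"),
                  character(1), USE.NAMES = FALSE)
  if (is.null(region_baselines)) {
    region_baselines <- stats::setNames(
      exp(seq(log(27), log(210), length.out = length(regions))), regions)
  }
  if (is.null(age_multipliers)) {
    age_multipliers <- stats::setNames(rep(1, length(age_groups)), age_groups)
  }
  if (is.null(sex_multipliers)) {
    sex_multipliers <- stats::setNames(rep(1, length(sexes)), sexes)
  }
  if (length(population) == 1L && is.null(names(population))) {
    population <- stats::setNames(rep(population, length(age_groups)), age_groups)
  }
  stopifnot(
    "innovation_sd must be >= 0" = is.finite(innovation_sd) && innovation_sd >= 0,
    "populations must be positive" = all(is.finite(population) & population > 0),
    "persistence must be a probability" =
      is.finite(persistence) && persistence >= 0 && persistence < 1,
    "burn_in_months must be >= 12" = burn_in_months >= 12L,
    "new_starters_per_month must be >= 0" =
      is.finite(new_starters_per_month) && new_starters_per_month >= 0,
    "every region needs a baseline" = all(regions %in% names(region_baselines)),
    "every age group needs a multiplier" = all(age_groups %in% names(age_multipliers)),
    "every sex needs a multiplier" = all(sexes %in% names(sex_multipliers)),
    "every age group needs a population" = all(age_groups %in% names(population))
  )
  structure(list(
    regions = regions, age_groups = age_groups, sexes = sexes,
    region_baselines = region_baselines, age_multipliers = age_multipliers,
    sex_multipliers = sex_multipliers, trend_slope = trend_slope,
    seasonal_amplitude = seasonal_amplitude, seasonal_phase = seasonal_phase,
    ar = ar, ma = ma, innovation_sd = innovation_sd,
    pulse_effect = pulse_effect, pulse_variant = pulse_variant,
    ramp_slope = ramp_slope, plateau_slope = plateau_slope,
    slope_2022 = slope_2022, population = population,
    new_starters_per_month = new_starters_per_month,
    persistence = persistence, burn_in_months = as.integer(burn_in_months),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Deterministic mean components shared by both outcome generators.
sim_mean_components <- function(config, t = 1:60) {
  seasonal <- config$seasonal_amplitude *
    sin(2 * pi * (t + config$seasonal_phase) / 12)
  list(trend = config$trend_slope * t, seasonal = seasonal)
}

sim_arma_noise <- function(config, n = 60L) {
  if (config$innovation_sd == 0) return(numeric(n))
  model <- list()
  if (length(config$ar)) model$ar <- config$ar
  if (length(config$ma)) model$ma <- config$ma
  as.numeric(stats::arima.sim(model = model, n = n, sd = config$innovation_sd))
}

#' Simulate stratified monthly dispensing volume series
#'
#' For every region/stratum the monthly DDD/TID outcome is
#' `baseline + trend*t + seasonal_t + pulse_effect*pulse_t +
#' ramp_slope*ramp_t + ARMA noise`, truncated at 0 (the truncation count is
#' kept in the `truncated` attribute), and then converted to a dispensed DDD
#' total by inverting the DDD/TID formula with the stratum's population and
#' the exact calendar days of each month. Fully deterministic in
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A named list of [monthly_series()] (keys `region|age_group|sex`),
#'   each with attributes `true_v` (the simulated DDD/TID vector) and
#'   `truncated` (number of months truncated at 0).
#' @export
simulate_volume_series <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cal <- study_calendar()
  parts <- sim_mean_components(config)
  pulse <- build_volume_pulse(config$pulse_variant)
  ramp <- build_volume_ramp()
  out <- list()
  for (region in config$regions) {
    for (age in config$age_groups) {
      for (sex in config$sexes) {
        base <- config$region_baselines[[region]] *
          config$age_multipliers[[age]] * config$sex_multipliers[[sex]]
        v <- base + parts$trend + parts$seasonal +
          config$pulse_effect * pulse + config$ramp_slope * ramp +
          sim_arma_noise(config)
        truncated <- sum(v < 0)
        v <- pmax(v, 0)
        n <- config$population[[age]]
        s <- monthly_series(
          tibble::tibble(month_index = cal$month_index,
                         ddd = v * cal$days_in_month * n / 1000,
                         population = n, days = cal$days_in_month),
          region = region, age_group = age, sex = sex)
        attr(s, "true_v") <- v
        attr(s, "truncated") <- truncated
        out[[paste(region, age, sex, sep = "|")]] <- s
      }
    }
  }
  out
}

#' Simulate stratified monthly incident-recipient counts
#'
#' The expected monthly incidence per 100,000 follows
#' `baseline + trend*t + seasonal_t + pulse_effect*pulse_t +
#' plateau_slope*plateau_t + slope_2022*ramp2022_t`, where the pulse is the
#' March-May 2020 indicator (so a negative `pulse_effect` models the early
#' lockdown decline). Counts are drawn as Poisson with mean
#' `expected * population / 100,000`. A configurable age gradient (via
#' `age_multipliers`) lets the youngest stratum sit lowest, as registry
#' incidence does. Negative expectations are truncated to 0 with a warning.
#'
#' @param config A [simulation_config()] (interpreting `region_baselines`
#'   etc. on the incidence scale, per 100,000).
#' @return A tibble with columns `region`, `age_group`, `sex`,
#'   `month_index`, `expected_incidence`, `population`, `incident_count`.
#' @export
simulate_incidence_series <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  parts <- sim_mean_components(config)
  reg <- build_incidence_regressors()
  grid <- expand.grid(sex = config$sexes, age_group = config$age_groups,
                      region = config$regions, stringsAsFactors = FALSE)
  n_trunc <- 0L
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    region <- grid$region[i]; age <- grid$age_group[i]; sex <- grid$sex[i]
    base <- config$region_baselines[[region]] *
      config$age_multipliers[[age]] * config$sex_multipliers[[sex]]
    mu <- base + parts$trend + parts$seasonal +
      config$pulse_effect * reg$incidence_pulse +
      config$plateau_slope * reg$incidence_ramp_plateau +
      config$slope_2022 * reg$incidence_ramp_2022
    n_trunc <<- n_trunc + sum(mu < 0)
    mu <- pmax(mu, 0)
    pop <- config$population[[age]]
    tibble::tibble(region = region, age_group = age, sex = sex,
                   month_index = 1:60, expected_incidence = mu,
                   population = pop,
                   incident_count = stats::rpois(60L, mu * pop / 1e5))
  })
  if (n_trunc > 0) {
    warning("simulate_incidence_series(): ", n_trunc,
            " month(s) had negative expected incidence, truncated to 0",
            call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Simulate person-level antidepressant dispensing histories
#'
#' Generates N06A dispensing events for a single stratum: each month a
#' Poisson number of new treatment starters begins dispensing, and every
#' current user refills in consecutive months with probability
#' `persistence` until they stop (stopped users do not return, so the
#' generator's logged starter counts are exactly the incident recipients
#' under the 12-month washout). History begins `burn_in_months` before
#' January 2018 so the washout lookback is complete from month 1.
#'
#' @param config A [simulation_config()].
#' @return A tibble of events (`person_id`, `year`, `month`, `atc_code`)
#'   restricted to months up to December 2022, with attribute
#'   `new_starters`: a tibble (`month_index`, `n_new`) of the generator's
#'   bookkeeping for months 1..60.
#' @export
simulate_person_events <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  first_month <- 1L - config$burn_in_months
  months <- first_month:60L
  person_id <- 0L
  ids <- integer(0)
  event_month <- integer(0)
  new_per_month <- stats::setNames(integer(length(months)),
                                   as.character(months))
  for (m in months) {
    n_new <- stats::rpois(1L, config$new_starters_per_month)
    new_per_month[as.character(m)] <- n_new
    if (n_new == 0L) next
    for (i in seq_len(n_new)) {
      person_id <- person_id + 1L
      # consecutive refill run: geometric duration
      len <- 1L + stats::rgeom(1L, prob = 1 - config$persistence)
      run <- m:(m + len - 1L)
      run <- run[run <= 60L]
      ids <- c(ids, rep(person_id, length(run)))
      event_month <- c(event_month, run)
    }
  }
  keep <- event_month >= first_month & event_month <= 60L
  # floored %/% and %% make this inverse valid for pre-2018 indices too
  events <- tibble::tibble(
    person_id = ids[keep],
    year = 2018L + (event_month[keep] - 1L) %/% 12L,
    month = (event_month[keep] - 1L) %% 12L + 1L,
    atc_code = "N06AB06"
  )
  starters <- tibble::tibble(
    month_index = 1:60,
    n_new = as.integer(new_per_month[as.character(1:60)])
  )
  attr(events, "new_starters") <- starters
  events
}
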