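# Intervention regressors for the pandemic ITS analyses, as pure functions
# of the 60-month study calendar. Timing anchors: March 2020 = index 27,
# June 2020 = 30, December 2021 = 48, December 2022 = 60.

#' Stockpiling pulse regressor for the volume analysis (March-May 2020)
#'
#' Encodes the short-term dispensing disturbance at pandemic onset: a surge
#' of dispensed volumes in March 2020 followed by a compensating decrease in
#' April and May 2020. The `"slovenia"` variant mirrors the pattern observed
#' there - a decrease in March and April followed by an increase in May 2020.
#' With the default shape `(a, b) = (1, 0.5)` the column sums to zero, so the
#' fitted coefficient reads as the amount of DDD/TID shifted into March from
#' April-May.
#'
#' @param variant `"standard"` (+a, -b, -b over March-May 2020) or
#'   `"slovenia"` (-b, -b, +a).
#' @param a,b Positive shape magnitudes; defaults `a = 1`, `b = 0.5`.
#' @return Numeric vector of length 60, nonzero only at indices 27..29.
#' @export
build_volume_pulse <- function(variant = c("standard", "slovenia"),
                               a = 1, b = 0.5) {
  variant <- match.arg(variant)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("build_volume_pulse(): shape parameters a and b must be positive",
         call. = FALSE)
  }
  out <- numeric(60L)
  shape <- if (variant == "standard") c(a, -b, -b) else c(-b, -b, a)
  out[27:29] <- shape
  out
}

#' Ramp regressor for the volume analysis (June 2020 onwards)
#'
#' Increases by one unit per month from June 2020 (value 1 at index 30) to
#' the end of the observation window (value 31 at December 2022), and is 0
#' before onset. Its coefficient is the monthly rate of pandemic-related
#' change in the outcome's trend, so the cumulative change at month \eqn{t}
#' is coefficient times ramp value at \eqn{t} (31 at December 2022).
#'
#' @return Numeric vector of length 60.
#' @export
build_volume_ramp <- function() {
  idx <- 1:60
  pmax(0, idx - 29L)
}

#' The three intervention regressors for the incidence analysis
#'
#' * `incidence_pulse`: indicator 1 over March-May 2020 (indices 27..29),
#'   capturing the temporary decline in incident use during the first
#'   lockdowns; its coefficient is expected negative.
#' * `incidence_ramp_plateau`: ramp from June 2020 (1) to December 2021 (19),
#'   then held at 19 throughout 2022 - trend growth that moderates once
#'   restrictions ease.
#' * `incidence_ramp_2022`: ramp from January 2022 (1) to December 2022 (12),
#'   capturing any remaining trend in 2022.
#'
#' @return A tibble with columns `month_index`, `incidence_pulse`,
#'   `incidence_ramp_plateau`, `incidence_ramp_2022`.
#' @export
build_incidence_regressors <- function() {
  idx <- 1:60
  tibble::tibble(
    month_index = idx,
    incidence_pulse = as.numeric(idx >= 27L & idx <= 29L),
    incidence_ramp_plateau = pmin(pmax(0, idx - 29L), 19),
    incidence_ramp_2022 = pmax(0, idx - 48L)
  )
}

#' Full intervention regressor matrix
#'
#' Bundles all intervention columns, keyed by month index, for audit and for
#' feeding [fit_its()].
#'
#' @inheritParams build_volume_pulse
#' @return A tibble with columns `month_index`, `volume_pulse`,
#'   `volume_ramp`, `incidence_pulse`, `incidence_ramp_plateau`,
#'   `incidence_ramp_2022`.
#' @export
regressor_matrix <- function(variant = c("standard", "slovenia"),
                             a = 1, b = 0.5) {
  inc <- build_incidence_regressors()
  tibble::tibble(
    month_index = inc$month_index,
    volume_pulse = build_volume_pulse(variant, a = a, b = b),
    volume_ramp = build_volume_ramp(),
    incidence_pulse = inc$incidence_pulse,
    incidence_ramp_plateau = inc$incidence_ramp_plateau,
    incidence_ramp_2022 = inc$incidence_ramp_2022
  )
}

# Accumulated regressor values over the pandemic window 3/2020-12/2022,
# the multipliers that turn a monthly-rate coefficient into a cumulative
# change: pulse active 3 months at 1; plateau ramp sums to 190 + 19*12 = 418;
# 2022 ramp sums to 78; the volume ramp reaches 31 at December 2022.
.regressor_totals <- c(
  incidence_pulse = 3,
  incidence_ramp_plateau = 418,
  incidence_ramp_2022 = 78,
  volume_ramp_at_end = 31
)
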