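# Pandemic-attribution arithmetic: turn fitted monthly-rate coefficients
# into cumulative pandemic-related changes with middle/low/high estimates
# and the share of the observed value, gated on statistical significance.

new_attribution <- function(middle, low, high, observed, computed,
                            outcome, terms_used = character()) {
  share <- if (computed) middle / observed * 100 else NA_real_
  structure(list(
    middle = if (computed) middle else NA_real_,
    low = if (computed) low else NA_real_,
    high = if (computed) high else NA_real_,
    observed = observed,
    share_pct = share,
    computed = computed,
    outcome = outcome,
    terms_used = terms_used
  ), class = "attribution_estimate")
}

#' @export
print.attribution_estimate <- function(x, ...) {
  cat(sprintf("<attribution_estimate> (%s)\n", x$outcome))
  if (!x$computed) {
    cat("  not computed: no statistically significant pandemic coefficient\n")
  } else {
    digits <- if (x$outcome == "volume") 3L else 1L
    cat(sprintf("  middle %s [low %s, high %s], observed %s, share %.1f%%\n",
                format(round(x$middle, digits)), format(round(x$low, digits)),
                format(round(x$high, digits)), format(x$observed),
                x$share_pct))
  }
  invisible(x)
}

#' Share of an estimated change on the observed value
#'
#' @param middle Estimated cumulative pandemic-related change (outcome units).
#' @param observed Observed value it is compared against (must be positive).
#' @return Percentage `middle / observed * 100`.
#' @export
share_of_observed <- function(middle, observed) {
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    stop("share_of_observed(): observed value must be positive; share undefined",
         call. = FALSE)
  }
  middle / observed * 100
}

#' Pandemic-related change in dispensed volume at the end of the window
#'
#' Converts the fitted monthly rate of pandemic-related change (the
#' `volume_ramp` coefficient, in DDD/TID/month) into the cumulative change
#' at December 2022, when the ramp has accumulated 31 months: middle
#' estimate = rate x 31, low/high = the 95% CI bounds x 31, and the share
#' of the observed December 2022 DDD/TID. The estimate is computed only when
#' the monthly rate is statistically significant (p < 0.05); otherwise
#' `computed` is `FALSE` and the estimates are absent.
#'
#' @param fit An `its_fit` containing a `volume_ramp` coefficient, or a
#'   one-row data frame / list with `estimate`, `ci_low`, `ci_high` and
#'   either `p_value` or `significant`.
#' @param observed_dec2022 Observed DDD/TID in December 2022 (positive).
#' @return An `attribution_estimate` with `middle`, `low`, `high`,
#'   `observed`, `share_pct`, `computed`.
#' @export
volume_attribution <- function(fit, observed_dec2022) {
  if (!is.finite(observed_dec2022) || observed_dec2022 <= 0) {
    stop("volume_attribution(): observed value must be positive; share undefined",
         call. = FALSE)
  }
  row <- coef_row(fit, "volume_ramp")
  mult <- .regressor_totals[["volume_ramp_at_end"]]
  if (!row$significant) {
    return(new_attribution(NA, NA, NA, observed_dec2022, computed = FALSE,
                           outcome = "volume"))
  }
  new_attribution(
    middle = row$estimate * mult,
    low = row$ci_low * mult,
    high = row$ci_high * mult,
    observed = observed_dec2022,
    computed = TRUE,
    outcome = "volume",
    terms_used = "volume_ramp"
  )
}

#' Cumulative pandemic-related change in incidence over 3/2020-12/2022
#'
#' Sums the contributions of the three incidence regressors over the whole
#' pandemic window. Each regressor's accumulated value over 3/2020-12/2022
#' is fixed by its shape: 3 for the pulse (three months at indicator 1),
#' 418 for the plateau ramp (1+...+19 plus 19 x 12 plateau months), 78 for
#' the 2022 ramp (1+...+12). Only statistically significant coefficients
#' (p < 0.05) contribute; the low/high estimates use the corresponding 95%
#' CI bounds of each contributing regressor, so the low-high range may
#' include 0. With no significant coefficient, `computed` is `FALSE`.
#'
#' @param fit An `its_fit` containing the three incidence coefficients, or
#'   a data frame with rows named in `term` (`incidence_pulse`,
#'   `incidence_ramp_plateau`, `incidence_ramp_2022`) and columns
#'   `estimate`, `ci_low`, `ci_high`, plus `p_value` or `significant`.
#' @param observed_total Observed total incidence per 100,000 over
#'   3/2020-12/2022 (positive).
#' @return An `attribution_estimate`.
#' @export
incidence_attribution <- function(fit, observed_total) {
  if (!is.finite(observed_total) || observed_total <= 0) {
    stop("incidence_attribution(): observed value must be positive; share undefined",
         call. = FALSE)
  }
  terms <- c("incidence_pulse", "incidence_ramp_plateau", "incidence_ramp_2022")
  rows <- lapply(terms, function(t) coef_row(fit, t))
  sig <- vapply(rows, function(r) isTRUE(r$significant), logical(1))
  if (!any(sig)) {
    return(new_attribution(NA, NA, NA, observed_total, computed = FALSE,
                           outcome = "incidence"))
  }
  mult <- .regressor_totals[terms]
  middle <- sum(vapply(which(sig), function(i) rows[[i]]$estimate * mult[[i]],
                       numeric(1)))
  low <- sum(vapply(which(sig), function(i) rows[[i]]$ci_low * mult[[i]],
                    numeric(1)))
  high <- sum(vapply(which(sig), function(i) rows[[i]]$ci_high * mult[[i]],
                     numeric(1)))
  new_attribution(middle, low, high, observed_total, computed = TRUE,
                  outcome = "incidence", terms_used = terms[sig])
}

# Accept an its_fit, a coefficient table with a `term` column, or a one-row
# list/data frame describing the single requested coefficient.
coef_row <- function(fit, term) {
  tbl <- if (inherits(fit, "its_fit")) {
    fit$coefficients
  } else {
    tibble::as_tibble(as.data.frame(fit, stringsAsFactors = FALSE))
  }
  row <- if ("term" %in% names(tbl)) tbl[tbl$term == term, ] else tbl
  if (nrow(row) != 1L) {
    stop("attribution: expected exactly one coefficient row for ",
         deparse(term), call. = FALSE)
  }
  if (!"significant" %in% names(row)) {
    if (!"p_value" %in% names(row)) {
      stop("attribution: coefficient row needs `significant` or `p_value`",
           call. = FALSE)
    }
    row$significant <- row$p_value < 0.05
  }
  needed <- c("estimate", "ci_low", "ci_high")
  missing_cols <- setdiff(needed, names(row))
  if (length(missing_cols)) {
    stop("attribution: coefficient row missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  row
}

#' Format attribution estimates as a table row
#'
#' Rounds to the display convention (3 decimals for DDD/TID, 1 decimal for
#' incidence; shares to 1 decimal) and prints dashes for non-computed cells.
#'
#' @param x An `attribution_estimate`, or a list of them.
#' @param labels Optional character vector of row labels.
#' @return A tibble with character columns `observed`, `middle`, `low`,
#'   `high`, `share_pct` (dashes where not computed).
#' @export
attribution_table <- function(x, labels = NULL) {
  if (inherits(x, "attribution_estimate")) x <- list(x)
  rows <- lapply(x, function(a) {
    digits <- if (a$outcome == "volume") 3L else 1L
    fmt <- function(v, dg) {
      if (!a$computed || is.na(v)) "-" else formatC(round(v, dg), format = "f",
                                                    digits = dg)
    }
    tibble::tibble(
      observed = formatC(a$observed, format = "f", digits = digits),
      middle = fmt(a$middle, digits),
      low = fmt(a$low, digits),
      high = fmt(a$high, digits),
      share_pct = fmt(a$share_pct, 1L)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(labels)) out <- dplyr::bind_cols(tibble::tibble(label = labels), out)
  out
}
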