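# Seasonal ARIMA interrupted-time-series fitting with external intervention
# regressors, z-tests on coefficients, and residual diagnostics (Ljung-Box,
# KPSS level/trend stationarity).

#' Specify (or hold) seasonal ARIMA orders
#'
#' @param p,d,q Non-seasonal AR, differencing and MA orders.
#' @param P,D,Q Seasonal counterparts, seasonal period fixed at 12.
#' @return An object of class `its_orders`.
#' @export
its_orders <- function(p = 0L, d = 0L, q = 0L, P = 0L, D = 0L, Q = 0L) {
  ord <- vapply(list(p, d, q, P, D, Q), as.integer, integer(1))
  if (any(is.na(ord)) || any(ord < 0L)) {
    stop("its_orders(): orders must be non-negative integers", call. = FALSE)
  }
  structure(list(order = ord[1:3], seasonal = ord[4:6], period = 12L),
            class = "its_orders")
}

#' @export
format.its_orders <- function(x, ...) {
  sprintf("(%d,%d,%d)(%d,%d,%d)[12]",
          x$order[1], x$order[2], x$order[3],
          x$seasonal[1], x$seasonal[2], x$seasonal[3])
}

#' @export
print.its_orders <- function(x, ...) {
  cat("ARIMA orders", format(x), "\n")
  invisible(x)
}

as_xreg_matrix <- function(xreg) {
  if (is.null(xreg)) return(NULL)
  if (is.data.frame(xreg)) {
    xreg <- xreg[, setdiff(names(xreg), "month_index"), drop = FALSE]
    xreg <- as.matrix(xreg)
  }
  if (!is.matrix(xreg)) xreg <- matrix(xreg, ncol = 1L, dimnames = list(NULL, "xreg"))
  if (is.null(colnames(xreg))) colnames(xreg) <- paste0("x", seq_len(ncol(xreg)))
  storage.mode(xreg) <- "double"
  xreg
}

check_design_rank <- function(X) {
  qrX <- qr(scale(X, center = FALSE, scale = apply(abs(X), 2, max) + (colSums(abs(X)) == 0)))
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a seasonal ARIMA interrupted-time-series model
#'
#' Fits a regression with seasonal ARIMA errors to a monthly outcome series:
#' the regression part holds an intercept, a deterministic linear trend
#' (month index), and the supplied intervention regressors, so a ramp
#' coefficient is a change in slope relative to the pre-existing trend.
#' Coefficients are estimated by maximum likelihood ([stats::arima()]);
#' significance is assessed with the z-test (estimate / SE against a
#' standard normal) and 95% confidence intervals are estimate +/- 1.96 SE,
#' both evaluated at the 0.05 level. When all ARMA orders and differencing
#' are zero the model is ordinary least squares on `[1, t, X]`, fitted as
#' such, which also keeps noiseless inputs exact.
#'
#' @param y Numeric outcome vector of length 60 (monthly DDD/TID or
#'   incidence per 100,000).
#' @param xreg Intervention regressor columns: a data frame (a
#'   `month_index` column is ignored) or matrix with one row per month.
#' @param orders An [its_orders()] object; `NULL` (default) runs
#'   [select_orders()] first.
#' @param outcome Label stored on the fit, `"volume"` or `"incidence"`.
#' @param include_trend Include the deterministic linear trend term
#'   (default `TRUE`).
#' @return An object of class `its_fit`: a list with `orders`,
#'   `coefficients` (tibble: term, estimate, se, z, p_value, ci_low,
#'   ci_high, significant), `loglik`, `aicc`, `residuals`, `outcome`,
#'   `n`, and the underlying model object.
#' @export
fit_its <- function(y, xreg = NULL, orders = NULL,
                    outcome = c("volume", "incidence"),
                    include_trend = TRUE) {
  outcome <- match.arg(outcome)
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) {
    stop("fit_its(): outcome vector must be finite", call. = FALSE)
  }
  X <- as_xreg_matrix(xreg)
  if (!is.null(X) && nrow(X) != n) {
    stop("fit_its(): xreg has ", nrow(X), " rows but y has length ", n,
         call. = FALSE)
  }
  if (include_trend) {
    X <- cbind(trend = seq_len(n), X)
  }
  if (is.null(orders)) {
    orders <- select_orders(y, xreg = X, include_trend = FALSE)
  }
  if (!inherits(orders, "its_orders")) {
    stop("fit_its(): `orders` must come from its_orders()", call. = FALSE)
  }
  d <- orders$order[2]
  D <- orders$seasonal[2]
  check_design_rank(cbind(intercept = if (d + D == 0) rep(1, n) else NULL, X))

  fit <- fit_arima_xreg(y, X, orders)
  est <- fit$coef
  se <- fit$se
  z <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    z = unname(z),
    p_value = unname(p),
    ci_low = unname(est - 1.96 * se),
    ci_high = unname(est + 1.96 * se),
    significant = unname(p < 0.05)
  )
  n_eff <- n - d - orders$period * D
  k <- length(est) + 1  # + innovation variance
  aicc <- fit$aic + 2 * k * (k + 1) / max(n_eff - k - 1, 1)

  structure(list(
    orders = orders,
    coefficients = coefs,
    loglik = fit$loglik,
    aic = fit$aic,
    aicc = aicc,
    sigma2 = fit$sigma2,
    residuals = fit$residuals,
    outcome = outcome,
    n = n,
    model = fit$model
  ), class = "its_fit")
}

# Internal: estimate the regression-with-ARIMA-errors model. Pure OLS path
# for the degenerate all-zero order; otherwise stats::arima by ML with a
# CSS-ML retry.
fit_arima_xreg <- function(y, X, orders) {
  n <- length(y)
  if (all(orders$order == 0L) && all(orders$seasonal == 0L)) {
    lmfit <- stats::lm(y ~ X)
    est <- stats::coef(lmfit)
    names(est) <- c("intercept", colnames(X))
    sm <- suppressWarnings(summary(lmfit))  # noiseless inputs are legitimate here
    se <- sm$coefficients[, "Std. Error"]
    # ML (not unbiased) innovation variance, consistent with the ARIMA path
    rss <- sum(stats::resid(lmfit)^2)
    sigma2 <- rss / n
    ll <- as.numeric(stats::logLik(lmfit))
    return(list(coef = est, se = unname(se), loglik = ll,
                aic = stats::AIC(lmfit), sigma2 = sigma2,
                residuals = unname(stats::resid(lmfit)), model = lmfit))
  }
  d <- orders$order[2]; D <- orders$seasonal[2]
  include_mean <- (d + D == 0L)
  fit <- try(suppressWarnings(stats::arima(
    y, order = orders$order,
    seasonal = list(order = orders$seasonal, period = orders$period),
    xreg = X, include.mean = include_mean, method = "ML",
    optim.control = list(maxit = 500))), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$loglik)) {
    fit <- try(suppressWarnings(stats::arima(
      y, order = orders$order,
      seasonal = list(order = orders$seasonal, period = orders$period),
      xreg = X, include.mean = include_mean, method = "CSS-ML",
      optim.control = list(maxit = 500))), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    stop("fit_its(): ARIMA estimation failed to converge for orders ",
         format(orders), ": ", attr(fit, "condition")$message, call. = FALSE)
  }
  est <- stats::coef(fit)
  vc <- fit$var.coef
  se <- rep(NA_real_, length(est))
  names(se) <- names(est)
  se[rownames(vc)] <- sqrt(pmax(diag(vc), 0))
  names(est)[names(est) == "intercept"] <- "intercept"
  drop_n <- d + orders$period * D
  res <- as.numeric(stats::residuals(fit))
  if (drop_n > 0) res <- res[-seq_len(drop_n)]
  list(coef = est, se = se, loglik = fit$loglik, aic = fit$aic,
       sigma2 = fit$sigma2, residuals = res, model = fit)
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Interrupted time series fit (%s outcome), ARIMA %s, n = %d\n",
              x$outcome, format(x$orders), x$n))
  cat(sprintf("log-likelihood %.2f, AICc %.2f\n", x$loglik, x$aicc))
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.its_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
residuals.its_fit <- function(object, ...) object$residuals

#' Extract one coefficient row from an ITS fit
#'
#' @param fit An `its_fit`.
#' @param term Coefficient name (e.g. `"volume_ramp"`).
#' @return A one-row tibble from `fit$coefficients`.
#' @export
its_coef <- function(fit, term) {
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1L) {
    stop("its_coef(): no coefficient named ", deparse(term),
         "; available: ", paste(fit$coefficients$term, collapse = ", "),
         call. = FALSE)
  }
  row
}

#' Bounded stepwise AICc search for seasonal ARIMA orders
#'
#' Chooses \eqn{(p,d,q)(P,D,Q)_{12}} by minimising AICc over a greedy
#' stepwise neighbourhood search with the intervention regressors included
#' in every candidate fit. The amount of ordinary differencing `d` is set
#' first by sequential KPSS testing (trend-stationarity on the level series,
#' then level-stationarity of the differenced series; at most 2); seasonal
#' differencing `D` (0 or 1) by an STL seasonal-strength heuristic
#' (threshold 0.64). The regression-only model with ARMA(0,0) errors is then
#' fitted and kept whenever its residuals show no remaining autocorrelation
#' (Ljung-Box, maximum lag 12, at the 0.05 level) - the same adequacy
#' criterion applied to final fits - which keeps the selection parsimonious
#' for series that the deterministic part already explains. Only when that
#' gate fails does the stepwise search run, starting from four standard
#' candidate models and moving one order at a time within `p, q <= 3`,
#' `P, Q <= 2`.
#'
#' @inheritParams fit_its
#' @param max_p,max_q,max_P,max_Q Search bounds.
#' @param include_trend Add the deterministic trend column before searching
#'   (set `FALSE` when `xreg` already carries it).
#' @return An [its_orders()] object; attribute `"trace"` holds the AICc of
#'   every candidate tried.
#' @export
select_orders <- function(y, xreg = NULL, max_p = 3L, max_q = 3L,
                          max_P = 2L, max_Q = 2L, include_trend = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) {
    stop("select_orders(): outcome vector must be finite", call. = FALSE)
  }
  X <- as_xreg_matrix(xreg)
  if (include_trend) X <- cbind(trend = seq_len(n), X)

  d <- choose_d(y)
  D <- choose_seasonal_D(y, d)

  tried <- new.env(parent = emptyenv())
  trace <- list()
  evaluate <- function(p, q, P, Q) {
    key <- paste(p, d, q, P, D, Q, sep = ".")
    if (!is.null(tried[[key]])) return(tried[[key]])
    ord <- its_orders(p, d, q, P, D, Q)
    val <- tryCatch({
      f <- fit_its(y, xreg = X, orders = ord, include_trend = FALSE)
      f$aicc
    }, error = function(e) Inf)
    tried[[key]] <- val
    trace[[length(trace) + 1L]] <<- list(orders = format(ord), aicc = val)
    val
  }

  # adequacy gate: keep the regression-only error model if its residuals
  # already pass the Ljung-Box criterion used on final fits
  null_fit <- tryCatch(
    fit_its(y, xreg = X, orders = its_orders(0, d, 0, 0, D, 0),
            include_trend = FALSE),
    error = function(e) NULL)
  if (!is.null(null_fit) && length(null_fit$residuals) > 12L) {
    lb <- ljung_box(null_fit$residuals, lag = 12L)
    if (lb$p_value >= 0.05) {
      out <- its_orders(0, d, 0, 0, D, 0)
      attr(out, "trace") <- list(list(orders = format(out),
                                      aicc = null_fit$aicc))
      return(out)
    }
  }

  starts <- list(c(2, 2, 1, 1), c(0, 0, 0, 0), c(1, 0, 1, 0), c(0, 1, 0, 1))
  starts <- lapply(starts, function(s) pmin(s, c(max_p, max_q, max_P, max_Q)))
  best <- NULL
  best_aicc <- Inf
  for (s in starts) {
    a <- evaluate(s[1], s[2], s[3], s[4])
    if (a < best_aicc) { best_aicc <- a; best <- s }
  }
  if (is.null(best)) {
    stop("select_orders(): all starting fits failed", call. = FALSE)
  }
  repeat {
    improved <- FALSE
    for (delta in list(c(1, 0, 0, 0), c(-1, 0, 0, 0), c(0, 1, 0, 0),
                       c(0, -1, 0, 0), c(0, 0, 1, 0), c(0, 0, -1, 0),
                       c(0, 0, 0, 1), c(0, 0, 0, -1), c(1, 1, 0, 0),
                       c(-1, -1, 0, 0))) {
      cand <- best + delta
      if (any(cand < 0) || cand[1] > max_p || cand[2] > max_q ||
          cand[3] > max_P || cand[4] > max_Q) next
      a <- evaluate(cand[1], cand[2], cand[3], cand[4])
      if (a < best_aicc - 1e-8) {
        best_aicc <- a
        best <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  if (!is.finite(best_aicc)) {
    stop("select_orders(): no candidate model converged; tried ",
         paste(vapply(trace, function(t) t$orders, character(1)),
               collapse = ", "), call. = FALSE)
  }
  out <- its_orders(best[1], d, best[2], best[3], D, best[4])
  attr(out, "trace") <- trace
  out
}

# d via sequential KPSS (at most 2): the model carries a deterministic
# trend, so the level series is tested against trend-stationarity.
choose_d <- function(y, alpha = 0.05) {
  k <- kpss_test(y, null = "trend")
  if (k$p_value >= alpha) return(0L)
  k1 <- kpss_test(diff(y), null = "level")
  if (k1$p_value >= alpha) return(1L)
  2L
}

# Seasonal difference if the STL seasonal strength exceeds 0.64.
choose_seasonal_D <- function(y, d = 0L, threshold = 0.64) {
  z <- if (d > 0) diff(y, differences = d) else y
  if (length(z) < 2 * 12 + 1) return(0L)
  dec <- try(stats::stl(stats::ts(z, frequency = 12L), s.window = "periodic",
                        robust = TRUE), silent = TRUE)
  if (inherits(dec, "try-error")) return(0L)
  rem <- dec$time.series[, "remainder"]
  seas <- dec$time.series[, "seasonal"]
  strength <- max(0, 1 - stats::var(rem) / stats::var(rem + seas))
  if (is.finite(strength) && strength >= threshold) 1L else 0L
}

#' Ljung-Box portmanteau test on residuals
#'
#' Thin wrapper around [stats::Box.test()] with the Ljung-Box statistic,
#' using lags 1..`lag` and, by default, no degrees-of-freedom adjustment for
#' fitted ARMA parameters (`fitdf = 0`); set `fitdf` to the number of fitted
#' ARMA parameters to enable the adjustment.
#'
#' @param residuals Numeric residual vector.
#' @param lag Maximum lag (default 12).
#' @param fitdf Degrees of freedom consumed by fitted parameters (default 0).
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
ljung_box <- function(residuals, lag = 12L, fitdf = 0L) {
  residuals <- as.numeric(residuals)
  if (length(residuals) <= lag) {
    stop("ljung_box(): need more residuals than the maximum lag", call. = FALSE)
  }
  bt <- stats::Box.test(residuals, lag = lag, type = "Ljung-Box", fitdf = fitdf)
  tibble::tibble(statistic = unname(bt$statistic),
                 df = unname(bt$parameter),
                 p_value = unname(bt$p.value))
}

# KPSS critical values (level- and trend-stationarity nulls) at upper tail
# probabilities 0.10, 0.05, 0.025, 0.01.
.kpss_table <- list(
  p = c(0.10, 0.05, 0.025, 0.01),
  level = c(0.347, 0.463, 0.574, 0.739),
  trend = c(0.119, 0.146, 0.176, 0.216)
)

#' KPSS stationarity test
#'
#' Tests the null hypothesis that a series is level-stationary (residuals of
#' a regression on a constant) or trend-stationary (constant plus linear
#' trend). The statistic is \eqn{\sum_t S_t^2 / (n^2 \hat\omega^2)} with
#' \eqn{S_t} the partial sums of the regression residuals and
#' \eqn{\hat\omega^2} a Bartlett-kernel long-run variance with truncation
#' lag `lags` (default `trunc(4 (n/100)^{1/4})`). P-values are linearly
#' interpolated from the standard critical-value table; statistics outside
#' the tabulated range are clamped to [0.01, 0.10] and flagged.
#'
#' @param x Numeric series.
#' @param null `"level"` or `"trend"` stationarity.
#' @param lags Bartlett truncation lag; `NULL` for the default rule.
#' @return A tibble with `statistic`, `lags`, `p_value`, `p_clamped`.
#' @export
kpss_test <- function(x, null = c("level", "trend"), lags = NULL) {
  null <- match.arg(null)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L || any(!is.finite(x))) {
    stop("kpss_test(): need at least 8 finite observations", call. = FALSE)
  }
  if (is.null(lags)) lags <- trunc(4 * (n / 100)^0.25)
  lags <- as.integer(lags)
  t_ <- seq_len(n)
  e <- if (null == "level") x - mean(x) else stats::resid(stats::lm(x ~ t_))
  S <- cumsum(e)
  lrv <- sum(e^2) / n
  if (lags > 0) {
    for (s in seq_len(lags)) {
      w <- 1 - s / (lags + 1)
      lrv <- lrv + 2 * w * sum(e[(s + 1):n] * e[1:(n - s)]) / n
    }
  }
  stat <- sum(S^2) / (n^2 * lrv)
  cv <- .kpss_table[[null]]
  pv <- .kpss_table$p
  clamped <- stat < min(cv) || stat > max(cv)
  p <- stats::approx(cv, pv, xout = stat, rule = 2)$y
  tibble::tibble(statistic = stat, lags = lags, p_value = p,
                 p_clamped = clamped)
}

#' Residual diagnostics for an ITS fit
#'
#' Runs the Ljung-Box test with maximum lag 12 for remaining autocorrelation
#' and the KPSS test twice (level-stationarity and trend-stationarity nulls)
#' on the model residuals; all pass flags are evaluated at the 0.05 level
#' (a test passes when its p-value is >= 0.05).
#'
#' @param fit An `its_fit`, or a numeric residual vector.
#' @param lag Maximum Ljung-Box lag (default 12).
#' @param fitdf Ljung-Box degrees-of-freedom adjustment (default 0; see
#'   [ljung_box()]).
#' @return An object of class `its_diagnostics`: a tibble with one row per
#'   test (`test`, `statistic`, `p_value`, `pass`).
#' @export
diagnose <- function(fit, lag = 12L, fitdf = 0L) {
  res <- if (inherits(fit, "its_fit")) fit$residuals else as.numeric(fit)
  if (length(res) <= lag) {
    stop("diagnose(): residual vector must be longer than the Ljung-Box lag (",
         lag, ")", call. = FALSE)
  }
  lb <- ljung_box(res, lag = lag, fitdf = fitdf)
  kl <- kpss_test(res, null = "level")
  kt <- kpss_test(res, null = "trend")
  out <- tibble::tibble(
    test = c("ljung_box", "kpss_level", "kpss_trend"),
    statistic = c(lb$statistic, kl$statistic, kt$statistic),
    p_value = c(lb$p_value, kl$p_value, kt$p_value),
    pass = c(lb$p_value >= 0.05, kl$p_value >= 0.05, kt$p_value >= 0.05)
  )
  class(out) <- c("its_diagnostics", class(out))
  out
}

#' Export a fit's coefficient table as CSV
#'
#' One row per coefficient: name, estimate, SE, z, p, ci_low, ci_high.
#'
#' @param fit An `its_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  utils::write.csv(fit$coefficients, path, row.names = FALSE)
  invisible(path)
}
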