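test_that("with all-zero orders fit_its reduces to OLS on [1, t, X]", {
  set.seed(51)
  X <- volume_regressors()
  y <- 40 + 0.15 * (1:60) + 5 * X[, "volume_pulse"] +
    0.3 * X[, "volume_ramp"] + rnorm(60, sd = 2)
  fit <- fit_its(y, xreg = X, orders = its_orders())
  M <- cbind(1, 1:60, X)
  beta <- solve(crossprod(M), crossprod(M, y))[, 1]
  expect_equal(unname(coef(fit)[c("intercept", "trend", "volume_pulse",
                                  "volume_ramp")]),
               unname(beta), tolerance = 1e-8)
})

test_that("a noiseless ramp effect is recovered exactly", {
  y <- 10 + 0.2 * build_volume_ramp()
  fit <- fit_its(y, xreg = cbind(volume_ramp = build_volume_ramp()),
                 orders = its_orders())
  ramp <- its_coef(fit, "volume_ramp")
  expect_equal(ramp$estimate, 0.2, tolerance = 1e-6)
  expect_lt(ramp$p_value, 1e-10)
  expect_true(ramp$significant)
})

test_that("coefficient table satisfies the CI and significance invariants", {
  set.seed(52)
  X <- volume_regressors()
  y <- 50 + 0.1 * (1:60) + 0.2 * X[, "volume_ramp"] +
    as.numeric(arima.sim(list(ar = 0.5), 60, sd = 1.5))
  fit <- fit_its(y, xreg = X, orders = its_orders(1, 0, 0))
  cf <- fit$coefficients
  expect_equal(cf$ci_high - cf$estimate, 1.96 * cf$se)
  expect_equal(cf$estimate - cf$ci_low, 1.96 * cf$se)
  expect_identical(cf$significant, cf$p_value < 0.05)
  expect_setequal(c("ar1", "intercept", "trend", "volume_pulse",
                    "volume_ramp"), cf$term)
  expect_length(fit$residuals, 60L)
})

test_that("user-specified orders bypass the search and are echoed", {
  set.seed(53)
  y <- rnorm(60)
  ord <- its_orders(2, 0, 1, 1, 0, 0)
  fit <- fit_its(y, xreg = volume_regressors(), orders = ord)
  expect_identical(fit$orders$order, c(2L, 0L, 1L))
  expect_identical(fit$orders$seasonal, c(1L, 0L, 0L))
})

test_that("collinear regressors raise a design error naming the column", {
  X <- cbind(volume_ramp = build_volume_ramp(),
             ramp_copy = build_volume_ramp())
  expect_error(fit_its(rnorm(60), xreg = X, orders = its_orders()),
               "rank-deficient design.*ramp_copy")
})

test_that("order search keeps the null model for white noise in >= 90% of replicates", {
  set.seed(54)
  X <- volume_regressors()
  hits <- 0L
  for (i in 1:100) {
    o <- select_orders(rnorm(60), xreg = X)
    if (all(o$order == 0L) && all(o$seasonal == 0L)) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("order search reacts to a deterministic seasonal cycle", {
  set.seed(55)
  X <- volume_regressors()
  ok <- 0L
  for (i in 1:10) {
    y <- 10 * sin(2 * pi * (1:60) / 12) + rnorm(60)
    o <- select_orders(y, xreg = X)
    if (o$seasonal[2] == 1L || sum(o$seasonal[c(1, 3)]) > 0L) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("KPSS statistic matches an independent reference implementation", {
  # expected values computed once with statsmodels.tsa.stattools.kpss
  # (regression "c" / "ct", nlags = 3) on this seeded vector
  set.seed(42)
  x <- round(rnorm(60), 6)
  kl <- kpss_test(x, "level")
  kt <- kpss_test(x, "trend")
  expect_equal(kl$statistic, 0.1847145515, tolerance = 1e-8)
  expect_equal(kt$statistic, 0.0971915648, tolerance = 1e-8)
  expect_equal(kl$lags, 3L)
})

test_that("KPSS p-values interpolate the critical-value table and clamp outside it", {
  # a statistic equal to a tabulated critical value maps to its level
  x <- rnorm(64)
  k <- kpss_test(x, "level")
  expect_true(k$p_value >= 0.01 && k$p_value <= 0.10)
  # strongly trending series: statistic beyond the table, clamped at 0.01
  trendy <- cumsum(rep(1, 60)) + rnorm(60, sd = 0.01)
  k2 <- kpss_test(trendy, "level")
  expect_equal(k2$p_value, 0.01)
  expect_true(k2$p_clamped)
})

test_that("diagnostics are deterministic and evaluated at the 0.05 level", {
  set.seed(56)
  res <- rnorm(48)
  d1 <- diagnose(res)
  d2 <- diagnose(res)
  expect_identical(d1$statistic, d2$statistic)
  expect_identical(d1$p_value, d2$p_value)
  expect_identical(d1$pass, d1$p_value >= 0.05)
  expect_identical(d1$test, c("ljung_box", "kpss_level", "kpss_trend"))
})

test_that("diagnostics flag autocorrelated and trending residuals", {
  set.seed(57)
  ar9 <- as.numeric(arima.sim(list(ar = 0.9), 60))
  d_ar <- diagnose(ar9)
  expect_false(d_ar$pass[d_ar$test == "ljung_box"])

  trended <- rnorm(60, sd = 0.5) + 0.3 * (1:60)
  d_tr <- diagnose(trended)
  expect_false(d_tr$pass[d_tr$test == "kpss_level"])
})

test_that("too-short residual vectors are rejected", {
  expect_error(diagnose(rnorm(12)), "longer than the Ljung-Box lag")
  expect_error(ljung_box(rnorm(10)), "more residuals than the maximum lag")
})

test_that("fit summaries export one CSV row per coefficient", {
  set.seed(58)
  fit <- fit_its(rnorm(60) + 30, xreg = volume_regressors(),
                 orders = its_orders())
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_summary(fit, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(fit$coefficients))
  expect_true(all(c("term", "estimate", "se", "z", "p_value", "ci_low",
                    "ci_high") %in% names(back)))
})
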