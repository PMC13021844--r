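# Published worked examples used below (observed value; significant monthly
# rate with 95% CI; expected middle/low/high and share): Germany, Slovenia,
# Scotland and Wales volumes, and the stratified incidence rows.

volume_rows <- tibble::tibble(
  label = c("germany", "slovenia", "scotland", "wales"),
  observed = c(58.070, 70.229, 176.800, 188.200),
  estimate = c(0.101, 0.227, -0.225, -0.678),
  ci_low = c(0.050, 0.154, -0.311, -1.335),
  ci_high = c(0.152, 0.300, -0.139, -0.021),
  middle = c(3.131, 7.037, -6.975, -21.018),
  share = c(5.4, 10.0, -3.9, -11.2)
)
# low/high cells are printed from unrounded CIs, so only the CI-times-31
# identity is asserted for them, not the printed decimals

test_that("volume attribution reproduces the published end-of-period arithmetic", {
  for (i in seq_len(nrow(volume_rows))) {
    row <- volume_rows[i, ]
    a <- volume_attribution(
      list(estimate = row$estimate, ci_low = row$ci_low,
           ci_high = row$ci_high, significant = TRUE),
      observed_dec2022 = row$observed)
    expect_true(a$computed)
    expect_equal(round(a$middle, 3), row$middle)
    expect_equal(a$low, row$ci_low * 31)
    expect_equal(a$high, row$ci_high * 31)
    expect_equal(round(a$share_pct, 1), row$share)
    expect_true(a$low <= a$middle && a$middle <= a$high)
    expect_equal(sign(a$share_pct), sign(a$middle))
  }
})

test_that("a non-significant monthly rate yields no attribution and dashes", {
  a <- volume_attribution(
    list(estimate = -0.008, ci_low = -0.071, ci_high = 0.055,
         p_value = 0.8),
    observed_dec2022 = 27.420)
  expect_false(a$computed)
  expect_true(is.na(a$middle) && is.na(a$low) && is.na(a$high))
  tab <- attribution_table(a, labels = "croatia")
  expect_equal(tab$middle, "-")
  expect_equal(tab$share_pct, "-")
})

test_that("incidence attribution sums only significant regressor contributions", {
  cf <- tibble::tibble(
    term = c("incidence_pulse", "incidence_ramp_plateau",
             "incidence_ramp_2022"),
    estimate = c(-20, 1.0, 0.5),
    ci_low = c(-30, 0.6, -0.1),
    ci_high = c(-10, 1.4, 1.1),
    significant = c(TRUE, TRUE, FALSE)
  )
  a <- incidence_attribution(cf, observed_total = 1000)
  expect_equal(a$middle, -20 * 3 + 1.0 * 418)
  expect_equal(a$low, -30 * 3 + 0.6 * 418)
  expect_equal(a$high, -10 * 3 + 1.4 * 418)
  expect_equal(a$share_pct, a$middle / 1000 * 100)
  expect_identical(a$terms_used, c("incidence_pulse", "incidence_ramp_plateau"))

  cf$significant <- FALSE
  a0 <- incidence_attribution(cf, observed_total = 1000)
  expect_false(a0$computed)
})

test_that("incidence share arithmetic matches the published stratified table", {
  rows <- tibble::tibble(
    label = c("lombardy_f", "croatia_f", "finland_f", "sweden_f", "germany_m"),
    observed = c(533.6, 953.9, 3275.9, 2353.4, 552.8),
    middle = c(295.8, 361.2, 815.7, 259.5, -11.1),
    share = c(55.4, 37.9, 24.9, 11.0, -2.0)
  )
  expect_equal(round(share_of_observed(rows$middle, rows$observed), 1),
               rows$share)
})

test_that("noiseless synthetic effects are attributed exactly", {
  reg <- build_incidence_regressors()
  beta <- c(pulse = -15, plateau = 0.8, r2022 = 0.4)
  y <- 100 + 0.1 * (1:60) + beta["pulse"] * reg$incidence_pulse +
    beta["plateau"] * reg$incidence_ramp_plateau +
    beta["r2022"] * reg$incidence_ramp_2022
  fit <- fit_its(y, xreg = reg, orders = its_orders(), outcome = "incidence")
  a <- incidence_attribution(fit, observed_total = 5000)
  expect_equal(a$middle,
               unname(beta["pulse"] * 3 + beta["plateau"] * 418 +
                        beta["r2022"] * 78),
               tolerance = 1e-6)

  ramp <- build_volume_ramp()
  yv <- 50 + 0.05 * (1:60) + 0.2 * ramp
  fv <- fit_its(yv, xreg = cbind(volume_ramp = ramp), orders = its_orders())
  av <- volume_attribution(fv, observed_dec2022 = 60)
  expect_equal(av$middle, 0.2 * 31, tolerance = 1e-6)
})

test_that("attribution is monotone in a significant coefficient", {
  base <- list(estimate = 0.2, ci_low = 0.1, ci_high = 0.3,
               significant = TRUE)
  shifted <- list(estimate = 0.25, ci_low = 0.15, ci_high = 0.35,
                  significant = TRUE)
  a1 <- volume_attribution(base, observed_dec2022 = 100)
  a2 <- volume_attribution(shifted, observed_dec2022 = 100)
  expect_equal(a2$middle - a1$middle, 0.05 * 31)
  expect_equal(a2$low - a1$low, 0.05 * 31)
})

test_that("the low-high range may straddle zero and observed must be positive", {
  cf <- tibble::tibble(
    term = c("incidence_pulse", "incidence_ramp_plateau",
             "incidence_ramp_2022"),
    estimate = c(-20, 0.2, 0), ci_low = c(-30, 0.01, -1),
    ci_high = c(-10, 0.39, 1), significant = c(TRUE, TRUE, FALSE)
  )
  a <- incidence_attribution(cf, observed_total = 800)
  expect_lt(a$low, 0)
  expect_gt(a$high, 0)
  expect_error(volume_attribution(
    list(estimate = 1, ci_low = 0.5, ci_high = 1.5, significant = TRUE),
    observed_dec2022 = 0), "positive")
  expect_error(incidence_attribution(cf, observed_total = -5), "positive")
  expect_error(share_of_observed(10, 0), "positive")
})
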