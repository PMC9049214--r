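# deterministic 30-month fixture used for the frozen HAC/diagnostic checks
its_fixture <- function() {
  t <- 0:29
  y <- 10 - 0.1 * t - 1.5 * (t >= 15) + 0.2 * pmax(0, t - 14) +
    0.8 * sin(1:30)
  as_monthly_series(tibble::tibble(
    month = seq(as.Date("2017-06-01"), by = "month", length.out = 30),
    value = y
  ))
}

test_that("monthly aggregation produces a gap-free indexed series", {
  vs <- assemble_visits(
    dplyr::bind_rows(
      make_rx(pat = sprintf("P%d", 1:10), date = "2019-01-15"),
      make_rx(pat = sprintf("Q%d", 1:5), date = "2019-03-10",
              code = "C09AA01", name = "enalapril")
    ),
    make_dx(pat = sprintf("R%d", 1:90), date = "2019-01-20")
  )
  s <- suppressMessages(aggregate_monthly(vs, outcome = "rx_rate"))
  # Jan..Mar 2019, no gaps, 10 antibiotic visits of 100 in January
  expect_equal(nrow(s), 3)
  expect_equal(s$t0, 0:2)
  expect_equal(s$value[1], 10)
  # February has no visits at all -> flagged missing
  expect_equal(s$denominator[2], 0)
  expect_true(is.na(s$value[2]))
  # March visits carry only a non-antibiotic drug -> rate 0
  expect_equal(s$value[3], 0)
})

test_that("a 50-month synthetic stream yields a 50-month series", {
  sim <- simulate_dataset(small_sim_config(seed = 2))
  vs <- assemble_visits(sim$prescriptions, sim$diagnoses, sim$patients,
                        sim$physicians, sim$institutions)
  s <- aggregate_monthly(vs, outcome = "rx_rate")
  expect_equal(nrow(s), 50)
  expect_equal(range(s$month),
               as.Date(c("2017-06-01", "2021-07-01")))
  # stratified numerators add up to the overall series
  urban <- vs
  urban$visits <- urban$visits[urban$visits$institution_area_type == "urban", ]
  urban$prescriptions <- urban$prescriptions[
    urban$prescriptions$visit_id %in% urban$visits$visit_id, ]
  rural <- vs
  rural$visits <- rural$visits[rural$visits$institution_area_type == "rural", ]
  rural$prescriptions <- rural$prescriptions[
    rural$prescriptions$visit_id %in% rural$visits$visit_id, ]
  su <- aggregate_monthly(urban, outcome = "rx_rate")
  sr <- aggregate_monthly(rural, outcome = "rx_rate")
  expect_equal(su$numerator + sr$numerator, s$numerator)
  expect_equal(su$denominator + sr$denominator, s$denominator)
})

test_that("classical decomposition recovers injected seasonality", {
  months <- seq(as.Date("2017-06-01"), by = "month", length.out = 48)
  moy <- as.integer(format(months, "%m"))
  inject <- 3 * cos(2 * pi * (1:12 - 1) / 12)
  inject <- inject - mean(inject)
  base <- 20 - 0.1 * 0:47
  s <- as_monthly_series(tibble::tibble(month = months,
                                        value = base + inject[moy]))
  sa <- seasonal_adjust(s)
  expect_equal(sum(sa$seasonal$s), 0, tolerance = 1e-9)
  expect_equal(sa$seasonal$s, inject, tolerance = 0.05)
  # additivity: adjusted + seasonal reconstructs raw exactly
  expect_equal(sa$adjusted$value + sa$seasonal$s[moy], sa$adjusted$raw,
               tolerance = 1e-12)
  # pure line -> all factors ~ 0 and adjusted ~ raw
  flat <- as_monthly_series(tibble::tibble(month = months, value = base))
  sa0 <- seasonal_adjust(flat)
  expect_lt(max(abs(sa0$seasonal$s)), 1e-9)
  expect_equal(sa0$adjusted$value, base, tolerance = 1e-9)
  expect_error(seasonal_adjust(as_monthlies <- s[1:20, ]), "24 months")
})

test_that("noiseless segmented series is interpolated exactly", {
  s <- simulate_monthly_series(sd = 0)
  f <- fit_segmented(s)
  expect_equal(f$coefficients$estimate[1:4], c(20, -0.2, -2.8, 0.3),
               tolerance = 1e-10)
  expect_equal(f$coefficients$estimate[5], 0.1, tolerance = 1e-10)
  expect_equal(unname(fitted(f$lm_fit)), s$value, tolerance = 1e-10)
  # null generator: level/slope changes near zero
  set.seed(4)
  s0 <- simulate_monthly_series(beta = c(20, -0.2, 0, 0), sd = 0.5)
  f0 <- fit_segmented(s0)
  expect_lt(abs(f0$coefficients$estimate[3]), 1.5)
  expect_lt(abs(f0$coefficients$estimate[4]), 0.3)
})

test_that("segmented OLS equals the normal-equation solution", {
  f <- fit_segmented(its_fixture(), interruption = "2018-09")
  X <- f$design
  y <- f$series$value
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(f$coefficients$estimate[1:4], as.vector(beta_oracle),
               tolerance = 1e-10)
  # frozen coefficients (independent reference implementation)
  expect_equal(f$coefficients$estimate[1:4],
               c(10.092667588, -0.0984901318, -1.5423210842, 0.2040193927),
               tolerance = 1e-8)
})

test_that("Newey-West covariance matches the frozen reference and limits", {
  f <- fit_segmented(its_fixture(), interruption = "2018-09", hac_lag = 3)
  # frozen HAC standard errors at L = 3 (reference: statsmodels cov_hac)
  expect_equal(f$coefficients$se[1:4],
               c(0.3163384909, 0.0388084239, 0.4899078307, 0.0492002646),
               tolerance = 1e-8)
  # L = 0 reduces to the White heteroskedasticity-only covariance
  f0 <- fit_segmented(its_fixture(), interruption = "2018-09", hac_lag = 0)
  expect_equal(f0$coefficients$se[1:4],
               c(0.2796284861, 0.0330238419, 0.3896250997, 0.0464449523),
               tolerance = 1e-8)
  # default lag rule: T = 50 -> L = 3
  expect_equal(fit_segmented(simulate_monthly_series(sd = 0))$hac_lag, 3)
  # i.i.d. homoskedastic noise, lag-zero limit: HAC SEs match the
  # classical OLS SEs up to sampling noise (at positive lags the Bartlett
  # weighting biases the SEs of this design downward; see the vignette)
  set.seed(8)
  ratio <- replicate(100, {
    s <- simulate_monthly_series(rho = 0, sd = 1)
    f <- fit_segmented(s, hac_lag = 0)
    ols_se <- sqrt(diag(vcov(f$lm_fit)))[3]
    f$coefficients$se[3] / ols_se
  })
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("Durbin-Watson behaves at its limit cases", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)     # 12 / 4
  expect_equal(durbin_watson(rep(2, 10)), 0)          # perfect + correlation
  set.seed(12)
  d <- mean(replicate(200, durbin_watson(rnorm(100))))
  expect_equal(d, 2, tolerance = 0.1)                 # white noise
  expect_warning(out <- durbin_watson(rep(0, 5)), "undefined")
  expect_true(is.na(out))
  f <- fit_segmented(its_fixture(), interruption = "2018-09")
  expect_equal(f$durbin_watson, 0.8307756578, tolerance = 1e-8)
})

test_that("serial-correlation score test matches the frozen reference", {
  f <- fit_segmented(its_fixture(), interruption = "2018-09")
  ch <- cumby_huizinga_test(f, lags = 1:2)
  expect_equal(ch$statistic, c(9.4082729454, 28.8873869053),
               tolerance = 1e-7)
  expect_equal(ch$p_value, c(0.0021600859, 0.0000005336), tolerance = 1e-6)
  # hand evaluation of T * R^2 on a 6-point fixture at q = 1
  y6 <- c(1, 3, 2, 5, 4, 6)
  fit6 <- lm(y6 ~ seq_along(y6))
  e <- residuals(fit6)
  Z <- cbind(1, seq_along(y6), c(0, e[-6]))
  aux <- lm.fit(Z, e)
  r2 <- 1 - sum(aux$residuals^2) / sum((e - mean(e))^2)
  got <- cumby_huizinga_test(fit6, lags = 1)
  expect_equal(got$statistic, 6 * r2, tolerance = 1e-12)
})
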