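# Interrupted time-series machinery: monthly outcome series, classical
# additive seasonal adjustment, segmented OLS with Newey-West (HAC) errors,
# and autocorrelation diagnostics.

first_of_month <- function(x) as.Date(format(as.Date(x), "%Y-%m-01"))

month_diff <- function(a, b) {
  # whole months from b to a
  a <- as.POSIXlt(first_of_month(a)); b <- as.POSIXlt(first_of_month(b))
  (a$year - b$year) * 12L + (a$mon - b$mon)
}

#' Build a monthly outcome series
#'
#' Aggregates classified visits into a gap-free monthly series of either the
#' antibiotic prescription rate (antibiotic-prescribing visits / all visits,
#' percent) or the proportion of inappropriate prescriptions (inappropriate /
#' antibiotic-prescribing visits, percent). Months with a zero denominator
#' are kept in the series with `value` `NA`, flagged, and excluded from any
#' downstream fit.
#'
#' @param vs A `visit_set` (needed for `outcome = "rx_rate"`).
#' @param records Appropriateness records from
#'   [assign_visit_appropriateness()] (needed for
#'   `outcome = "inappropriate_prop"`; for `rx_rate` the numerator is taken
#'   from antibiotic items directly).
#' @param outcome `"rx_rate"` or `"inappropriate_prop"`.
#' @param catalog Antibiotic catalogue (used for `rx_rate`).
#' @return A `monthly_series`: tibble with `month` (first-of-month `Date`),
#'   `t0` (0-based month index from the first month), `numerator`,
#'   `denominator`, `value` (percent).
#' @export
aggregate_monthly <- function(vs = NULL, records = NULL,
                              outcome = c("rx_rate", "inappropriate_prop"),
                              catalog = load_antibiotic_catalog()) {
  outcome <- match.arg(outcome)
  if (outcome == "rx_rate") {
    stopifnot(inherits(vs, "visit_set"))
    items <- classify_antibiotics(vs$prescriptions, catalog)
    v <- vs$visits
    v$has_abx <- v$visit_id %in% items$visit_id
    num_dat <- v[v$has_abx, "visit_date"]
    den_dat <- v["visit_date"]
  } else {
    stopifnot(!is.null(records))
    num_dat <- records[records$appropriateness == "inappropriate",
                       "visit_date"]
    den_dat <- records["visit_date"]
  }
  months <- seq(min(first_of_month(den_dat$visit_date)),
                max(first_of_month(den_dat$visit_date)), by = "month")
  cnt <- function(d) {
    as.integer(table(factor(format(d$visit_date, "%Y-%m-01"),
                            levels = format(months, "%Y-%m-01"))))
  }
  out <- tibble::tibble(
    month = months,
    t0 = seq_along(months) - 1L,
    numerator = cnt(num_dat),
    denominator = cnt(den_dat)
  )
  out$value <- ifelse(out$denominator > 0,
                      100 * out$numerator / out$denominator, NA_real_)
  n_empty <- sum(out$denominator == 0)
  if (n_empty > 0) {
    message(n_empty, " month(s) with zero denominator flagged missing")
  }
  class(out) <- c("monthly_series", class(out))
  out
}

#' Coerce a data frame to a monthly series
#'
#' @param df Tibble with at least `month` (Date) and `value`; `t0`,
#'   `numerator`, `denominator` are filled if absent.
#' @return A `monthly_series`.
#' @export
as_monthly_series <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("month", "value") %in% names(df)))
  df$month <- first_of_month(df$month)
  if (!"t0" %in% names(df)) df$t0 <- month_diff(df$month, df$month[1])
  if (!"numerator" %in% names(df)) df$numerator <- NA_integer_
  if (!"denominator" %in% names(df)) df$denominator <- NA_integer_
  class(df) <- c("monthly_series", class(df))
  df
}

#' Classical additive seasonal adjustment
#'
#' Decomposes the monthly series additively: the trend is a 2x12 centered
#' moving average, the seasonal factor of calendar month m is the mean
#' detrended value of that month, re-centered so the twelve factors sum to
#' zero, and the adjusted series is raw minus the seasonal factor — so
#' adjusted + seasonal reconstructs the raw series exactly. This is the
#' classical stand-in for the X-12-ARIMA seasonal adjustment used with the
#' original data.
#'
#' @param series A `monthly_series` of at least 24 months with no missing
#'   values.
#' @return A `seasonal_adjustment`: list with `seasonal` (tibble
#'   `month_of_year, s` with `sum(s) == 0`), `adjusted` (a `monthly_series`
#'   with the adjusted values; the raw series is kept in column `raw`),
#'   and `trend` (centered moving average, `NA` at the ends).
#' @export
seasonal_adjust <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  if (nrow(series) < 24) {
    abort_abx("seasonal adjustment requires at least 24 months, got ",
              nrow(series))
  }
  if (anyNA(series$value)) {
    abort_abx("seasonal adjustment requires a complete series; ",
              "months flagged missing must be handled first")
  }
  start_year <- as.integer(format(series$month[1], "%Y"))
  start_mon <- as.integer(format(series$month[1], "%m"))
  x <- stats::ts(series$value, frequency = 12,
                 start = c(start_year, start_mon))
  dec <- stats::decompose(x, type = "additive")
  # dec$figure is indexed from the series start month; map to Jan..Dec
  s <- numeric(12)
  s[((start_mon - 1 + 0:11) %% 12) + 1] <- dec$figure
  moy <- as.integer(format(series$month, "%m"))
  adjusted <- series
  adjusted$raw <- series$value
  adjusted$value <- series$value - s[moy]
  structure(
    list(
      seasonal = tibble::tibble(month_of_year = 1:12, s = s),
      adjusted = adjusted,
      trend = as.numeric(dec$trend)
    ),
    class = "seasonal_adjustment"
  )
}

#' Segmented (interrupted time-series) regression
#'
#' Fits by ordinary least squares the segmented model
#' \deqn{Y_t = \beta_0 + \beta_1 t_0 + \beta_2 Intv_t + \beta_3 taft_t +
#'   \epsilon_t}
#' where `Intv` is 0 before the interruption month and 1 from it on, and
#' `taft` counts months elapsed since the interruption (0 at and before the
#' interruption month, then 1, 2, ...). `beta2` is therefore the immediate
#' level change at the interruption and `beta1 + beta3` the post-period
#' trend. Standard errors are Newey-West HAC with Bartlett weights; the
#' default lag is `floor(4 (T/100)^{2/9})`.
#'
#' @param series A `monthly_series` (seasonally adjusted or raw); months
#'   with `NA` values are dropped from the fit with a message.
#' @param interruption Interruption month, e.g. `"2020-03"` (any value
#'   [as.Date()] accepts after appending `"-01"`). Default March 2020.
#' @param hac_lag Newey-West lag `L`; `NULL` for the default rule.
#' @param alpha Error level for the confidence intervals.
#' @return An `its_fit`: list with `coefficients` (tibble of `term,
#'   estimate, se, ci_low, ci_high, p` for beta0-beta3 and the derived
#'   post-period trend `trend_after`), `hac_lag`, `vcov_hac`,
#'   `durbin_watson`, plus the underlying `lm` fit, design matrix, residuals
#'   and the series.
#' @export
fit_segmented <- function(series, interruption = "2020-03",
                          hac_lag = NULL, alpha = 0.05) {
  stopifnot(inherits(series, "monthly_series"))
  intr <- first_of_month(paste0(substr(as.character(interruption), 1, 7),
                                "-01"))
  dat <- series[!is.na(series$value), , drop = FALSE]
  if (nrow(dat) < nrow(series)) {
    message(nrow(series) - nrow(dat), " missing month(s) dropped from fit")
  }
  rel <- month_diff(dat$month, intr)
  dat$intv <- as.integer(rel >= 0)
  dat$taft <- pmax(0L, rel)
  if (sum(dat$intv == 0) < 4 || sum(dat$intv == 1) < 4) {
    abort_abx("need at least 4 observations on each side of the interruption")
  }
  fit <- stats::lm(value ~ t0 + intv + taft, data = dat)
  X <- stats::model.matrix(fit)
  if (qr(X)$rank < ncol(X)) abort_abx("rank-deficient segmented design")
  e <- stats::residuals(fit)
  T_ <- length(e)
  L <- hac_lag %||% floor(4 * (T_ / 100)^(2 / 9))
  V <- newey_west_cov(fit, L = L)
  b <- stats::coef(fit)
  se <- sqrt(diag(V))
  # derived post-period trend beta1 + beta3 with HAC variance
  a <- c(0, 1, 0, 1)
  b_after <- sum(a * b)
  se_after <- sqrt(drop(t(a) %*% V %*% a))
  z <- stats::qnorm(1 - alpha / 2)
  est <- c(b, trend_after = b_after)
  ses <- c(se, trend_after = se_after)
  coefs <- tibble::tibble(
    term = c("level", "trend_before", "level_change", "slope_change",
             "trend_after"),
    estimate = unname(est), se = unname(ses),
    ci_low = unname(est - z * ses), ci_high = unname(est + z * ses),
    p = unname(2 * stats::pnorm(-abs(est / ses)))
  )
  structure(
    list(coefficients = coefs, hac_lag = L, vcov_hac = V,
         durbin_watson = durbin_watson(e),
         lm_fit = fit, design = X, residuals = e, series = dat,
         interruption = intr, alpha = alpha),
    class = "its_fit"
  )
}

#' @export
print.its_fit <- function(x, ...) {
  cat("<its_fit> segmented regression, interruption ",
      format(x$interruption, "%Y-%m"), ", T = ", length(x$residuals),
      ", HAC lag ", x$hac_lag, "\n", sep = "")
  co <- x$coefficients
  cat(paste0(
    format(co$term, width = 14), format_pct(co$estimate, 2), " (",
    format_pct(co$ci_low, 2), " to ", format_pct(co$ci_high, 2), ")"
  ), sep = "\n")
  cat("Durbin-Watson d =", format(x$durbin_watson, digits = 3), "\n")
  invisible(x)
}

#' Newey-West HAC covariance of regression coefficients
#'
#' Sandwich covariance robust to heteroskedasticity and autocorrelation:
#' Bartlett weights `w_l = 1 - l/(L+1)` applied to the lag-l residual
#' cross-product terms. With `L = 0` it reduces to the White
#' heteroskedasticity-only estimator. No small-sample degrees-of-freedom
#' correction is applied.
#'
#' @param fit An `lm` or `its_fit` object.
#' @param L Maximum lag `>= 0`; `NULL` for `floor(4 (T/100)^{2/9})`.
#' @return The HAC covariance matrix of the coefficients.
#' @export
newey_west_cov <- function(fit, L = NULL) {
  if (inherits(fit, "its_fit")) fit <- fit$lm_fit
  X <- stats::model.matrix(fit)
  e <- stats::residuals(fit)
  T_ <- length(e)
  L <- L %||% floor(4 * (T_ / 100)^(2 / 9))
  stopifnot(L >= 0, L < T_)
  Xe <- X * e
  M <- crossprod(Xe)
  if (L > 0) {
    for (l in seq_len(L)) {
      w <- 1 - l / (L + 1)
      G <- crossprod(Xe[(l + 1):T_, , drop = FALSE],
                     Xe[1:(T_ - l), , drop = FALSE])
      M <- M + w * (G + t(G))
    }
  }
  XtXinv <- solve(crossprod(X))
  V <- XtXinv %*% M %*% XtXinv
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Durbin-Watson statistic
#'
#' `d = sum((e_t - e_{t-1})^2) / sum(e_t^2)`, in `[0, 4]`; values near 2
#' indicate no first-order autocorrelation, near 0 strong positive, near 4
#' strong negative autocorrelation.
#'
#' @param x Residual vector, or an `lm`/`its_fit` object.
#' @return The statistic (scalar); `NA` with a warning if all residuals are
#'   zero.
#' @export
durbin_watson <- function(x) {
  if (inherits(x, "its_fit")) x <- x$residuals
  if (inherits(x, "lm")) x <- stats::residuals(x)
  if (length(x) < 2) abort_abx("need at least 2 residuals")
  denom <- sum(x^2)
  if (denom == 0) {
    warning("all residuals are zero; Durbin-Watson undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(diff(x)^2) / denom
}

#' Serial-correlation score test of the regression errors
#'
#' Tests zero autocorrelation of the error terms at lags 1..q by the
#' auxiliary regression of the residuals on the original regressors plus q
#' lagged residuals (pre-sample lags set to zero); the statistic is
#' `T * R^2`, referred to chi-square with q degrees of freedom. This is the
#' Breusch-Godfrey special case of the Cumby-Huizinga test under an i.i.d.
#' null.
#'
#' @param fit An `lm` or `its_fit` object.
#' @param lags Vector of maximum lags q to test (each entry gives one
#'   cumulative test of lags 1..q). `q < T/4` required.
#' @return Tibble of `lag, statistic, df, p_value`.
#' @export
cumby_huizinga_test <- function(fit, lags = 1) {
  if (inherits(fit, "its_fit")) fit <- fit$lm_fit
  X <- stats::model.matrix(fit)
  e <- stats::residuals(fit)
  T_ <- length(e)
  stopifnot(all(lags >= 1), all(lags < T_ / 4))
  one <- function(q) {
    Z <- sapply(seq_len(q), function(l) c(rep(0, l), e[1:(T_ - l)]))
    aux <- stats::lm.fit(cbind(X, Z), e)
    r2 <- 1 - sum(aux$residuals^2) / sum((e - mean(e))^2)
    stat <- T_ * r2
    tibble::tibble(lag = q, statistic = stat, df = q,
                   p_value = stats::pchisq(stat, df = q, lower.tail = FALSE))
  }
  dplyr::bind_rows(lapply(lags, one))
}
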