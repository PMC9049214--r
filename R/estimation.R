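# Rate and proportion estimation: Clopper-Pearson exact binomial intervals,
# Goodman simultaneous multinomial intervals, diagnosis-spectrum direct
# standardization, and random-intercept logistic odds ratios.

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval obtained by inverting the binomial tails: the lower
#' bound is the `alpha/2` quantile of Beta(x, n-x+1) (0 when x = 0) and the
#' upper bound the `1-alpha/2` quantile of Beta(x+1, n-x) (1 when x = n).
#' The method is conservative: coverage is at least the nominal level for
#' every (n, p).
#'
#' @param x Success count(s), `0 <= x <= n`.
#' @param n Trial count(s), `n >= 1`; recycled against `x`.
#' @param alpha Nominal two-sided error level (default 0.05).
#' @return Tibble with `x, n, rate, ci_low, ci_high` (percent scale),
#'   `alpha` and `method`.
#' @examples
#' clopper_pearson_ci(32, 323)   # 9.9% (6.9-13.7)
#' @export
clopper_pearson_ci <- function(x, n, alpha = 0.05) {
  if (any(n < 1)) abort_abx("rate undefined: n must be >= 1")
  if (any(x < 0 | x > n)) abort_abx("x must satisfy 0 <= x <= n")
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  tibble::tibble(
    x = x, n = n,
    rate = 100 * x / n,
    ci_low = 100 * lower, ci_high = 100 * upper,
    alpha = alpha, method = "clopper_pearson"
  )
}

#' Goodman simultaneous confidence intervals for multinomial proportions
#'
#' Simultaneous intervals covering all k category proportions jointly with
#' probability at least 1 - alpha, using the Bonferroni-adjusted chi-square
#' critical value A = qchisq(1 - alpha/k, df = 1) of Goodman (1965). Each
#' category's bounds are the roots of the quadratic
#' (n + A) p^2 - (2 x + A) p + x^2 / n = 0.
#'
#' @param counts Integer vector of k >= 2 category counts.
#' @param alpha Simultaneous error level (default 0.05).
#' @return Tibble with `count, proportion, ci_low, ci_high` (proportion
#'   scale, 0-1); the critical value and k are attached as attributes
#'   `A` and `k`.
#' @examples
#' goodman_ci(c(171056, 463081, 653335, 206))
#' @export
goodman_ci <- function(counts, alpha = 0.05) {
  k <- length(counts)
  if (k < 2) abort_abx("Goodman intervals require k >= 2 categories")
  if (any(counts < 0)) abort_abx("counts must be nonnegative")
  n <- sum(counts)
  if (n < 1) abort_abx("total count must be >= 1")
  A <- stats::qchisq(1 - alpha / k, df = 1)
  x <- counts
  half <- sqrt(A * (A + 4 * x * (n - x) / n))
  out <- tibble::tibble(
    count = x,
    proportion = x / n,
    ci_low = (2 * x + A - half) / (2 * (n + A)),
    ci_high = (2 * x + A + half) / (2 * (n + A))
  )
  attr(out, "A") <- A
  attr(out, "k") <- k
  out
}

#' Directly standardized rate over a diagnostic spectrum
#'
#' Reweights stratum-specific category rates by a fixed standard population's
#' category distribution (here: the diagnostic spectrum of the whole
#' population over the whole period), removing case-mix differences between
#' strata. Categories of the standard absent from the stratum contribute
#' weight times zero and are flagged.
#'
#' @param stratum_rates Tibble with columns `category`, `x` (antibiotic
#'   visits) and `n` (all visits) for one stratum.
#' @param standard Tibble with columns `category` and `weight`; weights must
#'   sum to 1.
#' @param alpha Error level for the normal-approximation interval.
#' @return One-row tibble: `rate`, `se`, `ci_low`, `ci_high` (percent
#'   scale), and `n_missing_categories` (standard categories with no visits
#'   in the stratum). Missing categories are listed in the
#'   `"missing_categories"` attribute.
#' @export
standardized_rate <- function(stratum_rates, standard, alpha = 0.05) {
  if (abs(sum(standard$weight) - 1) > 1e-8) {
    abort_abx("standard population weights must sum to 1")
  }
  m <- dplyr::left_join(standard, stratum_rates, by = "category")
  missing <- m$category[is.na(m$n) | m$n == 0]
  m$x[is.na(m$x)] <- 0
  m$n[is.na(m$n)] <- 0
  r <- ifelse(m$n > 0, m$x / m$n, 0)
  v <- ifelse(m$n > 0, m$weight^2 * r * (1 - r) / m$n, 0)
  rate <- sum(m$weight * r)
  se <- sqrt(sum(v))
  z <- stats::qnorm(1 - alpha / 2)
  out <- tibble::tibble(
    rate = 100 * rate, se = 100 * se,
    ci_low = 100 * max(0, rate - z * se),
    ci_high = 100 * min(1, rate + z * se),
    n_missing_categories = length(missing)
  )
  attr(out, "missing_categories") <- missing
  out
}

#' Diagnostic-spectrum standard population
#'
#' Category weights of the whole population over the whole study period,
#' from the per-category visit counts.
#'
#' @param category_counts Tibble with columns `category` and `n`.
#' @return Tibble `category, weight` with weights summing to 1.
#' @export
standard_population <- function(category_counts) {
  tibble::tibble(
    category = category_counts$category,
    weight = category_counts$n / sum(category_counts$n)
  )
}

DEFAULT_OR_COVARIATES <- c(
  "institution_area_type", "institution_level",
  "patient_age_group", "patient_gender", "patient_payment", "year",
  "physician_age_group", "physician_gender", "physician_education"
)

DEFAULT_OR_REFERENCES <- c(
  institution_area_type = "rural", institution_level = "CHSS_VC",
  patient_age_group = "18-44", patient_gender = "male",
  patient_payment = "insurance", year = "2017",
  physician_age_group = "<30", physician_gender = "male",
  physician_education = "high_school_or_below"
)

#' Random-intercept logistic model for inappropriate prescribing
#'
#' Fits a binary logistic regression for the outcome "visit classified
#' inappropriate" (all other appropriateness categories, including
#' not-linked, combined into the non-event class) with a normal random
#' intercept per primary care institution, by maximum likelihood (Laplace
#' approximation via [lme4::glmer()]). Odds ratios are exponentiated fixed
#' effects with Wald 95% intervals; each covariate's reference level has
#' OR 1 by construction.
#'
#' @param records Output of [assign_visit_appropriateness()].
#' @param covariates Character vector of covariate columns; defaults to the
#'   full set of area type, institution level, patient age/gender/payment,
#'   visit year and physician age/gender/education. Covariates with fewer
#'   than two observed levels are dropped with a message.
#' @param group Grouping column for the random intercept
#'   (default `"institution_id"`).
#' @param references Named character vector of reference levels; defaults to
#'   rural, station/village-clinic level, patient 18-44/male/insurance,
#'   year 2017, physician <30/male/high-school-or-below.
#' @param alpha Error level for the Wald intervals.
#' @return An object of class `or_model`: list with `or_table` (tibble of
#'   `term, or, ci_low, ci_high, p`, reference rows with OR exactly 1),
#'   `sigma_u` (random-intercept SD) and `fit` (the `glmerMod` object).
#' @export
fit_inappropriate_or_model <- function(records,
                                       covariates = DEFAULT_OR_COVARIATES,
                                       group = "institution_id",
                                       references = DEFAULT_OR_REFERENCES,
                                       alpha = 0.05) {
  dat <- tibble::as_tibble(records)
  dat$.outcome <- as.integer(dat$appropriateness == "inappropriate")
  covariates <- intersect(covariates, names(dat))
  usable <- character(0)
  for (cv in covariates) {
    lv <- unique(stats::na.omit(dat[[cv]]))
    if (length(lv) < 2) {
      message("covariate '", cv, "' has <2 observed levels; dropped")
      next
    }
    f <- factor(dat[[cv]])
    ref <- unname(references[cv])
    if (!is.na(ref) && !is.null(ref) && ref %in% levels(f)) {
      f <- stats::relevel(f, ref = ref)
    }
    dat[[cv]] <- f
    usable <- c(usable, cv)
  }
  if (length(usable) == 0) abort_abx("no usable covariates")
  fml <- stats::as.formula(paste(
    ".outcome ~", paste(usable, collapse = " + "),
    "+ (1 |", group, ")"
  ))
  fit <- lme4::glmer(fml, data = dat, family = stats::binomial(),
                     nAGQ = 1L,
                     control = lme4::glmerControl(calc.derivs = FALSE))
  if (isTRUE(fit@optinfo$conv$opt != 0)) {
    abort_abx("random-intercept logistic fit did not converge: ",
              paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(1 - alpha / 2)
  est <- tibble::tibble(
    term = names(beta),
    or = unname(exp(beta)),
    ci_low = unname(exp(beta - z * se)),
    ci_high = unname(exp(beta + z * se)),
    p = unname(2 * stats::pnorm(-abs(beta / se))),
    reference = FALSE
  )
  refs <- dplyr::bind_rows(lapply(usable, function(cv) {
    tibble::tibble(term = paste0(cv, levels(dat[[cv]])[1]),
                   or = 1, ci_low = NA_real_, ci_high = NA_real_,
                   p = NA_real_, reference = TRUE)
  }))
  sigma_u <- sqrt(unname(lme4::VarCorr(fit)[[group]][1, 1]))
  structure(
    list(or_table = dplyr::bind_rows(est, refs), sigma_u = sigma_u,
         fit = fit),
    class = "or_model"
  )
}

#' @export
print.or_model <- function(x, ...) {
  cat("<or_model> random-intercept logistic regression\n")
  cat("institution random-intercept SD:", format(x$sigma_u, digits = 3),
      "\n\n")
  tbl <- x$or_table[!x$or_table$reference & x$or_table$term != "(Intercept)", ]
  cat(paste0(
    format(tbl$term, width = 30), "  OR ",
    format_pct(tbl$or, 2), " (", format_pct(tbl$ci_low, 2), "-",
    format_pct(tbl$ci_high, 2), ")"
  ), sep = "\n")
  invisible(x)
}
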