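test_that("Clopper-Pearson bounds invert the exact binomial tails", {
  # boundary behaviour
  expect_equal(clopper_pearson_ci(0, 10)$ci_low, 0)
  expect_equal(clopper_pearson_ci(10, 10)$ci_high, 100)
  expect_error(clopper_pearson_ci(1, 0), "n must be")
  expect_error(clopper_pearson_ci(5, 4), "0 <= x <= n")
  # tail-inversion oracle by bisection: upper bound U solves
  # P(X <= x | U) = alpha/2, lower bound L solves P(X >= x | L) = alpha/2
  x <- 5; n <- 20; alpha <- 0.05
  upper <- uniroot(function(p) pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  lower <- uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  ci <- clopper_pearson_ci(x, n, alpha)
  expect_equal(ci$ci_low / 100, lower, tolerance = 1e-8)
  expect_equal(ci$ci_high / 100, upper, tolerance = 1e-8)
})

test_that("interval widths shrink as n grows at fixed proportion", {
  ns <- c(20, 80, 320, 1280)
  cp_w <- sapply(ns, function(n) {
    ci <- clopper_pearson_ci(round(0.3 * n), n)
    ci$ci_high - ci$ci_low
  })
  expect_true(all(diff(cp_w) < 0))
  gm_w <- sapply(ns, function(n) {
    ci <- goodman_ci(c(round(0.3 * n), n - round(0.3 * n)))
    ci$ci_high[1] - ci$ci_low[1]
  })
  expect_true(all(diff(gm_w) < 0))
})

test_that("Goodman intervals solve the defining quadratic and behave at bounds", {
  expect_error(goodman_ci(5), "k >= 2")
  # degenerate category with all the mass
  ci <- goodman_ci(c(50, 0, 0))
  expect_lte(ci$ci_high[1], 1)
  expect_gt(ci$ci_low[1], 0)
  expect_equal(ci$ci_low[2], 0, tolerance = 1e-12)
  # k = 2: the two intervals are mirror images around complementarity
  two <- goodman_ci(c(60, 40))
  expect_equal(two$ci_low[1], 1 - two$ci_high[2], tolerance = 1e-10)
  expect_equal(two$ci_high[1], 1 - two$ci_low[2], tolerance = 1e-10)
  # root-finding oracle: bounds are where the per-category chi-square
  # statistic (x - np)^2 / (n p (1-p)) equals the critical value A
  set.seed(2)
  x <- as.vector(rmultinom(1, 500, c(0.4, 0.3, 0.2, 0.1)))
  n <- sum(x)
  ci <- goodman_ci(x)
  A <- attr(ci, "A")
  for (i in seq_along(x)) {
    stat <- function(p) (x[i] - n * p)^2 / (n * p * (1 - p)) - A
    phat <- x[i] / n
    lo <- uniroot(stat, c(1e-9, phat), tol = 1e-12)$root
    hi <- uniroot(stat, c(phat, 1 - 1e-9), tol = 1e-12)$root
    expect_equal(ci$ci_low[i], lo, tolerance = 1e-7)
    expect_equal(ci$ci_high[i], hi, tolerance = 1e-7)
  }
  expect_equal(sum(ci$proportion), 1)
})

test_that("standardized rates reweight the category mix correctly", {
  # constancy: identical category rates give back that rate
  st <- tibble::tibble(category = c("a", "b", "c"),
                       weight = c(0.5, 0.3, 0.2))
  rates <- tibble::tibble(category = c("a", "b", "c"),
                          x = c(10, 20, 40), n = c(100, 200, 400))
  out <- standardized_rate(rates, st)
  expect_equal(out$rate, 10)
  # 3-category toy by hand: 0.5*0.1 + 0.3*0.2 + 0.2*0.4 = 0.19
  rates2 <- tibble::tibble(category = c("a", "b", "c"),
                           x = c(10, 40, 160), n = c(100, 200, 400))
  expect_equal(standardized_rate(rates2, st)$rate, 19)
  # stratum spectrum equal to the standard -> standardized = crude
  rates3 <- tibble::tibble(category = c("a", "b", "c"),
                           x = c(13, 22, 9), n = c(500, 300, 200))
  st3 <- standard_population(tibble::tibble(category = c("a", "b", "c"),
                                            n = c(500, 300, 200)))
  crude <- 100 * sum(rates3$x) / sum(rates3$n)
  expect_equal(standardized_rate(rates3, st3)$rate, crude)
  # point estimate invariant to rescaling all stratum sizes
  rates4 <- rates3
  rates4$x <- rates4$x * 3; rates4$n <- rates4$n * 3
  expect_equal(standardized_rate(rates4, st3)$rate,
               standardized_rate(rates3, st3)$rate)
  # absent category contributes weight * 0 and is flagged
  out5 <- standardized_rate(rates3[1:2, ], st3)
  expect_equal(out5$n_missing_categories, 1)
  expect_equal(attr(out5, "missing_categories"), "c")
  expect_error(standardized_rate(rates3, dplyr::mutate(st3, weight = 2)),
               "sum to 1")
})

test_that("random-intercept logistic reduces to plain logistic when sigma_u = 0", {
  set.seed(31)
  n_inst <- 60; per <- 60
  dat <- tibble::tibble(
    institution_id = rep(sprintf("I%02d", 1:n_inst), each = per),
    grp = sample(c("a", "b"), n_inst * per, TRUE)
  )
  p <- plogis(-0.4 + log(2) * (dat$grp == "b"))
  dat$appropriateness <- factor(
    ifelse(runif(nrow(dat)) < p, "inappropriate", "appropriate"),
    levels = c("appropriate", "potentially_appropriate", "inappropriate",
               "not_linked")
  )
  m <- fit_inappropriate_or_model(dat, covariates = "grp",
                                  references = c(grp = "a"))
  glm_or <- exp(coef(glm(I(appropriateness == "inappropriate") ~ grp,
                         family = binomial(), data = dat))["grpb"])
  got <- m$or_table$or[m$or_table$term == "grpb"]
  expect_equal(got, unname(glm_or), tolerance = 0.02)
  # a zero variance component is estimated near (not at) the boundary
  expect_lt(m$sigma_u, 0.2)
  # reference level OR is exactly 1
  expect_equal(m$or_table$or[m$or_table$reference], 1)
})

test_that("random-intercept logistic recovers a generating OR at sigma_u 0.3", {
  set.seed(33)
  n_inst <- 150; per <- 80
  u <- rnorm(n_inst, 0, 0.3)
  dat <- tibble::tibble(
    institution_id = rep(sprintf("I%03d", 1:n_inst), each = per),
    grp = sample(c("a", "b"), n_inst * per, TRUE)
  )
  p <- plogis(-0.5 + log(1.5) * (dat$grp == "b") +
                u[rep(1:n_inst, each = per)])
  dat$appropriateness <- factor(
    ifelse(runif(nrow(dat)) < p, "inappropriate", "appropriate"),
    levels = levels(factor(c("appropriate", "potentially_appropriate",
                             "inappropriate", "not_linked")))
  )
  m <- fit_inappropriate_or_model(dat, covariates = "grp",
                                  references = c(grp = "a"))
  row <- m$or_table[m$or_table$term == "grpb", ]
  expect_gt(1.5, row$ci_low)
  expect_lt(1.5, row$ci_high)
  expect_equal(m$sigma_u, 0.3, tolerance = 0.35)
})
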