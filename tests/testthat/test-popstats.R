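test_that("exact binomial intervals reproduce the published small-count bounds", {
  expect_equal(round(100 * clopper_pearson(1, 5040)$upper, 2), 0.11)
  ci0 <- clopper_pearson(0, 5040)
  expect_equal(ci0$lower, 0)
  expect_equal(ci0$upper, 0.000732, tolerance = 1e-3)
  expect_equal(clopper_pearson(0, 123)$lower, 0)
  expect_equal(clopper_pearson(123, 123)$upper, 1)
  expect_error(clopper_pearson(5, 4), "\\[0, n\\]")
  expect_error(clopper_pearson(1, 0), "positive")
})

test_that("Beta-quantile intervals agree with binomial-CDF bisection to 1e-9", {
  grid_n <- c(1:40, 60, 100, 250, 500)
  for (n in grid_n) {
    xs <- unique(round(seq(0, n, length.out = min(n + 1, 12))))
    ci <- clopper_pearson(xs, n)
    for (i in seq_along(xs)) {
      oracle <- cp_bisect(xs[[i]], n)
      expect_equal(ci$lower[[i]], oracle[["lower"]], tolerance = 1e-9,
                   label = sprintf("lower x=%d n=%d", xs[[i]], n))
      expect_equal(ci$upper[[i]], oracle[["upper"]], tolerance = 1e-9,
                   label = sprintf("upper x=%d n=%d", xs[[i]], n))
    }
  }
})

test_that("interval containment and monotonicity hold", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:2000, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n)
    expect_lte(ci$lower, x / n)
    expect_gte(ci$upper, x / n)
    wide <- clopper_pearson(x, n, level = 0.99)
    expect_lte(wide$lower, ci$lower)
    expect_gte(wide$upper, ci$upper)
    if (x < n) {
      up <- clopper_pearson(x + 1, n)
      expect_gte(up$lower, ci$lower)
      expect_gte(up$upper, ci$upper)
    }
  }
})

test_that("carrier frequencies round to the published percentages", {
  expect_equal(round(100 * carrier_frequency(cohort("Total", 125748, 284))$estimate, 2), 0.23)
  expect_equal(round(100 * carrier_frequency(cohort("EAS", 9197, 28))$estimate, 2), 0.30)
  cf0 <- carrier_frequency(cohort("AJ", 5040, 0, "clinvar"))
  expect_equal(cf0$estimate, 0)
  expect_equal(round(100 * cf0$ci$upper, 2), 0.07)
})

test_that("incidence denominators derive from the squared allele-scale interval", {
  inc <- estimate_incidence(cohort("Finnish", 10824, 53))
  expect_equal(inc$denominator, (2 * 10824 / 53)^2)
  expect_equal(inc$denominator, 166801, tolerance = 5e-3)
  expect_equal(inc$ci_denominators[[1L]], 297304, tolerance = 5e-3)
  expect_equal(inc$ci_denominators[[2L]], 97504, tolerance = 5e-3)
  expect_gt(inc$ci_denominators[[1L]], inc$ci_denominators[[2L]])
  # zero counts: undefined denominator, finite upper-q-derived bound
  inc0 <- estimate_incidence(cohort("AJ", 5040, 0, "clinvar"))
  expect_true(is.na(inc0$denominator))
  expect_true(is.na(inc0$ci_denominators[[1L]]))
  expect_false(is.na(inc0$ci_denominators[[2L]]))
  # saturated cohort: q = 1
  expect_equal(estimate_incidence(cohort("all", 10, 20))$denominator, 1)
})

test_that("the carrier estimate is the 2q scale with the HWE bracketing", {
  set.seed(11)
  for (i in 1:25) {
    N <- sample(100:50000, 1)
    x <- sample(1:(N %/% 10), 1)
    fit <- carrier_fit(cohort("c", N, x))
    q <- fit$q
    expect_equal(fit$carrier_frequency, 2 * q)
    expect_lt(2 * q * (1 - q), fit$carrier_frequency)
    expect_lte(fit$carrier_frequency, 2 * q)
    expect_gte(fit$carrier_frequency, fit$cf_ci$lower)
    expect_lte(fit$carrier_frequency, fit$cf_ci$upper)
  }
})

test_that("pooling sums counts and sizes under a single scheme", {
  k <- pool_cohorts(list(cohort("gnomAD Korean", 1909, 0),
                         cohort("KOVA", 5305, 3),
                         cohort("KRGDB", 1722, 1)), "Korean")
  expect_equal(k$n_individuals, 8936L)
  expect_equal(k$disease_allele_count, 4L)
  expect_equal(round(100 * carrier_frequency(k)$estimate, 2), 0.04)
  # identity and equal-rate pooling
  single <- cohort("one", 100, 1)
  expect_identical(pool_cohorts(list(single)), single)
  two <- pool_cohorts(list(cohort("a", 100, 1), cohort("b", 100, 1)), "ab")
  expect_equal(carrier_frequency(two)$estimate, 0.01)
  expect_error(pool_cohorts(list(cohort("a", 100, 1),
                                 cohort("b", 100, 1, "hgmd"))), "scheme")
  expect_error(pool_cohorts(list(cohort("a", 100, 1), cohort("a", 100, 1))),
               "distinct")
})

test_that("burden projections scale census figures with the stated rounding", {
  pr <- project_burden(0.0004, 19963024, 51700000, 260562)
  expect_equal(pr$carriers_total, 21000)
  expect_equal(pr$carriers_newborn, 104)
  expect_equal(pr$expected_cases_per_year, 0.01)
  pr2 <- project_burden(0.01, 40000, 1e6, 10000)
  expect_equal(pr2$carriers_newborn, 100)
  expect_equal(pr2$expected_cases_per_year, 0.25)
  pr0 <- project_burden(0, NA, 1e6, 10000)
  expect_equal(pr0$carriers_total, 0)
  expect_equal(pr0$carriers_newborn, 0)
  expect_error(project_burden(0.01, -5, 1e6, 1e4), "positive")
})

test_that("fit accessors expose the estimates coherently", {
  fit <- carrier_fit(cohort("Finnish", 10824, 53))
  co <- coef(fit)
  expect_named(co, c("carrier_frequency", "q", "incidence"))
  expect_equal(co[["incidence"]], co[["q"]]^2)
  ci <- confint(fit)
  expect_equal(unname(ci["carrier_frequency", ]),
               unlist(fit$cf_ci, use.names = FALSE))
  wider <- confint(fit, "q", level = 0.99)
  expect_lte(wider[1L, "lower"], ci["q", "lower"])
  s <- summary(fit)
  expect_equal(s[["incidence_denominator"]], fit$incidence_denominator)
  expect_output(print(fit), "0.49 \\(0.37-0.64\\)")
})
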