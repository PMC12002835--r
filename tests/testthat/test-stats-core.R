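# Unit tests for the statistical kernels against spec examples, hand
# computations and the independent oracles (small instance counts here;
# the large randomized equivalence sweep lives in the acceptance suite).

test_that("bh_adjust reproduces the step-up definition and its edge cases", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "vascage_invalid_pvalues")
  expect_error(bh_adjust(c(0.5, NA)), class = "vascage_invalid_pvalues")
})

test_that("pearson_age_corr matches the closed-form definitions", {
  x <- c(20, 40, 60, 80)
  res <- pearson_age_corr(x, 10 + 0.1 * x)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 0.1)
  expect_equal(res$mean_y, 15)

  res <- pearson_age_corr(1:5, c(2, 1, 4, 3, 5))
  ct <- cor.test(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)
  expect_equal(res$slope, unname(coef(lm(c(2, 1, 4, 3, 5) ~ seq(1, 5)))[2]))

  expect_true(pearson_age_corr(1:5, rep(5, 5))$degenerate)
  expect_error(pearson_age_corr(rep(3, 5), 1:5), class = "vascage_constant_age")
  expect_error(pearson_age_corr(1:2, 1:2), class = "vascage_too_few_samples")
})

test_that("wilcoxon_one_sample exact mode agrees with exhaustive enumeration", {
  expect_equal(wilcoxon_one_sample(c(-1, 1), 0)$p_value, 1)
  expect_equal(wilcoxon_one_sample(1:6, 0)$p_value, 2 / 64)
  expect_lt(wilcoxon_one_sample(1:10, 0)$p_value, 0.01)

  set.seed(42)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    # mix of continuous and tied values to exercise midranks
    vals <- if (i %% 2) rnorm(n) else sample(-3:3, n, replace = TRUE)
    mu0 <- 0
    if (all(vals == mu0)) next
    got <- wilcoxon_one_sample(vals, mu0, mode = "exact")
    expect_equal(got$p_value, oracle_signed_rank(vals, mu0), tolerance = 1e-12)
  }
})

test_that("wilcoxon_one_sample matches wilcox.test on tie-free data", {
  set.seed(7)
  for (i in 1:20) {
    vals <- rnorm(sample(c(5:12, 30:40), 1), mean = 0.3)
    got <- wilcoxon_one_sample(vals, 0)
    ref <- wilcox.test(vals, mu = 0, exact = length(vals) <= 25, correct = FALSE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("wilcoxon_one_sample handles zeros and degeneracy per the drop convention", {
  res <- wilcoxon_one_sample(c(5, 5, 5), 5)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  # zeros dropped: (0, 1, 2, 3) vs mu0 = 0 behaves like (1, 2, 3)
  expect_equal(wilcoxon_one_sample(c(0, 1, 2, 3), 0)$p_value,
               wilcoxon_one_sample(c(1, 2, 3), 0)$p_value)
  expect_equal(wilcoxon_one_sample(c(1, 2, 3), 0)$median_diff, 2)
})

test_that("kruskal_wallis matches the rank formula and flags identical data", {
  res <- kruskal_wallis(list(c(1, 1, 1), c(1, 1), c(1, 1, 1)))
  expect_true(res$degenerate)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  got <- kruskal_wallis(groups)
  ora <- oracle_kw(groups)
  expect_equal(got$statistic, ora$stat)
  expect_equal(got$p_value, ora$p)

  # two-group case is monotone-consistent with rank-sum ordering
  lo <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  hi <- kruskal_wallis(list(c(1, 2, 4), c(3, 5, 6)))
  expect_lt(lo$p_value, hi$p_value)
  expect_error(kruskal_wallis(list(1:3)), class = "vascage_invalid_groups")
})

test_that("chi_square_2x2 reproduces the closed form, including the aortopathy table", {
  res <- chi_square_2x2(4, 3, 0, 7)
  expect_equal(res$statistic, 5.6)
  expect_equal(res$p_value, 0.01796, tolerance = 1e-3)
  expect_lt(res$p_value, 0.05)

  res <- chi_square_2x2(5, 5, 5, 5)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  res <- chi_square_2x2(3, 3, 2, 3)
  expect_equal(res$statistic, oracle_chi2(3, 3, 2, 3)$stat)
  expect_equal(res$p_value, oracle_chi2(3, 3, 2, 3)$p)

  yt <- chi_square_2x2(4, 3, 0, 7, correction = "yates")
  expect_equal(yt$statistic, oracle_chi2(4, 3, 0, 7, yates = TRUE)$stat)

  expect_error(chi_square_2x2(0, 0, 3, 4), class = "vascage_zero_margin")
  expect_error(chi_square_2x2(1.5, 2, 3, 4), class = "vascage_invalid_table")
})

test_that("fisher_exact_2x2 matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(4, 3, 0, 7)$p_value, oracle_fisher(4, 3, 0, 7))
  expect_equal(fisher_exact_2x2(4, 3, 0, 7)$p_value, 0.06993, tolerance = 1e-4)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
  expect_lt(fisher_exact_2x2(10, 0, 0, 10)$p_value, 1e-4)
})

test_that("2x2 tests are invariant under simultaneous row and column swaps", {
  set.seed(3)
  for (i in 1:20) {
    t0 <- random_2x2()
    chi <- chi_square_2x2(t0[1], t0[2], t0[3], t0[4])
    fis <- fisher_exact_2x2(t0[1], t0[2], t0[3], t0[4])
    # swap rows AND columns: (a,b,c,d) -> (d,c,b,a)
    chi_sw <- chi_square_2x2(t0[4], t0[3], t0[2], t0[1])
    fis_sw <- fisher_exact_2x2(t0[4], t0[3], t0[2], t0[1])
    expect_equal(chi$p_value, chi_sw$p_value)
    expect_equal(fis$p_value, fis_sw$p_value)
  }
})

test_that("ols_fit matches the normal equations and reports collinearity", {
  x <- 1:20
  y <- 3 + 2 * x
  res <- suppressWarnings(ols_fit(y, cbind(x = x, z = rnorm(20))))  # perfect fit
  expect_equal(res$r2, 1)
  expect_equal(unname(res$coefficients["x"]), 2)
  expect_equal(unname(res$coefficients["z"]), 0, tolerance = 1e-10)

  set.seed(5)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  y <- 1 + 0.5 * X[, 1] - 2 * X[, 2] + rnorm(30)
  got <- ols_fit(y, X)
  ora <- oracle_ols(y, X)
  expect_equal(unname(got$coefficients), ora$beta, tolerance = 1e-10)
  expect_equal(unname(got$coef_p), ora$p, tolerance = 1e-10)
  expect_equal(got$r2, ora$r2, tolerance = 1e-10)

  Xc <- cbind(a = 1:30, b = 2 * (1:30))
  err <- tryCatch(ols_fit(y, Xc), error = function(e) e)
  expect_s3_class(err, "vascage_collinear_design")
  expect_match(conditionMessage(err), "b")
})

test_that("p-values are floored, never exactly zero", {
  res <- pearson_age_corr(1:10, 2 * (1:10))
  expect_gt(res$p, 0)
  huge <- chi_square_2x2(1000, 0, 0, 1000)
  expect_gt(huge$p_value, 0)
})
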