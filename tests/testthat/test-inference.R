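test_that("Hotelling at p = 1 matches the squared paired t statistic", {
  set.seed(1)
  for (rep in 1:5) {
    first <- matrix(rnorm(20), 20, 1)
    last <- matrix(rnorm(20, mean = 0.3), 20, 1)
    res <- paired_hotelling(first, last, n_dims = 1)
    tt <- t.test(last[, 1], first[, 1], paired = TRUE)
    expect_equal(res$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical visits give T2 = 0, p = 1", {
  set.seed(2)
  x <- matrix(rnorm(14 * 13), 14, 13)
  res <- paired_hotelling(x, x, n_dims = 13)
  expect_equal(res$t2, 0)
  expect_equal(res$p_value, 1)
})

test_that("the df pair follows (n_dims, n_pairs - n_dims)", {
  set.seed(3)
  first <- matrix(rnorm(14 * 13), 14, 13)
  last <- first + matrix(rnorm(14 * 13, sd = 0.2), 14, 13)
  res <- paired_hotelling(first, last, n_dims = 13)
  expect_equal(res$df1, 13L)
  expect_equal(res$df2, 1L)
  expect_error(paired_hotelling(first[1:13, ], last[1:13, ], n_dims = 13),
               "more pairs than dimensions")
  expect_error(paired_hotelling(first, last[1:10, ]), "identical dimensions")
})

test_that("Hotelling is invariant to a common invertible linear map", {
  set.seed(4)
  first <- matrix(rnorm(20 * 5), 20, 5)
  last <- first + matrix(rnorm(20 * 5, sd = 0.5), 20, 5)
  a <- matrix(rnorm(25), 5, 5) + diag(5)
  res1 <- paired_hotelling(first, last, n_dims = 5)
  res2 <- paired_hotelling(first %*% a, last %*% a, n_dims = 5)
  expect_equal(res1$t2, res2$t2, tolerance = 1e-8)
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-8)
})

test_that("null Hotelling p-values are uniform", {
  set.seed(5)
  pvals <- replicate(500, {
    d <- matrix(rnorm(14 * 5), 14, 5)
    paired_hotelling(matrix(0, 14, 5), d, n_dims = 5)$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the LMM recovers an injected treatment slope", {
  tab <- simulate_score_table(n_subjects = 14, visits = 7, slope = -0.05,
                              subject_sd = 0.3, resid_sd = 0.1, seed = 6)
  fit <- fit_score_lmm(tab)
  expect_lt(abs(fit$beta_time - (-0.05)), 3 * fit$se_time)
  expect_lt(fit$p_value, 0.05)
  expect_gt(fit$random_intercept_var, 0)
  expect_equal(fit$n_subjects, 14L)
  expect_equal(fit$n_observations, 98L)
  expect_equal(fit$lrt_df, 1L)
})

test_that("constant scores give a zero slope and a null LRT", {
  tab <- simulate_score_table(n_subjects = 6, visits = 4, slope = 0,
                              subject_sd = 0, resid_sd = 0, seed = 7)
  # zero-variance data: lme4 warns about the degenerate vcov, by design
  fit <- suppressWarnings(fit_score_lmm(tab))
  expect_equal(fit$beta_time, 0, tolerance = 1e-8)
  expect_lt(fit$lrt_chisq, 1e-6)
})

test_that("with no between-subject variance the LMM slope matches OLS", {
  tab <- simulate_score_table(n_subjects = 10, visits = 5, slope = -0.04,
                              subject_sd = 0, resid_sd = 0, seed = 8)
  fit <- fit_score_lmm(tab)
  # same protocol coding as fit_score_lmm: second factor level = 1
  prot <- as.numeric(tab$protocol == sort(unique(tab$protocol))[2])
  ols <- lm(score ~ prot * years_from_first_dose, data = cbind(tab, prot))
  expect_equal(fit$beta_time, coef(ols)[["years_from_first_dose"]],
               tolerance = 1e-6)
})

test_that("the time LRT is a genuine 1-df reduction with protocol interaction present", {
  # placebo-first subjects break the collinearity between the time main
  # effect and the per-protocol slopes, so the reduced model must differ
  tab <- simulate_score_table(n_subjects = 14, visits = 7, slope = -0.05,
                              subject_sd = 0.2, resid_sd = 0.05, seed = 9)
  fit <- fit_score_lmm(tab)
  expect_gt(fit$lrt_chisq, 1)
  alt <- fit_score_lmm(tab, drop_interaction_with_time = TRUE)
  expect_gt(alt$lrt_chisq, fit$lrt_chisq * 0.5)
})

test_that("single observation per subject falls back to OLS with a flag", {
  tab <- simulate_score_table(n_subjects = 8, visits = 1, slope = -0.05,
                              subject_sd = 0.1, resid_sd = 0.05, seed = 10)
  tab$years_from_first_dose <- seq_len(8)  # spread times across subjects
  expect_warning(fit <- fit_score_lmm(tab), "OLS")
  expect_true(fit$ols_fallback)
  expect_true(is.finite(fit$beta_time))
})

test_that("control age regression is exact on a noiseless line", {
  ages <- seq(3, 16, length.out = 20)
  res <- suppressWarnings(control_age_regression(2 + 0.3 * ages, ages))
  expect_equal(res$slope, 0.3, tolerance = 1e-10)
  expect_lt(res$p, 1e-12)
  expect_error(control_age_regression(rnorm(5), rep(7, 5)), "singular")
  expect_error(control_age_regression(1:2, 1:2), "at least 3")
})

test_that("duplicating the data keeps the slope but shrinks the p-value", {
  set.seed(11)
  ages <- runif(30, 3, 16)
  scores <- 1 + 0.02 * ages + rnorm(30, sd = 0.15)
  res1 <- control_age_regression(scores, ages)
  res2 <- control_age_regression(rep(scores, 2), rep(ages, 2))
  expect_equal(res2$slope, res1$slope, tolerance = 1e-10)
  expect_lt(res2$p, res1$p)
})

test_that("null control-age-regression p-values are uniform", {
  set.seed(12)
  pvals <- replicate(800, control_age_regression(rnorm(30), runif(30, 3, 16))$p)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
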