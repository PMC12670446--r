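# Shared fitted pipeline for scoring tests (moderate cohort, full PC basis).
scoring_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- fit_cohort_axis(cohort_spec(n_normative = 60, n_achondro = 40,
                                            n_treated = 4,
                                            visits_per_treated = 3,
                                            seed = 71))
    }
    cache
  }
})

test_that("score calibration is exact: normative prediction 0, plus-axis 1, orthogonal 0", {
  fx <- scoring_fixture()
  axis <- fx$axis
  m <- axis$n_components
  age <- 8.3
  sex <- "F"
  mu <- drop(morphoscore:::predict_normative(axis, age, 0))

  at_mu <- predict(axis, mu, age, sex)
  expect_equal(at_mu$normalized_score, 0, tolerance = 1e-8)
  expect_equal(at_mu$raw_projection, 0, tolerance = 1e-8)

  plus_axis <- predict(axis, mu + axis$v, age, sex)
  expect_equal(plus_axis$normalized_score, 1, tolerance = 1e-8)
  expect_equal(plus_axis$raw_projection, axis$norm_v, tolerance = 1e-8)

  set.seed(1)
  w <- rnorm(m)
  w <- w - sum(w * axis$v) / sum(axis$v^2) * axis$v   # orthogonal to v
  expect_equal(predict(axis, mu + w, age, sex)$normalized_score, 0,
               tolerance = 1e-8)

  expect_error(predict(axis, mu[-1], age, sex), "components")
})

test_that("group means converge to 0 (normative) and 1 (affected) on large cohorts", {
  fx <- fit_cohort_axis(cohort_spec(n_normative = 200, n_achondro = 200,
                                    n_treated = 0, seed = 90))
  md <- fx$metadata
  sc <- predict(fx$axis, fx$scores, md$age_years, md$sex)
  norm_scores <- sc$normalized_score[md$group == "normative"]
  ach_scores <- sc$normalized_score[md$group == "achondroplasia"]
  se_norm <- sd(norm_scores) / sqrt(length(norm_scores))
  se_ach <- sd(ach_scores) / sqrt(length(ach_scores))
  expect_lt(abs(mean(norm_scores) - 0), 3 * se_norm + 1e-6)
  expect_lt(abs(mean(ach_scores) - 1), 3 * se_ach + 1e-6)
})

test_that("fitted axis recovers the injected group displacement", {
  fx <- fit_cohort_axis(cohort_spec(n_normative = 100, n_achondro = 100,
                                    n_treated = 0, group_effect_scale = 0.05,
                                    noise_sd = 0.005, sex_effect_scale = 0,
                                    growth_coeffs = c(0, 0, 0),
                                    subject_sd = 0, seed = 55))
  g <- truth_axis_in_frame(fx$cohort, fx$gpa)
  expect_gte(cosine(fx$axis$group_vector_landmark, g), 0.99)
})

test_that("a shared cubic age trend does not move the axis", {
  base_spec <- cohort_spec(n_normative = 100, n_achondro = 100, n_treated = 0,
                           group_effect_scale = 0.05, noise_sd = 0.005,
                           subject_sd = 0, sex_effect_scale = 0,
                           growth_coeffs = c(0, 0, 0), seed = 61)
  aged_spec <- cohort_spec(n_normative = 100, n_achondro = 100, n_treated = 0,
                           group_effect_scale = 0.05, noise_sd = 0.005,
                           subject_sd = 0, sex_effect_scale = 0,
                           growth_coeffs = c(0.05, -0.004, 2e-4), seed = 61)
  fx0 <- fit_cohort_axis(base_spec)
  fx1 <- fit_cohort_axis(aged_spec)
  g0 <- truth_axis_in_frame(fx0$cohort, fx0$gpa)
  g1 <- truth_axis_in_frame(fx1$cohort, fx1$gpa)
  expect_gte(cosine(fx0$axis$group_vector_landmark, g0), 0.99)
  expect_gte(cosine(fx1$axis$group_vector_landmark, g1), 0.99)
})

test_that("indistinguishable groups raise the degenerate-axis error", {
  set.seed(3)
  scores <- matrix(rep(rnorm(5), each = 40), 40, 5)  # identical rows per PC
  scores <- scores * 0  # zero variance, zero group effect
  age <- runif(40, 3, 16)
  sex <- sample(c("F", "M"), 40, replace = TRUE)
  group <- rep(c("normative", "achondroplasia"), each = 20)
  expect_error(fit_phenotype_axis(scores, age, sex, group),
               "degenerate axis")
})

test_that("rank-deficient designs are reported with the offending column", {
  set.seed(4)
  scores <- matrix(rnorm(40 * 3), 40, 3)
  age <- rep(7, 40)  # constant age: age terms collinear with intercept
  sex <- sample(c("F", "M"), 40, replace = TRUE)
  group <- rep(c("normative", "achondroplasia"), each = 20)
  expect_error(fit_phenotype_axis(scores, age, sex, group), "singular design")
})

test_that("SD standardization centers and scales the reference group exactly", {
  fx <- scoring_fixture()
  md <- fx$metadata
  sc <- predict(fx$axis, fx$scores, md$age_years, md$sex)
  tab <- cbind(md[, c("scan_id", "group")], sc)
  out <- standardize_scores(tab)
  ref <- out$sd_standardized_score[out$group == "achondroplasia"]
  expect_equal(mean(ref), 0, tolerance = 1e-12)
  expect_equal(sd(ref), 1, tolerance = 1e-12)

  # affine invariance of the standardized values
  tab2 <- tab
  tab2$normalized_score <- 3.2 * tab2$normalized_score - 0.7
  out2 <- standardize_scores(tab2)
  expect_equal(out2$sd_standardized_score, out$sd_standardized_score,
               tolerance = 1e-10)

  one_row <- tab[c(which(tab$group == "achondroplasia")[1:2],
                   which(tab$group == "treated")[1]), ]
  expect_true(is.finite(
    standardize_scores(one_row)$sd_standardized_score[3]))
  expect_error(standardize_scores(tab[tab$group == "treated", ][1, ]),
               "at least 2")
})

test_that("age standardization triggers on a real control age trend and recovers it", {
  set.seed(8)
  n <- 80
  ages <- runif(n, 3, 16)
  controls <- 1 + 0.1 * (ages - mean(ages)) + rnorm(n, sd = 0.01)
  treated_ages <- runif(20, 5, 9)
  treated <- 0.8 + 0.1 * (treated_ages - mean(ages)) + rnorm(20, sd = 0.01)
  out <- age_standardize(treated, treated_ages, controls, ages, alpha = 0.05)
  expect_true(out$test$significant)
  expect_lt(abs(out$test$slope - 0.1), 2 * out$test$se)
  resid_fit <- lm(out$scores ~ treated_ages)
  expect_lt(abs(coef(resid_fit)[["treated_ages"]]), 0.02)
})

test_that("age standardization leaves scores alone when controls show no trend", {
  set.seed(9)
  ages <- runif(60, 3, 16)
  controls <- 1 + rnorm(60, sd = 0.05)
  treated_ages <- runif(15, 5, 9)
  treated <- 0.9 + rnorm(15, sd = 0.05)
  out <- age_standardize(treated, treated_ages, controls, ages, alpha = 1e-6)
  expect_identical(out$scores, treated)
  # alpha = 1 forces standardization, alpha = 0 forbids it
  forced <- age_standardize(treated, treated_ages, controls, ages, alpha = 1)
  expect_false(identical(forced$scores, treated))
  forbidden <- age_standardize(treated, treated_ages, controls, ages, alpha = 0)
  expect_identical(forbidden$scores, treated)
})

test_that("vertex scores are 1 on the axis shape, 0 on the normative shape", {
  fx <- scoring_fixture()
  axis <- fx$axis
  space <- fx$space
  age <- 7.5
  mu <- drop(morphoscore:::predict_normative(axis, age, 1))
  m <- axis$n_components
  pred_cfg <- morphoscore:::unflatten_config(
    space$center + as.numeric(space$rotation[, seq_len(m)] %*% mu))
  vs0 <- vertex_scores(pred_cfg, age, "M", axis, space)
  expect_lt(max(abs(vs0)), 1e-8)

  plus_cfg <- pred_cfg + axis$group_vector_landmark
  vs1 <- vertex_scores(plus_cfg, age, "M", axis, space)
  vnorm <- sqrt(rowSums(axis$group_vector_landmark^2))
  thr <- 1e-3 * axis$norm_v / sqrt(space$k)
  expect_equal(vs1[vnorm > thr], rep(1, sum(vnorm > thr)), tolerance = 1e-8)
  expect_true(all(vs1[vnorm <= thr] == 0))
})

test_that("axis-weighted mean of vertex scores equals the global score", {
  fx <- scoring_fixture()
  md <- fx$metadata
  global <- predict(fx$axis, fx$scores, md$age_years, md$sex)
  w <- rowSums(fx$axis$group_vector_landmark^2)
  for (i in seq_len(nrow(md))) {
    vs <- vertex_scores(fx$gpa$configurations[[md$scan_id[i]]],
                        md$age_years[i], md$sex[i], fx$axis, fx$space)
    expect_equal(sum(w * vs) / sum(w), global$normalized_score[i],
                 tolerance = 1e-8)
  }
})

test_that("vertex score change is antisymmetric and additive over visits", {
  set.seed(10)
  a <- rnorm(30); b <- rnorm(30); c <- rnorm(30)
  expect_equal(vertex_score_change(a, a), rep(0, 30))
  expect_equal(vertex_score_change(a, b), -vertex_score_change(b, a))
  expect_equal(vertex_score_change(a, c),
               vertex_score_change(a, b) + vertex_score_change(b, c))
  expect_error(vertex_score_change(a, b[-1]), "landmark counts")
})
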