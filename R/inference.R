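# Inference: paired multivariate test of shape change and the longitudinal
# mixed model of phenotype score under treatment.

#' Paired Hotelling's T2 test on leading shape components
#'
#' Tests whether the mean multivariate change between two paired visits is
#' zero, restricted to the first `n_dims` principal component axes (small
#' samples cannot support the full dimensionality). T2 = n * dbar' S^-1 dbar
#' with S the sample covariance (n - 1 denominator) of the paired differences;
#' the F transform F = (n - p) / (p (n - 1)) * T2 is referred to F(p, n - p).
#'
#' @param first_scores,last_scores n x m matrices of paired PC scores (row i
#'   of each = the same subject's first and last visit).
#' @param n_dims Number of leading components to test; defaults to
#'   `min(m, n - 1)`. Must be < n.
#' @return Object of class `hotelling_test`: `t2`, `f_stat`, `df1`, `df2`,
#'   `p_value`, `n_pairs`, `n_dims`.
#' @examples
#' first <- matrix(rnorm(14 * 13), 14, 13)
#' last <- first + matrix(rnorm(14 * 13, sd = 0.1), 14, 13)
#' paired_hotelling(first, last, n_dims = 13)
#' @export
paired_hotelling <- function(first_scores, last_scores, n_dims = NULL) {
  first_scores <- as.matrix(first_scores)
  last_scores <- as.matrix(last_scores)
  if (!identical(dim(first_scores), dim(last_scores))) {
    stop("paired score matrices must have identical dimensions", call. = FALSE)
  }
  n <- nrow(first_scores)
  n_dims <- as.integer(n_dims %||% min(ncol(first_scores), n - 1L))
  if (n_dims < 1L || n_dims > ncol(first_scores)) {
    stop("n_dims out of range", call. = FALSE)
  }
  if (n <= n_dims) {
    stop(sprintf(
      "need more pairs than dimensions (n = %d, dims = %d): the F transform has %d denominator df",
      n, n_dims, n - n_dims), call. = FALSE)
  }
  d <- (last_scores - first_scores)[, seq_len(n_dims), drop = FALSE]
  dbar <- colMeans(d)
  if (all(dbar == 0)) {
    t2 <- 0
  } else {
    s <- stats::cov(d)
    sol <- tryCatch(solve(s, dbar), error = function(e) {
      stop(sprintf(
        "singular difference covariance in %d dimensions; reduce n_dims", n_dims),
        call. = FALSE)
    })
    t2 <- n * sum(dbar * sol)
  }
  df1 <- n_dims
  df2 <- n - n_dims
  f_stat <- (n - n_dims) / (n_dims * (n - 1)) * t2
  structure(list(
    t2 = t2, f_stat = f_stat, df1 = df1, df2 = df2,
    p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
    n_pairs = n, n_dims = n_dims
  ), class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat(sprintf(
    "Paired Hotelling T2 = %.4g on %d pairs, %d dims: F(%d,%d) = %.4f, P = %.4f\n",
    x$t2, x$n_pairs, x$n_dims, x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}

#' Linear mixed model of phenotype score under treatment
#'
#' Fits, by maximum likelihood with `lme4::lmer`,
#' `score ~ protocol + time + protocol:time + (1 | subject)`
#' to the treated cohort, where `time` is years from first dose (negative for
#' pre-dose visits of placebo-first subjects, which are retained) and the
#' random intercept absorbs stable between-individual score differences. The
#' treatment-time effect is tested by a likelihood-ratio chi-square (df = 1)
#' against the same model with the `time` main effect deleted (both ML fits);
#' the protocol main effect and the interaction are tested by single-term
#' deletion in the same way.
#'
#' The protocol indicator and the interaction are coded as explicit numeric
#' columns (protocol 0/1, interaction = protocol x time) so that deleting the
#' `time` main effect is a genuine 1-df reduction: with factor coding R would
#' re-expand `protocol:time` into per-protocol slopes that span the deleted
#' term.
#'
#' @param score_table Data frame with one row per scan.
#' @param score_col,time_col,subject_col,protocol_col Column names (defaults
#'   match [simulate_score_table()] output).
#' @param drop_interaction_with_time If `TRUE`, the reduced model for the time
#'   test deletes the interaction together with the time main effect.
#' @return Object of class `score_lmm`: `beta_time`, `se_time`,
#'   `beta_protocol`, `beta_interaction`, `random_intercept_var`,
#'   `residual_var`, `lrt_chisq`, `lrt_df`, `p_value`, per-term tests
#'   (`protocol_test`, `interaction_test`), `n_subjects`, `n_observations`,
#'   `ols_fallback`, and the `lme4` fit as `model`.
#' @examples
#' tab <- simulate_score_table(seed = 42)
#' fit_score_lmm(tab)
#' @export
fit_score_lmm <- function(score_table, score_col = "score",
                          time_col = "years_from_first_dose",
                          subject_col = "subject_id",
                          protocol_col = "protocol",
                          drop_interaction_with_time = FALSE) {
  protocol <- factor(score_table[[protocol_col]])
  if (nlevels(protocol) > 2L) {
    stop("at most 2 treatment protocols are supported", call. = FALSE)
  }
  df <- data.frame(
    score = score_table[[score_col]],
    time = score_table[[time_col]],
    subject = factor(score_table[[subject_col]]),
    prot = as.numeric(protocol == levels(protocol)[2L])
  )
  if (nlevels(protocol) < 2L) df$prot <- 0
  df$prot_time <- df$prot * df$time
  if (anyNA(df)) stop("score table contains missing values", call. = FALSE)
  n_subj <- nlevels(df$subject)
  if (n_subj < 2L) stop("need at least 2 subjects", call. = FALSE)
  obs_per_subj <- table(df$subject)
  has_protocol <- nlevels(protocol) >= 2L

  if (max(obs_per_subj) < 2L) {
    warning("single observation per subject: random intercept unidentifiable, falling back to OLS",
            call. = FALSE)
    form <- if (has_protocol) score ~ prot + time + prot_time else score ~ time
    fit <- stats::lm(form, data = df)
    red <- stats::update(fit, . ~ . - time)
    lrt <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(red)))
    cf <- stats::coef(summary(fit))
    return(structure(list(
      beta_time = cf["time", "Estimate"], se_time = cf["time", "Std. Error"],
      beta_protocol = NA_real_, beta_interaction = NA_real_,
      random_intercept_var = NA_real_,
      residual_var = stats::sigma(fit)^2,
      lrt_chisq = max(lrt, 0), lrt_df = 1L,
      p_value = stats::pchisq(max(lrt, 0), 1L, lower.tail = FALSE),
      protocol_test = NULL, interaction_test = NULL,
      n_subjects = n_subj, n_observations = nrow(df),
      ols_fallback = TRUE, model = fit
    ), class = "score_lmm"))
  }

  fit_ml <- function(formula) {
    suppressMessages(lme4::lmer(formula, data = df, REML = FALSE,
                                control = lme4::lmerControl(calc.derivs = FALSE)))
  }
  lrt_vs <- function(full, reduced_formula) {
    red <- fit_ml(reduced_formula)
    chisq <- as.numeric(2 * (stats::logLik(full) - stats::logLik(red)))
    # degenerate zero-variance data give infinite log-likelihoods in both
    # models; their difference carries no evidence
    chisq <- if (is.nan(chisq)) 0 else max(0, chisq)
    list(chisq = chisq, df = 1L,
         p = stats::pchisq(chisq, 1L, lower.tail = FALSE))
  }

  if (has_protocol) {
    full <- fit_ml(score ~ prot + time + prot_time + (1 | subject))
    time_red <- if (drop_interaction_with_time) {
      score ~ prot + (1 | subject)
    } else {
      score ~ prot + prot_time + (1 | subject)
    }
    time_test <- lrt_vs(full, time_red)
    protocol_test <- lrt_vs(full, score ~ time + prot_time + (1 | subject))
    interaction_test <- lrt_vs(full, score ~ prot + time + (1 | subject))
  } else {
    full <- fit_ml(score ~ time + (1 | subject))
    time_test <- lrt_vs(full, score ~ 1 + (1 | subject))
    protocol_test <- NULL
    interaction_test <- NULL
  }

  fe <- lme4::fixef(full)
  # vcov can fail on degenerate (zero-variance) fits; SEs become NA then
  se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(full)))),
                 error = function(e) {
                   stats::setNames(rep(NA_real_, length(fe)), names(fe))
                 })
  vc <- as.data.frame(lme4::VarCorr(full))
  subj_var <- vc$vcov[vc$grp == "subject"][1L]
  resid_var <- vc$vcov[vc$grp == "Residual"][1L]

  structure(list(
    beta_time = unname(fe[["time"]]),
    se_time = unname(se[["time"]]),
    beta_protocol = if ("prot" %in% names(fe)) unname(fe[["prot"]]) else NA_real_,
    beta_interaction = if ("prot_time" %in% names(fe)) unname(fe[["prot_time"]]) else NA_real_,
    random_intercept_var = subj_var,
    residual_var = resid_var,
    lrt_chisq = time_test$chisq, lrt_df = time_test$df,
    p_value = time_test$p,
    protocol_test = protocol_test,
    interaction_test = interaction_test,
    n_subjects = n_subj, n_observations = nrow(df),
    ols_fallback = FALSE, model = full
  ), class = "score_lmm")
}

#' @export
print.score_lmm <- function(x, ...) {
  cat(sprintf(
    "Score LMM (%d subjects, %d scans)%s\n", x$n_subjects, x$n_observations,
    if (x$ols_fallback) " [OLS fallback]" else ""))
  cat(sprintf("time effect: chi2 = %.3g, df = %d, P = %.4g, b = %.4g /y\n",
              x$lrt_chisq, x$lrt_df, x$p_value, x$beta_time))
  if (!is.null(x$protocol_test)) {
    cat(sprintf("protocol:    chi2 = %.3g, P = %.3g\n",
                x$protocol_test$chisq, x$protocol_test$p))
  }
  if (!is.null(x$interaction_test)) {
    cat(sprintf("interaction: chi2 = %.3g, P = %.3g\n",
                x$interaction_test$chisq, x$interaction_test$p))
  }
  invisible(x)
}

#' Linear regression of control scores on age
#'
#' Ordinary least squares of phenotype score on age in the untreated affected
#' controls; used to decide whether treated scores need age standardization.
#'
#' @param scores,ages Numeric vectors (>= 3 points, non-constant ages).
#' @return List with `slope`, `se`, `t`, `p` (two-sided), `intercept`, `n`.
#' @export
control_age_regression <- function(scores, ages) {
  scores <- as.numeric(scores)
  ages <- as.numeric(ages)
  if (length(scores) != length(ages) || length(scores) < 3L) {
    stop("need at least 3 paired (score, age) observations", call. = FALSE)
  }
  if (stats::sd(ages) < 1e-12) {
    stop("singular design: ages are constant", call. = FALSE)
  }
  fit <- stats::lm(scores ~ ages)
  cf <- stats::coef(summary(fit))
  list(slope = cf["ages", "Estimate"], se = cf["ages", "Std. Error"],
       t = cf["ages", "t value"], p = cf["ages", "Pr(>|t|)"],
       intercept = cf["(Intercept)", "Estimate"], n = length(scores))
}
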