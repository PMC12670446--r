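# Phenotype axis: regression-derived direction in shape space separating the
# affected and normative control means after cubic age and sex adjustment.

code_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) {
      stop("numeric `sex` must be coded 0/1", call. = FALSE)
    }
    return(as.numeric(sex))
  }
  sex <- toupper(substr(as.character(sex), 1L, 1L))
  if (!all(sex %in% c("F", "M"))) {
    stop("`sex` must be 'F'/'M' (or 0/1)", call. = FALSE)
  }
  as.numeric(sex == "M")
}

code_group <- function(group) {
  if (is.numeric(group)) {
    if (!all(group %in% c(0, 1))) {
      stop("numeric `group` must be coded 0 (normative) / 1 (affected)",
           call. = FALSE)
    }
    return(as.numeric(group))
  }
  group <- as.character(group)
  lv <- unique(group)
  if (!"normative" %in% lv || length(lv) != 2L) {
    stop("`group` must have exactly two levels, one of them 'normative'",
         call. = FALSE)
  }
  as.numeric(group != "normative")
}

axis_design <- function(age, sex01, group01, center_age) {
  ac <- age - center_age
  cbind(intercept = 1, age = ac, age2 = ac^2, age3 = ac^3,
        sex = sex01, group = group01)
}

#' Fit the phenotype axis from control shape scores
#'
#' For every retained principal component, regresses the PC score of the
#' pooled controls on an intercept, centered age, age squared and cubed, sex
#' (0 = female, 1 = male) and a group indicator (0 = normative, 1 = affected)
#' by ordinary least squares. The vector of group coefficients across PCs is
#' the phenotype axis: the displacement from the age- and sex-adjusted
#' normative mean to the affected mean. A scan's phenotype score is its scalar
#' projection onto this axis divided once more by the axis norm, so the
#' normative mean scores 0 and the affected mean scores 1 (see
#' [predict.phenotype_axis()]).
#'
#' Treated subjects must not be included: the axis contrasts untreated
#' controls only.
#'
#' @param scores N x m matrix of retained-PC scores for the control scans.
#' @param age Numeric ages in years.
#' @param sex `'F'`/`'M'` or 0/1.
#' @param group `'normative'` vs one affected label, or 0/1.
#' @param space Optional [fit_pca()] space used to map the axis (and
#'   predictions) back to landmark coordinates.
#' @param center_age Age-centering constant; defaults to the pooled control
#'   mean age.
#' @return Object of class `phenotype_axis`: `coefficients` (6 x m matrix,
#'   rows intercept/age/age2/age3/sex/group), `v` (the group-coefficient
#'   vector), `norm_v`, `group_vector_landmark` (k x 3, when `space` given),
#'   `center_age`, `fit_sample_counts`, `space`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_normative = 60, n_achondro = 40,
#'                                       n_treated = 0, seed = 5))
#' fit <- gpa(cohort$configurations)
#' space <- fit_pca(fit, n_retained = 10)
#' sc <- project(fit$configurations, space, 10)
#' md <- cohort$metadata
#' axis <- fit_phenotype_axis(sc, md$age_years, md$sex, md$group, space)
#' axis
#' @export
fit_phenotype_axis <- function(scores, age, sex, group, space = NULL,
                               center_age = NULL) {
  scores <- as.matrix(scores)
  age <- as.numeric(age)
  if (!all(is.finite(age))) stop("ages must be finite", call. = FALSE)
  sex01 <- code_sex(sex)
  group01 <- code_group(group)
  if (length(unique(group01)) < 2L) {
    stop("both groups must be present to fit the axis", call. = FALSE)
  }
  n <- nrow(scores)
  stopifnot(length(age) == n, length(sex01) == n, length(group01) == n)
  center_age <- center_age %||% mean(age)
  x <- axis_design(age, sex01, group01, center_age)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    bad <- colnames(x)[qr_x$pivot[(qr_x$rank + 1L):ncol(x)]]
    stop(sprintf("singular design: column(s) %s are collinear",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  coefs <- qr.coef(qr_x, scores)
  rownames(coefs) <- colnames(x)
  v <- coefs["group", ]
  norm_v <- sqrt(sum(v^2))
  if (norm_v < 1e-10) {
    stop("degenerate axis: the groups are indistinguishable (||v|| = 0)",
         call. = FALSE)
  }
  landmark_v <- NULL
  if (!is.null(space)) {
    stopifnot(inherits(space, "shape_space"))
    if (ncol(scores) > ncol(space$rotation)) {
      stop("scores have more components than the shape space", call. = FALSE)
    }
    landmark_v <- unflatten_config(
      as.numeric(space$rotation[, seq_len(ncol(scores)), drop = FALSE] %*% v))
  }
  structure(list(
    coefficients = coefs,
    v = v,
    norm_v = norm_v,
    group_vector_landmark = landmark_v,
    center_age = center_age,
    fit_sample_counts = c(normative = sum(group01 == 0),
                          affected = sum(group01 == 1)),
    n_components = ncol(scores),
    space = space
  ), class = "phenotype_axis")
}

#' @export
print.phenotype_axis <- function(x, ...) {
  cat(sprintf(
    "Phenotype axis over %d PCs (||v|| = %.4g)\nfitted on %d normative + %d affected controls; age centered at %.2f y\n",
    x$n_components, x$norm_v, x$fit_sample_counts[["normative"]],
    x$fit_sample_counts[["affected"]], x$center_age))
  invisible(x)
}

#' @export
summary.phenotype_axis <- function(object, ...) {
  print(object)
  cat("\nLargest |group coefficient| components:\n")
  ord <- order(abs(object$v), decreasing = TRUE)[seq_len(min(5L, length(object$v)))]
  print(round(stats::setNames(object$v[ord], paste0("PC", ord)), 4))
  invisible(object)
}

#' @export
coef.phenotype_axis <- function(object, ...) object$coefficients

# Normative (group = 0) predicted PC scores for given ages/sexes: N x m.
predict_normative <- function(axis, age, sex01) {
  x0 <- axis_design(age, sex01, 0, axis$center_age)
  x0 %*% axis$coefficients
}

#' Score scans on a phenotype axis
#'
#' For each scan, the residual from the model-predicted normative shape of the
#' same age and sex is projected onto the axis. `raw_projection` is the scalar
#' projection (residual . v) / ||v||; `normalized_score` divides once more by
#' ||v||, so a scan at the predicted normative shape scores 0 and a scan
#' displaced by exactly the axis vector scores 1.
#'
#' @param object A [fit_phenotype_axis()] fit.
#' @param scores N x m PC score matrix (or length-m vector) in the same shape
#'   space the axis was fitted in.
#' @param age,sex Scan covariates, as in [fit_phenotype_axis()].
#' @param ... Unused.
#' @return Data frame with `raw_projection` and `normalized_score`.
#' @export
predict.phenotype_axis <- function(object, scores, age, sex, ...) {
  scores <- if (is.null(dim(scores))) matrix(scores, 1L) else as.matrix(scores)
  if (ncol(scores) != object$n_components) {
    stop(sprintf("scores have %d components but the axis was fitted on %d",
                 ncol(scores), object$n_components), call. = FALSE)
  }
  sex01 <- code_sex(sex)
  r <- scores - predict_normative(object, as.numeric(age), sex01)
  raw <- as.numeric(r %*% object$v) / object$norm_v
  data.frame(raw_projection = raw,
             normalized_score = raw / object$norm_v)
}

#' @rdname predict.phenotype_axis
#' @param axis A [fit_phenotype_axis()] fit (functional-form alias of the
#'   `predict` method).
#' @export
score_scan <- function(scores, age, sex, axis) {
  predict(axis, scores, age, sex)
}

#' Standardize phenotype scores against a reference group
#'
#' Expresses normalized scores in standard deviations of a reference group
#' (typically the affected controls): subtracts the reference mean and divides
#' by the reference SD, so reference rows end up with mean 0 and SD 1.
#'
#' @param score_table Data frame with at least `group` and the score column.
#' @param reference_group Group label defining the reference rows.
#' @param score_col Column to standardize (default `"normalized_score"`).
#' @return The table with an added `sd_standardized_score` column.
#' @export
standardize_scores <- function(score_table, reference_group = "achondroplasia",
                               score_col = "normalized_score") {
  ref <- score_table[[score_col]][score_table$group == reference_group]
  if (length(ref) < 2L) {
    stop("reference group needs at least 2 members", call. = FALSE)
  }
  s <- stats::sd(ref)
  if (s < 1e-12) {
    stop("degenerate reference: zero score SD in the reference group",
         call. = FALSE)
  }
  score_table$sd_standardized_score <- (score_table[[score_col]] - mean(ref)) / s
  score_table
}

#' Age-standardize treated scores using the control age trend
#'
#' Regresses control scores on age by ordinary least squares. If the slope is
#' significant at `alpha`, treated scores are residualized using the control
#' coefficients (score minus slope times age centered at the control mean
#' age); otherwise they are returned unchanged and the non-significant test
#' is reported.
#'
#' @param treated_scores,treated_ages Scores and ages of the treated scans.
#' @param control_scores,control_ages Scores and ages of the untreated
#'   affected controls (>= 3 distinct ages required).
#' @param alpha Significance level for the control age effect (default 0.05).
#' @return List with `scores` (the possibly-adjusted treated scores) and
#'   `test` (slope, se, t, p, significant, mean_control_age, n).
#' @export
age_standardize <- function(treated_scores, treated_ages, control_scores,
                            control_ages, alpha = 0.05) {
  test <- control_age_regression(control_scores, control_ages)
  test$significant <- test$p < alpha
  test$mean_control_age <- mean(control_ages)
  adjusted <- if (test$significant) {
    treated_scores - test$slope * (treated_ages - test$mean_control_age)
  } else {
    treated_scores
  }
  list(scores = adjusted, test = test)
}
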