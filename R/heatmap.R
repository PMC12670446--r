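# Per-vertex phenotype score fields for heatmap rendering.

#' Per-vertex phenotype scores for one aligned scan
#'
#' Decomposes the global phenotype score into local contributions: at each
#' landmark j, the scan's 3-vector displacement from the model-predicted
#' normative shape of its age and sex is projected onto the local axis vector
#' v_j and divided by |v_j|^2, so a scan displaced by exactly the axis scores
#' 1 everywhere the axis has local signal. Landmarks where the axis magnitude
#' falls below `eps * ||v|| / sqrt(k)` carry no signal and are scored 0.
#' The |v_j|^2-weighted mean of the vertex scores equals the scan's global
#' normalized score (up to the thresholded vertices).
#'
#' @param config k x 3 scan configuration, already aligned into the shape
#'   space frame.
#' @param age,sex Scan covariates.
#' @param axis A [fit_phenotype_axis()] fit carrying a landmark-space axis
#'   (fitted with `space`).
#' @param space The [fit_pca()] shape space.
#' @param eps Relative threshold below which a vertex's axis magnitude is
#'   treated as zero signal (default 1e-3).
#' @return Numeric vector of k per-vertex scores (positive = locally more
#'   affected-like, negative = more normative-like than predicted).
#' @export
vertex_scores <- function(config, age, sex, axis, space, eps = 1e-3) {
  stopifnot(inherits(axis, "phenotype_axis"), inherits(space, "shape_space"))
  if (is.null(axis$group_vector_landmark)) {
    stop("axis has no landmark-space vector; fit it with `space`", call. = FALSE)
  }
  config <- as_config(config)
  k <- nrow(config)
  if (k != space$k) {
    stop("configuration landmark count does not match the shape space",
         call. = FALSE)
  }
  mu_pc <- drop(predict_normative(axis, as.numeric(age), code_sex(sex)))
  pred_flat <- space$center +
    as.numeric(space$rotation[, seq_len(axis$n_components), drop = FALSE] %*% mu_pc)
  d <- config - unflatten_config(pred_flat)
  v <- axis$group_vector_landmark
  vnorm2 <- rowSums(v^2)
  thr2 <- (eps * axis$norm_v / sqrt(k))^2
  out <- numeric(k)
  ok <- vnorm2 > thr2
  out[ok] <- rowSums(d * v)[ok] / vnorm2[ok]
  out
}

#' Change in per-vertex scores between two visits
#'
#' Elementwise difference `last - first`; negative values mean the region
#' moved toward the normative morphology.
#'
#' @param first_visit_field,last_visit_field Per-vertex score vectors of equal
#'   length, as returned by [vertex_scores()].
#' @return Numeric vector of per-vertex score changes.
#' @export
vertex_score_change <- function(first_visit_field, last_visit_field) {
  if (length(first_visit_field) != length(last_visit_field)) {
    stop("vertex score fields have different landmark counts", call. = FALSE)
  }
  last_visit_field - first_visit_field
}
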