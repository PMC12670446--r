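#' Principal component shape space of aligned configurations
#'
#' Flattens each aligned configuration to a 3k-vector (x1, y1, z1, x2, ...),
#' centers on the sample mean shape, and eigendecomposes the sample covariance
#' (via singular value decomposition). Coordinates share units after unit-size
#' scaling, so the covariance (not correlation) matrix is decomposed.
#'
#' @param aligned A [gpa()] fit, a list of aligned k x 3 matrices, or an
#'   N x 3k data matrix of flattened configurations.
#' @param n_retained Optional retained-component count (e.g. from
#'   [parallel_analysis()]); stored on the object and used as the default
#'   dimension for [project()].
#' @return Object of class `shape_space`: `center` (3k mean vector),
#'   `consensus` (k x 3, the GPA consensus when available, else the mean
#'   shape), `rotation` (3k x m orthonormal basis), `eigenvalues`,
#'   `variance_explained_cum`, `k`, `n_samples`, `n_retained`, `scan_ids`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_normative = 20, n_achondro = 10,
#'                                       n_treated = 0, seed = 11))
#' space <- fit_pca(gpa(cohort$configurations))
#' space
#' @export
fit_pca <- function(aligned, n_retained = NULL) {
  consensus <- NULL
  scan_ids <- NULL
  if (inherits(aligned, "gpa")) {
    consensus <- aligned$consensus
    scan_ids <- aligned$scan_ids
    aligned <- aligned$configurations
  }
  if (is.list(aligned)) {
    scan_ids <- scan_ids %||% names(aligned)
    x <- t(vapply(aligned, flatten_config,
                  numeric(3L * nrow(aligned[[1L]]))))
  } else {
    x <- as.matrix(aligned)
    scan_ids <- scan_ids %||% rownames(x)
  }
  if (nrow(x) < 2L) {
    stop("insufficient data: PCA needs at least 2 samples", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  k <- ncol(x) / 3L
  structure(list(
    center = as.numeric(pc$center),
    consensus = consensus %||% unflatten_config(as.numeric(pc$center)),
    rotation = pc$rotation,
    eigenvalues = eig,
    variance_explained_cum = cumsum(eig) / sum(eig),
    k = as.integer(k),
    n_samples = nrow(x),
    n_retained = if (is.null(n_retained)) NULL else as.integer(n_retained),
    scan_ids = scan_ids
  ), class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  m <- length(x$eigenvalues)
  cat(sprintf("Shape space: %d samples, %d landmarks, %d components\n",
              x$n_samples, x$k, m))
  if (!is.null(x$n_retained) && x$n_retained >= 1L) {
    cat(sprintf("retained: %d components (%.1f%% of variance)\n",
                x$n_retained,
                100 * x$variance_explained_cum[x$n_retained]))
  }
  invisible(x)
}

# Sample-covariance eigenvalues of a data matrix, via SVD of the centered data.
cov_eigenvalues <- function(x) {
  xc <- sweep(x, 2L, colMeans(x))
  svd(xc, nu = 0L, nv = 0L)$d^2 / (nrow(x) - 1L)
}

#' Parallel analysis for principal component retention
#'
#' Horn-style retention rule: a component is supported if its observed
#' eigenvalue exceeds the chosen percentile of eigenvalues obtained from
#' reference data with no correlation structure. The default reference
#' permutes each variable independently across samples, preserving every
#' marginal distribution exactly; a Gaussian reference with matched
#' per-variable SDs is also available. The retained count is the largest m
#' such that components 1..m all pass.
#'
#' @param x A [gpa()] fit, list of aligned configurations, or N x p data
#'   matrix.
#' @param n_permutations Number of reference datasets (default 100).
#' @param percentile Null percentile a component must exceed (default 95).
#' @param seed Optional integer seed for the reference draws.
#' @param reference `"permutation"` (default) or `"normal"`.
#' @return Object of class `parallel_analysis`: `n_retained`, `observed`
#'   eigenvalues, per-component null `thresholds`, and the settings used.
#' @examples
#' x <- matrix(rnorm(100 * 20), 100, 20)  # structureless data
#' parallel_analysis(x, n_permutations = 50, seed = 1)$n_retained
#' @export
parallel_analysis <- function(x, n_permutations = 100L, percentile = 95,
                              seed = NULL,
                              reference = c("permutation", "normal")) {
  reference <- match.arg(reference)
  if (inherits(x, "gpa")) x <- x$configurations
  if (is.list(x)) {
    x <- t(vapply(x, flatten_config, numeric(3L * nrow(x[[1L]]))))
  }
  x <- as.matrix(x)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  }
  observed <- cov_eigenvalues(x)
  n <- nrow(x)
  p <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  null_eig <- with_seed(seed, {
    t(vapply(seq_len(n_permutations), function(i) {
      ref <- if (reference == "permutation") {
        apply(x, 2L, sample)
      } else {
        sweep(matrix(stats::rnorm(n * p), n, p), 2L, sds, `*`)
      }
      cov_eigenvalues(ref)
    }, numeric(length(observed))))
  })
  thresholds <- apply(null_eig, 2L, stats::quantile, probs = percentile / 100)
  passes <- observed > thresholds
  n_retained <- if (!passes[1L]) 0L else {
    first_fail <- which(!passes)
    if (length(first_fail) == 0L) length(passes) else first_fail[1L] - 1L
  }
  structure(list(
    n_retained = as.integer(n_retained),
    observed = observed,
    thresholds = thresholds,
    n_permutations = n_permutations,
    percentile = percentile,
    reference = reference
  ), class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf(
    "Parallel analysis (%s reference, %d draws, %gth percentile): retain %d component(s)\n",
    x$reference, x$n_permutations, x$percentile, x$n_retained))
  invisible(x)
}

#' Project configurations into a shape space
#'
#' Returns coordinates on the first `n_components` principal axes of the
#' space, after centering on the space's mean shape.
#'
#' @param shape A k x 3 aligned configuration, a list of them, or an N x 3k
#'   matrix of flattened configurations. Must already be in the space's
#'   alignment frame.
#' @param space A [fit_pca()] shape space.
#' @param n_components Number of leading components; defaults to the space's
#'   retained count, or all components if none is set.
#' @return A score vector (single shape) or N x n_components score matrix.
#' @export
project <- function(shape, space, n_components = NULL) {
  stopifnot(inherits(space, "shape_space"))
  n_components <- as.integer(n_components %||% space$n_retained %||%
                               ncol(space$rotation))
  if (n_components < 1L || n_components > ncol(space$rotation)) {
    stop(sprintf("n_components must lie in 1..%d", ncol(space$rotation)),
         call. = FALSE)
  }
  single <- FALSE
  if (is.list(shape)) {
    x <- t(vapply(shape, flatten_config, numeric(3L * nrow(shape[[1L]]))))
  } else {
    shape <- as.matrix(shape)
    if (ncol(shape) == 3L) {
      x <- matrix(flatten_config(shape), 1L)
      single <- TRUE
    } else {
      x <- shape
    }
  }
  if (ncol(x) != length(space$center)) {
    stop("configuration dimension does not match the shape space", call. = FALSE)
  }
  scores <- sweep(x, 2L, space$center) %*% space$rotation[, seq_len(n_components), drop = FALSE]
  if (single) drop(scores) else scores
}

#' Reconstruct configurations from shape-space scores
#'
#' Inverse of [project()]: maps PC scores back to landmark coordinates.
#'
#' @param scores Score vector or N x m score matrix.
#' @param space A [fit_pca()] shape space.
#' @return A k x 3 configuration (vector input) or N x 3k matrix.
#' @export
reconstruct <- function(scores, space) {
  stopifnot(inherits(space, "shape_space"))
  single <- is.null(dim(scores))
  scores <- if (single) matrix(scores, 1L) else as.matrix(scores)
  m <- ncol(scores)
  flat <- sweep(scores %*% t(space$rotation[, seq_len(m), drop = FALSE]),
                2L, space$center, `+`)
  if (single) unflatten_config(drop(flat)) else flat
}
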