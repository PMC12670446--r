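#' Bilateral landmark correspondence map
#'
#' Records which landmarks form left/right pairs and which lie on the facial
#' midline (sagittal plane, by convention x = 0). The map drives
#' [reflect_relabel()] and hence [symmetrize()]: reflecting a configuration
#' about x = 0 turns left landmarks into right ones, so their labels must be
#' swapped to restore homology.
#'
#' @param pairs Two-column integer matrix; column 1 holds left-side indices,
#'   column 2 the matching right-side indices.
#' @param midline Integer vector of midline landmark indices.
#' @param k Total landmark count. Defaults to the number of mapped indices.
#' @return An object of class `bilateral_map` with elements `pairs`, `midline`,
#'   `k` and the label-swap permutation `perm`.
#' @examples
#' tpl <- make_template(n_pairs = 5, n_midline = 3, seed = 1)
#' tpl$map
#' @export
bilateral_map <- function(pairs, midline = integer(), k = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  midline <- as.integer(midline)
  idx <- c(pairs[, 1L], pairs[, 2L], midline)
  k <- as.integer(k %||% length(idx))
  if (length(idx) != k || anyDuplicated(idx) || !setequal(idx, seq_len(k))) {
    stop("bilateral map indices must partition 1..k with no repeats",
         call. = FALSE)
  }
  perm <- seq_len(k)
  perm[pairs[, 1L]] <- pairs[, 2L]
  perm[pairs[, 2L]] <- pairs[, 1L]
  structure(list(pairs = pairs, midline = midline, k = k, perm = perm),
            class = "bilateral_map")
}

#' @export
print.bilateral_map <- function(x, ...) {
  cat(sprintf("Bilateral map: %d landmarks (%d pairs, %d midline)\n",
              x$k, nrow(x$pairs), length(x$midline)))
  invisible(x)
}

#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometrics size measure: the square root of the
#' summed squared distances of all landmarks to their centroid.
#'
#' @param config A k x 3 landmark matrix.
#' @return A positive scalar.
#' @examples
#' centroid_size(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))  # 1.5
#' @export
centroid_size <- function(config) {
  config <- as_config(config)
  cs <- sqrt(sum(sweep(config, 2L, colMeans(config))^2))
  if (cs < 1e-12) {
    stop("degenerate configuration: all landmarks coincide (centroid size 0)",
         call. = FALSE)
  }
  cs
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Finds the translation, proper rotation (no reflection; determinant +1) and,
#' optionally, positive scaling of `mobile` minimizing the summed squared
#' distances to `target`.
#'
#' @param mobile,target k x 3 landmark matrices with the same k.
#' @param scale Solve for an optimal positive scale factor? Default `TRUE`.
#' @return List of class `opa` with `aligned` (the transformed mobile),
#'   `rotation`, `scale`, `translation` and `residual` (root summed squared
#'   distance to `target` after alignment).
#' @examples
#' tpl <- make_template(seed = 2)$template
#' moved <- 1.7 * tpl %*% diag(3) + matrix(5, nrow(tpl), 3)
#' opa_align(moved, tpl)$residual
#' @export
opa_align <- function(mobile, target, scale = TRUE) {
  mobile <- as_config(mobile, "mobile")
  target <- as_config(target, "target")
  if (nrow(mobile) != nrow(target)) {
    stop(sprintf("landmark counts differ: mobile has %d, target has %d",
                 nrow(mobile), nrow(target)), call. = FALSE)
  }
  centroid_size(mobile)
  centroid_size(target)
  mu_x <- colMeans(mobile)
  mu_y <- colMeans(target)
  xc <- sweep(mobile, 2L, mu_x)
  yc <- sweep(target, 2L, mu_y)
  m <- crossprod(xc, yc)
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  beta <- if (scale) sum(sv$d * c(1, 1, d)) / sum(xc^2) else 1
  aligned <- beta * xc %*% rot
  aligned <- sweep(aligned, 2L, mu_y, `+`)
  structure(list(
    aligned = aligned,
    rotation = rot,
    scale = beta,
    translation = mu_y - mu_x,
    residual = sqrt(sum((aligned - target)^2))
  ), class = "opa")
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centered and scaled to unit centroid size, then the
#' first is optimally rotated (and rescaled) onto the second; the residual root
#' summed squared distance is returned.
#'
#' @param a,b k x 3 landmark matrices.
#' @return Non-negative scalar; 0 iff the shapes are similar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as_config(a, "a")
  b <- as_config(b, "b")
  au <- sweep(a, 2L, colMeans(a)) / centroid_size(a)
  bu <- sweep(b, 2L, colMeans(b)) / centroid_size(b)
  opa_align(au, bu, scale = TRUE)$residual
}

#' Generalized Procrustes analysis
#'
#' Iteratively superimposes a set of configurations into a common shape frame:
#' every configuration is centered and scaled to unit centroid size, rotated
#' onto the running consensus, and the consensus (the mean shape, re-centered
#' and rescaled to unit size) is updated until its root-mean-square movement
#' falls below `tol` or `max_iter` is reached.
#'
#' @param configs List of k x 3 landmark matrices (all the same k), or a
#'   `synthetic_cohort` object.
#' @param tol Convergence tolerance on consensus RMS movement.
#' @param max_iter Iteration cap; hitting it sets `converged = FALSE` with a
#'   warning rather than an error.
#' @return Object of class `gpa`: `configurations` (aligned, unit centroid
#'   size, centered at the origin), `consensus`, `centroid_sizes` (original
#'   sizes), `iterations`, `converged`, `scan_ids`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_normative = 10, n_achondro = 5,
#'                                       n_treated = 0, seed = 3))
#' fit <- gpa(cohort$configurations)
#' fit
#' @export
gpa <- function(configs, tol = 1e-8, max_iter = 100L) {
  if (inherits(configs, "synthetic_cohort")) configs <- configs$configurations
  if (!is.list(configs) || length(configs) < 2L) {
    stop("gpa() needs a list of at least 2 configurations", call. = FALSE)
  }
  scan_ids <- names(configs) %||% sprintf("scan%04d", seq_along(configs))
  configs <- lapply(configs, as_config)
  k <- nrow(configs[[1L]])
  same_k <- vapply(configs, nrow, 0L) == k
  if (!all(same_k)) {
    stop("all configurations must share the same landmark count", call. = FALSE)
  }
  sizes <- vapply(configs, centroid_size, 0)
  unit <- mapply(function(x, s) sweep(x, 2L, colMeans(x)) / s,
                 configs, sizes, SIMPLIFY = FALSE)

  consensus <- unit[[1L]]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    unit <- lapply(unit, function(x) opa_align(x, consensus, scale = FALSE)$aligned)
    new_consensus <- Reduce(`+`, unit) / length(unit)
    new_consensus <- sweep(new_consensus, 2L, colMeans(new_consensus))
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    delta <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("GPA did not converge in %d iterations", max_iter),
            call. = FALSE)
  }
  unit <- lapply(unit, function(x) opa_align(x, consensus, scale = FALSE)$aligned)
  names(unit) <- scan_ids
  structure(list(
    configurations = unit,
    consensus = consensus,
    centroid_sizes = stats::setNames(sizes, scan_ids),
    iterations = iter,
    converged = converged,
    scan_ids = scan_ids
  ), class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf(
    "Generalized Procrustes fit: %d configurations, %d landmarks\n%s after %d iteration(s)\n",
    length(x$configurations), nrow(x$consensus),
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Reflect a configuration and restore bilateral homology
#'
#' Negates the x coordinate of every landmark (mirror about the sagittal plane
#' x = 0), then swaps the labels of each left/right pair so that landmark j of
#' the output is again homologous with landmark j of the input. Midline labels
#' are unchanged. Applying the operation twice is the identity.
#'
#' @param config k x 3 landmark matrix.
#' @param map A [bilateral_map()] valid for k landmarks.
#' @return The reflected, relabeled k x 3 matrix.
#' @export
reflect_relabel <- function(config, map) {
  config <- as_config(config)
  if (!inherits(map, "bilateral_map")) {
    stop("`map` must be a bilateral_map", call. = FALSE)
  }
  if (map$k != nrow(config)) {
    stop(sprintf("bilateral map covers %d landmarks but configuration has %d",
                 map$k, nrow(config)), call. = FALSE)
  }
  refl <- config
  refl[, 1L] <- -refl[, 1L]
  refl[map$perm, , drop = FALSE]
}

#' Bilateral symmetrization of a configuration
#'
#' Computes the reflected-and-relabeled copy of the configuration, aligns it
#' back onto the original by ordinary Procrustes superimposition (translation
#' and rotation only: reflection is an isometry, and allowing scale would
#' shrink the reflected copy toward the original and break idempotence), and
#' returns the pointwise average of the two. The result carries only the
#' symmetric component of shape; symmetrizing again changes nothing (to
#' numerical tolerance), and a perfectly symmetric input is a fixed point.
#'
#' @inheritParams reflect_relabel
#' @return A k x 3 symmetric landmark matrix.
#' @export
symmetrize <- function(config, map) {
  config <- as_config(config)
  refl <- reflect_relabel(config, map)
  (config + opa_align(refl, config, scale = FALSE)$aligned) / 2
}
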