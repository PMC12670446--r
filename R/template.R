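#' Build a bilaterally symmetric template configuration
#'
#' Generates a face-like point cloud on the front half of an ellipsoid:
#' `n_pairs` jittered points on the +x side mirrored exactly onto the -x side,
#' plus `n_midline` points lying exactly on the sagittal plane x = 0. The
#' template is exactly symmetric under its own bilateral map and stands in for
#' a dense facial atlas: the analysis only needs homology and bilateral
#' structure, not anatomy.
#'
#' Landmark order is: left-side pair members (indices 1..n_pairs), their right
#' mirrors (n_pairs+1..2*n_pairs), then midline points.
#'
#' @param n_pairs Number of bilateral landmark pairs.
#' @param n_midline Number of midline landmarks.
#' @param seed Integer seed for reproducibility; `NULL` uses the current RNG
#'   stream.
#' @param semiaxes Ellipsoid semi-axes (x = left-right, y = vertical,
#'   z = depth).
#' @param jitter SD of the Gaussian jitter applied to surface points.
#' @return List with `template` (k x 3 matrix, k = 2*n_pairs + n_midline) and
#'   `map` (a [bilateral_map()]).
#' @examples
#' tpl <- make_template(n_pairs = 25, n_midline = 10, seed = 1)
#' max(abs(reflect_relabel(tpl$template, tpl$map) - tpl$template))  # 0
#' @export
make_template <- function(n_pairs = 25L, n_midline = 10L, seed = NULL,
                          semiaxes = c(1, 1.3, 0.8), jitter = 0.05) {
  n_pairs <- as.integer(n_pairs)
  n_midline <- as.integer(n_midline)
  if (n_pairs < 0L || n_midline < 0L || 2L * n_pairs + n_midline < 4L) {
    stop("template needs n_pairs >= 0, n_midline >= 0 and at least 4 landmarks",
         call. = FALSE)
  }
  with_seed(seed, {
    k <- 2L * n_pairs + n_midline
    pts <- matrix(0, k, 3L)
    if (n_pairs > 0L) {
      frac <- stats::runif(n_pairs, 0.15, 0.95)   # x offset fraction, kept off the midline
      ang <- stats::runif(n_pairs, 0, pi)          # position on the front half (z >= 0)
      r <- sqrt(1 - frac^2)
      left <- cbind(semiaxes[1L] * frac,
                    semiaxes[2L] * r * cos(ang),
                    semiaxes[3L] * r * sin(ang))
      left <- left + matrix(stats::rnorm(3L * n_pairs, sd = jitter), n_pairs, 3L)
      right <- left
      right[, 1L] <- -right[, 1L]
      pts[seq_len(n_pairs), ] <- left
      pts[n_pairs + seq_len(n_pairs), ] <- right
    }
    if (n_midline > 0L) {
      ang <- stats::runif(n_midline, 0, pi)
      mid <- cbind(0,
                   semiaxes[2L] * cos(ang),
                   semiaxes[3L] * sin(ang))
      mid[, 2L:3L] <- mid[, 2L:3L] +
        matrix(stats::rnorm(2L * n_midline, sd = jitter), n_midline, 2L)
      pts[2L * n_pairs + seq_len(n_midline), ] <- mid
    }
    map <- bilateral_map(
      pairs = cbind(seq_len(n_pairs), n_pairs + seq_len(n_pairs)),
      midline = if (n_midline > 0L) 2L * n_pairs + seq_len(n_midline) else integer(),
      k = k
    )
    list(template = pts, map = map)
  })
}

# Orthonormal basis (3k x 7) for the similarity tangent directions of a
# configuration: 3 translations, 3 infinitesimal rotations, 1 scaling.
# Displacements along these are removed by Procrustes alignment, so effect
# fields are orthogonalized against them to be pure shape changes.
similarity_tangent_basis <- function(template) {
  k <- nrow(template)
  cen <- sweep(template, 2L, colMeans(template))
  zero <- numeric(k)
  one <- rep(1, k)
  cols <- cbind(
    flatten_config(cbind(one, zero, zero)),
    flatten_config(cbind(zero, one, zero)),
    flatten_config(cbind(zero, zero, one)),
    flatten_config(cbind(zero, -cen[, 3L], cen[, 2L])),   # rotation about x
    flatten_config(cbind(cen[, 3L], zero, -cen[, 1L])),   # rotation about y
    flatten_config(cbind(-cen[, 2L], cen[, 1L], zero)),   # rotation about z
    flatten_config(cen)                                   # scaling
  )
  qr.Q(qr(cols))
}

#' Smooth, bilaterally symmetric displacement field
#'
#' Draws i.i.d. Gaussian noise at every landmark, smooths it with a Gaussian
#' distance kernel over the template geometry so that nearby landmarks move
#' coherently, symmetrizes it under the bilateral map (so the field cannot
#' create asymmetry), projects out the template's similarity tangent
#' directions (translations, infinitesimal rotations, scaling — which
#' Procrustes alignment would silently absorb, making part of the injected
#' effect unrecoverable), and rescales the result to a prescribed
#' root-mean-square magnitude. Used by the cohort simulator for group, sex,
#' growth and per-subject effects.
#'
#' @param template k x 3 template configuration (defines landmark geometry).
#' @param map The template's [bilateral_map()].
#' @param smoothness Gaussian kernel bandwidth, in template coordinate units.
#' @param scale Target RMS magnitude `sqrt(sum(field^2) / k)`; 0 gives the
#'   zero field.
#' @param seed Optional integer seed.
#' @return A k x 3 displacement matrix with `reflect_relabel(field, map)`
#'   equal to `field`.
#' @export
make_effect_field <- function(template, map, smoothness = 0.5, scale = 1,
                              seed = NULL) {
  template <- as_config(template, "template")
  if (smoothness <= 0) stop("`smoothness` must be > 0", call. = FALSE)
  if (scale < 0) stop("`scale` must be >= 0", call. = FALSE)
  k <- nrow(template)
  if (scale == 0) {
    return(matrix(0, k, 3L))
  }
  with_seed(seed, {
    d2 <- as.matrix(stats::dist(template))^2
    kern <- exp(-d2 / (2 * smoothness^2))
    field <- kern %*% matrix(stats::rnorm(3L * k), k, 3L)
    field <- (field + reflect_relabel(field, map)) / 2
    basis <- similarity_tangent_basis(template)
    flat <- flatten_config(field)
    field <- unflatten_config(flat - basis %*% crossprod(basis, flat))
    # projection preserves bilateral symmetry: the symmetric/antisymmetric
    # split of the tangent basis is exact, so re-symmetrize only to clean
    # rounding error
    field <- (field + reflect_relabel(field, map)) / 2
    rms <- sqrt(sum(field^2) / k)
    if (rms < 1e-12) {
      stop("effect field degenerated to zero; try a different seed", call. = FALSE)
    }
    field * (scale / rms)
  })
}
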