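# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded generators never perturb global reproducibility.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Landmark configurations are k x 3 numeric matrices. The flattened layout is
# (x1, y1, z1, x2, y2, z2, ...), matching the wide-CSV column convention.
flatten_config <- function(x) {
  as.numeric(t(x))
}

unflatten_config <- function(v) {
  matrix(v, ncol = 3L, byrow = TRUE)
}

as_config <- function(x, arg = "config") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) {
    stop(sprintf("`%s` must be a k x 3 landmark matrix, got %d column(s)",
                 arg, ncol(x)), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite coordinates", arg), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

config_centroid <- function(x) colMeans(x)

# Uniform random rotation in SO(3) via QR of a Gaussian matrix with sign fix.
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_dec)
  q <- q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
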