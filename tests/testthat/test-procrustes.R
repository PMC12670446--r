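test_that("centroid size matches hand computation and scaling laws", {
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(centroid_size(tetra), 1.5)  # centroid (1/4,1/4,1/4), sum sq 9/4
  expect_equal(centroid_size(3.7 * tetra), 3.7 * 1.5)
  expect_equal(centroid_size(sweep(tetra, 2, c(5, -2, 9), `+`)), 1.5)
  expect_error(centroid_size(matrix(1, 4, 3)), "degenerate")
})

test_that("OPA recovers similarity transforms and refuses shape mismatches", {
  tpl <- small_template()$template
  moved <- similarity_copy(tpl, seed = 10)
  fit <- opa_align(moved, tpl)
  expect_lt(fit$residual, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  self <- opa_align(tpl, tpl)
  expect_equal(self$residual, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-10)
  expect_equal(self$scale, 1, tolerance = 1e-12)

  expect_error(opa_align(tpl[1:5, ], tpl), "landmark counts differ")
})

test_that("OPA never uses improper rotations, even for mirrored input", {
  tpl <- asymmetric_config(small_template(), seed = 4)
  mirrored <- tpl
  mirrored[, 1] <- -mirrored[, 1]
  fit <- opa_align(mirrored, tpl)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$residual, 0.01)  # a reflection could match exactly; a rotation cannot
})

test_that("OPA residual matches a brute-force rotation-space minimization", {
  # independent oracle: numerical optimization over unit quaternions + scale
  quat_to_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    rbind(
      c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
      c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
      c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
    )
  }
  set.seed(77)
  for (rep in 1:3) {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    ac <- sweep(a, 2, colMeans(a))
    bc <- sweep(b, 2, colMeans(b))
    objective <- function(par) {
      rot <- quat_to_rot(par[1:4])
      s <- exp(par[5])
      sum((s * ac %*% rot - bc)^2)
    }
    best <- Inf
    for (start in 1:40) {
      par0 <- c(rnorm(4), rnorm(1, 0, 0.3))
      opt <- optim(par0, objective, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, opt$value)
    }
    expect_equal(opa_align(a, b)$residual, sqrt(best), tolerance = 1e-6)
  }
})

test_that("GPA aligns similarity copies of one shape onto a common consensus", {
  tpl <- small_template()$template
  copies <- lapply(1:12, function(i) similarity_copy(tpl, seed = 100 + i))
  fit <- gpa(copies)
  expect_true(fit$converged)
  d <- vapply(fit$configurations,
              function(x) sqrt(sum((x - fit$consensus)^2)), 0)
  expect_lt(max(d), 1e-8)
  # unit centroid size and centered consensus
  expect_equal(centroid_size(fit$consensus), 1, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(fit$consensus))), 1e-10)
  sizes <- vapply(fit$configurations, centroid_size, 0)
  expect_equal(unname(sizes), rep(1, 12), tolerance = 1e-8)
})

test_that("GPA consensus of two shapes is equidistant from both", {
  tpl <- small_template()
  a <- asymmetric_config(tpl, seed = 1)
  b <- asymmetric_config(tpl, seed = 2)
  fit <- gpa(list(a, b))
  d <- vapply(fit$configurations,
              function(x) sqrt(sum((x - fit$consensus)^2)), 0)
  expect_equal(d[[1]], d[[2]], tolerance = 1e-8)
})

test_that("input order changes GPA output only up to a global rotation", {
  tpl <- small_template()
  configs <- lapply(1:6, function(i) asymmetric_config(tpl, seed = i))
  fit1 <- gpa(configs)
  fit2 <- gpa(rev(configs))
  pairdist <- function(fit, ord) {
    cfg <- fit$configurations[ord]
    n <- length(cfg)
    out <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      out <- c(out, sqrt(sum((cfg[[i]] - cfg[[j]])^2)))
    }
    out
  }
  expect_equal(pairdist(fit1, 1:6), pairdist(fit2, 6:1), tolerance = 1e-8)
})

test_that("GPA rejects degenerate input sets", {
  tpl <- small_template()$template
  expect_error(gpa(list(tpl)), "at least 2")
  expect_error(gpa(list(tpl, tpl[1:5, ])), "same landmark count")
})

test_that("reflect-relabel is an involution that preserves centroid size", {
  tpl <- small_template()
  cfg <- asymmetric_config(tpl, seed = 9)
  refl <- reflect_relabel(cfg, tpl$map)
  expect_false(isTRUE(all.equal(refl, cfg)))
  expect_identical(reflect_relabel(refl, tpl$map), cfg)
  expect_equal(centroid_size(refl), centroid_size(cfg))
})

test_that("symmetrize fixes symmetric inputs and is idempotent", {
  tpl <- small_template()
  expect_equal(symmetrize(tpl$template, tpl$map), tpl$template,
               tolerance = 1e-10)
  for (s in 1:5) {
    cfg <- asymmetric_config(tpl, seed = 200 + s)
    sym1 <- symmetrize(cfg, tpl$map)
    sym2 <- symmetrize(sym1, tpl$map)
    expect_lt(max(abs(sym2 - sym1)), 1e-8)
    # output is symmetric: its reflection aligns back onto it
    resid <- opa_align(reflect_relabel(sym1, tpl$map), sym1)$residual
    expect_lt(resid, 1e-6)
  }
})

test_that("alignment results are invariant to similarity transforms of the input", {
  tpl <- small_template()
  configs <- lapply(1:5, function(i) asymmetric_config(tpl, seed = 300 + i))
  moved <- lapply(seq_along(configs), function(i) {
    similarity_copy(configs[[i]], seed = 400 + i)
  })
  d1 <- gpa(configs)
  d2 <- gpa(moved)
  dist1 <- sqrt(sum((d1$configurations[[1]] - d1$configurations[[2]])^2))
  dist2 <- sqrt(sum((d2$configurations[[1]] - d2$configurations[[2]])^2))
  expect_equal(dist1, dist2, tolerance = 1e-8)
})
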