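# Shared fixtures, built in code at test time.

cosine <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Small template + map used across superimposition tests.
small_template <- function(seed = 42L) {
  make_template(n_pairs = 8L, n_midline = 4L, seed = seed)
}

# Random similarity transform of a configuration.
similarity_copy <- function(config, seed = NULL) {
  with_seed <- get("with_seed", envir = asNamespace("morphoscore"))
  rot <- get("random_rotation", envir = asNamespace("morphoscore"))
  with_seed(seed, {
    s <- runif(1, 0.5, 2)
    tr <- runif(3, -10, 10)
    sweep(s * config %*% rot(), 2, tr, `+`)
  })
}

# Asymmetric configuration derived from a symmetric template.
asymmetric_config <- function(tpl, seed = 1L, sd = 0.1) {
  set.seed(seed)
  tpl$template + matrix(rnorm(3 * nrow(tpl$template), sd = sd),
                        nrow(tpl$template), 3)
}

# Align+PCA+axis-fit on a simulated cohort; returns pieces needed by the
# scoring tests. Axis is fitted on the full PC basis unless m is given.
fit_cohort_axis <- function(spec, m = NULL) {
  cohort <- simulate_cohort(spec)
  md <- cohort$metadata
  sym <- lapply(cohort$configurations, symmetrize,
                map = cohort$truth$bilateral_map)
  fit <- gpa(sym)
  space <- fit_pca(fit)
  m <- if (is.null(m)) ncol(space$rotation) else m
  sc <- project(fit$configurations, space, m)
  ctrl <- md$group %in% c("normative", "achondroplasia")
  axis <- fit_phenotype_axis(sc[ctrl, , drop = FALSE], md$age_years[ctrl],
                             md$sex[ctrl], md$group[ctrl], space = space)
  list(cohort = cohort, gpa = fit, space = space, scores = sc, axis = axis,
       metadata = md)
}

# Rotate the generator's true axis field into the GPA consensus frame.
truth_axis_in_frame <- function(cohort, gpa_fit) {
  tpl <- cohort$truth$template
  tplu <- sweep(tpl, 2, colMeans(tpl)) / centroid_size(tpl)
  rot <- opa_align(tplu, gpa_fit$consensus)$rotation
  cohort$truth$group_axis_true %*% rot
}
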