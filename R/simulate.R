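#' Specify a synthetic landmark cohort
#'
#' Collects the design of a simulated study: a large cross-sectional normative
#' cohort, a cross-sectional affected (achondroplasia-like) control cohort, and
#' a small longitudinal treated cohort followed over repeated visits, some of
#' whose members start on placebo and receive the drug one year later. The
#' defaults describe the validation study used throughout the package: 60
#' landmarks, 200 normative and 96 affected controls, and 14 treated subjects
#' seen at 7 visits half a year apart, 4 of them on the placebo-first protocol,
#' with treatment moving shape along the true group axis at -0.05 score units
#' per year.
#'
#' @param n_pairs,n_midline Template landmark structure (see [make_template()]).
#' @param n_normative,n_achondro Cross-sectional cohort sizes (one scan per
#'   subject).
#' @param n_treated Number of treated subjects.
#' @param visits_per_treated Scans per treated subject.
#' @param visit_spacing_years Time between consecutive visits, years.
#' @param protocol_split Fraction of treated subjects assigned the
#'   placebo-first protocol (first dose one year after their first visit).
#' @param age_range_years Length-2 interval from which cross-sectional ages are
#'   drawn uniformly.
#' @param group_effect_scale RMS magnitude of the affected-group displacement
#'   field (template coordinate units).
#' @param sex_effect_scale RMS magnitude of the sex displacement field.
#' @param growth_coeffs Cubic polynomial coefficients (year, year^2, year^3)
#'   applied to a unit-RMS growth field as a function of age centered on the
#'   cohort age range.
#' @param subject_sd Per-coordinate SD of each subject's random smooth shape
#'   offset.
#' @param treatment_slope True score change per year on drug, in normalized
#'   score units (1 = the normative-to-affected mean displacement).
#' @param noise_sd Per-coordinate SD of i.i.d. Gaussian measurement noise.
#' @param smoothness Kernel bandwidth for all smooth effect fields.
#' @param seed Integer seed controlling the whole cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 25L, n_midline = 10L,
                        n_normative = 200L, n_achondro = 96L,
                        n_treated = 14L, visits_per_treated = 7L,
                        visit_spacing_years = 0.5, protocol_split = 4 / 14,
                        age_range_years = c(3, 16),
                        group_effect_scale = 0.08, sex_effect_scale = 0.03,
                        growth_coeffs = c(0.02, -0.002, 1e-4),
                        subject_sd = 0.03, treatment_slope = -0.05,
                        noise_sd = 0.01, smoothness = 0.5, seed = 1L) {
  spec <- list(
    n_pairs = as.integer(n_pairs), n_midline = as.integer(n_midline),
    n_normative = as.integer(n_normative), n_achondro = as.integer(n_achondro),
    n_treated = as.integer(n_treated),
    visits_per_treated = as.integer(visits_per_treated),
    visit_spacing_years = visit_spacing_years,
    protocol_split = protocol_split,
    age_range_years = as.numeric(age_range_years),
    group_effect_scale = group_effect_scale,
    sex_effect_scale = sex_effect_scale,
    growth_coeffs = as.numeric(growth_coeffs),
    subject_sd = subject_sd, treatment_slope = treatment_slope,
    noise_sd = noise_sd, smoothness = smoothness, seed = as.integer(seed)
  )
  counts <- c(spec$n_pairs, spec$n_midline, spec$n_normative, spec$n_achondro,
              spec$n_treated, spec$visits_per_treated)
  if (any(counts < 0L)) stop("all counts must be >= 0", call. = FALSE)
  if (2L * spec$n_pairs + spec$n_midline < 4L) {
    stop("need at least 4 landmarks (2*n_pairs + n_midline >= 4)", call. = FALSE)
  }
  if (spec$noise_sd < 0 || spec$subject_sd < 0) {
    stop("noise_sd and subject_sd must be >= 0", call. = FALSE)
  }
  if (spec$protocol_split < 0 || spec$protocol_split > 1) {
    stop("protocol_split must lie in [0, 1]", call. = FALSE)
  }
  if (length(spec$age_range_years) != 2L ||
      diff(spec$age_range_years) < 0) {
    stop("age_range_years must be an ordered interval", call. = FALSE)
  }
  if (length(spec$growth_coeffs) != 3L) {
    stop("growth_coeffs must have 3 elements (year, year^2, year^3)",
         call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Cohort spec: k = %d landmarks; %d normative + %d affected + %d treated x %d visits (seed %d)\n",
    2L * x$n_pairs + x$n_midline, x$n_normative, x$n_achondro, x$n_treated,
    x$visits_per_treated, x$seed))
  invisible(x)
}

#' Simulate a bilateral landmark cohort with known ground truth
#'
#' Generates one scan per cross-sectional subject and a visit series per
#' treated subject. Each scan is the symmetric template plus additive effects
#' in landmark space — cubic age growth, sex, affected-group displacement,
#' a per-subject random smooth offset, a treatment displacement along the true
#' group axis proportional to years on drug, and i.i.d. Gaussian noise —
#' followed by a random similarity acquisition transform (uniform rotation,
#' translation in \[-10, 10\]^3, scale in \[0.5, 2\]) that the Procrustes stage
#' must undo. Placebo-first subjects have pre-dose visits with negative years
#' from first dose; those scans receive no treatment displacement.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `configurations` (named list of
#'   k x 3 matrices), `metadata` (data frame with scan_id, subject_id, group,
#'   sex, age_years, protocol, years_from_first_dose, true_score), and `truth`
#'   (template, bilateral map, group axis field, per-subject offsets, true
#'   treatment slope).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_normative = 20, n_achondro = 10,
#'                                       n_treated = 2, seed = 7))
#' table(cohort$metadata$group)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    tpl <- make_template(spec$n_pairs, spec$n_midline,
                         seed = NULL)
    template <- tpl$template
    map <- tpl$map
    k <- nrow(template)

    group_axis <- make_effect_field(template, map, spec$smoothness,
                                    scale = spec$group_effect_scale)
    sex_field <- make_effect_field(template, map, spec$smoothness,
                                   scale = spec$sex_effect_scale)
    growth_field <- make_effect_field(template, map, spec$smoothness, scale = 1)

    age_mid <- mean(spec$age_range_years)
    growth_at <- function(age) {
      t <- age - age_mid
      sum(spec$growth_coeffs * c(t, t^2, t^3))
    }
    subject_offset <- function() {
      if (spec$subject_sd == 0) return(matrix(0, k, 3L))
      f <- make_effect_field(template, map, spec$smoothness, scale = 1)
      f * spec$subject_sd / stats::sd(as.vector(f))
    }
    acquire <- function(shape) {
      rot <- random_rotation()
      s <- stats::runif(1L, 0.5, 2)
      tr <- stats::runif(3L, -10, 10)
      sweep(s * shape %*% rot, 2L, tr, `+`)
    }

    configs <- list()
    meta <- list()
    offsets <- list()
    scan_no <- 0L

    add_scan <- function(subject_id, group, sex, age, protocol, t_dose,
                         offset) {
      scan_no <<- scan_no + 1L
      sid <- sprintf("scan%04d", scan_no)
      on_drug_years <- if (group == "treated") max(t_dose, 0) else 0
      group01 <- as.numeric(group %in% c("achondroplasia", "treated"))
      true_score <- group01 + spec$treatment_slope * on_drug_years
      shape <- template +
        growth_at(age) * growth_field +
        (sex == "M") * sex_field +
        group01 * group_axis +
        spec$treatment_slope * on_drug_years * group_axis +
        offset +
        matrix(stats::rnorm(3L * k, sd = spec$noise_sd), k, 3L)
      configs[[sid]] <<- acquire(shape)
      meta[[sid]] <<- data.frame(
        scan_id = sid, subject_id = subject_id, group = group, sex = sex,
        age_years = age, protocol = protocol,
        years_from_first_dose = if (group == "treated") t_dose else NA_real_,
        true_score = true_score, stringsAsFactors = FALSE
      )
    }

    for (i in seq_len(spec$n_normative)) {
      subj <- sprintf("norm%03d", i)
      off <- subject_offset()
      offsets[[subj]] <- off
      add_scan(subj, "normative", sample(c("F", "M"), 1L),
               stats::runif(1L, spec$age_range_years[1L], spec$age_range_years[2L]),
               "none", NA_real_, off)
    }
    for (i in seq_len(spec$n_achondro)) {
      subj <- sprintf("ach%03d", i)
      off <- subject_offset()
      offsets[[subj]] <- off
      add_scan(subj, "achondroplasia", sample(c("F", "M"), 1L),
               stats::runif(1L, spec$age_range_years[1L], spec$age_range_years[2L]),
               "none", NA_real_, off)
    }
    n_placebo <- round(spec$protocol_split * spec$n_treated)
    for (i in seq_len(spec$n_treated)) {
      subj <- sprintf("trt%02d", i)
      off <- subject_offset()
      offsets[[subj]] <- off
      protocol <- if (i <= n_placebo) "placebo-first" else "drug"
      first_age <- max(spec$age_range_years[1L], stats::rnorm(1L, 5, 1))
      sex <- sample(c("F", "M"), 1L)
      for (v in seq_len(spec$visits_per_treated) - 1L) {
        visit_time <- v * spec$visit_spacing_years
        t_dose <- if (protocol == "placebo-first") visit_time - 1 else visit_time
        add_scan(subj, "treated", sex, first_age + visit_time, protocol,
                 t_dose, off)
      }
    }

    metadata <- do.call(rbind, unname(meta))
    if (is.null(metadata)) {
      metadata <- data.frame(
        scan_id = character(), subject_id = character(), group = character(),
        sex = character(), age_years = numeric(), protocol = character(),
        years_from_first_dose = numeric(), true_score = numeric(),
        stringsAsFactors = FALSE
      )
    }
    rownames(metadata) <- NULL
    structure(list(
      configurations = configs,
      metadata = metadata,
      truth = list(
        template = template, bilateral_map = map,
        group_axis_true = group_axis,
        treatment_slope_true = spec$treatment_slope,
        per_subject_offsets = offsets,
        sex_field = sex_field, growth_field = growth_field
      ),
      spec = spec
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d scans, %d landmarks\n",
              length(x$configurations),
              if (length(x$configurations)) nrow(x$configurations[[1L]]) else 0L))
  print(table(x$metadata$group))
  invisible(x)
}

#' Simulate a longitudinal score table for the treated cohort
#'
#' Generates phenotype scores directly at score level under the linear
#' mixed-model data-generating process the longitudinal analysis assumes:
#' per-subject random intercepts around an affected baseline, a linear drug
#' effect in years from first dose (no effect while a placebo-first subject is
#' still pre-dose), and independent per-visit noise. This is the ground truth
#' used to calibrate [fit_score_lmm()].
#'
#' @param n_subjects,visits,spacing Design shape: subjects, visits per subject
#'   and visit spacing in years.
#' @param slope True score change per year on drug.
#' @param protocol_split Fraction of subjects on the placebo-first protocol
#'   (first dose one year into the study, so early visits have negative years
#'   from first dose).
#' @param baseline Mean pre-treatment score (1 = affected mean).
#' @param subject_sd SD of the per-subject random intercept.
#' @param resid_sd SD of the per-visit score noise.
#' @param seed Optional integer seed.
#' @return Data frame with subject_id, protocol, years_from_first_dose, score
#'   and the noiseless true_score.
#' @export
simulate_score_table <- function(n_subjects = 14L, visits = 7L, spacing = 0.5,
                                 slope = -0.05, protocol_split = 4 / 14,
                                 baseline = 1, subject_sd = 0.3,
                                 resid_sd = 0.1, seed = NULL) {
  with_seed(seed, {
    n_placebo <- round(protocol_split * n_subjects)
    rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      protocol <- if (i <= n_placebo) "placebo-first" else "drug"
      u <- stats::rnorm(1L, sd = subject_sd)
      visit_time <- (seq_len(visits) - 1L) * spacing
      t_dose <- if (protocol == "placebo-first") visit_time - 1 else visit_time
      true <- baseline + slope * pmax(t_dose, 0)
      rows[[i]] <- data.frame(
        subject_id = sprintf("trt%02d", i), protocol = protocol,
        years_from_first_dose = t_dose,
        score = true + u + stats::rnorm(visits, sd = resid_sd),
        true_score = true, stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
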