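# End-to-end study orchestration: simulate/load -> symmetrize -> GPA ->
# PCA + parallel analysis -> axis fit -> scoring -> inference -> heatmaps.

#' Configure a full phenotype-scoring study
#'
#' Exactly one input source must be given: a [cohort_spec()] for simulation,
#' or paths to landmark, metadata and bilateral-map files. Configuration can
#' also be loaded from a YAML file with [read_study_config()].
#'
#' @param cohort A [cohort_spec()], or `NULL` when reading data from disk.
#' @param landmarks_csv,metadata_csv,bilateral_map_csv Input paths (wide
#'   landmark CSV, metadata CSV with scan_id/subject_id/group/sex/age_years/
#'   protocol/years_from_first_dose, and bilateral map CSV).
#' @param out_dir Output directory for all study artifacts.
#' @param seed Study seed, recorded in every output's provenance; governs the
#'   simulation and the parallel-analysis reference draws. Defaults to the
#'   cohort spec's seed (or 1 for disk input).
#' @param n_permutations,percentile,pa_reference Parallel-analysis settings.
#' @param alpha Significance level for the control age-effect test.
#' @param hotelling_dims Leading PCs for the paired test; `"auto"` caps at
#'   `min(13, n_pairs - 1)`.
#' @param max_retained Optional cap on retained components.
#' @return Object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(), landmarks_csv = NULL,
                         metadata_csv = NULL, bilateral_map_csv = NULL,
                         out_dir = tempfile("morphoscore_study"),
                         seed = NULL, n_permutations = 100L, percentile = 95,
                         pa_reference = "permutation", alpha = 0.05,
                         hotelling_dims = "auto", max_retained = NULL) {
  from_disk <- !is.null(landmarks_csv)
  if (from_disk && !is.null(cohort)) {
    stop("provide either a cohort spec or data paths, not both", call. = FALSE)
  }
  if (!from_disk && is.null(cohort)) {
    stop("provide a cohort spec or data paths", call. = FALSE)
  }
  if (from_disk && (is.null(metadata_csv) || is.null(bilateral_map_csv))) {
    stop("disk input needs landmarks_csv, metadata_csv and bilateral_map_csv",
         call. = FALSE)
  }
  seed <- seed %||% (if (!is.null(cohort)) cohort$seed else 1L)
  structure(list(
    cohort = cohort, landmarks_csv = landmarks_csv,
    metadata_csv = metadata_csv, bilateral_map_csv = bilateral_map_csv,
    out_dir = out_dir, seed = as.integer(seed),
    n_permutations = as.integer(n_permutations), percentile = percentile,
    pa_reference = pa_reference, alpha = alpha,
    hotelling_dims = hotelling_dims, max_retained = max_retained
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror [study_config()] arguments; a `cohort:` block holds
#' [cohort_spec()] arguments.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configuration requires the 'yaml' package", call. = FALSE)
  }
  conf <- yaml::read_yaml(path)
  if (!is.null(conf$cohort)) {
    conf$cohort <- do.call(cohort_spec, conf$cohort)
  }
  do.call(study_config, conf)
}

first_last_rows <- function(meta) {
  treated <- meta[meta$group == "treated", ]
  split_rows <- split(treated, treated$subject_id)
  first <- do.call(rbind, lapply(split_rows, function(d) {
    d[which.min(d$age_years), ]
  }))
  last <- do.call(rbind, lapply(split_rows, function(d) {
    d[which.max(d$age_years), ]
  }))
  list(first = first, last = last)
}

#' Run a complete phenotype-scoring study
#'
#' Executes every stage on one configuration: cohort simulation (or loading),
#' bilateral symmetrization, generalized Procrustes alignment, shape PCA with
#' parallel analysis for component retention, phenotype-axis regression on the
#' untreated controls, scoring of every scan (normalized, control-SD
#' standardized, and age-standardized if the controls show a significant age
#' trend), the paired Hotelling test of first-vs-last treated shape, the
#' longitudinal mixed model of score change, and per-subject first/last/change
#' heatmap PLYs. All intermediate artifacts are written to `out_dir` so any
#' stage can be re-run independently, together with a provenance log (seed,
#' package version, stage timings).
#'
#' @param config A [study_config()], or a YAML path accepted by
#'   [read_study_config()].
#' @return Object of class `study_report` collecting the fitted stage objects
#'   (`gpa`, `space`, `parallel`, `axis`, `scores`, `age_test`, `hotelling`,
#'   `lmm`, `truth` when simulated) and the artifact `paths`.
#' @examples
#' \donttest{
#' cfg <- study_config(cohort = cohort_spec(n_normative = 40, n_achondro = 20,
#'                                          n_treated = 4, seed = 9),
#'                     n_permutations = 30)
#' report <- run_study(cfg)
#' report
#' }
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- c()
  stage <- function(name, expr) {
    s <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      manifest <- file.path(out, "partial_manifest.txt")
      writeLines(c(sprintf("study aborted in stage: %s", name),
                   sprintf("error: %s", conditionMessage(e)),
                   "artifacts written so far:",
                   list.files(out, recursive = TRUE)), manifest)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    res
  }

  # -- input ----------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$cohort)) {
    spec <- config$cohort
    spec$seed <- config$seed
    cohort <- stage("simulate", simulate_cohort(spec))
    configs <- cohort$configurations
    meta <- cohort$metadata
    map <- cohort$truth$bilateral_map
    truth <- cohort$truth
    stage("write_input", {
      write_landmarks_csv(configs, file.path(out, "landmarks_raw.csv"))
      utils::write.csv(meta, file.path(out, "metadata.csv"), row.names = FALSE)
      write_bilateral_map_csv(map, file.path(out, "bilateral_map.csv"))
    })
  } else {
    configs <- stage("load", read_landmarks_csv(config$landmarks_csv))
    meta <- utils::read.csv(config$metadata_csv, stringsAsFactors = FALSE)
    map <- read_bilateral_map_csv(config$bilateral_map_csv)
  }
  meta <- meta[match(names(configs), meta$scan_id), ]

  # -- superimposition ------------------------------------------------------
  sym <- stage("symmetrize", lapply(configs, symmetrize, map = map))
  fit <- stage("gpa", gpa(sym))
  stage("write_aligned", {
    write_landmarks_csv(fit$configurations, file.path(out, "landmarks_aligned.csv"))
    write_landmarks_csv(list(consensus = fit$consensus),
                        file.path(out, "consensus.csv"))
  })

  # -- shape space ----------------------------------------------------------
  pa <- stage("parallel_analysis",
              parallel_analysis(fit, n_permutations = config$n_permutations,
                                percentile = config$percentile,
                                seed = config$seed + 1L,
                                reference = config$pa_reference))
  n_ret <- max(pa$n_retained, 2L)
  if (!is.null(config$max_retained)) n_ret <- min(n_ret, config$max_retained)
  space <- stage("pca", fit_pca(fit, n_retained = n_ret))
  all_scores <- stage("project", project(fit$configurations, space, n_ret))
  stage("write_space", {
    write_shape_space(space, file.path(out, "shape_space"))
    sc <- data.frame(scan_id = names(fit$configurations), all_scores,
                     check.names = FALSE)
    colnames(sc) <- c("scan_id", paste0("PC", seq_len(n_ret)))
    utils::write.csv(sc, file.path(out, "pc_scores.csv"), row.names = FALSE)
  })

  # -- phenotype axis and scores -------------------------------------------
  ctrl <- meta$group %in% c("normative", "achondroplasia")
  axis <- stage("axis", fit_phenotype_axis(
    all_scores[ctrl, , drop = FALSE], meta$age_years[ctrl], meta$sex[ctrl],
    meta$group[ctrl], space = space))
  pred <- stage("score", predict(axis, all_scores, meta$age_years, meta$sex))
  score_tab <- cbind(
    meta[, c("scan_id", "subject_id", "group", "sex", "age_years",
             "protocol", "years_from_first_dose")],
    pred)
  score_tab <- stage("standardize", standardize_scores(score_tab))

  treated <- score_tab$group == "treated"
  ach <- score_tab$group == "achondroplasia"
  ast <- stage("age_standardize", age_standardize(
    score_tab$normalized_score[treated], score_tab$age_years[treated],
    score_tab$normalized_score[ach], score_tab$age_years[ach],
    alpha = config$alpha))
  score_tab$age_standardized_score <- score_tab$normalized_score
  score_tab$age_standardized_score[treated] <- ast$scores
  stage("write_scores", utils::write.csv(
    score_tab, file.path(out, "scores.csv"), row.names = FALSE))
  stage("write_axis", {
    utils::write.csv(data.frame(component = seq_along(axis$v), v = axis$v),
                     file.path(out, "axis_pc.csv"), row.names = FALSE)
    write_landmarks_csv(list(axis = axis$group_vector_landmark),
                        file.path(out, "axis_landmark.csv"))
  })

  # -- inference ------------------------------------------------------------
  fl <- first_last_rows(meta)
  n_pairs <- nrow(fl$first)
  hot <- NULL
  if (!is.null(n_pairs) && n_pairs >= 2L) {
    dims <- if (identical(config$hotelling_dims, "auto")) {
      min(13L, n_pairs - 1L, n_ret)
    } else {
      min(as.integer(config$hotelling_dims), n_ret)
    }
    hot <- stage("hotelling", paired_hotelling(
      all_scores[match(fl$first$scan_id, score_tab$scan_id), , drop = FALSE],
      all_scores[match(fl$last$scan_id, score_tab$scan_id), , drop = FALSE],
      n_dims = dims))
  }
  lmm <- NULL
  if (sum(treated) >= 4L && length(unique(score_tab$subject_id[treated])) >= 2L) {
    lmm <- stage("lmm", fit_score_lmm(
      score_tab[treated, ], score_col = "age_standardized_score"))
  }
  stage("write_inference", jsonlite::write_json(list(
    seed = config$seed,
    hotelling = if (!is.null(hot)) unclass(hot)[c(
      "t2", "f_stat", "df1", "df2", "p_value", "n_pairs", "n_dims")],
    age_effect = ast$test,
    lmm = if (!is.null(lmm)) unclass(lmm)[c(
      "beta_time", "se_time", "beta_protocol", "beta_interaction",
      "random_intercept_var", "residual_var", "lrt_chisq", "lrt_df",
      "p_value", "n_subjects", "n_observations")]
  ), file.path(out, "inference.json"), auto_unbox = TRUE, digits = NA,
    null = "null"))

  # -- heatmaps -------------------------------------------------------------
  if (!is.null(n_pairs) && n_pairs >= 1L) {
    stage("heatmaps", {
      hm_dir <- file.path(out, "heatmaps")
      dir.create(hm_dir, showWarnings = FALSE)
      for (i in seq_len(n_pairs)) {
        subj <- fl$first$subject_id[i]
        cfg_f <- fit$configurations[[fl$first$scan_id[i]]]
        cfg_l <- fit$configurations[[fl$last$scan_id[i]]]
        vf <- vertex_scores(cfg_f, fl$first$age_years[i], fl$first$sex[i],
                            axis, space)
        vl <- vertex_scores(cfg_l, fl$last$age_years[i], fl$last$sex[i],
                            axis, space)
        write_heatmap_ply(space$consensus, vf,
                          file.path(hm_dir, sprintf("%s_first.ply", subj)))
        write_heatmap_ply(space$consensus, vl,
                          file.path(hm_dir, sprintf("%s_last.ply", subj)))
        write_heatmap_ply(space$consensus, vertex_score_change(vf, vl),
                          file.path(hm_dir, sprintf("%s_change.ply", subj)))
      }
    })
  }

  # -- provenance -----------------------------------------------------------
  log_lines <- c(
    sprintf("morphoscore %s study run",
            as.character(utils::packageVersion("morphoscore"))),
    sprintf("R %s", getRversion()),
    sprintf("seed: %d", config$seed),
    sprintf("scans: %d; landmarks: %d", length(configs), map$k),
    sprintf("retained components: %d (parallel analysis suggested %d)",
            n_ret, pa$n_retained),
    "stage timings (s):",
    sprintf("  %-18s %.3f", names(timings), unlist(timings))
  )
  writeLines(log_lines, file.path(out, "run_log.txt"))

  structure(list(
    config = config, gpa = fit, space = space, parallel = pa, axis = axis,
    scores = score_tab, age_test = ast$test, hotelling = hot, lmm = lmm,
    truth = truth, n_retained = n_ret,
    paths = list(out_dir = out,
                 scores = file.path(out, "scores.csv"),
                 inference = file.path(out, "inference.json"),
                 log = file.path(out, "run_log.txt"))
  ), class = "study_report")
}

#' Cosine similarity between the fitted axis and the injected ground truth
#'
#' For a simulated study, maps the generator's true group displacement field
#' into the GPA consensus frame (by Procrustes-aligning the unit-size template
#' onto the consensus and applying the same rotation to the field) and returns
#' its cosine similarity with the fitted landmark-space phenotype axis. Values
#' near 1 mean the pipeline recovered the injected group effect.
#'
#' @param report A [run_study()] report from a simulated cohort.
#' @return Cosine similarity in \[-1, 1\].
#' @export
axis_recovery_cosine <- function(report) {
  stopifnot(inherits(report, "study_report"))
  if (is.null(report$truth)) {
    stop("axis recovery needs a simulated study (ground truth present)",
         call. = FALSE)
  }
  tpl <- report$truth$template
  tpl_unit <- sweep(tpl, 2L, colMeans(tpl)) / centroid_size(tpl)
  rot <- opa_align(tpl_unit, report$gpa$consensus)$rotation
  g <- report$truth$group_axis_true %*% rot
  v <- report$axis$group_vector_landmark
  sum(g * v) / sqrt(sum(g^2) * sum(v^2))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Phenotype-scoring study report\n")
  cat(sprintf("  scans: %d, retained PCs: %d (%.1f%% variance)\n",
              nrow(x$scores), x$n_retained,
              100 * x$space$variance_explained_cum[x$n_retained]))
  grp <- tapply(x$scores$normalized_score, x$scores$group, mean)
  cat("  mean normalized score by group:\n")
  for (g in names(grp)) cat(sprintf("    %-15s %.3f\n", g, grp[[g]]))
  if (!is.null(x$hotelling)) {
    cat("  ")
    print(x$hotelling)
  }
  if (!is.null(x$lmm)) {
    cat(sprintf("  LMM time effect: chi2 = %.3g, df = %d, P = %.4g, b = %.4g /y\n",
                x$lmm$lrt_chisq, x$lmm$lrt_df, x$lmm$p_value, x$lmm$beta_time))
  }
  cat(sprintf("  artifacts: %s\n", x$paths$out_dir))
  invisible(x)
}
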