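# End-to-end pipeline orchestration: simulate or load meshes + cohort,
# resample, align and build the template, fit the PCA atlas, measure
# morphometrics, correlate modes with descriptors, fit the risk models, and
# cluster -- all into a run directory of plain-text artifacts with a log.
# Runs are deterministic given (config, seed); stages are cached by a
# content hash of their relevant configuration so a rerun into the same
# directory reuses finished stages.

#' Pipeline configuration
#'
#' @param out_dir Run directory.
#' @param mesh_dir Directory of mesh files (used with `cohort_csv`).
#' @param cohort_csv Cohort CSV with `subject_id` and `mesh_path` columns.
#' @param simulate List of arguments for [simulate_cohort()] (used when no
#'   `cohort_csv` is given).
#' @param n_points Surface sample size per subject. Default 15000 (2000 is
#'   plenty for the synthetic tubes and much faster).
#' @param variance_threshold Cumulative variance for mode retention (0, 1].
#' @param stations Named arc-length fractions of the measurement stations.
#' @param template_max_rounds,template_tol Template-build controls.
#' @param icp_max_iter,icp_tol ICP controls.
#' @param pattern_cutoff Dilatation cutoff (mm) for [classify_pattern()].
#' @param cluster_k Clusters for [cluster_scores()] (`"auto"` or integer).
#' @param seed Integer seed for all stochastic stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            mesh_dir = NULL, cohort_csv = NULL, simulate = NULL,
                            n_points = 15000, variance_threshold = 0.90,
                            stations = c(sinus = 0.1, stj = 0.25, midaa = 0.5),
                            template_max_rounds = 10, template_tol = NULL,
                            icp_max_iter = 100, icp_tol = 1e-9,
                            pattern_cutoff = 40, cluster_k = "auto", seed = 1L) {
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]", call. = FALSE)
  if (n_points < 100) stop("n_points must be >= 100", call. = FALSE)
  if (icp_tol <= 0 || icp_max_iter < 1 || template_max_rounds < 1 ||
      (!is.null(template_tol) && template_tol <= 0))
    stop("tolerances and iteration caps must be positive", call. = FALSE)
  if (is.null(cohort_csv) && is.null(simulate))
    stop("either `cohort_csv` (+ `mesh_dir`) or `simulate` must be given", call. = FALSE)
  structure(list(out_dir = out_dir, mesh_dir = mesh_dir, cohort_csv = cohort_csv,
                 simulate = simulate, n_points = n_points,
                 variance_threshold = variance_threshold, stations = stations,
                 template_max_rounds = template_max_rounds,
                 template_tol = template_tol, icp_max_iter = icp_max_iter,
                 icp_tol = icp_tol, pattern_cutoff = pattern_cutoff,
                 cluster_k = cluster_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config, stage) {
  keep <- config[setdiff(names(config), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(stage, utils::capture.output(utils::str(keep))), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full shape-analysis pipeline
#'
#' Stages: (i) simulate or load meshes and cohort; (ii) resample every
#' surface to a common point count; (iii) rigid alignment and iterative
#' template construction; (iv) PCA shape atlas (scree table, mode scores);
#' (v) per-subject morphometrics; (vi) mode-descriptor correlations; (vii)
#' logistic risk models (shape modes at the variance threshold versus
#' diameter-only) with ROC curves; (viii) k-means clustering of the
#' mode-score plane; (ix) group summaries when a control group is present.
#' Every stage writes CSV artifacts plus a log line with its parameters; the
#' log also records the strain-projection fallback count (when strain inputs
#' exist) and the retained-mode count, the two quantities that fail silently
#' otherwise.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run artifacts (`cohort`, `atlas`,
#'   `template`, `morphometrics`, `correlations`, `risk_modes`,
#'   `risk_diameter`, `clusters`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                                append = TRUE)
  cat(sprintf("# pipeline run, package aortashape %s\n",
              as.character(utils::packageVersion("aortashape"))),
      file = log_path)
  writeLines(utils::capture.output(utils::str(config)), file.path(out, "config.txt"))

  cache_ok <- function(stage, files) {
    keyfile <- file.path(out, paste0(".", stage, ".key"))
    key <- config_hash(config, stage)
    if (file.exists(keyfile) && identical(readLines(keyfile)[1], key) &&
        all(file.exists(file.path(out, files)))) {
      log_line("[%s] reused cached artifacts (key %s)", stage, key)
      return(TRUE)
    }
    writeLines(key, keyfile)
    FALSE
  }

  ## stage: inputs
  if (!is.null(config$simulate)) {
    sim <- do.call(simulate_cohort,
                   c(config$simulate, list(seed = config$seed)))
    meshes <- sim$meshes
    cohort <- sim$cohort
    log_line("[input] simulated %d meshes (seed %d)", length(meshes), config$seed)
  } else {
    cohort <- read_cohort(config$cohort_csv)
    base <- config$mesh_dir %||% dirname(config$cohort_csv)
    paths <- ifelse(is.na(cohort$mesh_path),
                    file.path(base, paste0(cohort$subject_id, ".stl")),
                    file.path(base, cohort$mesh_path))
    missing_mesh <- !file.exists(paths)
    if (any(missing_mesh))
      stop(sprintf("mesh file missing for subject(s): %s",
                   paste(cohort$subject_id[missing_mesh], collapse = ", ")),
           call. = FALSE)
    meshes <- lapply(seq_along(paths), function(i)
      read_mesh(paths[i], subject_id = cohort$subject_id[i]))
    names(meshes) <- cohort$subject_id
    log_line("[input] read %d meshes from %s", length(meshes), base)
  }
  write_cohort(cohort, file.path(out, "cohort.csv"))

  ## stage: morphometrics (also fills diameters used for reference selection)
  prof <- do.call(rbind, lapply(meshes, function(m)
    morphometric_profile(m, stations = config$stations,
                         cutoff = config$pattern_cutoff)))
  rownames(prof) <- NULL
  write.csv(prof, file.path(out, "morphometrics.csv"), row.names = FALSE)
  log_line("[morpho] measured %d subjects at stations %s", nrow(prof),
           paste(sprintf("%s=%.2f", names(config$stations), config$stations),
                 collapse = ", "))
  for (col in c("diameter_sinus", "diameter_stj", "diameter_midaa",
                "tortuosity", "curvature", "pattern"))
    cohort[[col]] <- prof[[col]][match(cohort$subject_id, prof$subject_id)]

  ## stage: sampling
  clouds <- lapply(meshes, resample_surface, n_points = config$n_points,
                   seed = config$seed)
  log_line("[sample] %d points per subject (seed %d)", config$n_points, config$seed)

  ## stage: alignment + template + atlas (cached: the expensive stage)
  tb <- NULL
  if (cache_ok("atlas", c("template.ply", "transforms.csv",
                          file.path("atlas", "atlas.json")))) {
    atlas <- load_atlas(file.path(out, "atlas"))
  } else {
    # reference by mean mid-ascending diameter; if a diameter was not
    # measurable (station slice crossed an open boundary) fall back to the
    # bounding-box-size rule built into build_template
    ref <- if (anyNA(cohort$diameter_midaa)) NULL else
      select_initial_reference(cohort)
    tb <- build_template(clouds, reference = ref,
                         max_rounds = config$template_max_rounds,
                         tol = config$template_tol,
                         icp_args = list(max_iter = config$icp_max_iter,
                                         tol = config$icp_tol))
    log_line("[align] reference %s; %d round(s), converged = %s, last change %.4g mm",
             ref, tb$iteration_count, tb$converged, tail(tb$history, 1))
    write_point_cloud_ply(tb$template, file.path(out, "template.ply"))
    tf_rows <- do.call(rbind, lapply(names(tb$transforms), function(id) {
      tf <- tb$transforms[[id]]
      m <- rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
      data.frame(subject_id = id, t(as.numeric(m)))
    }))
    names(tf_rows)[-1] <- paste0("m", rep(1:4, each = 4), rep(1:4, times = 4))
    write.csv(tf_rows, file.path(out, "transforms.csv"), row.names = FALSE)
    atlas <- fit_pca(tb, variance_threshold = config$variance_threshold)
    save_atlas(atlas, file.path(out, "atlas"))
  }
  write.csv(scree_table(atlas), file.path(out, "scree.csv"), row.names = FALSE)
  log_line("[atlas] %d modes; mode 1 explains %.1f%%; %d mode(s) retained at %.0f%% variance",
           length(atlas$eigenvalues), 100 * atlas$variance_fractions[1],
           atlas$n_modes_retained_90, 100 * config$variance_threshold)

  ## stage: correlations
  corr <- correlate_modes(atlas$scores, cohort,
                          columns = intersect(c("diameter_sinus", "diameter_stj",
                                                "diameter_midaa", "tortuosity",
                                                "curvature", "orifice_area",
                                                "flow_jet", "wss_stj", "strain_midaa"),
                                              names(cohort)),
                          modes = seq_len(min(6, ncol(atlas$scores))))
  write.csv(corr, file.path(out, "correlations.csv"), row.names = FALSE)
  log_line("[stats] %d mode-descriptor correlations (p_adjust = %s)",
           nrow(corr), attr(corr, "p_adjust"))

  ## stage: risk models + ROC
  ataa <- cohort$group != "control"
  risk_modes <- NULL; risk_diam <- NULL
  labels <- cohort$surgery[ataa]
  if (sum(labels) >= 2 && sum(!labels) >= 2) {
    k90 <- modes_for_variance(atlas, config$variance_threshold)
    risk_modes <- fit_risk_model(atlas$scores[ataa, seq_len(k90), drop = FALSE],
                                 labels, predictor = "modes_90")
    risk_diam <- fit_risk_model(atlas$scores[ataa, , drop = FALSE], labels,
                                predictor = "diameter",
                                diameter = cohort$diameter_midaa[ataa])
    write.csv(rbind(data.frame(model = "modes_90", risk_modes$roc$points),
                    data.frame(model = "diameter", risk_diam$roc$points)),
              file.path(out, "roc.csv"), row.names = FALSE)
    write.csv(data.frame(model = c("modes_90", "diameter"),
                         auc = c(risk_modes$auc, risk_diam$auc),
                         n_predictors = c(risk_modes$n_modes, 1),
                         ridge_active = c(risk_modes$ridge_active,
                                          risk_diam$ridge_active)),
              file.path(out, "auc.csv"), row.names = FALSE)
    log_line("[risk] AUC modes_%.0f = %.3f (%d modes)%s; AUC diameter = %.3f",
             100 * config$variance_threshold, risk_modes$auc, risk_modes$n_modes,
             if (risk_modes$ridge_active) " [ridge]" else "", risk_diam$auc)
  } else {
    log_line("[risk] skipped: fewer than 2 subjects per surgery class")
  }

  ## stage: clusters
  clusters <- cluster_scores(atlas$scores, k = config$cluster_k, seed = config$seed)
  write.csv(data.frame(subject_id = atlas$subject_ids, cluster = clusters$labels),
            file.path(out, "clusters.csv"), row.names = FALSE)
  log_line("[cluster] k = %d, mean silhouette %.3f", clusters$k, clusters$silhouette)

  ## stage: group summary
  if (any(cohort$group == "control")) {
    gs <- group_mode_summary(atlas$scores, cohort$group)
    write.csv(gs, file.path(out, "group_mode1.csv"), row.names = FALSE)
    log_line("[groups] mode-1 summary vs control written")
  }

  write_cohort(cohort, file.path(out, "cohort_with_descriptors.csv"))
  log_line("[done]")
  invisible(list(cohort = cohort, atlas = atlas, template = tb,
                 morphometrics = prof, correlations = corr,
                 risk_modes = risk_modes, risk_diameter = risk_diam,
                 clusters = clusters, out_dir = out))
}
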