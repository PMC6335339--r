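# ordered group pairs, clinically worse group first
severity_pairs <- function(groups, severity_order) {
  ord <- c(intersect(severity_order, groups), setdiff(groups, severity_order))
  utils::combn(ord, 2, simplify = FALSE)
}

run_stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log$stages[[name]] <- round(proc.time()[["elapsed"]] - t0, 2)
  res
}

#' Nodal group statistics with FDR correction across regions
#'
#' Covariate-adjusted omnibus tests per node for a subjects x nodes metric
#' matrix, with Benjamini-Hochberg correction across the nodes (per metric
#' family).
#'
#' @param nodal subjects x nodes numeric matrix.
#' @param manifest cohort manifest aligned with the matrix rows.
#' @param covariate_cols covariate column names.
#' @param fdr_q FDR level (default 0.05).
#' @return data.frame: node, F, p, fdr_significant.
#' @export
nodal_group_stats <- function(nodal, manifest,
                              covariate_cols = c("age", "sex", "education"),
                              fdr_q = 0.05) {
  covs <- if (length(covariate_cols)) manifest[covariate_cols] else NULL
  res <- lapply(seq_len(ncol(nodal)), function(j) {
    y <- nodal[, j]
    if (sd(y) == 0) {
      # degenerate node (e.g. isolated in every subject): untestable
      return(data.frame(node = j, F = NA_real_, p = NA_real_))
    }
    om <- ancova_omnibus(y, manifest$group, covs)
    data.frame(node = j, F = om$F, p = om$p)
  })
  out <- do.call(rbind, res)
  ok <- is.finite(out$p)
  out$fdr_significant <- NA
  out$fdr_significant[ok] <- fdr_correct(out$p[ok], fdr_q)
  out
}

#' Run the full connectome group-analysis pipeline
#'
#' Orchestrates the study replica end to end: simulate (or read) a cohort,
#' compute per-subject global and nodal metrics, covariate-adjusted group
#' statistics with FDR on nodal metrics, NBS for every group pair, ROC of
#' NBS-component strengths, rich-club/feeder/local strength comparisons,
#' F-score-ranked SVM LOOCV classification per pair, and a fiber-threshold
#' sweep checking the stability of the group differences. Every stochastic
#' stage derives its seed from the global seed and the stage name, so a rerun
#' with identical inputs is byte-identical.
#'
#' @param source a [synthetic_config()] to simulate, a manifest path, or a
#'   `cohort` object.
#' @param covariate_cols manifest covariate columns to adjust for.
#' @param n_random surrogate ensemble size for small-world ratios (0 skips).
#' @param nbs_threshold_p,nbs_n_perm NBS primary threshold (edgewise
#'   two-sided p) and permutation count.
#' @param consistency backbone presence threshold for rich-club analysis.
#' @param classifier_mode `"paper"` (grid on outer LOOCV accuracy, the
#'   study-replica procedure) or `"nested"` (leakage-free inner selection).
#' @param fraction_grid feature-fraction grid for the classifier.
#' @param fiber_thresholds fiber-number thresholds swept for stability
#'   (default 1:5; `NULL` skips the sweep).
#' @param severity_order group labels from clinically worst to best; fixes
#'   pair orientation and the classifier/ROC positive class.
#' @param alpha significance level used when reporting significant NBS
#'   components.
#' @param seed global integer seed.
#' @param out_dir if non-`NULL`, write all result tables there (deterministic
#'   text files; see [write_report()]).
#' @return a `strucnet_report` list with elements `cohort`, `metrics`,
#'   `global_stats`, `nodal_stats`, `nbs`, `roc`, `richclub`,
#'   `richclub_stats`, `classification`, `sweep`, `config`, `log`.
#' @export
run_pipeline <- function(source,
                         covariate_cols = c("age", "sex", "education"),
                         n_random = 100,
                         nbs_threshold_p = 0.01, nbs_n_perm = 5000,
                         consistency = 0.8,
                         classifier_mode = c("paper", "nested"),
                         fraction_grid = seq(0.01, 0.20, by = 0.01),
                         fiber_thresholds = 1:5,
                         severity_order = c("converter", "nonconverter",
                                            "control"),
                         alpha = 0.05,
                         seed = 20190110,
                         out_dir = NULL) {
  classifier_mode <- match.arg(classifier_mode)
  log <- new.env()
  log$stages <- list()

  cohort <- run_stage("cohort", log, {
    if (inherits(source, "synthetic_config")) {
      source$seed <- derive_seed(seed, "simulate")
      sample_cohort(source)
    } else if (inherits(source, "cohort")) {
      source
    } else {
      read_cohort(source)
    }
  })
  man <- cohort$manifest
  groups <- unique(man$group)
  pairs <- severity_pairs(groups, severity_order)
  global_cols <- c("Sp", "Eglob", "Eloc", "Lp", "Cp")

  metrics <- run_stage("metrics", log,
    cohort_global_metrics(cohort, n_random = n_random,
                          seed = derive_seed(seed, "metrics")))

  global_stats <- run_stage("global_stats", log,
    compare_metrics(metrics,
                    c(global_cols, if (n_random > 0) c("lambda", "gamma", "sigma")),
                    covariate_cols, fdr_q = NULL))

  nodal <- run_stage("nodal_metrics", log, cohort_nodal_metrics(cohort))
  nodal_stats <- run_stage("nodal_stats", log, list(
    global_efficiency = nodal_group_stats(nodal$nodal_global_efficiency, man,
                                          covariate_cols),
    local_efficiency = nodal_group_stats(nodal$nodal_local_efficiency, man,
                                         covariate_cols)))

  nbs <- run_stage("nbs", log, {
    res <- lapply(pairs, function(pr) {
      nbs_test(cohort, pr, covariate_cols, threshold_p = nbs_threshold_p,
               n_perm = nbs_n_perm,
               seed = derive_seed(seed, paste0("nbs:", paste(pr, collapse = "-"))))
    })
    names(res) <- vapply(pairs, paste, "", collapse = "_vs_")
    res
  })

  roc <- run_stage("roc", log, {
    out <- list()
    for (nm in names(nbs)) {
      r <- nbs[[nm]]
      sig <- Filter(function(cm) cm$corrected_p < alpha, r$components)
      if (!length(sig)) next
      comp <- sig[[1]]
      keep <- man$group %in% r$group_pair
      strength <- vapply(man$subject_id[keep], function(id)
        component_strength(cohort$matrices[[id]], comp), numeric(1))
      # patients have reduced strength, so lower strength = more positive-like
      out[[nm]] <- roc_auc(-strength, man$group[keep],
                           positive = r$group_pair[1])
    }
    out
  })

  richclub <- run_stage("richclub", log,
    richclub_analysis(cohort, consistency = consistency))
  richclub_stats <- run_stage("richclub_stats", log, {
    st <- merge(richclub$strengths,
                man[, c("subject_id", covariate_cols)], by = "subject_id",
                sort = FALSE)
    compare_metrics(st, c("rich_club", "feeder", "local"), covariate_cols)
  })

  classification <- run_stage("classification", log, {
    n_nodes <- nrow(cohort$matrices[[1]])
    idx <- edge_index_map(n_nodes)
    res <- lapply(pairs, function(pr) {
      keep <- man$group %in% pr
      X <- t(vapply(man$subject_id[keep], function(id) {
        m <- cohort$matrices[[id]]
        m[cbind(idx[, 1], idx[, 2])]
      }, numeric(nrow(idx))))
      svm_loocv(X, man$group[keep], positive = pr[1],
                fraction_grid = fraction_grid, mode = classifier_mode,
                seed = derive_seed(seed, paste0("svm:", paste(pr, collapse = "-"))))
    })
    names(res) <- vapply(pairs, paste, "", collapse = "_vs_")
    res
  })

  sweep <- run_stage("sweep", log, {
    if (is.null(fiber_thresholds)) NULL else {
      rows <- lapply(fiber_thresholds, function(w) {
        thr_cohort <- cohort
        thr_cohort$matrices <- lapply(cohort$matrices, apply_fiber_threshold,
                                      w_min = w)
        mt <- cohort_global_metrics(thr_cohort, n_random = 0)
        cs <- compare_metrics(mt, global_cols, covariate_cols)
        cs$w_min <- w
        cs
      })
      do.call(rbind, rows)
    }
  })

  report <- structure(list(
    cohort = cohort, metrics = metrics, global_stats = global_stats,
    nodal_stats = nodal_stats, nbs = nbs, roc = roc,
    richclub = richclub, richclub_stats = richclub_stats,
    classification = classification, sweep = sweep,
    config = list(covariate_cols = covariate_cols, n_random = n_random,
                  nbs_threshold_p = nbs_threshold_p, nbs_n_perm = nbs_n_perm,
                  consistency = consistency,
                  classifier_mode = classifier_mode,
                  fraction_grid = fraction_grid,
                  fiber_thresholds = fiber_thresholds,
                  severity_order = severity_order, alpha = alpha,
                  seed = seed),
    log = list(stage_seconds = log$stages)),
    class = "strucnet_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.strucnet_report <- function(x, ...) {
  cat("strucnet pipeline report\n")
  print(x$cohort)
  cat("\nGlobal metric group statistics (covariate-adjusted):\n")
  print(x$global_stats[, c("metric", "F", "p")], row.names = FALSE,
        digits = 4)
  cat("\nNBS:\n")
  for (nm in names(x$nbs)) print(x$nbs[[nm]])
  for (nm in names(x$roc)) {
    cat(sprintf("  component-strength ROC %s: AUC = %.3f\n", nm,
                x$roc[[nm]]$auc))
  }
  cat("\nRich-club strength statistics:\n")
  print(x$richclub_stats[, c("metric", "F", "p")], row.names = FALSE,
        digits = 4)
  cat("\nClassification:\n")
  for (nm in names(x$classification)) {
    cl <- x$classification[[nm]]
    cat(sprintf("  %s: accuracy %.2f%%, sens %.2f%%, spec %.2f%%, AUC %.3f\n",
                nm, cl$accuracy, cl$sensitivity, cl$specificity, cl$auc))
  }
  invisible(x)
}

# deterministic CSV writer with a provenance header
write_result_csv <- function(df, path, params = "") {
  con <- file(path, "w")
  writeLines(sprintf("# strucnet %s %s",
                     as.character(packageVersion("strucnet")), params), con)
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Write a pipeline report as deterministic text files
#'
#' Emits CSV/JSON result tables (metrics, group statistics, NBS components
#' with 1-based node indices, rich-club strengths, classification
#' summaries, threshold sweep, resolved configuration). Content is fully
#' determined by the report, so identical runs produce byte-identical files.
#'
#' @param report a `strucnet_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- sprintf("seed=%d", report$config$seed)
  write_result_csv(report$metrics, file.path(dir, "metrics.csv"), params)
  write_result_csv(report$global_stats, file.path(dir, "global_stats.csv"),
                   params)
  write_result_csv(report$nodal_stats$global_efficiency,
                   file.path(dir, "nodal_stats_global_efficiency.csv"), params)
  write_result_csv(report$nodal_stats$local_efficiency,
                   file.path(dir, "nodal_stats_local_efficiency.csv"), params)
  write_result_csv(report$richclub$strengths,
                   file.path(dir, "richclub_strengths.csv"), params)
  write_result_csv(report$richclub_stats,
                   file.path(dir, "richclub_stats.csv"), params)
  if (!is.null(report$sweep)) {
    write_result_csv(report$sweep, file.path(dir, "threshold_sweep.csv"),
                     params)
  }
  nbs_json <- lapply(report$nbs, function(r) {
    list(group_pair = r$group_pair, threshold_p = r$threshold_p,
         threshold_t = r$threshold_t, n_perm = r$n_perm, seed = r$seed,
         components = lapply(r$components, function(cm) {
           list(size_edges = cm$size_edges, size_nodes = cm$size_nodes,
                corrected_p = cm$corrected_p,
                edges = cbind(cm$edges, t = round(cm$t, 6)))
         }))
  })
  jsonlite::write_json(nbs_json, file.path(dir, "nbs.json"),
                       auto_unbox = TRUE, digits = NA)
  clf_json <- lapply(report$classification, function(cl) {
    list(mode = cl$mode, positive = cl$positive, accuracy = cl$accuracy,
         sensitivity = cl$sensitivity, specificity = cl$specificity,
         auc = cl$auc, chosen_fraction = cl$chosen_fraction,
         predictions = cl$predictions)
  })
  jsonlite::write_json(clf_json, file.path(dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA)
  roc_json <- lapply(report$roc, function(r)
    list(positive = r$positive, auc = r$auc))
  jsonlite::write_json(roc_json, file.path(dir, "roc.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
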