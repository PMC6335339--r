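# pooled-variance two-sample t statistics for every column of X;
# zero-variance columns get t = 0 (tallied by the caller via attribute)
column_tstats <- function(X, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  X1 <- X[i1, , drop = FALSE]; X2 <- X[i2, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X2^2) - n2 * m2^2) / (n2 - 1)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  nzero <- sum(!is.finite(t) | se <= 0)
  t[!is.finite(t)] <- 0
  attr(t, "n_zero_variance") <- nzero
  t
}

# subjects x edges matrix for the subjects of a group pair, plus bookkeeping
pair_edge_matrix <- function(cohort, group_pair) {
  man <- cohort$manifest
  keep <- which(man$group %in% group_pair)
  if (length(unique(man$group[keep])) != 2) {
    stop(sprintf("both groups must be present: %s",
                 paste(group_pair, collapse = ", ")))
  }
  n_nodes <- nrow(cohort$matrices[[1]])
  idx <- edge_index_map(n_nodes)
  E <- t(vapply(keep, function(r) {
    m <- cohort$matrices[[man$subject_id[r]]]
    m[cbind(idx[, 1], idx[, 2])]
  }, numeric(nrow(idx))))
  list(E = E, keep = keep, idx = idx, n_nodes = n_nodes,
       i1 = which(man$group[keep] == group_pair[1]),
       i2 = which(man$group[keep] == group_pair[2]))
}

#' Edgewise covariate-adjusted two-sample t statistics
#'
#' For a pair of groups, residualizes each admitted edge's weights on the
#' covariates across the pooled subjects, then computes a pooled-variance
#' two-sample t on the residuals. Edges are admitted when nonzero in at least
#' `edge_presence` of the pair's subjects (default 50%); heavily zero edges
#' destabilize t statistics. Sign convention: positive t means the
#' first-named group has larger weights.
#'
#' @param cohort a `cohort` object.
#' @param group_pair character vector of two group labels.
#' @param covariate_cols manifest columns to adjust for (default age, sex,
#'   education); `NULL` or empty for unadjusted.
#' @param edge_presence minimum nonzero fraction for edge admission.
#' @return list with `t` (per admitted edge), `mask` (admitted-edge logical
#'   over all N(N-1)/2 edges), `index_map`, `residuals` (subjects x admitted
#'   edges), `i1`, `i2`, `df`, `n_zero_variance`.
#' @export
edgewise_tstats <- function(cohort, group_pair,
                            covariate_cols = c("age", "sex", "education"),
                            edge_presence = 0.5) {
  pe <- pair_edge_matrix(cohort, group_pair)
  mask <- colMeans(pe$E > 0) >= edge_presence
  if (!any(mask)) stop("edge admission mask is empty")
  covs <- if (length(covariate_cols)) {
    cohort$manifest[pe$keep, covariate_cols, drop = FALSE]
  } else NULL
  R <- residualize(pe$E[, mask, drop = FALSE], covs)
  t <- column_tstats(R, pe$i1, pe$i2)
  list(t = as.numeric(t), mask = mask, index_map = pe$idx,
       residuals = R, i1 = pe$i1, i2 = pe$i2,
       df = length(pe$i1) + length(pe$i2) - 2,
       n_zero_variance = attr(t, "n_zero_variance"))
}

# edge rows (k x 2) -> max connected-component size in edges (0 if none)
max_component_edges <- function(edge_rows) {
  if (nrow(edge_rows) == 0) return(0L)
  g <- igraph::graph_from_edgelist(edge_rows, directed = FALSE)
  memb <- igraph::components(g)$membership
  max(tabulate(memb[edge_rows[, 1]]))
}

#' Connected components of suprathreshold edges
#'
#' Thresholds a per-edge statistic vector and returns the connected
#' components of the surviving edges, sized in edges and nodes, largest
#' first.
#'
#' @param t numeric per-edge statistics.
#' @param edge_nodes two-column matrix of node pairs aligned with `t`.
#' @param threshold primary threshold on the statistic scale.
#' @param direction `"two-sided"` (|t| > threshold), `"greater"` or
#'   `"less"`.
#' @return list of components, each with `edges` (rows of `edge_nodes`),
#'   `t` values, `nodes`, `size_edges`, `size_nodes`.
#' @export
extract_components <- function(t, edge_nodes, threshold,
                               direction = c("two-sided", "greater", "less")) {
  direction <- match.arg(direction)
  sup <- switch(direction,
                "two-sided" = abs(t) > threshold,
                "greater" = t > threshold,
                "less" = t < -abs(threshold))
  if (!any(sup)) return(list())
  ed <- edge_nodes[sup, , drop = FALSE]
  tv <- t[sup]
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[ed[, 1]]
  comps <- lapply(sort(unique(comp_of_edge)), function(cid) {
    rows <- comp_of_edge == cid
    nodes <- sort(unique(as.vector(ed[rows, , drop = FALSE])))
    list(edges = ed[rows, , drop = FALSE], t = tv[rows], nodes = nodes,
         size_edges = sum(rows), size_nodes = length(nodes))
  })
  comps[order(-vapply(comps, `[[`, 1L, "size_edges"))]
}

#' Network-based statistic (NBS) permutation test
#'
#' Identifies connected components of edges whose covariate-adjusted
#' two-sample t statistic exceeds a primary cluster-defining threshold, and
#' assigns each a family-wise-error corrected p-value from the permutation
#' null distribution of the maximal suprathreshold component size (number of
#' edges). Covariate effects are removed once by linear regression before
#' permutation; permutations then shuffle the residual rows between the two
#' groups.
#'
#' @param cohort a `cohort` object.
#' @param group_pair character vector of two group labels.
#' @param covariate_cols manifest covariate columns (default age, sex,
#'   education).
#' @param threshold_p primary threshold as an edgewise two-sided p-value
#'   (default 0.01), converted to the matching |t| quantile.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param edge_presence edge admission fraction (see [edgewise_tstats()]).
#' @param direction tail convention passed to [extract_components()].
#' @return an `nbs_result`: `components` (with `corrected_p` each),
#'   `threshold_t`, `threshold_p`, `null_max_sizes`, `n_perm`, `seed`,
#'   `group_pair`, `n_admitted_edges`, `n_zero_variance`.
#' @export
nbs_test <- function(cohort, group_pair,
                     covariate_cols = c("age", "sex", "education"),
                     threshold_p = 0.01, n_perm = 5000, seed = 20190110,
                     edge_presence = 0.5,
                     direction = c("two-sided", "greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(n_perm >= 100)
  et <- edgewise_tstats(cohort, group_pair, covariate_cols, edge_presence)
  thr_t <- qt(1 - threshold_p / 2, df = et$df)
  edge_nodes <- et$index_map[et$mask, , drop = FALSE]
  comps <- extract_components(et$t, edge_nodes, thr_t, direction)

  R <- et$residuals
  n <- nrow(R)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      tb <- column_tstats(R[perm, , drop = FALSE], et$i1, et$i2)
      sup <- switch(direction,
                    "two-sided" = abs(tb) > thr_t,
                    "greater" = tb > thr_t,
                    "less" = tb < -abs(thr_t))
      if (!any(sup)) 0L else max_component_edges(edge_nodes[sup, , drop = FALSE])
    }, integer(1))
  })
  for (k in seq_along(comps)) {
    comps[[k]]$corrected_p <-
      (1 + sum(null_max >= comps[[k]]$size_edges)) / (1 + n_perm)
  }
  structure(list(components = comps, threshold_t = thr_t,
                 threshold_p = threshold_p, direction = direction,
                 null_max_sizes = null_max, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), group_pair = group_pair,
                 n_admitted_edges = sum(et$mask),
                 n_zero_variance = et$n_zero_variance),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS: %s vs %s, primary p < %g (|t| > %.2f, %s), %d permutations\n",
              x$group_pair[1], x$group_pair[2], x$threshold_p, x$threshold_t,
              x$direction, x$n_perm))
  cat(sprintf("  %d admitted edges; %d suprathreshold component(s)\n",
              x$n_admitted_edges, length(x$components)))
  for (k in seq_along(x$components)) {
    cm <- x$components[[k]]
    cat(sprintf("  component %d: %d edges, %d nodes, corrected p = %.4g\n",
                k, cm$size_edges, cm$size_nodes, cm$corrected_p))
  }
  invisible(x)
}

#' Mean connection strength of a component in one subject
#'
#' The subject-level summary used for ROC analysis of an NBS component: the
#' mean of the subject's edge weights over the component's edge set.
#'
#' @param subject_matrix connectivity matrix.
#' @param component a component from [nbs_test()] / [extract_components()],
#'   or a two-column matrix of node pairs.
#' @return scalar mean strength.
#' @export
component_strength <- function(subject_matrix, component) {
  edges <- if (is.list(component)) component$edges else component
  if (is.null(dim(edges)) || nrow(edges) == 0) stop("empty component")
  mean(subject_matrix[cbind(edges[, 1], edges[, 2])])
}
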