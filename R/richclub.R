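#' Group backbone network of consistent edges
#'
#' An edge enters the backbone when it is nonzero in strictly more than
#' `consistency` of the group's subjects (the comparison is strict, so at the
#' default 0.8 an edge present in exactly 80% of subjects is dropped).
#'
#' @param group_matrices list of connectivity matrices (one group's
#'   subjects).
#' @param consistency required presence fraction in `(0, 1)` (default 0.8).
#' @return a `backbone` list: `edge_mask` (binary N x N symmetric matrix),
#'   `degree` (per node, on the backbone), `consistency`, `n_subjects`.
#' @export
build_backbone <- function(group_matrices, consistency = 0.8) {
  stopifnot(length(group_matrices) >= 2, consistency > 0, consistency < 1)
  n <- nrow(group_matrices[[1]])
  presence <- Reduce(`+`, lapply(group_matrices, function(m) (m > 0) * 1))
  mask <- (presence / length(group_matrices)) > consistency
  mode(mask) <- "numeric"
  diag(mask) <- 0
  if (sum(mask) == 0) warning("empty backbone at this consistency threshold")
  structure(list(edge_mask = mask, degree = as.integer(colSums(mask)),
                 consistency = consistency,
                 n_subjects = length(group_matrices)),
            class = "backbone")
}

#' Identify hub nodes of a backbone network
#'
#' Hubs are nodes whose backbone degree strictly exceeds the mean plus one
#' (sample, n-1 divisor) standard deviation of the degree distribution.
#'
#' @param backbone a `backbone` from [build_backbone()].
#' @return integer vector of hub node indices (possibly empty; a constant
#'   degree vector yields no hubs, with a warning).
#' @export
identify_hubs <- function(backbone) {
  k <- backbone$degree
  if (sum(k) == 0) stop("backbone has no edges")
  cut <- mean(k) + sd(k)
  if (sd(k) == 0) warning("constant degree vector: no hubs identifiable")
  which(k > cut)
}

#' Classify backbone edges as rich-club, feeder or local
#'
#' Hub-hub edges are rich-club, edges with exactly one hub endpoint are
#' feeder, and edges between non-hubs are local; the three classes partition
#' the backbone edge set.
#'
#' @param backbone a `backbone`.
#' @param hub_set integer vector of hub node indices.
#' @return N x N character matrix with entries `"rich_club"`, `"feeder"`,
#'   `"local"` on backbone edges and `NA` elsewhere.
#' @export
classify_edges <- function(backbone, hub_set) {
  n <- nrow(backbone$edge_mask)
  is_hub <- seq_len(n) %in% hub_set
  nhub <- outer(is_hub, is_hub, `+`)  # 0, 1 or 2 hub endpoints
  cls <- matrix(NA_character_, n, n)
  cls[backbone$edge_mask > 0] <-
    c("local", "feeder", "rich_club")[nhub[backbone$edge_mask > 0] + 1]
  cls
}

#' Per-subject connection strength by edge class
#'
#' Sums a subject's weights over each class of backbone edges (each
#' undirected edge counted once).
#'
#' @param subject_matrix connectivity matrix (same N as the backbone).
#' @param classes edge-class matrix from [classify_edges()].
#' @return named numeric vector: `rich_club`, `feeder`, `local`.
#' @export
subject_class_strengths <- function(subject_matrix, classes) {
  stopifnot(all(dim(subject_matrix) == dim(classes)))
  ut <- upper.tri(classes)
  vapply(c(rich_club = "rich_club", feeder = "feeder", local = "local"),
         function(cl) {
           sel <- ut & !is.na(classes) & classes == cl
           sum(subject_matrix[sel])
         }, numeric(1))
}

#' Binary group-mean network at a fixed sparsity
#'
#' Averages the group's connectivity matrices and keeps the
#' `floor(sparsity x N(N-1)/2)` strongest edges as a binary graph (the
#' construction behind group-level hub visualizations). Ties at the cutoff
#' are broken by the deterministic row-major edge order and reported.
#'
#' @param group_matrices list of connectivity matrices.
#' @param sparsity fraction of possible edges to keep, in `(0, 1]`.
#' @return binary N x N matrix with attribute `n_ties_broken`.
#' @export
groupmean_sparsity_network <- function(group_matrices, sparsity = 0.1) {
  stopifnot(sparsity > 0, sparsity <= 1)
  n <- nrow(group_matrices[[1]])
  mbar <- Reduce(`+`, group_matrices) / length(group_matrices)
  idx <- edge_index_map(n)
  w <- mbar[cbind(idx[, 1], idx[, 2])]
  k <- min(floor(sparsity * nrow(idx)), sum(w > 0))
  out <- matrix(0, n, n)
  ties <- 0L
  if (k >= 1) {
    ord <- order(-w, seq_along(w))  # strongest first, row-major tie-break
    kept <- ord[seq_len(k)]
    cutw <- w[ord[k]]
    ties <- as.integer(sum(w == cutw) > 1 && k < sum(w >= cutw))
    out[idx[kept, , drop = FALSE]] <- 1
    out[idx[kept, c(2, 1), drop = FALSE]] <- 1
  }
  attr(out, "n_ties_broken") <- ties
  out
}

#' Rich-club/feeder/local strength analysis of a cohort
#'
#' For each group, builds that group's own consistency backbone, identifies
#' its hubs, classifies its edges, and computes every group member's
#' rich-club, feeder and local connection strengths. A pooled-backbone
#' variant (one backbone from all subjects) is available for sensitivity
#' analysis.
#'
#' @param cohort a `cohort` object.
#' @param consistency backbone presence threshold (default 0.8).
#' @param pooled if `TRUE`, use a single backbone built from all subjects.
#' @return list with `strengths` (data.frame: subject_id, group, rich_club,
#'   feeder, local) and `backbones` (per group: backbone, hub set, class
#'   matrix).
#' @export
richclub_analysis <- function(cohort, consistency = 0.8, pooled = FALSE) {
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$matrices))
  man <- cohort$manifest
  groups <- unique(man$group)
  pooled_bb <- if (pooled) build_backbone(cohort$matrices, consistency) else NULL
  backbones <- list()
  rows <- list()
  for (g in groups) {
    ids <- man$subject_id[man$group == g]
    bb <- if (pooled) pooled_bb else build_backbone(cohort$matrices[ids], consistency)
    hubs <- identify_hubs(bb)
    cls <- classify_edges(bb, hubs)
    backbones[[g]] <- list(backbone = bb, hubs = hubs, classes = cls)
    for (id in ids) {
      s <- subject_class_strengths(cohort$matrices[[id]], cls)
      rows[[id]] <- data.frame(subject_id = id, group = g,
                               rich_club = s[["rich_club"]],
                               feeder = s[["feeder"]], local = s[["local"]],
                               stringsAsFactors = FALSE)
    }
  }
  strengths <- do.call(rbind, rows[man$subject_id])
  rownames(strengths) <- NULL
  list(strengths = strengths, backbones = backbones, pooled = pooled)
}
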