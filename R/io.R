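#' Validate a connectivity matrix
#'
#' A connectivity matrix is an N x N symmetric numeric matrix of nonnegative
#' finite streamline counts with a zero diagonal. Asymmetries within
#' `tol` are repaired by averaging (tractography counters are integers, so any
#' real asymmetry signals a corrupt file); larger asymmetries are an error.
#'
#' @param m numeric matrix.
#' @param tol maximum tolerated absolute asymmetry (default 1e-8).
#' @return the validated (and possibly symmetrized) matrix.
#' @export
validate_connectivity <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("connectivity matrix must be a numeric matrix")
  }
  if (nrow(m) != ncol(m)) {
    stop(sprintf("connectivity matrix must be square, got %d x %d",
                 nrow(m), ncol(m)))
  }
  if (any(!is.finite(m))) stop("connectivity matrix contains NaN/Inf entries")
  if (any(m < 0)) stop("connectivity matrix contains negative entries")
  asym <- abs(m - t(m))
  if (any(asym > tol)) {
    worst <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "asymmetry %.3g at cell (%d, %d) exceeds tolerance %g",
      max(asym), worst[1], worst[2], tol))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

#' Read a connectivity matrix from a dense delimited text file
#'
#' Accepts comma-, tab- or whitespace-delimited dense numeric tables, with an
#' optional leading `#` provenance/header comment block. The matrix must be
#' square, nonnegative, finite, and symmetric within `tol` (averaged if so).
#'
#' @param path file path.
#' @param tol asymmetry tolerance passed to [validate_connectivity()].
#' @return a validated numeric connectivity matrix.
#' @export
read_connectivity_matrix <- function(path, tol = 1e-8) {
  if (!file.exists(path)) stop(sprintf("matrix file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("matrix file is empty: %s", path))
  sep <- if (grepl(",", lines[[1]])) "," else if (grepl("\t", lines[[1]])) "\t" else ""
  parsed <- lapply(lines, function(l) {
    fields <- if (sep == "") strsplit(trimws(l), "\\s+")[[1]]
              else strsplit(l, sep, fixed = TRUE)[[1]]
    suppressWarnings(as.numeric(fields))
  })
  labels <- NULL
  if (any(is.na(parsed[[1]])) && length(lines) > 1L) {
    # header row of node labels
    labels <- if (sep == "") strsplit(trimws(lines[[1]]), "\\s+")[[1]]
              else trimws(strsplit(lines[[1]], sep, fixed = TRUE)[[1]])
    parsed <- parsed[-1]
  }
  ncols <- lengths(parsed)
  if (length(unique(ncols)) != 1L) {
    stop(sprintf("ragged rows in matrix file %s", path))
  }
  m <- do.call(rbind, parsed)
  if (any(is.na(m))) stop(sprintf("non-numeric entries in matrix file %s", path))
  if (nrow(m) != ncol(m)) {
    stop(sprintf("matrix file %s is not square (%d x %d)", path, nrow(m), ncol(m)))
  }
  m <- validate_connectivity(m, tol = tol)
  if (!is.null(labels) && length(labels) == ncol(m)) {
    dimnames(m) <- list(labels, labels)
  }
  m
}

#' Write a connectivity matrix as delimited text
#'
#' Writes a dense tab-separated matrix preceded by a `#` provenance header
#' (tool version and parameters). Node labels, if present as dimnames, are
#' written as a header row. Round-trips integer-valued matrices exactly.
#'
#' @param m connectivity matrix.
#' @param path output file path.
#' @export
write_connectivity_matrix <- function(m, path) {
  m <- validate_connectivity(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# strucnet %s connectivity matrix, N=%d, 1-based node indexing in labels",
                     as.character(packageVersion("strucnet")), nrow(m)), con)
  if (!is.null(rownames(m))) writeLines(paste(rownames(m), collapse = "\t"), con)
  write.table(format(m, trim = TRUE, scientific = FALSE), con,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a connectivity matrix from streamline endpoint region pairs
#'
#' Each streamline contributes one count to the unordered region pair holding
#' its two endpoints; streamlines with both endpoints in the same region are
#' discarded (tallied in attribute `"n_discarded"`).
#'
#' @param endpoint_pairs two-column matrix (or data.frame) of 1-based region
#'   indices, one row per streamline.
#' @param n_regions number of regions N.
#' @return N x N connectivity matrix with attribute `n_discarded`.
#' @export
count_streamlines <- function(endpoint_pairs, n_regions) {
  stopifnot(n_regions >= 1)
  ep <- as.matrix(endpoint_pairs)
  m <- matrix(0, n_regions, n_regions)
  discarded <- 0L
  if (length(ep) > 0) {
    if (ncol(ep) != 2L) stop("endpoint_pairs must have two columns")
    storage.mode(ep) <- "double"
    if (any(ep < 1 | ep > n_regions | ep != round(ep))) {
      stop("region index out of range [1, n_regions]")
    }
    self <- ep[, 1] == ep[, 2]
    discarded <- sum(self)
    ep <- ep[!self, , drop = FALSE]
    for (k in seq_len(nrow(ep))) {
      i <- ep[k, 1]; j <- ep[k, 2]
      m[i, j] <- m[i, j] + 1
      m[j, i] <- m[j, i] + 1
    }
  }
  attr(m, "n_discarded") <- as.integer(discarded)
  m
}

#' Apply a fiber-number threshold to a connectivity matrix
#'
#' Edges whose streamline count is strictly less than `w_min` are set to zero;
#' edges at or above the threshold are unchanged (the comparison is strict, so
#' `w_min = 1` keeps every nonzero edge).
#'
#' @param m connectivity matrix.
#' @param w_min positive threshold.
#' @return thresholded matrix (attributes preserved).
#' @export
apply_fiber_threshold <- function(m, w_min) {
  stopifnot(is.numeric(w_min), length(w_min) == 1L, w_min >= 1)
  m[m < w_min] <- 0
  m
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Deterministic row-major upper-triangle order: (1,2), (1,3), ..., (1,N),
#' (2,3), ... The inverse is [devectorize_edges()]; the round trip is lossless.
#'
#' @param m connectivity matrix.
#' @return list with `values` (length N(N-1)/2) and `index_map`
#'   (two-column matrix of 1-based node pairs, i < j).
#' @export
vectorize_edges <- function(m) {
  n <- nrow(m)
  idx <- edge_index_map(n)
  list(values = m[cbind(idx[, 1], idx[, 2])], index_map = idx, n_nodes = n)
}

#' Rebuild a connectivity matrix from an edge vector
#'
#' @param values numeric vector of length N(N-1)/2 in the order produced by
#'   [vectorize_edges()].
#' @param n_nodes N.
#' @return symmetric N x N matrix with zero diagonal.
#' @export
devectorize_edges <- function(values, n_nodes) {
  idx <- edge_index_map(n_nodes)
  stopifnot(length(values) == nrow(idx))
  m <- matrix(0, n_nodes, n_nodes)
  m[cbind(idx[, 1], idx[, 2])] <- values
  m[cbind(idx[, 2], idx[, 1])] <- values
  m
}

#' Row-major upper-triangle edge index map
#'
#' @param n number of nodes.
#' @return two-column integer matrix of all pairs (i, j), i < j, ordered
#'   row-major: (1,2), (1,3), ..., (2,3), ...
#' @export
edge_index_map <- function(n) {
  stopifnot(n >= 1)
  if (n < 2) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i = i, j = as.integer(j))
}

#' Read a cohort manifest and its connectivity matrices
#'
#' The manifest is a CSV with required columns `subject_id`, `group`, `age`,
#' `sex`, `education`, `matrix_path` and optional clinical-score columns.
#' Matrix paths are resolved relative to the manifest's directory unless
#' absolute.
#'
#' @param path manifest CSV path.
#' @param read_matrices if `FALSE`, return the manifest only.
#' @return a `cohort` object: list with `manifest` (data.frame) and
#'   `matrices` (named list of connectivity matrices).
#' @export
read_cohort <- function(path, read_matrices = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  man <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "education")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stop(sprintf("manifest lacks required columns: %s",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(man$subject_id)) stop("duplicate subject_id in manifest")
  if (any(man$age < 0) || any(man$education < 0)) {
    stop("age and education must be nonnegative")
  }
  matrices <- NULL
  if (read_matrices) {
    if (!"matrix_path" %in% names(man)) stop("manifest lacks matrix_path column")
    base <- dirname(path)
    matrices <- lapply(seq_len(nrow(man)), function(r) {
      p <- man$matrix_path[r]
      if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
      read_connectivity_matrix(p)
    })
    names(matrices) <- man$subject_id
    ns <- vapply(matrices, nrow, 1L)
    if (length(unique(ns)) > 1L) stop("matrices differ in node count")
  }
  new_cohort(manifest = man, matrices = matrices)
}

new_cohort <- function(manifest, matrices, truth = NULL) {
  structure(list(manifest = manifest, matrices = matrices, truth = truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$manifest)
  groups <- table(x$manifest$group)
  cat(sprintf("structural connectome cohort: %d subjects (%s)\n", n,
              paste(sprintf("%s=%d", names(groups), groups), collapse = ", ")))
  if (!is.null(x$matrices)) {
    cat(sprintf("  %d-node connectivity matrices\n", nrow(x$matrices[[1]])))
  }
  scores <- setdiff(names(x$manifest),
                    c("subject_id", "group", "age", "sex", "education",
                      "matrix_path"))
  if (length(scores)) {
    cat(sprintf("  clinical scores: %s\n", paste(scores, collapse = ", ")))
  }
  if (!is.null(x$truth)) cat("  simulation ground truth attached\n")
  invisible(x)
}

#' Write a cohort (manifest + matrices) to a directory
#'
#' Emits one tab-delimited matrix file per subject plus `manifest.csv`, in the
#' formats [read_cohort()] reads. For synthetic cohorts the planted-edge truth
#' is written as a sidecar `truth_edges.tsv`.
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$matrices))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$matrix_path <- sprintf("%s.tsv", man$subject_id)
  for (r in seq_len(nrow(man))) {
    write_connectivity_matrix(cohort$matrices[[man$subject_id[r]]],
                              file.path(dir, man$matrix_path[r]))
  }
  mpath <- file.path(dir, "manifest.csv")
  con <- file(mpath, "w")
  writeLines(sprintf("# strucnet %s cohort manifest",
                     as.character(packageVersion("strucnet"))), con)
  write.table(man, con, sep = ",", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(cohort$truth)) {
    tpath <- file.path(dir, "truth_edges.tsv")
    tcon <- file(tpath, "w")
    writeLines(c("# strucnet synthetic ground truth: planted edges (1-based node indices)",
                 sprintf("# effect_converter=%g effect_nonconverter=%g",
                         cohort$truth$effect_converter,
                         cohort$truth$effect_nonconverter)), tcon)
    write.table(cohort$truth$planted_edges, tcon, sep = "\t",
                quote = FALSE, row.names = FALSE)
    close(tcon)
  }
  invisible(mpath)
}
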