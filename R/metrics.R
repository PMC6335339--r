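#' All-pairs shortest-path distance matrix of a weighted network
#'
#' Edge lengths are the reciprocal of the streamline count (`1/w` for
#' `w > 0`), so stronger connections are shorter: this mapping reconciles the
#' magnitudes of efficiency and path length on raw count-weighted networks.
#' Unreachable pairs have infinite distance.
#'
#' @param m connectivity matrix.
#' @return N x N numeric distance matrix, zero diagonal, `Inf` where
#'   disconnected.
#' @export
shortest_path_distances <- function(m) {
  n <- nrow(m)
  len <- m
  len[m > 0] <- 1 / m[m > 0]
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(m)
  d
}

# mean inverse distance over ordered pairs; dist matrix variant
efficiency_from_distances <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d   # 1/Inf -> 0 for disconnected pairs
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency of a connectivity matrix
#'
#' Mean of `1/d_ij` over all ordered node pairs, with disconnected pairs
#' contributing zero; distances from [shortest_path_distances()].
#'
#' @param m connectivity matrix.
#' @return scalar global efficiency.
#' @export
global_efficiency <- function(m) {
  efficiency_from_distances(shortest_path_distances(m))
}

# Onnela weighted clustering coefficient per node; weights rescaled by the
# network-wide maximum so each C_i lies in [0, 1]; nodes with degree < 2 get 0
onnela_clustering <- function(m) {
  n <- nrow(m)
  k <- colSums(m > 0)
  mx <- max(m)
  if (mx == 0) return(rep(0, n))
  w13 <- (m / mx)^(1 / 3)
  num <- diag(w13 %*% w13 %*% w13)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  as.numeric(ci)
}

# nodal local efficiency: global efficiency of the subgraph induced by each
# node's neighbors, keeping the original weights
local_efficiency_nodal <- function(m) {
  n <- nrow(m)
  vapply(seq_len(n), function(i) {
    nb <- which(m[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(m[nb, nb, drop = FALSE])
  }, numeric(1))
}

#' Nodal network metrics
#'
#' Per-node global efficiency (mean inverse distance to all other nodes),
#' local efficiency (global efficiency of the neighbor-induced subgraph),
#' binary degree and strength (weight sum). Isolated nodes get zero
#' efficiencies.
#'
#' @param m connectivity matrix.
#' @return list with numeric vectors `nodal_global_efficiency`,
#'   `nodal_local_efficiency`, `degree`, `strength`.
#' @export
nodal_metrics <- function(m) {
  m <- validate_connectivity(m)
  n <- nrow(m)
  d <- shortest_path_distances(m)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  list(nodal_global_efficiency = rowSums(inv) / (n - 1),
       nodal_local_efficiency = local_efficiency_nodal(m),
       degree = as.integer(colSums(m > 0)),
       strength = colSums(m))
}

# one degree-preserving surrogate: rewire the binary topology by repeated
# degree-preserving edge swaps (10 x |E| attempts), then permute the original
# weights over the surviving edges. Uses R's RNG (seed set by the caller).
random_surrogate <- function(m) {
  n <- nrow(m)
  g <- igraph::graph_from_adjacency_matrix(m > 0, mode = "undirected",
                                           diag = FALSE)
  ne <- igraph::ecount(g)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = 10 * ne))
  el <- igraph::as_edgelist(g2, names = FALSE)
  w <- sample(m[upper.tri(m)][m[upper.tri(m)] > 0])
  r <- matrix(0, n, n)
  r[el] <- w
  r[el[, c(2, 1)]] <- w
  r
}

# characteristic path length over connected ordered pairs only; also returns
# the number of disconnected ordered pairs
char_path_length <- function(d) {
  n <- nrow(d)
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  list(Lp = if (any(fin)) mean(off[fin]) else Inf,
       n_disconnected = sum(!fin))
}

#' Global network metrics with small-world normalization
#'
#' Computes network strength (mean nodal strength, `Sp`), global efficiency
#' (`Eglob`), local efficiency (`Eloc`, mean nodal local efficiency),
#' characteristic path length over connected pairs (`Lp`), mean Onnela
#' weighted clustering (`Cp`), and the small-world ratios `lambda = Lp /
#' <Lp_rand>`, `gamma = Cp / <Cp_rand>`, `sigma = gamma / lambda` against an
#' ensemble of `n_random` degree-preserving surrogates with weights reshuffled
#' among edges. `sigma > 1` with `lambda` near 1 and `gamma > 1` indicates
#' small-world organization.
#'
#' @param m connectivity matrix.
#' @param n_random surrogate ensemble size (default 100). Set to 0 to skip
#'   the small-world ratios (`lambda`, `gamma`, `sigma` are `NA`).
#' @param seed integer seed for the surrogate ensemble.
#' @return a `global_metrics` list with fields `Sp`, `Eglob`, `Eloc`, `Lp`,
#'   `Cp`, `lambda`, `gamma`, `sigma`, `n_random`, `n_disconnected_pairs`.
#' @export
global_metrics <- function(m, n_random = 100, seed = 20190110) {
  m <- validate_connectivity(m)
  if (all(m == 0)) stop("degenerate input: network has no edges")
  n <- nrow(m)
  d <- shortest_path_distances(m)
  cpl <- char_path_length(d)
  out <- list(Sp = mean(colSums(m)),
              Eglob = efficiency_from_distances(d),
              Eloc = mean(local_efficiency_nodal(m)),
              Lp = cpl$Lp,
              Cp = mean(onnela_clustering(m)),
              lambda = NA_real_, gamma = NA_real_, sigma = NA_real_,
              n_random = as.integer(n_random),
              n_disconnected_pairs = cpl$n_disconnected)
  if (n_random >= 1) {
    rand <- with_seed(seed, {
      vapply(seq_len(n_random), function(k) {
        r <- random_surrogate(m)
        dr <- shortest_path_distances(r)
        c(Lp = char_path_length(dr)$Lp, Cp = mean(onnela_clustering(r)))
      }, numeric(2))
    })
    out$lambda <- out$Lp / mean(rand["Lp", ])
    out$gamma <- out$Cp / mean(rand["Cp", ])
    out$sigma <- out$gamma / out$lambda
  }
  class(out) <- "global_metrics"
  out
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf(
    "global network metrics: Sp=%.4g Eglob=%.4g Eloc=%.4g Lp=%.4g Cp=%.4g\n",
    x$Sp, x$Eglob, x$Eloc, x$Lp, x$Cp))
  if (!is.na(x$lambda)) {
    cat(sprintf("  small-world (n_random=%d): lambda=%.3f gamma=%.3f sigma=%.3f\n",
                x$n_random, x$lambda, x$gamma, x$sigma))
  }
  if (x$n_disconnected_pairs > 0) {
    cat(sprintf("  note: %d disconnected ordered pairs excluded from Lp\n",
                x$n_disconnected_pairs))
  }
  invisible(x)
}

#' Per-subject global metrics for a cohort
#'
#' @param cohort a `cohort` object with matrices.
#' @param n_random surrogate ensemble size per subject (0 skips small-world
#'   ratios).
#' @param seed global seed; each subject's ensemble seed is derived from it
#'   and the subject id, so results do not depend on subject order.
#' @return data.frame with one row per subject: subject_id, group, covariates,
#'   and the global metrics.
#' @export
cohort_global_metrics <- function(cohort, n_random = 100, seed = 20190110) {
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$matrices))
  man <- cohort$manifest
  rows <- lapply(seq_len(nrow(man)), function(r) {
    id <- man$subject_id[r]
    gm <- global_metrics(cohort$matrices[[id]], n_random = n_random,
                         seed = derive_seed(seed, id))
    data.frame(subject_id = id, Sp = gm$Sp, Eglob = gm$Eglob, Eloc = gm$Eloc,
               Lp = gm$Lp, Cp = gm$Cp, lambda = gm$lambda, gamma = gm$gamma,
               sigma = gm$sigma, stringsAsFactors = FALSE)
  })
  merge(man[, setdiff(names(man), "matrix_path")], do.call(rbind, rows),
        by = "subject_id", sort = FALSE)
}

#' Per-subject nodal metrics for a cohort
#'
#' @param cohort a `cohort` object with matrices.
#' @return list of subjects x nodes matrices: `nodal_global_efficiency`,
#'   `nodal_local_efficiency`, `degree`, `strength`.
#' @export
cohort_nodal_metrics <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$matrices))
  per <- lapply(cohort$matrices, nodal_metrics)
  ids <- names(cohort$matrices)
  pack <- function(field) {
    m <- do.call(rbind, lapply(per, `[[`, field))
    rownames(m) <- ids
    m
  }
  list(nodal_global_efficiency = pack("nodal_global_efficiency"),
       nodal_local_efficiency = pack("nodal_local_efficiency"),
       degree = pack("degree"),
       strength = pack("strength"))
}
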