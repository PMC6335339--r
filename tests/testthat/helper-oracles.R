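# Independent brute-force oracles, written directly from the definitions and
# kept free of any package internals.

# Floyd-Warshall all-pairs shortest paths on 1/w edge lengths
oracle_distances <- function(m) {
  n <- nrow(m)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && m[i, j] > 0) d[i, j] <- 1 / m[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_global_efficiency <- function(m) {
  n <- nrow(m)
  d <- oracle_distances(m)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  }
  s / (n * (n - 1))
}

oracle_nodal_global_efficiency <- function(m) {
  n <- nrow(m)
  d <- oracle_distances(m)
  sapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    s / (n - 1)
  })
}

oracle_local_efficiency <- function(m) {
  n <- nrow(m)
  sapply(seq_len(n), function(i) {
    nb <- which(m[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(m[nb, nb, drop = FALSE])
  })
}

# Onnela weighted clustering, triple loop over neighbor pairs
oracle_clustering <- function(m) {
  n <- nrow(m)
  mx <- max(m)
  if (mx == 0) return(rep(0, n))
  w <- m / mx
  sapply(seq_len(n), function(i) {
    nb <- which(m[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    s <- 0
    for (j in nb) for (h in nb) {
      if (j != h) s <- s + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    s / (k * (k - 1))
  })
}

oracle_path_length <- function(m) {
  d <- oracle_distances(m)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_strength_mean <- function(m) mean(rowSums(m))

# random symmetric nonnegative integer-weighted graph
random_weighted_graph <- function(n, density = 0.5, wmax = 9) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < density) m[i, j] <- m[j, i] <- sample.int(wmax, 1)
  }
  m
}

# ring lattice: each node connected to `k` nearest neighbors (k even)
ring_lattice <- function(n, k = 4, w = 1) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i - 1 + s) %% n) + 1
    m[i, j] <- m[j, i] <- w
  }
  m
}

# Benjamini-Hochberg step-up by direct enumeration
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# classical one-way ANOVA F from textbook sums of squares
oracle_anova_F <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  (ssb / dfb) / (ssw / dfw)
}

# direct evaluation of the F-score definition, scalar loops
oracle_fscore <- function(x_pos, x_neg) {
  xall <- c(x_pos, x_neg)
  num <- (mean(x_pos) - mean(xall))^2 + (mean(x_neg) - mean(xall))^2
  den <- sum((x_pos - mean(x_pos))^2) / (length(x_pos) - 1) +
         sum((x_neg - mean(x_neg))^2) / (length(x_neg) - 1)
  if (den == 0) 0 else num / den
}

# AUC by brute-force pairwise comparison (ties count 1/2)
oracle_auc <- function(scores_pos, scores_neg) {
  s <- 0
  for (a in scores_pos) for (b in scores_neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(scores_pos) * length(scores_neg))
}

# small synthetic config helper for fast tests
small_config <- function(..., seed) {
  synthetic_config(
    n_nodes = 24,
    group_sizes = c(converter = 10, nonconverter = 10, control = 10),
    base_density = 0.25, planted_edges = 20, seed = seed, ...)
}
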