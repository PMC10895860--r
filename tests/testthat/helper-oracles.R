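# Independent brute-force oracles used across test files. These deliberately
# share no code with the package implementation.

# Mann-Whitney U by explicit pair counting: x > y counts 1, ties 1/2.
oracle_u <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  sum(cmp)
}

# Rank-sum z-score via an independent midrank construction (table-based tie
# counts, no rle/rank-loop as in the package).
oracle_wilcoxon_z <- function(x, y, tie_correct = TRUE) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- oracle_u(x, y)
  v <- n1 * n2 * (n + 1) / 12
  if (tie_correct) {
    tc <- as.numeric(table(c(x, y)))
    v <- v - n1 * n2 * sum(tc^3 - tc) / (12 * n * (n - 1))
  }
  if (v <= 0) return(0)
  (u - n1 * n2 / 2) / sqrt(v)
}

# Textbook Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

# Literal evaluations of the two log fold-change dialects.
oracle_lfc_seurat <- function(x, y) {
  log2(mean(exp(x) - 1) + 1) - log2(mean(exp(y) - 1) + 1)
}
oracle_lfc_scanpy <- function(x, y, eps = 1e-9) {
  log2(exp(mean(x)) - 1 + eps) - log2(exp(mean(y)) - 1 + eps)
}

oracle_cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

# A clean fixture: `n_noise` background genes identical in every cell plus
# one exclusive marker per cluster (positive inside its cluster with small
# deterministic jitter, exactly zero elsewhere).
make_planted_dataset <- function(n_clusters = 3, cells_per_cluster = 10,
                                 n_noise = 20, marker_value = 2) {
  K <- n_clusters
  N <- K * cells_per_cluster
  labels <- rep(paste0("c", seq_len(K)), each = cells_per_cluster)
  G <- n_noise + K
  mat <- matrix(1, G, N)  # background: count 1 everywhere
  gene_ids <- c(sprintf("noise%02d", seq_len(n_noise)),
                sprintf("marker_c%d", seq_len(K)))
  jitter <- rep_len(c(0, 1, 2), cells_per_cluster)
  for (k in seq_len(K)) {
    row <- n_noise + k
    mat[row, ] <- 0
    mat[row, labels == paste0("c", k)] <- marker_value + jitter
  }
  counts <- count_matrix(mat, gene_ids, sprintf("cell%03d", seq_len(N)))
  list(counts = counts,
       clusters = cluster_assignment(counts$cell_ids, labels),
       lognorm = lognormalize(counts),
       markers = setNames(sprintf("marker_c%d", seq_len(K)),
                          paste0("c", seq_len(K))))
}

# Random small count dataset with K clusters (no marker structure).
make_random_dataset <- function(n_genes = 30, n_cells = 40, K = 2,
                                seed = 1) {
  set.seed(seed)
  mat <- matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells)
  mat[1, ] <- pmax(mat[1, ], 1)  # guard against zero library sizes
  counts <- count_matrix(mat, sprintf("g%03d", seq_len(n_genes)),
                         sprintf("c%03d", seq_len(n_cells)))
  labels <- rep_len(paste0("k", seq_len(K)), n_cells)
  list(counts = counts,
       clusters = cluster_assignment(counts$cell_ids, labels),
       lognorm = lognormalize(counts))
}
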