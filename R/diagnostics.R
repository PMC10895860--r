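#' Check equivalence of score-based and p-value-based rankings
#'
#' For tests whose p-value is a fixed monotone transform of a z-score,
#' ranking by descending absolute statistic is mathematically identical to
#' ranking by ascending p-value, because the normal CDF is monotone and
#' every gene's p-value comes from the same distribution. For Welch's
#' t-test the degrees of freedom vary per gene, each p-value comes from a
#' different t distribution, and the equivalence can fail. This diagnostic
#' runs a test one-vs-rest on real or simulated data and reports every
#' discordant gene pair.
#'
#' @param lognorm A [lognorm_matrix()].
#' @param clusters A [cluster_assignment()].
#' @param cluster Target cluster label.
#' @param test `"wilcoxon"`, `"wilcoxon_notie"`, `"welch"`,
#'   `"welch_overestim"` or `"student"`.
#' @param max_pairs Cap on the number of discordant pairs listed.
#' @return List with `equivalent` (logical), `n_discordant`, and `pairs`, a
#'   data frame of discordant gene pairs with their statistics, degrees of
#'   freedom and p-values.
#' @export
rank_equivalence_report <- function(lognorm, clusters, cluster,
                                    test = c("wilcoxon", "wilcoxon_notie",
                                             "welch", "welch_overestim",
                                             "student"),
                                    max_pairs = 100) {
  test <- match.arg(test)
  clusters <- align_clusters(clusters, lognorm)
  labels <- clusters$labels
  i1 <- which(labels == cluster); i2 <- which(labels != cluster)
  r <- run_one_vs_rest(test, lognorm$values, NULL, NULL, i1, i2)
  a <- abs(r$statistic); lp <- r$log_p
  ord <- order(-a)
  a_s <- a[ord]; lp_s <- lp[ord]; genes_s <- lognorm$gene_ids[ord]
  df_s <- if (!is.null(r$df)) r$df[ord] else rep(NA_real_, length(a))
  pairs <- list()
  n_disc <- 0L
  # after sorting by |stat| descending, any p-value strictly below the
  # running maximum marks a discordant pair with the gene attaining that max
  run_max <- -Inf; run_idx <- NA_integer_
  for (i in seq_along(a_s)) {
    if (i > 1 && lp_s[i] < run_max - 1e-12 && a_s[i] < a_s[run_idx]) {
      n_disc <- n_disc + 1L
      if (length(pairs) < max_pairs) {
        pairs[[length(pairs) + 1]] <- data.frame(
          gene_high_stat = genes_s[run_idx], gene_low_stat = genes_s[i],
          stat_high = a_s[run_idx], stat_low = a_s[i],
          df_high = df_s[run_idx], df_low = df_s[i],
          p_high = exp(run_max), p_low = exp(lp_s[i]))
      }
    }
    if (is.na(run_idx) || lp_s[i] > run_max) {
      run_max <- lp_s[i]; run_idx <- i
    }
  }
  list(equivalent = n_disc == 0L, n_discordant = n_disc,
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL)
}

#' Top-set collapse onto fold-change ranking under p-value underflow
#'
#' With enough cells, two-sided p-values of strong markers fall below the
#' smallest positive double (about 5e-324) and collapse to exactly zero.
#' Under a p-then-fold-change ranking, the order among those genes is then
#' decided entirely by the fold-change, so once a cluster has at least `n`
#' zero-p genes its top-`n` set is identical to ranking by raw fold-change
#' alone. This check simulates datasets of increasing size and reports, per
#' cluster, the zero-p count and the top-`n` overlap between the
#' p-then-fold-change ranking (with underflow emulation) and a pure
#' fold-change-descending ranking.
#'
#' @param cell_sizes Integer vector of total cell numbers to simulate.
#' @param method_id A p-value-producing preset id (default the tie-corrected
#'   Wilcoxon with p-then-fold-change ranking).
#' @param params Base [sim_params()]; `n_cells` is overridden per size.
#' @param n Top-set size (default 20).
#' @return Data frame: n_cells, cluster, n_zero_p, overlap.
#' @export
underflow_collapse_check <- function(cell_sizes,
                                     method_id = "seurat-wilcox",
                                     params = sim_params(n_genes = 500),
                                     n = 20) {
  rows <- list()
  for (nc in cell_sizes) {
    p <- params
    p$n_cells <- as.integer(nc)
    sim <- simulate_dataset(p)
    lognorm <- lognormalize(sim$counts)
    for (k in sort(unique(sim$clusters$labels))) {
      ranking <- select_markers(lognorm, sim$clusters, method_id, k,
                                counts = sim$counts,
                                emulate_underflow = TRUE)
      lfc_order <- ranking$gene[order(-ranking$lfc,
                                      match(ranking$gene, lognorm$gene_ids))]
      rows[[length(rows) + 1]] <- data.frame(
        n_cells = nc, cluster = k,
        n_zero_p = sum(ranking$p_value == 0, na.rm = TRUE),
        overlap = overlap_proportion(ranking$gene, lfc_order, n))
    }
  }
  do.call(rbind, rows)
}

#' Divergence between log fold-change formula dialects
#'
#' Computes both log fold-change formulas (de-log-then-average versus
#' average-then-de-log, see [lfc_seurat()]) one-vs-rest for every gene and
#' flags two documented pathologies: genes undetected in one group whose
#' average-then-de-log fold-change explodes beyond `flag_threshold` log2
#' units, and genes with zero expression in the target cluster that
#' nevertheless enter a Welch t-test top-`n`.
#'
#' @param lognorm A [lognorm_matrix()].
#' @param clusters A [cluster_assignment()].
#' @param cluster Target cluster label.
#' @param counts Optional [count_matrix()] for detection flags; detection
#'   falls back to nonzero log-normalized values when absent.
#' @param flag_threshold Absolute log2 fold-change above which the
#'   average-then-de-log value counts as spurious (default 10).
#' @param n Top-set size for the zero-expression t-test flag (default 20).
#' @return Data frame per gene: `f_seurat`, `f_scanpy`, `difference`,
#'   `zero_in_group`, `spurious_lfc`, `zero_in_cluster`,
#'   `in_t_test_top`.
#' @export
lfc_divergence_report <- function(lognorm, clusters, cluster, counts = NULL,
                                  flag_threshold = 10, n = 20) {
  clusters <- align_clusters(clusters, lognorm)
  labels <- clusters$labels
  i1 <- which(labels == cluster); i2 <- which(labels != cluster)
  Y <- lognorm$values
  X <- if (!is.null(counts)) counts$counts else Y
  f_se <- mat_lfc(Y, i1, i2, "seurat")
  f_sc <- mat_lfc(Y, i1, i2, "scanpy")
  det1 <- rowSums(X[, i1, drop = FALSE] > 0)
  det2 <- rowSums(X[, i2, drop = FALSE] > 0)
  zero_in_group <- det1 == 0 | det2 == 0
  t_res <- mat_t_test(Y, i1, i2, "welch")
  t_top <- order(-abs(t_res$statistic))[seq_len(min(n, nrow(Y)))]
  in_top <- seq_len(nrow(Y)) %in% t_top
  data.frame(gene = lognorm$gene_ids,
             f_seurat = f_se, f_scanpy = f_sc,
             difference = f_sc - f_se,
             zero_in_group = zero_in_group,
             spurious_lfc = zero_in_group & abs(f_sc) > flag_threshold,
             zero_in_cluster = det1 == 0,
             in_t_test_top = in_top)
}
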