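#' Recovery of true marker genes
#'
#' Compares a selected gene set against a ground-truth set. A true positive
#' occurs in both lists. Following the benchmark's labeling convention the
#' remaining truth genes are counted as false positives and the remaining
#' selected genes as false negatives, so that `recall = TP / |truth|` and
#' `precision = TP / |selected|`; the F1 score is their harmonic mean
#' (defined as 0 when both are 0). An empty truth set yields all-zero
#' metrics.
#'
#' @param selected Character vector of selected genes (de-duplicated).
#' @param truth Character vector of true marker genes.
#' @return List with `TP`, `FP`, `FN`, `recall`, `precision`, `f1`.
#' @export
recovery_metrics <- function(selected, truth) {
  selected <- unique(selected); truth <- unique(truth)
  tp <- length(intersect(selected, truth))
  if (length(truth) == 0) {
    return(list(TP = 0L, FP = 0L, FN = length(selected),
                recall = 0, precision = 0, f1 = 0))
  }
  recall <- tp / length(truth)
  precision <- if (length(selected) == 0) 0 else tp / length(selected)
  f1 <- if (recall + precision == 0) 0 else
    2 * recall * precision / (recall + precision)
  list(TP = tp, FP = length(truth) - tp, FN = length(selected) - tp,
       recall = recall, precision = precision, f1 = f1)
}

#' Recovery of expert-annotated marker genes
#'
#' Recall of an expert marker set within the top `n` of a ranking, and
#' whether the cluster counts as successfully annotated (every expert gene
#' recovered). Expert genes absent from the ranked gene universe trigger a
#' warning and count as unrecoverable.
#'
#' @param ranking A [marker_ranking()].
#' @param expert Character vector of expert-annotated marker genes.
#' @param n Number of top genes to consider (conventionally tied to the
#'   expert set size).
#' @return List with `recall`, `annotated`, `found`, `missing_from_universe`.
#' @export
expert_recovery <- function(ranking, expert, n = length(expert)) {
  stopifnot(length(expert) > 0)
  missing <- setdiff(expert, ranking$gene)
  if (length(missing) > 0) {
    warning("expert genes absent from gene universe: ",
            paste(missing, collapse = ", "))
  }
  top <- if (n >= 1) top_n_genes(ranking, n) else character()
  found <- intersect(expert, top)
  list(recall = length(found) / length(expert),
       annotated = length(found) == length(expert),
       found = found, missing_from_universe = missing)
}

stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  with_seed(seed, {
    for (k in unique(labels)) {
      idx <- sample(which(labels == k))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

confusion_f1 <- function(truth, predicted, levels) {
  vapply(levels, function(k) {
    tp <- sum(truth == k & predicted == k)
    prec_den <- sum(predicted == k)
    rec_den <- sum(truth == k)
    prec <- if (prec_den == 0) 0 else tp / prec_den
    rec <- if (rec_den == 0) 0 else tp / rec_den
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
}

#' Predictive performance of selected marker gene sets
#'
#' Measures how much cluster information a set of per-cluster marker genes
#' carries by training a multiclass classifier on only those genes under
#' stratified k-fold cross-validation. Classifiers: `"knn3"` (3 nearest
#' neighbours, Euclidean metric on the pooled marker genes), `"svm_linear"`
#' (linear kernel, cost 1), and `"max_sum"`, which standardizes each gene
#' over the full dataset, sums each cluster's marker genes per cell and
#' predicts the cluster with the largest sum (no training; assessed on the
#' test folds). Performance is the per-cluster one-vs-rest F1 from the
#' multiclass confusion matrix, summarized as the median across clusters in
#' each fold.
#'
#' @param lognorm A [lognorm_matrix()].
#' @param clusters A [cluster_assignment()].
#' @param marker_sets Named list, cluster label -> character vector of marker
#'   genes (typically top 5 per cluster).
#' @param classifier `"knn3"`, `"svm_linear"` or `"max_sum"`.
#' @param folds Number of cross-validation folds (default 5); every cluster
#'   must contain at least this many cells.
#' @param seed Seed for the fold split.
#' @return Data frame with one row per fold (`fold`, `median_f1`); the
#'   per-cluster F1 matrix is attached as attribute `per_cluster`.
#' @export
predictive_eval <- function(lognorm, clusters, marker_sets,
                            classifier = c("knn3", "svm_linear", "max_sum"),
                            folds = 5, seed = 1L) {
  classifier <- match.arg(classifier)
  clusters <- align_clusters(clusters, lognorm)
  labels <- clusters$labels
  lev <- sort(unique(labels))
  if (any(table(labels) < folds)) {
    stop("cluster_too_small: every cluster needs at least ", folds,
         " cells", call. = FALSE)
  }
  pooled <- unique(unlist(marker_sets))
  if (length(pooled) == 0) stop("empty_marker_sets", call. = FALSE)
  pooled <- intersect(lognorm$gene_ids, pooled)
  expr <- t(lognorm$values[match(pooled, lognorm$gene_ids), , drop = FALSE])
  fold_id <- stratified_folds(labels, folds, seed)

  if (classifier == "max_sum") {
    mu <- colMeans(expr)
    sdv <- apply(expr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    std <- sweep(sweep(expr, 2, mu), 2, sdv, "/")
    sums <- vapply(lev, function(k) {
      genes <- intersect(marker_sets[[k]], pooled)
      if (length(genes) == 0) return(rep(-Inf, nrow(std)))
      rowSums(std[, genes, drop = FALSE])
    }, numeric(nrow(std)))
    pred_all <- lev[max.col(sums, ties.method = "first")]
  }

  per_cluster <- matrix(NA_real_, folds, length(lev),
                        dimnames = list(NULL, lev))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    pred <- switch(classifier,
      knn3 = as.character(FNN::knn(expr[!test, , drop = FALSE],
                                   expr[test, , drop = FALSE],
                                   factor(labels[!test]), k = 3)),
      svm_linear = {
        fit <- e1071::svm(expr[!test, , drop = FALSE],
                          factor(labels[!test]), kernel = "linear",
                          cost = 1, scale = FALSE)
        as.character(stats::predict(fit, expr[test, , drop = FALSE]))
      },
      max_sum = pred_all[test])
    per_cluster[f, ] <- confusion_f1(labels[test], pred, lev)
  }
  out <- data.frame(fold = seq_len(folds),
                    median_f1 = apply(per_cluster, 1, stats::median))
  attr(out, "per_cluster") <- per_cluster
  out
}

#' z-scores of predictive performance across methods
#'
#' Standardizes fold-averaged median F1 scores across methods within each
#' dataset, which absorbs between-dataset differences in clustering quality.
#' Higher mean z means better predictive performance; both sort directions
#' are available.
#'
#' @param scores Data frame with columns `method`, `dataset`, `median_f1`
#'   (one row per method/dataset, already averaged over folds).
#' @param decreasing Sort order of the result (default best first).
#' @return Data frame with `method` and `mean_z`.
#' @export
f1_zscores <- function(scores, decreasing = TRUE) {
  stopifnot(all(c("method", "dataset", "median_f1") %in% names(scores)))
  scores$z <- stats::ave(scores$median_f1, scores$dataset,
                         FUN = function(x) {
                           s <- stats::sd(x)
                           if (is.na(s) || s == 0) rep(0, length(x))
                           else (x - mean(x)) / s
                         })
  agg <- stats::aggregate(z ~ method, scores, mean)
  names(agg)[2] <- "mean_z"
  agg[order(agg$mean_z, decreasing = decreasing), , drop = FALSE]
}

overlap_proportion <- function(a, b, n) {
  a <- utils::head(a, n); b <- utils::head(b, n)
  den <- min(n, length(a), length(b))
  if (den == 0) return(NA_real_)
  length(intersect(a, b)) / den
}

#' Concordance matrix between methods
#'
#' For each cluster, the proportion of shared genes between every pair of
#' methods' top-`n` sets, `|A intersect B| / min(n, |A|, |B|)` (so
#' set-valued methods returning fewer than `n` genes are not penalized
#' mechanically), averaged over clusters with equal weights. A complete-
#' linkage hierarchical clustering of the Euclidean distances between matrix
#' rows accompanies the matrix.
#'
#' @param top_sets Named list, method -> named list, cluster -> character
#'   vector of genes in rank order.
#' @param n Top-set size (default 10).
#' @return List with the symmetric `matrix`, the `hclust` tree, and
#'   `absent`, the methods excluded for returning no genes.
#' @export
concordance_matrix <- function(top_sets, n = 10) {
  stopifnot(length(top_sets) >= 2)
  absent <- names(top_sets)[vapply(top_sets,
                                   function(m) all(lengths(m) == 0),
                                   logical(1))]
  use <- setdiff(names(top_sets), absent)
  clusters <- unique(unlist(lapply(top_sets[use], names)))
  M <- matrix(NA_real_, length(use), length(use),
              dimnames = list(use, use))
  for (i in seq_along(use)) {
    for (j in seq_len(i)) {
      vals <- vapply(clusters, function(k) {
        overlap_proportion(top_sets[[use[i]]][[k]],
                           top_sets[[use[j]]][[k]], n)
      }, numeric(1))
      M[i, j] <- M[j, i] <- mean(vals, na.rm = TRUE)
    }
  }
  tree <- if (length(use) >= 2) stats::hclust(stats::dist(M), "complete")
  else NULL
  list(matrix = M, hclust = tree, absent = absent)
}

#' Stability of a method under data perturbation
#'
#' Per-cluster overlap proportion between the top-`n` genes selected on the
#' full data and on a perturbed (down-sampled) version, summarized as the
#' median over clusters. Clusters absent after perturbation are excluded.
#'
#' @param full Named list, cluster -> genes in rank order, on the full data.
#' @param perturbed Same structure on the perturbed data.
#' @param n Top-set size (default 10).
#' @return Median overlap proportion; per-cluster values attached as
#'   attribute `per_cluster`.
#' @export
stability_score <- function(full, perturbed, n = 10) {
  common <- intersect(names(full), names(perturbed))
  vals <- vapply(common, function(k) {
    overlap_proportion(full[[k]], perturbed[[k]], n)
  }, numeric(1))
  out <- stats::median(vals, na.rm = TRUE)
  attr(out, "per_cluster") <- vals
  out
}

#' Characteristics of selected marker genes
#'
#' For each method's top-`n` genes per cluster: the mean and variance of
#' log-normalized expression inside the cluster of interest, the mean and
#' variance over all cells, and the proportion of selected genes that are
#' up-regulated (one-vs-rest log fold-change, de-log-then-average formula,
#' greater than 0; computed afresh so score-only methods are covered).
#' Expression summaries are medians over all selected (cluster, gene) pairs.
#'
#' @param rankings Named list, method -> named list, cluster ->
#'   [marker_ranking()].
#' @param lognorm A [lognorm_matrix()].
#' @param clusters A [cluster_assignment()].
#' @param n Genes per cluster to inspect (default 5).
#' @return Data frame, one row per method.
#' @export
characteristics_table <- function(rankings, lognorm, clusters, n = 5) {
  clusters <- align_clusters(clusters, lognorm)
  labels <- clusters$labels
  Y <- lognorm$values
  rows <- lapply(names(rankings), function(method) {
    recs <- lapply(names(rankings[[method]]), function(k) {
      genes <- top_n_genes(rankings[[method]][[k]], n)
      if (length(genes) == 0) return(NULL)
      gi <- match(genes, lognorm$gene_ids)
      ic <- labels == k
      lfc <- mat_lfc(Y[gi, , drop = FALSE], which(ic), which(!ic), "seurat")
      data.frame(
        cluster_mean = rowMeans(Y[gi, ic, drop = FALSE]),
        cluster_var = row_vars(Y[gi, ic, drop = FALSE]),
        gene_mean = rowMeans(Y[gi, , drop = FALSE]),
        gene_var = row_vars(Y[gi, , drop = FALSE]),
        up = lfc > 0)
    })
    recs <- do.call(rbind, recs)
    data.frame(method = method,
               cluster_mean = stats::median(recs$cluster_mean),
               cluster_var = stats::median(recs$cluster_var),
               gene_mean = stats::median(recs$gene_mean),
               gene_var = stats::median(recs$gene_var),
               prop_up = mean(recs$up))
  })
  do.call(rbind, rows)
}

#' Effect sizes of selected marker genes, quantile-normalized
#'
#' For each method's top-`n` genes per cluster, computes the one-vs-rest
#' AUC, absolute Cohen's d and absolute log2 fold-change, takes per-method
#' medians, quantile-normalizes the three metric columns so their
#' distributions coincide, and ranks methods by the median of the
#' normalized values.
#'
#' @inheritParams characteristics_table
#' @return Data frame with raw medians (`auc`, `abs_cohen_d`, `abs_lfc`),
#'   normalized columns (`*_qn`) and `rank_score`, sorted best first.
#' @export
effect_size_table <- function(rankings, lognorm, clusters, n = 5) {
  clusters <- align_clusters(clusters, lognorm)
  labels <- clusters$labels
  Y <- lognorm$values
  med <- t(vapply(names(rankings), function(method) {
    recs <- lapply(names(rankings[[method]]), function(k) {
      genes <- top_n_genes(rankings[[method]][[k]], n)
      if (length(genes) == 0) return(NULL)
      gi <- match(genes, lognorm$gene_ids)
      i1 <- which(labels == k); i2 <- which(labels != k)
      cbind(auc = mat_wilcoxon(Y[gi, , drop = FALSE], i1, i2)$auc,
            abs_cohen_d = abs(mat_cohens_d(Y[gi, , drop = FALSE], i1, i2)),
            abs_lfc = abs(mat_lfc(Y[gi, , drop = FALSE], i1, i2, "seurat")))
    })
    apply(do.call(rbind, recs), 2, stats::median)
  }, numeric(3)))
  qn <- limma::normalizeQuantiles(med)
  out <- data.frame(method = rownames(med), med,
                    auc_qn = qn[, 1], abs_cohen_d_qn = qn[, 2],
                    abs_lfc_qn = qn[, 3],
                    rank_score = apply(qn, 1, stats::median))
  out[order(-out$rank_score), , drop = FALSE]
}

#' Census of exactly-zero and adjusted p-values
#'
#' For each p-value-producing method: the number of exactly-zero p-values in
#' every cluster (no top-`n` cap) with its median over clusters, and the
#' distribution of adjusted p-values among the top `top_n` genes excluding
#' the zeros. Score-only methods are excluded and listed.
#'
#' @param rankings Named list, method -> named list, cluster ->
#'   [marker_ranking()].
#' @param top_n Number of top genes for the adjusted-p distribution
#'   (default 40).
#' @return List with `zero_counts` (data frame: method, cluster, n_zero),
#'   `zero_median` (per method), `adjusted` (data frame of non-zero adjusted
#'   p-values among the top genes) and `excluded` (score-only methods).
#' @export
pvalue_census <- function(rankings, top_n = 40) {
  has_p <- vapply(rankings, function(m) {
    any(vapply(m, function(r) any(!is.na(r$p_value)), logical(1)))
  }, logical(1))
  excluded <- names(rankings)[!has_p]
  zero_rows <- list(); adj_rows <- list()
  for (method in names(rankings)[has_p]) {
    for (k in names(rankings[[method]])) {
      r <- rankings[[method]][[k]]
      zero_rows[[length(zero_rows) + 1]] <-
        data.frame(method = method, cluster = k,
                   n_zero = sum(r$p_value == 0, na.rm = TRUE))
      top <- utils::head(r, top_n)
      keep <- !is.na(top$p_adjusted) & top$p_value > 0
      if (any(keep)) {
        adj_rows[[length(adj_rows) + 1]] <-
          data.frame(method = method, cluster = k,
                     p_adjusted = top$p_adjusted[keep])
      }
    }
  }
  zero_counts <- do.call(rbind, zero_rows)
  zero_median <- if (!is.null(zero_counts)) {
    stats::aggregate(n_zero ~ method, zero_counts, stats::median)
  }
  list(zero_counts = zero_counts, zero_median = zero_median,
       adjusted = if (length(adj_rows)) do.call(rbind, adj_rows),
       excluded = excluded)
}

#' Run the simulated marker-gene recovery benchmark
#'
#' Simulates datasets, runs the requested method presets on every cluster,
#' filters method output to up-regulated genes (the simulated truth contains
#' only up-regulated markers), and scores top-`n_top` recovery against the
#' simulation's true marker sets. The `random` negative control is exempt
#' from the up-regulation filter: restricting a random draw to genes that
#' really are up-regulated would enrich it for true markers and it would no
#' longer bound chance performance.
#'
#' @param params A [sim_params()]; each replicate uses `seed + replicate - 1`.
#' @param method_ids Character vector of preset ids (see
#'   [method_registry()]).
#' @param n_top Number of genes selected and number of true markers
#'   (default 20).
#' @param replicates Number of simulation replicates (default 1).
#' @return Long-form data frame: method, replicate, cluster, TP, recall,
#'   precision, f1.
#' @export
benchmark_recovery <- function(params, method_ids, n_top = 20,
                               replicates = 1) {
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    p <- params
    p$seed <- params$seed + rep_i - 1L
    sim <- simulate_dataset(p)
    lognorm <- lognormalize(sim$counts)
    truth_sets <- true_marker_sets(sim$truth, lognorm, n = n_top)
    for (method in method_ids) {
      rankings <- select_markers_all(lognorm, sim$clusters, method,
                                     counts = sim$counts, seed = p$seed)
      for (k in names(rankings)) {
        r <- rankings[[k]]
        if (method != "random") r <- r[r$direction == "up", , drop = FALSE]
        sel <- utils::head(r$gene, n_top)
        m <- recovery_metrics(sel, truth_sets[[k]])
        rows[[length(rows) + 1]] <-
          data.frame(method = method, replicate = rep_i, cluster = k,
                     TP = m$TP, recall = m$recall, precision = m$precision,
                     f1 = m$f1)
      }
    }
  }
  do.call(rbind, rows)
}
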