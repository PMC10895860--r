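p_value_tests <- c("wilcoxon", "wilcoxon_notie", "welch", "welch_overestim",
                   "student", "detection", "logistic", "poisson")
effect_statistics <- c("cohen", "auc", "detect_lfc")
score_only_tests <- c("roc", "cosine", "lfc", "random")
counts_tests <- c("detection", "poisson", "detect_lfc")

#' Define a marker-gene selection method
#'
#' A method is the combination of a two-group test or statistic, a comparison
#' strategy (one-vs-rest pools all non-target clusters; pairwise tests the
#' target against each other cluster and aggregates), an aggregation or
#' summary rule for pairwise results, a ranking strategy, a multiple-testing
#' correction, an up-regulated-only filter, and a log fold-change dialect.
#'
#' @param test One of the p-value tests (`"wilcoxon"`, `"wilcoxon_notie"`,
#'   `"welch"`, `"welch_overestim"`, `"student"`, `"detection"`,
#'   `"logistic"`, `"poisson"`), effect statistics (`"cohen"`, `"auc"`,
#'   `"detect_lfc"`) or score-only statistics (`"roc"`, `"cosine"`, `"lfc"`,
#'   `"random"`).
#' @param strategy `"one_vs_rest"` or `"pairwise"`.
#' @param aggregation For pairwise p-value tests one of `"any"`, `"all"`,
#'   `"some"`; for pairwise effect statistics one of `"mean"`, `"median"`,
#'   `"min"`, `"max"`, `"min_rank"`; otherwise `"none"`.
#' @param ranking `"p_then_lfc"`, `"score_raw"`, `"score_abs"` or
#'   `"effect_desc"`.
#' @param correction `"bonferroni"`, `"bh"` or `"none"`.
#' @param up_only Drop down-regulated genes (log fold-change <= 0) before
#'   ranking.
#' @param lfc_formula `"seurat"`, `"scanpy"` or `"counts"` (see
#'   [lfc_seurat()]).
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(test,
                        strategy = c("one_vs_rest", "pairwise"),
                        aggregation = "none",
                        ranking = c("p_then_lfc", "score_raw", "score_abs",
                                    "effect_desc"),
                        correction = c("none", "bonferroni", "bh"),
                        up_only = FALSE,
                        lfc_formula = c("seurat", "scanpy", "counts")) {
  strategy <- match.arg(strategy)
  ranking <- match.arg(ranking)
  correction <- match.arg(correction)
  lfc_formula <- match.arg(lfc_formula)
  all_tests <- c(p_value_tests, effect_statistics, score_only_tests)
  if (!test %in% all_tests) {
    stop("unknown_test: ", test, call. = FALSE)
  }
  if (aggregation %in% c("any", "all", "some")) {
    if (strategy != "pairwise" || !test %in% p_value_tests) {
      stop("invalid_aggregation: any/all/some require a pairwise p-value ",
           "test", call. = FALSE)
    }
  } else if (aggregation %in% c("mean", "median", "min", "max", "min_rank")) {
    if (strategy != "pairwise" || !test %in% effect_statistics) {
      stop("invalid_aggregation: effect summaries require a pairwise effect ",
           "statistic", call. = FALSE)
    }
  } else if (aggregation != "none") {
    stop("unknown_aggregation: ", aggregation, call. = FALSE)
  }
  if (strategy == "pairwise" && aggregation == "none") {
    stop("invalid_aggregation: pairwise strategy needs an aggregation rule",
         call. = FALSE)
  }
  structure(list(test = test, strategy = strategy, aggregation = aggregation,
                 ranking = ranking, correction = correction,
                 up_only = up_only, lfc_formula = lfc_formula),
            class = "method_spec")
}

#' Registry of named method presets
#'
#' Presets mirroring the documented method families of the major analysis
#' frameworks: one-vs-rest testing with Bonferroni correction and
#' p-then-fold-change ranking; one-vs-rest testing with Benjamini-Hochberg
#' correction and score-based ranking; pairwise testing with any/all/some
#' p-value aggregation; pairwise effect statistics with five summaries; plus
#' cosine-score, fold-change-only and random-baseline selectors.
#'
#' @return Named list of [method_spec()] objects.
#' @export
method_registry <- function() {
  reg <- list(
    # one-vs-rest, Bonferroni, p then fold-change (Seurat-style defaults)
    "seurat-wilcox"  = method_spec("wilcoxon", correction = "bonferroni"),
    "seurat-t"       = method_spec("welch", correction = "bonferroni"),
    "seurat-lr"      = method_spec("logistic", correction = "bonferroni"),
    "seurat-poisson" = method_spec("poisson", correction = "bonferroni",
                                   lfc_formula = "counts"),
    "seurat-roc"     = method_spec("roc", ranking = "score_raw"),
    # one-vs-rest, BH, score ranking (Scanpy-style defaults; raw-score
    # presets keep only up-regulated genes, absolute-score presets rank both
    # directions)
    "scanpy-t-raw" = method_spec("welch", ranking = "score_raw",
                                 correction = "bh", up_only = TRUE,
                                 lfc_formula = "scanpy"),
    "scanpy-t-abs" = method_spec("welch", ranking = "score_abs",
                                 correction = "bh", lfc_formula = "scanpy"),
    "scanpy-t-overestim-raw" = method_spec("welch_overestim",
                                           ranking = "score_raw",
                                           correction = "bh", up_only = TRUE,
                                           lfc_formula = "scanpy"),
    "scanpy-t-overestim-abs" = method_spec("welch_overestim",
                                           ranking = "score_abs",
                                           correction = "bh",
                                           lfc_formula = "scanpy"),
    "scanpy-wilcox-tie-raw" = method_spec("wilcoxon", ranking = "score_raw",
                                          correction = "bh", up_only = TRUE,
                                          lfc_formula = "scanpy"),
    "scanpy-wilcox-tie-abs" = method_spec("wilcoxon", ranking = "score_abs",
                                          correction = "bh",
                                          lfc_formula = "scanpy"),
    "scanpy-wilcox-raw" = method_spec("wilcoxon_notie",
                                      ranking = "score_raw",
                                      correction = "bh", up_only = TRUE,
                                      lfc_formula = "scanpy"),
    "scanpy-wilcox-abs" = method_spec("wilcoxon_notie",
                                      ranking = "score_abs",
                                      correction = "bh",
                                      lfc_formula = "scanpy"),
    # self-implemented baselines
    "student-t" = method_spec("student", correction = "bonferroni"),
    "logfc-raw" = method_spec("lfc", ranking = "score_raw"),
    "logfc-abs" = method_spec("lfc", ranking = "score_abs"),
    "cosg"      = method_spec("cosine", ranking = "score_raw"),
    "random"    = method_spec("random", ranking = "score_raw")
  )
  # pairwise p-value aggregation (scran findMarkers-style)
  for (test in c("t", "wilcox", "binom")) {
    tname <- c(t = "welch", wilcox = "wilcoxon", binom = "detection")[[test]]
    for (agg in c("any", "all", "some")) {
      reg[[paste0("scran-", test, "-", agg)]] <-
        method_spec(tname, strategy = "pairwise", aggregation = agg,
                    correction = "bh")
    }
  }
  # pairwise effect summaries (scran scoreMarkers-style)
  for (eff in c("cohen", "auc", "detect")) {
    ename <- c(cohen = "cohen", auc = "auc", detect = "detect_lfc")[[eff]]
    for (s in c("mean", "median", "min", "max", "rank")) {
      sname <- if (s == "rank") "min_rank" else s
      reg[[paste0("scoremarkers-", s, "-", eff)]] <-
        method_spec(ename, strategy = "pairwise", aggregation = sname,
                    ranking = "effect_desc")
    }
  }
  reg
}

#' Look up a method preset by id
#'
#' @param method_id Preset name; see [method_registry()].
#' @return A [method_spec()].
#' @export
get_method <- function(method_id) {
  reg <- method_registry()
  if (!method_id %in% names(reg)) {
    stop("unknown_preset: ", method_id, call. = FALSE)
  }
  reg[[method_id]]
}

#' Aggregate pairwise p-values into one value per gene
#'
#' For the `K - 1` p-values of a pairwise comparison strategy:
#' `"all"` takes the maximum (an intersection-union test); `"some"` applies a
#' Holm adjustment, sorts the adjusted values and returns the
#' `floor((K - 1) / 2) + 1`-th smallest (the middle-most); `"any"` combines
#' by Simes' rule, `min_j (K - 1) p_(j) / j` (callers additionally order
#' genes by their best rank across comparisons; see [select_markers()]).
#'
#' @param p Numeric vector of `K - 1` p-values in `[0, 1]`.
#' @param mode `"any"`, `"all"` or `"some"`.
#' @return A single combined p-value.
#' @export
aggregate_pairwise_p <- function(p, mode = c("any", "all", "some")) {
  mode <- match.arg(mode)
  if (length(p) == 0) stop("empty_p_list", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  switch(mode,
    all = max(p),
    any = min(1, min(m * sort(p) / seq_len(m))),
    some = {
      holm <- pmin(1, cummax(sort(p) * (m - seq_len(m) + 1)))
      sort(holm)[min(m, floor(m / 2) + 1)]
    })
}

# log-space version used internally by select_markers; identical algebra on
# log p-values so that aggregation survives double-precision underflow.
aggregate_logp <- function(logp, mode) {
  m <- length(logp)
  switch(mode,
    all = max(logp),
    any = min(0, min(log(m) + sort(logp) - log(seq_len(m)))),
    some = {
      holm <- pmin(0, cummax(sort(logp) + log(m - seq_len(m) + 1)))
      sort(holm)[min(m, floor(m / 2) + 1)]
    })
}

#' Summarize pairwise effect sizes into a per-gene ordering key
#'
#' @param effects Matrix of effects, genes in rows and the `K - 1` pairwise
#'   comparisons in columns.
#' @param summary `"mean"`, `"median"`, `"min"`, `"max"` or `"min_rank"`.
#'   The first four return the corresponding row summary (larger = stronger
#'   marker). `"min_rank"` ranks genes within each comparison by effect
#'   descending and returns the minimum rank across comparisons (smaller =
#'   stronger marker).
#' @return Numeric vector, one key per gene.
#' @export
summarize_pairwise_effects <- function(effects,
                                       summary = c("mean", "median", "min",
                                                   "max", "min_rank")) {
  summary <- match.arg(summary)
  effects <- as.matrix(effects)
  switch(summary,
    mean = rowMeans(effects),
    median = apply(effects, 1, stats::median),
    min = apply(effects, 1, min),
    max = apply(effects, 1, max),
    min_rank = {
      ranks <- apply(effects, 2, function(e) rank(-e, ties.method = "first"))
      apply(as.matrix(ranks), 1, min)
    })
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, G p)`) or Benjamini-Hochberg step-up adjustment; both
#' preserve the ordering of the input.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @param n Number of tests (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
adjust_p <- function(p, method = c("bonferroni", "bh"), n = length(p)) {
  method <- match.arg(method)
  stats::p.adjust(p, method = c(bonferroni = "bonferroni", bh = "BH")[method],
                  n = n)
}

#' Order marker records into a ranking
#'
#' Strategies: `"p_then_lfc"` sorts by ascending p-value with ties broken by
#' descending log fold-change, then by gene order; `"score_raw"` sorts by
#' descending score; `"score_abs"` by descending absolute score;
#' `"effect_desc"` is an alias of `"score_raw"` for effect summaries. With
#' `emulate_underflow = TRUE` the double-precision `p_value` column is used,
#' so p-values that underflow to exactly zero tie maximally and their order
#' is decided entirely by the fold-change; without it the natural-log
#' p-values kept alongside the records preserve the ordering.
#'
#' @param records Data frame with columns `gene`, `score`, `p_value`,
#'   `log_p`, `p_adjusted`, `lfc` as produced by [select_markers()].
#' @param strategy Ranking strategy.
#' @param emulate_underflow Rank on double-precision p-values.
#' @param cluster,method_id Metadata carried into the result.
#' @return A [marker_ranking()].
#' @export
rank_genes <- function(records, strategy = c("p_then_lfc", "score_raw",
                                             "score_abs", "effect_desc"),
                       emulate_underflow = FALSE, cluster = "cluster",
                       method_id = "unknown") {
  strategy <- match.arg(strategy)
  idx <- seq_len(nrow(records))
  if (strategy == "p_then_lfc") {
    has_logp <- !is.null(records$log_p) && !all(is.na(records$log_p))
    if (!has_logp && (is.null(records$p_value) ||
                      all(is.na(records$p_value)))) {
      stop("missing_field: p_then_lfc ranking requires p-values",
           call. = FALSE)
    }
    key <- if (emulate_underflow || !has_logp) {
      records$p_value
    } else {
      records$log_p
    }
    ord <- order(key, -records$lfc, idx)
  } else {
    if (is.null(records$score) || all(is.na(records$score))) {
      stop("missing_field: score ranking requires a score column",
           call. = FALSE)
    }
    key <- if (strategy == "score_abs") -abs(records$score) else
      -records$score
    ord <- order(key, idx)
  }
  marker_ranking(records[ord, , drop = FALSE], cluster = cluster,
                 method_id = method_id, ranking_strategy = strategy)
}

#' Take the top n genes of a ranking
#'
#' @param ranking A [marker_ranking()].
#' @param n Number of genes (at least 1). Set-valued methods may yield fewer
#'   than `n`; all available genes are returned in that case.
#' @return Character vector of gene ids, strongest first.
#' @export
top_n_genes <- function(ranking, n) {
  stopifnot(n >= 1)
  utils::head(ranking$gene, n)
}

run_one_vs_rest <- function(test, Y, X, lib, i1, i2) {
  switch(test,
    wilcoxon = mat_wilcoxon(Y, i1, i2, tie_correct = TRUE),
    wilcoxon_notie = mat_wilcoxon(Y, i1, i2, tie_correct = FALSE),
    welch = mat_t_test(Y, i1, i2, "welch"),
    welch_overestim = mat_t_test(Y, i1, i2, "overestim"),
    student = mat_t_test(Y, i1, i2, "student"),
    detection = mat_detection_test(X, i1, i2),
    logistic = mat_logistic_lrt(Y, i1, i2),
    poisson = mat_poisson_test(X, i1, i2, lib),
    stop("unknown_test: ", test, call. = FALSE))
}

run_effect <- function(test, Y, X, i1, i2) {
  switch(test,
    cohen = mat_cohens_d(Y, i1, i2),
    auc = mat_wilcoxon(Y, i1, i2, tie_correct = TRUE)$auc,
    detect_lfc = mat_detection_lfc(X, i1, i2),
    stop("unknown_test: ", test, call. = FALSE))
}

#' Select and rank marker genes for one cluster
#'
#' Runs a [method_spec()] on log-normalized expression (and raw counts where
#' the test needs them) for a target cluster, producing a full ranking of
#' the genes with score, p-value, adjusted p-value, log fold-change and
#' direction attached to every record. With a pairwise strategy the target
#' cluster is compared against each other cluster and the per-comparison
#' p-values or effects are aggregated according to the method spec; the `"any"`
#' aggregation orders genes primarily by their best within-comparison rank
#' with the Simes-combined p-value as tie-break.
#'
#' @param lognorm A [lognorm_matrix()].
#' @param clusters A [cluster_assignment()] covering the matrix's cells.
#' @param spec A [method_spec()] or preset id string.
#' @param cluster Target cluster label.
#' @param counts A [count_matrix()]; required by count-based tests
#'   (detection, Poisson, detection fold-change).
#' @param n_top Optionally truncate the ranking to its top `n_top` records.
#' @param seed Seed for the random-baseline selector.
#' @param emulate_underflow Rank on double-precision p-values so that
#'   underflowed zeros tie (see [rank_genes()]).
#' @return A [marker_ranking()].
#' @export
select_markers <- function(lognorm, clusters, spec, cluster, counts = NULL,
                           n_top = NULL, seed = 1L,
                           emulate_underflow = FALSE) {
  method_id <- "custom"
  if (is.character(spec)) {
    method_id <- spec
    spec <- get_method(spec)
  }
  stopifnot(inherits(spec, "method_spec"), inherits(lognorm, "lognorm_matrix"))
  clusters <- align_clusters(clusters, lognorm)
  labels <- clusters$labels
  if (!cluster %in% labels) {
    stop("unknown_cluster: ", cluster, call. = FALSE)
  }
  Y <- lognorm$values
  G <- nrow(Y)
  needs_counts <- spec$test %in% counts_tests || spec$lfc_formula == "counts"
  X <- NULL; lib <- NULL
  if (needs_counts) {
    if (is.null(counts)) {
      stop("missing_counts: method '", spec$test, "' needs raw counts",
           call. = FALSE)
    }
    stopifnot(identical(counts$cell_ids, lognorm$cell_ids))
    X <- counts$counts
    lib <- colSums(X)
  }
  i1 <- which(labels == cluster)
  rest <- which(labels != cluster)
  lfc <- if (spec$lfc_formula == "counts") {
    mat_lfc(X, i1, rest, "counts")
  } else {
    mat_lfc(Y, i1, rest, spec$lfc_formula)
  }

  score <- rep(NA_real_, G)
  log_p <- rep(NA_real_, G)
  min_rank_key <- NULL

  if (spec$test %in% score_only_tests) {
    score <- switch(spec$test,
      roc = {
        r <- mat_wilcoxon(Y, i1, rest, tie_correct = TRUE)
        2 * abs(r$auc - 0.5)
      },
      cosine = mat_cosine_score(Y, labels == cluster),
      lfc = lfc,
      random = with_seed(seed, sample(seq_len(G))))
  } else if (spec$strategy == "one_vs_rest") {
    r <- run_one_vs_rest(spec$test, Y, X, lib, i1, rest)
    score <- r$statistic
    log_p <- r$log_p
  } else if (spec$test %in% p_value_tests) {
    others <- setdiff(unique(labels), cluster)
    logp_mat <- vapply(others, function(k) {
      run_one_vs_rest(spec$test, Y, X, lib, i1, which(labels == k))$log_p
    }, numeric(G))
    logp_mat <- as.matrix(logp_mat)
    log_p <- apply(logp_mat, 1, aggregate_logp, mode = spec$aggregation)
    score <- -log_p
    if (spec$aggregation == "any") {
      comp_ranks <- apply(logp_mat, 2,
                          function(lp) rank(lp, ties.method = "first"))
      min_rank_key <- apply(as.matrix(comp_ranks), 1, min)
    }
  } else {
    others <- setdiff(unique(labels), cluster)
    eff_mat <- vapply(others, function(k) {
      run_effect(spec$test, Y, X, i1, which(labels == k))
    }, numeric(G))
    key <- summarize_pairwise_effects(as.matrix(eff_mat), spec$aggregation)
    score <- if (spec$aggregation == "min_rank") -key else key
  }

  p_value <- exp(log_p)
  p_adjusted <- if (spec$correction == "none") {
    rep(NA_real_, G)
  } else {
    adjust_p(p_value, spec$correction, n = G)
  }
  records <- data.frame(gene = lognorm$gene_ids, score = score,
                        p_value = p_value, log_p = log_p,
                        p_adjusted = p_adjusted, lfc = lfc,
                        stringsAsFactors = FALSE)
  if (!is.null(min_rank_key)) records$min_rank <- min_rank_key
  if (spec$up_only) {
    records <- records[records$lfc > 0, , drop = FALSE]
  }
  if (!is.null(min_rank_key)) {
    ord <- order(records$min_rank, records$log_p, seq_len(nrow(records)))
    ranking <- marker_ranking(records[ord, , drop = FALSE], cluster = cluster,
                              method_id = method_id,
                              ranking_strategy = "min_rank_then_p")
  } else {
    ranking <- rank_genes(records, spec$ranking, emulate_underflow,
                          cluster = cluster, method_id = method_id)
  }
  if (!is.null(n_top)) {
    ranking <- ranking[seq_len(min(n_top, nrow(ranking))), , drop = FALSE]
    class(ranking) <- c("marker_ranking", "data.frame")
  }
  ranking
}

#' Select markers for every cluster
#'
#' @inheritParams select_markers
#' @return Named list of [marker_ranking()] objects, one per cluster.
#' @export
select_markers_all <- function(lognorm, clusters, spec, counts = NULL,
                               n_top = NULL, seed = 1L,
                               emulate_underflow = FALSE) {
  clusters <- align_clusters(clusters, lognorm)
  ks <- sort(unique(clusters$labels))
  out <- lapply(ks, function(k) {
    select_markers(lognorm, clusters, spec, k, counts = counts,
                   n_top = n_top, seed = seed,
                   emulate_underflow = emulate_underflow)
  })
  names(out) <- ks
  out
}

# Evaluate an expression under a temporary seed, restoring RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
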