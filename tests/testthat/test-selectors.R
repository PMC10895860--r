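test_that("method specs validate their aggregation constraints", {
  expect_error(method_spec("wilcoxon", aggregation = "any"),
               "invalid_aggregation")
  expect_error(method_spec("cohen", strategy = "pairwise",
                           aggregation = "any"), "invalid_aggregation")
  expect_error(method_spec("wilcoxon", strategy = "pairwise",
                           aggregation = "mean"), "invalid_aggregation")
  expect_error(method_spec("welch", strategy = "pairwise",
                           aggregation = "none"), "invalid_aggregation")
  expect_error(method_spec("nope"), "unknown_test")
  expect_s3_class(method_spec("welch", strategy = "pairwise",
                              aggregation = "all"), "method_spec")
})

test_that("the registry exposes all preset families as valid specs", {
  reg <- method_registry()
  expect_gte(length(reg), 18)
  expect_true(all(vapply(reg, inherits, logical(1), "method_spec")))
  # every in-scope family is represented
  expect_true(all(c("seurat-wilcox", "seurat-t", "seurat-lr",
                    "seurat-poisson", "seurat-roc", "scanpy-t-raw",
                    "scanpy-wilcox-abs", "scran-t-any", "scran-wilcox-all",
                    "scran-binom-some", "scoremarkers-mean-auc",
                    "scoremarkers-rank-cohen", "scoremarkers-min-detect",
                    "cosg", "logfc-abs", "student-t", "random") %in%
                    names(reg)))
  expect_error(get_method("wilcoxon-typo"), "unknown_preset")
})

test_that("pairwise p-value aggregation follows its three stated rules", {
  p <- c(0.01, 0.04)
  expect_equal(aggregate_pairwise_p(p, "all"), 0.04)
  expect_equal(aggregate_pairwise_p(p, "any"), 0.02)
  expect_equal(aggregate_pairwise_p(p, "some"), 0.04)

  # equal inputs: all and any return that value; some returns the Holm
  # ceiling m * p (the largest multiplier dominates every adjusted value)
  expect_equal(aggregate_pairwise_p(rep(0.3, 4), "all"), 0.3)
  expect_equal(aggregate_pairwise_p(rep(0.3, 4), "any"), 0.3)
  expect_equal(aggregate_pairwise_p(rep(0.3, 4), "some"), 1)
  expect_equal(aggregate_pairwise_p(rep(0.1, 4), "some"), 0.4)

  expect_error(aggregate_pairwise_p(numeric(0), "all"), "empty_p_list")

  # monotonicity: raising any input never lowers any mode's output
  set.seed(14)
  for (i in 1:25) {
    p0 <- runif(sample(2:6, 1))
    j <- sample(length(p0), 1)
    p1 <- p0
    p1[j] <- min(1, p0[j] + runif(1))
    for (mode in c("any", "all", "some")) {
      expect_gte(aggregate_pairwise_p(p1, mode),
                 aggregate_pairwise_p(p0, mode))
    }
  }
})

test_that("pairwise effect summaries match brute force", {
  eff <- matrix(c(1, 3), 1)
  expect_equal(summarize_pairwise_effects(eff, "mean"), 2)
  expect_equal(summarize_pairwise_effects(eff, "median"), 2)
  expect_equal(summarize_pairwise_effects(eff, "min"), 1)
  expect_equal(summarize_pairwise_effects(eff, "max"), 3)

  # min-rank against per-comparison brute-force ranking
  set.seed(3)
  E <- matrix(rnorm(20 * 3), 20, 3)
  got <- summarize_pairwise_effects(E, "min_rank")
  brute <- apply(cbind(rank(-E[, 1], ties.method = "first"),
                       rank(-E[, 2], ties.method = "first"),
                       rank(-E[, 3], ties.method = "first")), 1, min)
  expect_equal(got, brute)

  # K = 2: a single comparison, every summary gives the same ordering
  e1 <- matrix(rnorm(15), 15, 1)
  ords <- lapply(c("mean", "median", "min", "max"), function(s)
    order(-summarize_pairwise_effects(e1, s)))
  expect_true(all(vapply(ords, identical, logical(1), ords[[1]])))
  expect_identical(order(summarize_pairwise_effects(e1, "min_rank")),
                   ords[[1]])
})

test_that("p-value adjustment matches closed forms and a step-up oracle", {
  expect_equal(adjust_p(0.2, "bonferroni"), 0.2)
  expect_equal(adjust_p(0.2, "bh"), 0.2)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(adjust_p(p, "bh"), oracle_bh(p), tolerance = 1e-12)
    # order preservation
    expect_identical(order(adjust_p(p, "bh"), p), order(p, p))
  }
})

test_that("gene ranking strategies apply their stated tie rules", {
  recs <- data.frame(gene = c("g1", "g2"), score = c(1, 2),
                     p_value = c(0, 0), log_p = c(-Inf, -Inf),
                     p_adjusted = c(0, 0), lfc = c(1.0, 2.0))
  rk <- rank_genes(recs, "p_then_lfc", emulate_underflow = TRUE)
  expect_identical(rk$gene, c("g2", "g1"))  # LFC decides among zero p

  recs2 <- data.frame(gene = c("g1", "g2"), score = c(1, 2),
                      p_value = c(0.001, 0.01), log_p = log(c(0.001, 0.01)),
                      p_adjusted = c(0.002, 0.02), lfc = c(1.0, 2.0))
  expect_identical(rank_genes(recs2, "p_then_lfc")$gene, c("g1", "g2"))

  recs3 <- data.frame(gene = c("a", "b"), score = c(-5, 3),
                      p_value = NA_real_, log_p = NA_real_,
                      p_adjusted = NA_real_, lfc = c(-1, 1))
  expect_identical(rank_genes(recs3, "score_raw")$gene[1], "b")
  expect_identical(rank_genes(recs3, "score_abs")$gene[1], "a")

  expect_error(rank_genes(recs3, "p_then_lfc"), "missing_field")
})

test_that("top_n_genes truncates deterministically", {
  recs <- data.frame(gene = paste0("g", 1:5), score = 5:1,
                     p_value = NA_real_, p_adjusted = NA_real_,
                     lfc = rep(1, 5))
  rk <- rank_genes(recs, "score_raw")
  expect_identical(top_n_genes(rk, 2), c("g1", "g2"))
  expect_identical(top_n_genes(rk, 99), paste0("g", 1:5))
  expect_identical(top_n_genes(rk, 2), top_n_genes(rk, 2))
})

test_that("a planted exclusive marker ranks first under every preset", {
  d <- make_planted_dataset(n_clusters = 3, cells_per_cluster = 8)
  reg <- method_registry()
  for (m in setdiff(names(reg), "random")) {
    rk <- select_markers(d$lognorm, d$clusters, m, "c2", counts = d$counts)
    expect_identical(rk$gene[1], "marker_c2")
  }
})

test_that("with two clusters one-vs-rest and pairwise selection coincide", {
  d <- make_random_dataset(n_genes = 40, n_cells = 30, K = 2, seed = 77)
  ovr <- select_markers(d$lognorm, d$clusters,
                        method_spec("welch", correction = "bh"), "k1")
  for (agg in c("any", "all", "some")) {
    pw <- select_markers(d$lognorm, d$clusters,
                         method_spec("welch", strategy = "pairwise",
                                     aggregation = agg, correction = "bh"),
                         "k1")
    expect_identical(pw$gene, ovr$gene)
  }
})

test_that("the random selector is a seeded, reproducible permutation", {
  d <- make_random_dataset(seed = 19)
  r1 <- select_markers(d$lognorm, d$clusters, "random", "k1", seed = 5)
  r2 <- select_markers(d$lognorm, d$clusters, "random", "k1", seed = 5)
  r3 <- select_markers(d$lognorm, d$clusters, "random", "k1", seed = 6)
  expect_identical(r1$gene, r2$gene)
  expect_false(identical(r1$gene, r3$gene))
  expect_setequal(r1$gene, d$lognorm$gene_ids)
})

test_that("up-only filtering preserves the relative order of survivors", {
  d <- make_random_dataset(n_genes = 50, n_cells = 40, K = 2, seed = 23)
  both <- select_markers(d$lognorm, d$clusters,
                         method_spec("welch", ranking = "score_raw",
                                     correction = "bh"), "k1")
  up <- select_markers(d$lognorm, d$clusters,
                       method_spec("welch", ranking = "score_raw",
                                   correction = "bh", up_only = TRUE), "k1")
  expect_identical(up$gene, both$gene[both$gene %in% up$gene])
  expect_true(all(up$direction == "up"))
})

test_that("p-then-lfc equals |score| ranking for a z-based method", {
  d <- make_random_dataset(n_genes = 80, n_cells = 50, K = 2, seed = 31)
  by_p <- select_markers(d$lognorm, d$clusters,
                         method_spec("wilcoxon"), "k1")
  by_abs <- select_markers(d$lognorm, d$clusters,
                           method_spec("wilcoxon", ranking = "score_abs"),
                           "k1")
  expect_identical(by_p$gene, by_abs$gene)
})

test_that("a singleton cluster fails t-based selection with a named error", {
  cm <- count_matrix(matrix(rpois(40, 2), 10, 4) + 1, paste0("g", 1:10),
                     paste0("c", 1:4))
  cl <- cluster_assignment(cm$cell_ids, c("A", "B", "B", "B"))
  ln <- lognormalize(cm)
  expect_error(select_markers(ln, cl, method_spec("welch"), "A"),
               "group_too_small")
  # rank-sum tolerates n1 = 1
  expect_s3_class(select_markers(ln, cl, method_spec("wilcoxon"), "A"),
                  "marker_ranking")
})
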