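#' Simulation parameters for the gamma-Poisson marker-gene simulator
#'
#' Parameterizes a splat-style generative model: gene base means are gamma
#' distributed, each gene-cluster pair receives a multiplicative
#' differential-expression (DE) factor `beta_gk = exp(N(de_loc, de_scale))`
#' with probability `de_prob` (and 1 otherwise; only up-regulation is
#' simulated), library sizes are lognormal, and counts are gamma-Poisson
#' with a common biological coefficient of variation, so that
#' `Var(X) = mu + bcv^2 mu^2`. The DE location/scale defaults of 3 and 0.2
#' produce strongly up-regulated markers comparable to expert-annotated
#' markers in real data. Dropout and expression-outlier machinery are not
#' modeled (their probabilities are zero in the study design this emulates).
#'
#' @param n_genes,n_cells,n_groups Dimensions of the simulation.
#' @param group_prob Cluster proportions (default equal); must sum to 1.
#' @param de_prob Probability that a gene is DE in a given cluster.
#' @param de_loc,de_scale Meanlog and sdlog of the lognormal DE factor.
#' @param mean_shape,mean_rate Gamma shape/rate of gene base means.
#' @param lib_loc,lib_scale Meanlog and sdlog of library sizes.
#' @param bcv Common biological coefficient of variation `phi`; 0 gives
#'   Poisson counts.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000, n_cells = 2000, n_groups = 5,
                       group_prob = rep(1 / n_groups, n_groups),
                       de_prob = 0.1, de_loc = 3, de_scale = 0.2,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_loc = log(5000), lib_scale = 0.35,
                       bcv = 0.4, seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
            n_groups = as.integer(n_groups), group_prob = group_prob,
            de_prob = de_prob, de_loc = de_loc, de_scale = de_scale,
            mean_shape = mean_shape, mean_rate = mean_rate,
            lib_loc = lib_loc, lib_scale = lib_scale, bcv = bcv,
            seed = as.integer(seed))
  if (p$n_genes < 1 || p$n_cells < 2 || p$n_groups < 2) {
    stop("invalid_params: need at least 1 gene, 2 cells and 2 groups",
         call. = FALSE)
  }
  if (length(p$group_prob) != p$n_groups ||
      abs(sum(p$group_prob) - 1) > 1e-8 || any(p$group_prob <= 0)) {
    stop("invalid_params: group proportions must be positive and sum to 1",
         call. = FALSE)
  }
  if (p$de_prob < 0 || p$de_prob > 1 || p$de_scale <= 0 ||
      p$mean_shape <= 0 || p$mean_rate <= 0 || p$lib_scale < 0 || p$bcv < 0) {
    stop("invalid_params: parameter out of range", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Simulate a clustered scRNA-seq dataset with known marker genes
#'
#' Draws gene base means `gamma_g ~ Gamma(shape, rate)`, DE factors
#' `beta_gk`, lognormal library sizes `L_i`, assigns cells to clusters by
#' the group proportions (cluster sizes are fixed at their expectations so
#' no cluster can be empty), and samples counts from a gamma-Poisson with
#' cell mean `mu_ig = L_i gamma_g beta_{g,k(i)} / sum_g' gamma_g'
#' beta_{g',k(i)}` and variance `mu + bcv^2 mu^2`.
#'
#' @param params A [sim_params()].
#' @return A list of class `sim_dataset` with elements `counts`
#'   ([count_matrix()]), `clusters` ([cluster_assignment()]) and `truth`, a
#'   `sim_truth` list carrying the DE factor matrix `de_factors` (genes x
#'   clusters), `gene_means`, the cluster names and the generating
#'   parameters.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    G <- params$n_genes; N <- params$n_cells; K <- params$n_groups
    gene_ids <- sprintf("gene%04d", seq_len(G))
    cell_ids <- sprintf("cell%05d", seq_len(N))
    group_names <- paste0("cluster", seq_len(K))

    gamma_g <- stats::rgamma(G, shape = params$mean_shape,
                             rate = params$mean_rate)
    is_de <- matrix(stats::runif(G * K) < params$de_prob, G, K)
    beta <- matrix(1, G, K, dimnames = list(gene_ids, group_names))
    n_de <- sum(is_de)
    if (n_de > 0) {
      beta[is_de] <- exp(stats::rnorm(n_de, params$de_loc, params$de_scale))
    }

    # fixed cluster sizes at their expectations, remainder spread from the
    # largest fractional parts, then a random ordering of cells over labels
    sizes <- floor(params$group_prob * N)
    rem <- N - sum(sizes)
    if (rem > 0) {
      frac <- params$group_prob * N - sizes
      sizes[order(-frac)[seq_len(rem)]] <- sizes[order(-frac)[seq_len(rem)]] + 1
    }
    labels <- sample(rep(group_names, sizes))

    lib <- stats::rlnorm(N, params$lib_loc, params$lib_scale)

    mu <- matrix(0, G, N)
    for (k in seq_len(K)) {
      cells_k <- which(labels == group_names[k])
      base_k <- gamma_g * beta[, k]
      mu[, cells_k] <- outer(base_k / sum(base_k), lib[cells_k])
    }
    if (params$bcv > 0) {
      shape <- 1 / params$bcv^2
      lam <- matrix(stats::rgamma(G * N, shape = shape, rate = shape / mu),
                    G, N)
    } else {
      lam <- mu
    }
    counts <- matrix(stats::rpois(G * N, lam), G, N,
                     dimnames = list(gene_ids, cell_ids))

    truth <- structure(list(de_factors = beta, gene_means = gamma_g,
                            groups = group_names, params = params),
                       class = "sim_truth")
    structure(list(counts = count_matrix(counts, gene_ids, cell_ids),
                   clusters = cluster_assignment(cell_ids, labels),
                   truth = truth),
              class = "sim_dataset")
  })
}

#' Ground-truth marker score from simulated DE factors
#'
#' For a target cluster `k'` the score of gene `g` is the mean log-ratio of
#' its DE factor in the target cluster against all other clusters:
#' `m_g = (1 / (K - 1)) sum_{i != k'} ln(beta_gk' / beta_gi)`. Genes DE
#' nowhere score 0; natural log is used (the ranking is base-invariant).
#'
#' @param truth A `sim_truth` (from [simulate_dataset()]) or a positive
#'   numeric matrix of DE factors, genes x clusters.
#' @param cluster Target cluster label or column index.
#' @return Numeric vector `m_g`, one score per gene.
#' @export
marker_score <- function(truth, cluster) {
  beta <- if (inherits(truth, "sim_truth")) truth$de_factors else
    as.matrix(truth)
  if (any(beta <= 0)) {
    stop("invalid_de_factor: DE factors must be positive", call. = FALSE)
  }
  if (ncol(beta) < 2) stop("invalid_de_factor: need K >= 2", call. = FALSE)
  kp <- if (is.character(cluster)) match(cluster, colnames(beta)) else cluster
  if (is.na(kp) || kp < 1 || kp > ncol(beta)) {
    stop("unknown_cluster: ", cluster, call. = FALSE)
  }
  lb <- log(beta)
  rowSums(lb[, kp] - lb[, -kp, drop = FALSE]) / (ncol(beta) - 1)
}

#' True marker sets from a completed simulation
#'
#' Genes whose mean log-normalized expression over all cells exceeds the
#' eligibility threshold are ranked per cluster by the marker score
#' [marker_score()] (descending); the top `n` genes with a strictly positive
#' score form the cluster's true marker set. Clusters with fewer eligible
#' positive-score genes return shorter sets.
#'
#' @param truth A `sim_truth`.
#' @param data The simulated [count_matrix()] (log-normalized internally) or
#'   a [lognorm_matrix()].
#' @param n Set size (default 20).
#' @param mean_threshold Eligibility threshold on mean log-normalized
#'   expression (default 0.1).
#' @return Named list of character vectors, one per cluster.
#' @export
true_marker_sets <- function(truth, data, n = 20, mean_threshold = 0.1) {
  stopifnot(inherits(truth, "sim_truth"))
  lognorm <- if (inherits(data, "count_matrix")) lognormalize(data) else data
  eligible <- rowMeans(lognorm$values) > mean_threshold
  out <- lapply(truth$groups, function(k) {
    m <- marker_score(truth, k)
    keep <- which(eligible & m > 0)
    keep <- keep[order(-m[keep], keep)]
    lognorm$gene_ids[utils::head(keep, n)]
  })
  names(out) <- truth$groups
  out
}

#' Estimate simulation parameters from a single-cluster count matrix
#'
#' Fits the generative model's estimable parameters from data assumed to
#' come from one homogeneous cell population: the library-size lognormal by
#' moments of log library sizes; the gene-mean gamma by maximum likelihood
#' (via `fitdistrplus`) on per-gene means of library-size-normalized
#' expression; and the common BCV `phi` by a moment estimator on counts
#' normalized to the median library size. Because expression is normalized
#' per cell, gene means are identifiable only up to scale: the gamma fit is
#' performed on means rescaled to unit average, so the fitted rate equals
#' the fitted shape by construction. The DE location and scale cannot be
#' estimated from data and are left at their defaults.
#'
#' @param counts A [count_matrix()] of cells from a single cluster.
#' @param expressed_threshold Minimum mean normalized count for a gene to
#'   enter the BCV moment estimator.
#' @return A [sim_params()] with estimated `mean_shape`, `mean_rate`,
#'   `lib_loc`, `lib_scale` and `bcv`; dimensions mirror the input.
#' @export
estimate_params <- function(counts, expressed_threshold = 0.1) {
  stopifnot(inherits(counts, "count_matrix"))
  X <- counts$counts
  if (ncol(X) < 10 || nrow(X) < 10) {
    stop("too_few_cells: moment estimation needs more data", call. = FALSE)
  }
  lib <- colSums(X)
  if (any(lib == 0)) stop("zero_library_size", call. = FALSE)
  lib_loc <- mean(log(lib))
  lib_scale <- stats::sd(log(lib))

  rel <- rowMeans(sweep(X, 2, lib, "/"))
  u <- rel[rel > 0] / mean(rel)
  fit <- fitdistrplus::fitdist(u, "gamma", method = "mle",
                               start = list(shape = 1, rate = 1),
                               lower = c(1e-3, 1e-3))
  mean_shape <- unname(fit$estimate["shape"])
  mean_rate <- unname(fit$estimate["rate"])

  # moment estimator for the quadratic overdispersion term on counts
  # normalized to the median library size; the mean term is scaled by
  # s * E[1/L] to account for library-size spread
  s <- stats::median(lib)
  Z <- sweep(X, 2, s / lib, "*")
  m <- rowMeans(Z)
  v <- row_vars(Z)
  keep <- m > expressed_threshold
  phi2 <- (v[keep] - m[keep] * s * mean(1 / lib)) / m[keep]^2
  bcv <- sqrt(max(0, mean(phi2)))

  sim_params(n_genes = nrow(X), n_cells = ncol(X),
             mean_shape = mean_shape, mean_rate = mean_rate,
             lib_loc = lib_loc, lib_scale = lib_scale, bcv = bcv)
}

#' Randomly remove a fraction of cells
#'
#' Simple random subsampling without replacement, keeping labels aligned;
#' used for stability experiments. Errors if any cluster would be emptied.
#'
#' @param counts A [count_matrix()].
#' @param clusters Matching [cluster_assignment()].
#' @param fraction Fraction of cells to remove, in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with reduced `counts` and `clusters`.
#' @export
downsample_cells <- function(counts, clusters, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  clusters <- align_clusters(clusters, counts)
  N <- length(counts$cell_ids)
  if (fraction == 0) return(list(counts = counts, clusters = clusters))
  keep <- with_seed(seed,
                    sort(sample(N, size = round((1 - fraction) * N))))
  labs <- clusters$labels[keep]
  if (!all(unique(clusters$labels) %in% labs)) {
    stop("cluster_emptied: downsampling removed an entire cluster",
         call. = FALSE)
  }
  list(counts = count_matrix(counts$counts[, keep, drop = FALSE],
                             counts$gene_ids, counts$cell_ids[keep]),
       clusters = cluster_assignment(counts$cell_ids[keep], labs))
}

#' Remove clusters one by one
#'
#' Drops the listed clusters in order, returning the sequence of reduced
#' datasets with `K - 1, K - 2, ..., 2` clusters. The removal list may cover
#' at most `K - 2` clusters; removing below two clusters is an error.
#'
#' @param counts A [count_matrix()].
#' @param clusters Matching [cluster_assignment()].
#' @param removal_order Character vector of cluster labels to drop, in order.
#' @return List of `list(counts, clusters)` stages, one per removal.
#' @export
remove_clusters <- function(counts, clusters, removal_order) {
  clusters <- align_clusters(clusters, counts)
  K <- clusters$K
  if (length(removal_order) > K - 2) {
    stop("too_many_removals: at least two clusters must remain",
         call. = FALSE)
  }
  if (!all(removal_order %in% clusters$labels)) {
    stop("unknown_cluster: ",
         paste(setdiff(removal_order, clusters$labels), collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", length(removal_order))
  cur_counts <- counts; cur_clusters <- clusters
  for (i in seq_along(removal_order)) {
    keep <- which(cur_clusters$labels != removal_order[i])
    cur_counts <- count_matrix(cur_counts$counts[, keep, drop = FALSE],
                               cur_counts$gene_ids,
                               cur_counts$cell_ids[keep])
    cur_clusters <- cluster_assignment(cur_clusters$cell_ids[keep],
                                       cur_clusters$labels[keep])
    out[[i]] <- list(counts = cur_counts, clusters = cur_clusters)
  }
  out
}

#' Write simulation ground truth as JSON
#'
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @param marker_sets Optional list from [true_marker_sets()] to embed.
#' @export
write_truth <- function(truth, path, marker_sets = NULL) {
  obj <- list(de_factors = unname(as.data.frame(truth$de_factors)),
              gene_means = truth$gene_means,
              groups = truth$groups,
              marker_scores = lapply(stats::setNames(truth$groups,
                                                     truth$groups),
                                     function(k) marker_score(truth, k)))
  if (!is.null(marker_sets)) obj$marker_sets <- marker_sets
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
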