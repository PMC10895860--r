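#' Log-normalize a count matrix
#'
#' Computes `Y_ig = ln(1 + s * X_ig / L_i)` where `L_i` is the library size
#' (total counts) of cell `i` and `s` is the scale factor, by default the
#' median library size. Natural log is used for normalized expression; base-2
#' logs appear only in reported fold-changes.
#'
#' @param counts A [count_matrix()].
#' @param scale_factor Positive scalar; defaults to the median library size.
#' @return A [lognorm_matrix()] carrying the scale factor used.
#' @export
lognormalize <- function(counts, scale_factor = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- colSums(counts$counts)
  if (any(lib == 0)) {
    stop("zero_library_size: cells with zero total counts cannot be ",
         "normalized", call. = FALSE)
  }
  if (is.null(scale_factor)) scale_factor <- stats::median(lib)
  vals <- log1p(sweep(counts$counts, 2, scale_factor / lib, "*"))
  lognorm_matrix(vals, counts$gene_ids, counts$cell_ids, scale_factor)
}

#' Select highly variable genes
#'
#' Ranks genes by the raw variance of their log-normalized expression across
#' all cells and returns the top `n`. Ties are broken by higher mean, then by
#' gene order, so the result is deterministic.
#'
#' @param lognorm A [lognorm_matrix()].
#' @param n Number of genes to keep (default 2000). When `n` exceeds the
#'   number of genes, all genes are returned.
#' @return Character vector of selected gene ids, in original matrix order.
#' @export
select_hvgs <- function(lognorm, n = 2000) {
  stopifnot(inherits(lognorm, "lognorm_matrix"))
  v <- row_vars(lognorm$values)
  m <- rowMeans(lognorm$values)
  ord <- order(-v, -m, seq_along(v))
  keep <- sort(ord[seq_len(min(n, length(v)))])
  lognorm$gene_ids[keep]
}

#' Force required genes into a gene subset
#'
#' Takes the union of a selected gene subset and a required list (for
#' example, expert-annotated markers that fell outside the highly variable
#' set), preserving the order of the selected genes and appending missing
#' required genes in their given order. Idempotent.
#'
#' @param selected Character vector of selected gene ids.
#' @param required Character vector of gene ids that must be present.
#' @param universe Optional character vector of all genes in the matrix; when
#'   supplied, required genes outside it raise an error.
#' @return Character vector: `selected` plus any missing `required` genes.
#' @export
force_include <- function(selected, required, universe = NULL) {
  if (!is.null(universe) && !all(required %in% universe)) {
    stop("unknown_required_gene: ",
         paste(setdiff(required, universe), collapse = ", "), call. = FALSE)
  }
  c(selected, setdiff(required, selected))
}

#' Subset a matrix container to a gene set
#'
#' @param data A [count_matrix()] or [lognorm_matrix()].
#' @param genes Character vector of gene ids to keep; order follows `genes`.
#' @return A container of the same class restricted to `genes`.
#' @export
subset_genes <- function(data, genes) {
  idx <- match(genes, data$gene_ids)
  if (anyNA(idx)) {
    stop("unknown_gene_id: ", paste(genes[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  if (inherits(data, "count_matrix")) {
    count_matrix(data$counts[idx, , drop = FALSE], genes, data$cell_ids)
  } else {
    lognorm_matrix(data$values[idx, , drop = FALSE], genes, data$cell_ids,
                   data$scale_factor)
  }
}

# Row variances without forming a residual matrix copy per gene.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  (rowSums(x^2) - n * m^2) / (n - 1)
}
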