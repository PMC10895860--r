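#' Construct a raw count matrix
#'
#' Bundles a genes-by-cells matrix of non-negative integer counts with unique
#' gene and cell identifiers. All downstream operations (normalization,
#' selection, simulation round trips) consume this container.
#'
#' @param counts Numeric matrix (genes in rows, cells in columns) of
#'   non-negative integer counts. Sparse `Matrix` input is densified.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param cell_ids Character vector of unique cell identifiers, one per column.
#' @return An object of class `count_matrix` with elements `counts`,
#'   `gene_ids`, `cell_ids`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts)) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts)) {
    stop("id_dimension_mismatch: id lengths do not match matrix dimensions",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate_gene_id: gene identifiers must be unique", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate_cell_id: cell identifiers must be unique", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("negative_count: counts must be non-negative and non-missing",
         call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("non_integer_count: counts must be integers", call. = FALSE)
  }
  counts <- round(counts)
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells\n",
              length(x$gene_ids), length(x$cell_ids)))
  invisible(x)
}

#' Construct a log-normalized expression matrix
#'
#' Holds natural-log normalized expression values on the same gene/cell axes
#' as the raw counts, together with the scale factor used during
#' normalization. Zero counts must map to zero values.
#'
#' @param values Numeric matrix of non-negative, finite log-normalized values.
#' @param gene_ids,cell_ids Identifiers, as in [count_matrix()].
#' @param scale_factor Positive scalar recorded from normalization.
#' @return An object of class `lognorm_matrix`.
#' @export
lognorm_matrix <- function(values, gene_ids = rownames(values),
                           cell_ids = colnames(values), scale_factor = 1) {
  values <- as.matrix(values)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop("id_dimension_mismatch: id lengths do not match matrix dimensions",
         call. = FALSE)
  }
  if (!all(is.finite(values)) || any(values < 0)) {
    stop("invalid_lognorm_value: values must be finite and non-negative",
         call. = FALSE)
  }
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      scale_factor <= 0) {
    stop("invalid_scale_factor: scale factor must be a positive scalar",
         call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 scale_factor = scale_factor),
            class = "lognorm_matrix")
}

#' Construct a cell-to-cluster assignment
#'
#' @param cell_ids Character vector of cell identifiers.
#' @param labels Cluster label for each cell; coerced to character. At least
#'   two distinct clusters are required and every cluster must be non-empty.
#' @return An object of class `cluster_assignment` with elements `cell_ids`,
#'   `labels` and `K`.
#' @export
cluster_assignment <- function(cell_ids, labels) {
  cell_ids <- as.character(cell_ids)
  labels <- as.character(labels)
  if (length(cell_ids) != length(labels)) {
    stop("id_dimension_mismatch: one label per cell required", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    stop("duplicate_cell_id: cell identifiers must be unique", call. = FALSE)
  }
  if (anyNA(labels)) {
    stop("unlabeled_cell: every cell must carry a cluster label",
         call. = FALSE)
  }
  K <- length(unique(labels))
  if (K < 2) {
    stop("single_cluster: at least two clusters are required", call. = FALSE)
  }
  structure(list(cell_ids = cell_ids, labels = labels, K = K),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells in %d clusters\n",
              length(x$cell_ids), x$K))
  print(table(x$labels))
  invisible(x)
}

#' Align a cluster assignment to a count matrix's cell order
#'
#' @param clusters A [cluster_assignment()].
#' @param data A [count_matrix()] or [lognorm_matrix()] whose cell order the
#'   assignment should follow.
#' @return A `cluster_assignment` reordered to `data$cell_ids`.
#' @export
align_clusters <- function(clusters, data) {
  idx <- match(data$cell_ids, clusters$cell_ids)
  if (anyNA(idx)) {
    stop("unknown_cell_id: assignment lacks labels for some cells",
         call. = FALSE)
  }
  cluster_assignment(clusters$cell_ids[idx], clusters$labels[idx])
}

#' Read a count matrix from disk
#'
#' Supports Matrix Market sparse files with `genes.tsv`/`barcodes.tsv`
#' sidecars (the 10x convention, genes as rows by default) and dense CSV with
#' gene identifiers in the first column and cell identifiers in the header.
#'
#' @param path Path to the `.mtx` or `.csv` file.
#' @param format `"mtx"` or `"csv"`; guessed from the file extension when
#'   missing.
#' @param genes_as_rows For mtx input, whether the stored matrix has genes in
#'   rows (default `TRUE`); set `FALSE` for cells-as-rows files, which are
#'   transposed on read.
#' @param genes_path,cells_path Sidecar paths for mtx input. Default to
#'   `genes.tsv` and `barcodes.tsv` next to the matrix file.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("guess", "mtx", "csv"),
                        genes_as_rows = TRUE,
                        genes_path = file.path(dirname(path), "genes.tsv"),
                        cells_path = file.path(dirname(path), "barcodes.tsv")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (!file.exists(path)) {
    stop("missing_file: ", path, call. = FALSE)
  }
  if (format == "mtx") {
    mat <- tryCatch(as.matrix(Matrix::readMM(path)), error = function(e) {
      stop("malformed_header: cannot parse Matrix Market file: ",
           conditionMessage(e), call. = FALSE)
    })
    if (!file.exists(genes_path) || !file.exists(cells_path)) {
      stop("missing_sidecar: gene/cell id files not found", call. = FALSE)
    }
    gene_ids <- utils::read.table(genes_path, sep = "\t",
                                  stringsAsFactors = FALSE)[[1]]
    cell_ids <- utils::read.table(cells_path, sep = "\t",
                                  stringsAsFactors = FALSE)[[1]]
    if (!genes_as_rows) mat <- t(mat)
    if (nrow(mat) != length(gene_ids) || ncol(mat) != length(cell_ids)) {
      stop("id_dimension_mismatch: sidecar id counts do not match matrix ",
           "dimensions", call. = FALSE)
    }
    count_matrix(mat, gene_ids, cell_ids)
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (ncol(df) < 2) {
      stop("malformed_header: CSV needs gene ids plus at least one cell ",
           "column", call. = FALSE)
    }
    gene_ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(mat)) {
      storage.mode(mat) <- "double"
      if (anyNA(mat)) {
        stop("non_integer_count: non-numeric entries in CSV", call. = FALSE)
      }
    }
    count_matrix(mat, gene_ids, colnames(df)[-1])
  }
}

#' Write a count matrix as Matrix Market plus id sidecars
#'
#' @param x A [count_matrix()].
#' @param path Path for the `.mtx` file; `genes.tsv` and `barcodes.tsv` are
#'   written alongside it.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
  utils::write.table(data.frame(x$gene_ids),
                     file.path(dirname(path), "genes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(x$cell_ids),
                     file.path(dirname(path), "barcodes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cell-to-cluster assignment from a two-column TSV
#'
#' @param path TSV with columns `cell_id` and `cluster` (header optional; the
#'   first two columns are used).
#' @param data Optional [count_matrix()]; when given, the assignment is
#'   aligned to its cell order and must cover exactly its cells.
#' @return A [cluster_assignment()].
#' @export
read_clusters <- function(path, data = NULL) {
  if (!file.exists(path)) stop("missing_file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (identical(tolower(df[1, 1]), "cell_id")) df <- df[-1, , drop = FALSE]
  cl <- cluster_assignment(df[[1]], df[[2]])
  if (!is.null(data)) cl <- align_clusters(cl, data)
  cl
}

#' Write a cell-to-cluster assignment
#'
#' @param clusters A [cluster_assignment()].
#' @param path Output TSV path.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(
    data.frame(cell_id = clusters$cell_ids, cluster = clusters$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

ranking_columns <- c("cluster", "rank", "gene", "score", "p_value",
                     "p_adjusted", "lfc", "direction")

#' Construct a marker ranking
#'
#' A per-cluster ordered table of marker records. Rank 1 is the strongest
#' marker. Score-only selectors leave `p_value`/`p_adjusted` as `NA`, which
#' serializes to empty fields (not `"0"`): an absent p-value is distinct from
#' an underflowed one.
#'
#' @param records Data frame with columns `gene`, `score`, `p_value`,
#'   `p_adjusted`, `lfc` (`log2` fold-change) and optionally `log_p` (natural
#'   log p-value kept for underflow-free ordering). Row order is rank order.
#' @param cluster Cluster label the ranking refers to.
#' @param method_id Identifier of the selection method.
#' @param ranking_strategy Strategy used to order the records.
#' @return A data frame of class `marker_ranking` with a `rank` column and
#'   `direction` derived from the sign of `lfc`.
#' @export
marker_ranking <- function(records, cluster, method_id = "unknown",
                           ranking_strategy = "unknown") {
  if (nrow(records) > 0) {
    for (col in c("score", "p_value", "p_adjusted", "lfc")) {
      if (is.null(records[[col]])) records[[col]] <- NA_real_
    }
    bad <- !is.na(records$p_value) & !is.na(records$p_adjusted) &
      records$p_adjusted < records$p_value - 1e-12
    if (any(bad)) {
      stop("invalid_adjusted_p: adjusted p-values below raw p-values",
           call. = FALSE)
    }
    records$direction <- ifelse(!is.na(records$lfc) & records$lfc > 0,
                                "up", "down")
    records$rank <- seq_len(nrow(records))
  } else {
    records <- data.frame(gene = character(), score = numeric(),
                          p_value = numeric(), p_adjusted = numeric(),
                          lfc = numeric(), direction = character(),
                          rank = integer(), stringsAsFactors = FALSE)
  }
  records$cluster <- rep(as.character(cluster), nrow(records))
  out <- records[, c(ranking_columns,
                     intersect("log_p", names(records))), drop = FALSE]
  class(out) <- c("marker_ranking", "data.frame")
  attr(out, "method_id") <- method_id
  attr(out, "ranking_strategy") <- ranking_strategy
  out
}

#' Write a marker ranking to TSV
#'
#' Columns are `cluster, rank, gene, score, p_value, p_adjusted, lfc,
#' direction`. Missing p-values become empty cells.
#'
#' @param ranking A [marker_ranking()] (or several row-bound together).
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)[, ranking_columns, drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("unwritable_path: ", path, call. = FALSE)
  })
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Read a marker ranking written by [write_ranking()]
#'
#' @param path TSV path.
#' @return A `marker_ranking` data frame (rankings for several clusters are
#'   returned as one table).
#' @export
read_ranking <- function(path) {
  if (!file.exists(path)) stop("missing_file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = "", colClasses = c(
                            cluster = "character", rank = "integer",
                            gene = "character", score = "numeric",
                            p_value = "numeric", p_adjusted = "numeric",
                            lfc = "numeric", direction = "character"))
  class(df) <- c("marker_ranking", "data.frame")
  df
}
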