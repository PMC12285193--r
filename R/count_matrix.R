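#' Raw count matrix container
#'
#' Bundles a cells x genes matrix of raw integer counts with cell/gene
#' identifiers, per-cell library sizes (row sums), and optional categorical
#' per-cell annotations such as sample of origin or cell state. All model
#' fitting in this package consumes raw counts; normalization is only used
#' for marker scoring and gene filtering.
#'
#' @param counts numeric matrix (cells x genes) of non-negative integers;
#'   dense or a \code{Matrix} sparse matrix.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   rownames or \code{cell_1..N}).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   colnames or \code{gene_1..G}).
#' @param annotations optional data.frame of per-cell categorical columns.
#' @return An object of class \code{count_matrix} with fields \code{counts},
#'   \code{cell_ids}, \code{gene_ids}, \code{library_sizes},
#'   \code{annotations}.
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL,
                         annotations = NULL) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stop("counts must be non-negative")
  off <- which(abs(counts - round(counts)) > 1e-6)
  if (length(off) > 0) {
    ij <- arrayInd(off[1], dim(counts))
    stop(sprintf("counts must be integers; first offending entry at [%d, %d] = %g",
                 ij[1], ij[2], counts[off[1]]))
  }
  counts <- round(counts)
  N <- nrow(counts); G <- ncol(counts)
  if (is.null(cell_ids)) {
    cell_ids <- rownames(counts)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(N))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(G))
  }
  if (length(cell_ids) != N) stop("cell_ids length must match nrow(counts)")
  if (length(gene_ids) != G) stop("gene_ids length must match ncol(counts)")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    if (nrow(annotations) != N) stop("annotations must have one row per cell")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts,
                 cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids),
                 library_sizes = rowSums(counts),
                 annotations = annotations),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes\n",
              length(x$cell_ids), length(x$gene_ids)))
  cat(sprintf("  median library size: %.0f\n", stats::median(x$library_sizes)))
  if (!is.null(x$annotations)) {
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' @param x a \code{count_matrix}.
#' @param cells,genes integer, logical, or character index of cells / genes.
#' @return A \code{count_matrix} restricted to the requested cells and genes.
#' @export
subset_counts <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  ci <- if (is.null(cells)) seq_along(x$cell_ids) else cells
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else genes
  if (is.character(ci)) ci <- match(ci, x$cell_ids)
  if (is.character(gi)) gi <- match(gi, x$gene_ids)
  ann <- if (is.null(x$annotations)) NULL else x$annotations[ci, , drop = FALSE]
  count_matrix(x$counts[ci, gi, drop = FALSE],
               cell_ids = x$cell_ids[ci], gene_ids = x$gene_ids[gi],
               annotations = ann)
}

#' Re-index a count matrix to a reference gene order
#'
#' Gene matching at encoding time is strict; this utility aligns a count
#' matrix to the exact gene set and order of a fitted model before encoding.
#'
#' @param x a \code{count_matrix}.
#' @param gene_ids target gene identifiers; every id must exist in \code{x}.
#' @return A \code{count_matrix} with genes in the requested order.
#' @export
reindex_genes <- function(x, gene_ids) {
  stopifnot(inherits(x, "count_matrix"))
  missing <- setdiff(gene_ids, x$gene_ids)
  if (length(missing) > 0) {
    stop("genes absent from data: ", paste(utils::head(missing, 10), collapse = ", "))
  }
  subset_counts(x, genes = match(gene_ids, x$gene_ids))
}

#' Median-library-size normalized, log1p-transformed expression
#'
#' Used for marker scoring and differential-expression gene filtering; the
#' generative model itself always consumes raw counts.
#'
#' @param x a \code{count_matrix}.
#' @return A dense numeric matrix of log1p median-normalized expression.
#' @export
normalized_expression <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- x$library_sizes
  lib[lib == 0] <- 1
  med <- stats::median(x$library_sizes)
  log1p(x$counts / lib * med)
}
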