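# Readers and writers for the standard plain-text formats: Matrix Market
# triplets (with barcode/gene sidecar files), dense CSV with a gene header,
# TSV embeddings, and long-format pattern CSVs. Writers and readers
# round-trip exactly.

#' Read a count matrix
#'
#' \code{format = "mtx"} expects a Matrix Market coordinate file (1-based
#' indices, cells x genes) with \code{barcodes.tsv} and \code{genes.tsv}
#' next to it (or supplied explicitly). \code{format = "csv"} expects a
#' dense matrix with a header row of gene ids and cell ids in the first
#' column. An optional annotations CSV (first column cell_id) attaches
#' per-cell categorical columns.
#'
#' @param path matrix file path.
#' @param format "mtx" or "csv" (default: guessed from the extension).
#' @param barcodes,genes sidecar file paths for mtx input.
#' @param annotations optional CSV of per-cell annotations.
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv"),
                        barcodes = NULL, genes = NULL, annotations = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    if (is.null(genes)) genes <- file.path(dir, "genes.tsv")
    cell_ids <- readLines(barcodes)
    gene_ids <- readLines(genes)
    if (nrow(m) != length(cell_ids) || ncol(m) != length(gene_ids)) {
      stop(sprintf("dimension mismatch: matrix %d x %d vs %d barcodes, %d genes",
                   nrow(m), ncol(m), length(cell_ids), length(gene_ids)))
    }
    cm <- count_matrix(as.matrix(m), cell_ids = cell_ids, gene_ids = gene_ids)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    cell_ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    cm <- count_matrix(mat, cell_ids = cell_ids, gene_ids = colnames(mat))
  }
  if (!is.null(annotations)) {
    ann <- utils::read.csv(annotations, check.names = FALSE,
                           stringsAsFactors = FALSE)
    idx <- match(cm$cell_ids, as.character(ann[[1]]))
    if (anyNA(idx)) stop("annotation file is missing some cell ids")
    cm$annotations <- ann[idx, -1, drop = FALSE]
    rownames(cm$annotations) <- NULL
  }
  cm
}

#' Write a count matrix
#'
#' @param x a \code{\link{count_matrix}}.
#' @param path output path; \code{.mtx} writes a Matrix Market triplet with
#'   \code{barcodes.tsv}/\code{genes.tsv} sidecars, anything else a dense
#'   CSV.
#' @return The path, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
    writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  } else {
    df <- data.frame(cell_id = x$cell_ids, x$counts, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write / read an embedding as TSV
#'
#' Columns: cell_id, v1..v_dv, z1..z_L, plus any annotations.
#'
#' @param embedding a \code{decipher_embedding}.
#' @param path file path.
#' @return \code{read_embedding} returns a \code{decipher_embedding} (with
#'   an identity transform).
#' @export
write_embedding <- function(embedding, path) {
  v <- embedding$v; z <- embedding$z
  colnames(v) <- paste0("v", seq_len(ncol(v)))
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  df <- data.frame(cell_id = embedding$cell_ids, v, z, check.names = FALSE)
  if (!is.null(embedding$annotations)) df <- cbind(df, embedding$annotations)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  vcols <- grep("^v[0-9]+$", names(df))
  zcols <- grep("^z[0-9]+$", names(df))
  other <- setdiff(seq_along(df), c(1L, vcols, zcols))
  structure(list(v = as.matrix(df[, vcols, drop = FALSE]),
                 z = as.matrix(df[, zcols, drop = FALSE]),
                 transform = diag(length(vcols)),
                 cell_ids = as.character(df[[1]]),
                 annotations = if (length(other) > 0) df[, other, drop = FALSE] else NULL),
            class = "decipher_embedding")
}

#' Write gene patterns as long-format CSV
#'
#' Columns: gene, time, mean, q25, q50, q75, condition.
#'
#' @param patterns a \code{gene_pattern_set}.
#' @param path file path.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "gene_pattern_set"))
  df <- do.call(rbind, lapply(seq_along(patterns$genes), function(gi) {
    data.frame(gene = patterns$genes[gi], time = patterns$time_grid,
               mean = patterns$mean[gi, ], q25 = patterns$q25[gi, ],
               q50 = patterns$q50[gi, ], q75 = patterns$q75[gi, ],
               condition = if (is.null(patterns$condition)) NA
                           else patterns$condition)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format pattern CSV into a pattern matrix
#'
#' Expects columns gene, condition, time, value (or the output of
#' \code{\link{write_patterns}}, using its mean column). When conditions
#' were sampled on different time grids, every series is resampled onto a
#' shared uniform grid by linear interpolation.
#'
#' @param path file path.
#' @param n_grid grid size used when resampling is needed (default 100).
#' @return A \code{\link{pattern_matrix}}.
#' @export
read_patterns <- function(path, n_grid = 100L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"value" %in% names(df) && "mean" %in% names(df)) df$value <- df$mean
  genes <- unique(df$gene)
  conds <- unique(as.character(df$condition))
  grids <- lapply(conds, function(cc) {
    sort(unique(df$time[as.character(df$condition) == cc]))
  })
  shared <- all(vapply(grids, identical, logical(1), y = grids[[1]]))
  grid <- if (shared) grids[[1]] else {
    seq(0, max(df$time), length.out = n_grid)
  }
  vals <- array(NA_real_, c(length(genes), length(conds), length(grid)))
  for (ci in seq_along(conds)) {
    sub <- df[as.character(df$condition) == conds[ci], ]
    for (gi in seq_along(genes)) {
      s <- sub[sub$gene == genes[gi], ]
      vals[gi, ci, ] <- if (shared) {
        s$value[match(grid, s$time)]
      } else {
        stats::approx(s$time, s$value, xout = grid, rule = 2,
                      ties = "ordered")$y
      }
    }
  }
  pattern_matrix(vals, grid, gene_ids = genes, condition_ids = conds)
}

#' Select genes by per-cluster differential expression
#'
#' For each cluster, ranks genes by the Welch t-statistic of that cluster
#' against all other cells on log1p median-normalized expression, and
#' returns the union of each cluster's \code{top_n} genes with an optional
#' marker list, in the input gene order.
#'
#' @param data a \code{\link{count_matrix}}.
#' @param labels per-cell cluster labels (>= 2 clusters).
#' @param top_n genes kept per cluster (default 400).
#' @param markers optional genes always included.
#' @return Character vector of selected gene ids.
#' @export
filter_genes <- function(data, labels, top_n = 400L, markers = NULL) {
  stopifnot(inherits(data, "count_matrix"), top_n >= 1)
  labels <- as.character(labels)
  ks <- unique(labels)
  if (length(ks) < 2) stop("need at least 2 clusters")
  expr <- normalized_expression(data)
  selected <- character(0)
  for (k in ks) {
    a <- expr[labels == k, , drop = FALSE]
    b <- expr[labels != k, , drop = FALSE]
    na <- nrow(a); nb <- nrow(b)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
    tstat <- (ma - mb) / sqrt(pmax(va / na + vb / nb, 1e-12))
    top <- data$gene_ids[order(tstat, decreasing = TRUE)[seq_len(min(top_n, ncol(expr)))]]
    selected <- union(selected, top)
  }
  if (!is.null(markers)) selected <- union(selected, markers)
  data$gene_ids[data$gene_ids %in% selected]
}
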