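#' Library-size log-normalization
#'
#' Scales each cell's counts to a common total and log-transforms:
#' `value(g, c) = ln(1 + count(g, c) * scale_total / total(c))`. This is
#' the conventional "normalized and log-transformed" layer that percent
#' ranking and the cluster summaries operate on. Zeros map to zeros, so
#' the sparsity pattern is preserved.
#'
#' @param counts an `ExpressionMatrix` with layer `"raw_counts"`.
#' @param scale_total target total per cell; 10,000 by default (the de
#'   facto droplet convention). Natural log.
#' @return An `ExpressionMatrix` with layer `"lognorm"`.
#' @export
normalize_log <- function(counts, scale_total = 1e4) {
  stopifnot(is_expression_matrix(counts))
  if (counts$layer != "raw_counts")
    stop("normalize_log expects raw counts, got layer '", counts$layer, "'",
         call. = FALSE)
  if (!is.numeric(scale_total) || length(scale_total) != 1 || scale_total <= 0)
    stop("scale_total must be a positive scalar", call. = FALSE)
  m <- counts$values
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("data error: cells with zero total counts: ",
         paste(utils::head(colnames(m)[totals == 0], 10), collapse = ", "),
         call. = FALSE)
  # per-column scaling applied directly to the stored nonzeros
  m@x <- log1p(m@x * rep.int(scale_total / totals, diff(m@p)))
  expression_matrix(m, gene_ids = gene_ids(counts),
                    cell_ids = cell_ids(counts), layer = "lognorm")
}

#' Per-cluster expression summary
#'
#' The statistics behind dot plots and heat maps: for each cluster and
#' gene, the mean log-normalized expression (`mean_expr`), the fraction of
#' cells with nonzero expression (`pct_expr`), and the cluster means
#' z-scored per gene across clusters (`z_expr`, sample SD; genes with zero
#' variance across clusters get 0 so displays render).
#'
#' @param lognorm an `ExpressionMatrix` with layer `"lognorm"`.
#' @param cells a `CellTable` covering every cell in `lognorm`.
#' @param genes gene identifiers to summarize (all genes by default).
#' @return A `ClusterSummary`: list of three cluster-by-gene matrices.
#' @export
cluster_summary <- function(lognorm, cells, genes = gene_ids(lognorm)) {
  stopifnot(is_expression_matrix(lognorm), inherits(cells, "CellTable"))
  if (lognorm$layer != "lognorm")
    stop("cluster_summary expects log-normalized values", call. = FALSE)
  genes <- as.character(genes)
  missing_genes <- setdiff(genes, gene_ids(lognorm))
  if (length(missing_genes))
    stop("data error: unknown gene(s): ",
         paste(utils::head(missing_genes, 10), collapse = ", "),
         call. = FALSE)
  idx <- match(cell_ids(lognorm), cells$barcode)
  if (anyNA(idx))
    stop("data error: cells missing from CellTable: ",
         paste(utils::head(cell_ids(lognorm)[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  cl <- factor(cells$cluster[idx])
  sub <- Matrix::t(lognorm$values[genes, , drop = FALSE])  # cells x genes
  n_cl <- as.vector(table(cl))
  group <- Matrix::sparseMatrix(i = as.integer(cl), j = seq_along(cl), x = 1,
                                dims = c(nlevels(cl), length(cl)))
  mean_expr <- as.matrix(group %*% sub) / n_cl
  pct_expr <- as.matrix(group %*% ((sub > 0) * 1)) / n_cl
  dimnames(mean_expr) <- dimnames(pct_expr) <- list(levels(cl), genes)
  z_expr <- apply(mean_expr, 2, function(v) {
    s <- stats::sd(v)
    if (length(v) < 2 || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  z_expr <- matrix(z_expr, nrow = nlevels(cl),
                   dimnames = list(levels(cl), genes))
  structure(list(mean_expr = mean_expr, pct_expr = pct_expr, z_expr = z_expr),
            class = "ClusterSummary")
}

#' @export
print.ClusterSummary <- function(x, ...) {
  cat(sprintf("ClusterSummary: %d clusters x %d genes\n",
              nrow(x$mean_expr), ncol(x$mean_expr)))
  invisible(x)
}

#' Fraction of cells expressing each gene, per cluster
#'
#' Standalone accessor for the dot-size statistic: a cell "expresses" a
#' gene when its normalized value is greater than zero (equivalently, raw
#' count of at least one).
#'
#' @inheritParams cluster_summary
#' @return cluster-by-gene matrix of fractions in `[0, 1]`.
#' @export
percent_expressing <- function(lognorm, cells, genes = gene_ids(lognorm)) {
  cluster_summary(lognorm, cells, genes)$pct_expr
}
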