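#' Construct an expression matrix
#'
#' The central container of the package: a sparse genes-by-cells matrix of
#' UMI counts or log-normalized values, tagged with the layer it holds so
#' downstream operations can refuse the wrong input (percent ranks are
#' defined on the log-normalized layer).
#'
#' @param values numeric matrix or `Matrix` sparse matrix, genes as rows,
#'   cells as columns; all entries must be non-negative.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell barcodes (columns).
#' @param layer either `"raw_counts"` or `"lognorm"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              layer = c("raw_counts", "lognorm")) {
  layer <- match.arg(layer)
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  values <- Matrix::drop0(values)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers; collapse before construction ",
         "(read_mtx_triplet() does this automatically)", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell barcodes", call. = FALSE)
  if (length(values@x) && min(values@x) < 0)
    stop("expression values must be non-negative", call. = FALSE)
  if (layer == "raw_counts" && length(values@x) &&
      any(abs(values@x - round(values@x)) > 1e-8))
    stop("raw counts must be integers", call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, layer = layer), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d cells (%.1f%% nonzero)\n",
              x$layer, nrow(x$values), ncol(x$values),
              100 * length(x$values@x) / max(1, prod(dim(x$values)))))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
cell_ids <- function(x) colnames(x$values)

#' @rdname expression_matrix
#' @export
layer_tag <- function(x) x$layer

is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

#' Construct a gene-set collection
#'
#' A named list of gene modules (cell cycle, disease gene lists, planted
#' simulation modules, ...). Within-set duplicates are removed keeping the
#' first occurrence; empty sets are rejected.
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled from `""`.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a non-empty named list", call. = FALSE)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names", call. = FALSE)
  sets <- lapply(sets, function(g) {
    g <- as.character(g)
    g <- g[!duplicated(g)]
    if (!length(g)) stop("empty gene set", call. = FALSE)
    g
  })
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %s)\n", length(x$sets),
              paste(vapply(x$sets, length, 0L), collapse = ", ")))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
names.GeneSetCollection <- function(x) names(x$sets)

#' Construct a per-cell metadata table
#'
#' Holds the strata used by the comparison machinery: cluster label,
#' genotype (e.g. WT vs KO) and developmental stage. Missing columns are
#' filled with a single `"unassigned"` level so group operations always
#' have something to stratify on.
#'
#' @param barcode character vector of unique cell barcodes.
#' @param cluster,genotype,stage categorical labels, recycled from
#'   `"unassigned"` when absent.
#' @return A `data.frame` with class `CellTable`.
#' @export
cell_table <- function(barcode, cluster = NULL, genotype = NULL,
                       stage = NULL) {
  barcode <- as.character(barcode)
  if (anyDuplicated(barcode))
    stop("duplicated barcodes: ",
         paste(unique(barcode[duplicated(barcode)]), collapse = ", "),
         call. = FALSE)
  fill <- function(v) {
    if (is.null(v)) rep("unassigned", length(barcode))
    else rep_len(as.character(v), length(barcode))
  }
  out <- data.frame(barcode = barcode, cluster = fill(cluster),
                    genotype = fill(genotype), stage = fill(stage),
                    stringsAsFactors = FALSE)
  class(out) <- c("CellTable", "data.frame")
  out
}

#' Construct a score table
#'
#' Cells-by-sets matrix of scGPS values together with `genes_used`, the
#' per-set count m of module genes actually found in the expression matrix
#' (m changes the statistic, so it is carried alongside the scores).
#'
#' @param scores numeric matrix, cells as rows, gene sets as columns; every
#'   entry must lie in `[0, 1]`.
#' @param genes_used named integer vector, one positive entry per set
#'   (`NA` only for tables re-read from disk, where m is recorded in the
#'   run log rather than the table itself).
#' @return An object of class `ScoreTable`.
#' @export
score_table <- function(scores, genes_used) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) && nrow(scores) > 0 || is.null(colnames(scores)))
    stop("scores must carry cell and set names", call. = FALSE)
  if (length(scores) && (min(scores) < -1e-12 || max(scores) > 1 + 1e-12))
    stop("scores must lie in [0, 1]", call. = FALSE)
  genes_used <- as.integer(genes_used[colnames(scores)])
  names(genes_used) <- colnames(scores)
  if (any(genes_used < 1L, na.rm = TRUE))
    stop("genes_used must be a positive count for every set", call. = FALSE)
  structure(list(scores = scores, cell_ids = rownames(scores),
                 set_names = colnames(scores), genes_used = genes_used),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat(sprintf("ScoreTable: %d cells x %d sets (m = %s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(x$genes_used, collapse = ", ")))
  invisible(x)
}
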