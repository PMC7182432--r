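#' Read a 10x-style Matrix Market triplet trio
#'
#' Ingests the CellRanger-style output layout: a Matrix Market coordinate
#' file plus one-record-per-line gene and barcode annotation files. Only
#' the first tab-separated field of each annotation line is used as the
#' identifier (10x genes.tsv carries id and symbol columns).
#'
#' Rows sharing a gene identifier are collapsed by summation with a
#' warning: the score is gene-identifier driven, so one identifier must map
#' to one row, and summing is deterministic and order-independent.
#'
#' @param matrix_path Matrix Market coordinate file (genes x cells).
#' @param genes_path,barcodes_path annotation files whose line counts must
#'   match the matrix header dimensions.
#' @param case_insensitive collapse/matching on upper-cased identifiers.
#'   Off by default: matching is exact and case-sensitive.
#' @return An [expression_matrix()] with layer `"raw_counts"`.
#' @export
read_mtx_triplet <- function(matrix_path, genes_path, barcodes_path,
                             case_insensitive = FALSE) {
  m <- Matrix::readMM(matrix_path)
  genes <- read_id_column(genes_path)
  barcodes <- read_id_column(barcodes_path)
  if (length(genes) != nrow(m))
    stop(sprintf("format error: %d genes listed but matrix header declares %d rows",
                 length(genes), nrow(m)), call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop(sprintf("format error: %d barcodes listed but matrix header declares %d columns",
                 length(barcodes), ncol(m)), call. = FALSE)
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  if (length(m@x)) {
    if (min(m@x) < 0)
      stop("format error: negative entries in count matrix", call. = FALSE)
    if (any(abs(m@x - round(m@x)) > 1e-8))
      stop("format error: non-integer entries in count matrix", call. = FALSE)
  }
  key <- if (case_insensitive) toupper(genes) else genes
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    warning(sprintf("collapsing %d duplicated gene identifier(s) by summation: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")),
            call. = FALSE)
    fk <- factor(key, levels = unique(key))
    # sparse aggregation matrix: summing rows preserves each cell's total
    agg <- Matrix::sparseMatrix(i = as.integer(fk), j = seq_along(key),
                                x = 1, dims = c(nlevels(fk), length(key)))
    m <- agg %*% m
    genes <- levels(fk)
  }
  expression_matrix(m, gene_ids = genes, cell_ids = barcodes,
                    layer = "raw_counts")
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
}

#' Write an expression matrix as a Matrix Market triplet trio
#'
#' Inverse of [read_mtx_triplet()]: writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` under `dir`. Values are written at full precision so a
#' write-then-read round trip is the identity.
#'
#' @param x an `ExpressionMatrix`.
#' @param dir output directory, created if needed.
#' @return Invisibly, the three file paths.
#' @export
write_mtx_triplet <- function(x, dir) {
  stopifnot(is_expression_matrix(x))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  tm <- methods::as(x$values, "TsparseMatrix")
  is_int <- x$layer == "raw_counts"
  con <- file(paths[1], "w")
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general",
                       if (is_int) "integer" else "real"),
               sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x))), con)
  vals <- if (is_int) sprintf("%d", as.integer(round(tm@x)))
          else sprintf("%.17g", tm@x)
  writeLines(sprintf("%d %d %s", tm@i + 1L, tm@j + 1L, vals), con)
  close(con)
  writeLines(gene_ids(x), paths[2])
  writeLines(cell_ids(x), paths[3])
  invisible(paths)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a line are dropped keeping the first occurrence; empty
#' lines are skipped.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("format error: empty GMT file", call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 3L))
    stop(sprintf("format error: GMT line %d has %d field(s); need name, description and at least one gene",
                 keep[which(nf < 3L)[1]], nf[nf < 3L][1]), call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Write a gene-set collection in GMT format
#'
#' @param collection a `GeneSetCollection`.
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  writeLines(vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a per-cell metadata table
#'
#' Delimited text with a header; a `barcode` column is required, while
#' `cluster`, `genotype` and `stage` are optional and filled with a single
#' `"unassigned"` level when absent.
#'
#' @param path TSV (default) or CSV file; the separator is taken from the
#'   file extension.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
  if (!"barcode" %in% names(df))
    stop("data error: no 'barcode' column in ", path, call. = FALSE)
  grab <- function(col) if (col %in% names(df)) df[[col]] else NULL
  cell_table(df$barcode, cluster = grab("cluster"),
             genotype = grab("genotype"), stage = grab("stage"))
}

#' Write a per-cell metadata table as TSV
#'
#' @param cells a `CellTable`.
#' @param path output file.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.table(as.data.frame(cells), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a score table as TSV
#'
#' One row per cell, one column per gene set, full `%.17g` precision so
#' that [read_scores()] reproduces the scores bit-exactly. The per-set
#' gene counts m are not part of the table; pipeline runs record them in
#' `run_log.json` because m changes the statistic.
#'
#' @param x a `ScoreTable`.
#' @param path output file.
#' @export
write_scores <- function(x, path) {
  stopifnot(inherits(x, "ScoreTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cell", x$set_names), collapse = "\t"), con)
  if (nrow(x$scores))
    writeLines(paste(x$cell_ids,
                     apply(matrix(sprintf("%.17g", x$scores),
                                  nrow = nrow(x$scores)), 1, paste,
                           collapse = "\t"),
                     sep = "\t"), con)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path TSV produced by [write_scores()].
#' @param genes_used optional named integer vector of per-set gene counts
#'   (e.g. recovered from a pipeline run log); left `NA` when unknown.
#' @return A [score_table()].
#' @export
read_scores <- function(path, genes_used = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "cell"))
    stop("format error: not a score table file", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sets <- header[-1]
  gu <- stats::setNames(rep(NA_integer_, length(sets)), sets)
  if (!is.null(genes_used)) gu[names(genes_used)] <- as.integer(genes_used)
  body <- lines[-1]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    cells <- vapply(parts, `[[`, "", 1L)
    scores <- t(vapply(parts, function(p) as.numeric(p[-1]),
                       numeric(length(sets))))
    if (length(sets) == 1L) scores <- matrix(scores, ncol = 1L)
  } else {
    cells <- character(0)
    scores <- matrix(numeric(0), nrow = 0, ncol = length(sets))
  }
  dimnames(scores) <- list(cells, sets)
  score_table(scores, gu)
}
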