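write_mtx_fixture <- function(dir, header, entries, genes, barcodes,
                              field = "integer") {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(sprintf("%%%%MatrixMarket matrix coordinate %s general", field),
               header, entries), file.path(dir, "matrix.mtx"))
  writeLines(genes, file.path(dir, "genes.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  file.path(dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
}

test_that("triplet files expand to the declared coordinates", {
  p <- write_mtx_fixture(withr::local_tempdir(), "3 2 2",
                         c("1 1 5", "3 2 2"),
                         c("A", "B", "C"), c("bc1", "bc2"))
  em <- read_mtx_triplet(p[1], p[2], p[3])
  expect_equal(dense_values(em),
               matrix(c(5, 0, 0, 0, 0, 2), nrow = 3, byrow = TRUE,
                      dimnames = list(c("A", "B", "C"), c("bc1", "bc2"))))
  expect_identical(layer_tag(em), "raw_counts")
})

test_that("duplicate gene rows are collapsed by summation with a warning", {
  p <- write_mtx_fixture(withr::local_tempdir(), "3 2 4",
                         c("1 1 5", "2 1 1", "3 1 2", "3 2 7"),
                         c("A", "B", "A"), c("bc1", "bc2"))
  expect_warning(em <- read_mtx_triplet(p[1], p[2], p[3]), "collapsing")
  expect_identical(gene_ids(em), c("A", "B"))
  expect_equal(dense_values(em)["A", ], c(bc1 = 7, bc2 = 7))
  # per-cell totals survive the collapse
  expect_equal(unname(Matrix::colSums(em$values)), c(8, 7))
})

test_that("annotation/header mismatches and bad entries are format errors", {
  d <- withr::local_tempdir()
  p <- write_mtx_fixture(d, "3 2 1", "1 1 5",
                         c("A", "B", "C"), c("bc1", "bc2", "bc3"))
  expect_error(read_mtx_triplet(p[1], p[2], p[3]), "3 barcodes.*2 columns")
  p <- write_mtx_fixture(d, "3 2 1", "1 1 5", c("A", "B"), c("bc1", "bc2"))
  expect_error(read_mtx_triplet(p[1], p[2], p[3]), "2 genes.*3 rows")
  p <- write_mtx_fixture(d, "3 2 1", "1 1 -4", c("A", "B", "C"),
                         c("bc1", "bc2"), field = "real")
  expect_error(read_mtx_triplet(p[1], p[2], p[3]), "negative")
  p <- write_mtx_fixture(d, "3 2 1", "1 1 2.5", c("A", "B", "C"),
                         c("bc1", "bc2"), field = "real")
  expect_error(read_mtx_triplet(p[1], p[2], p[3]), "non-integer")
})

test_that("mtx write-then-read is the identity on random sparse fixtures", {
  set.seed(41)
  for (rep in 1:5) {
    em <- random_counts_fixture(sample(5:40, 1), sample(3:30, 1))
    d <- withr::local_tempdir()
    write_mtx_triplet(em, d)
    back <- read_mtx_triplet(file.path(d, "matrix.mtx"),
                             file.path(d, "genes.tsv"),
                             file.path(d, "barcodes.tsv"))
    expect_identical(gene_ids(back), gene_ids(em))
    expect_identical(cell_ids(back), cell_ids(em))
    expect_equal(dense_values(back), dense_values(em))
  }
})

test_that("GMT lines parse with first-occurrence dedup and order preserved", {
  f <- withr::local_tempfile(lines = c("S1\tdesc\tA\tB\tA",
                                       "",
                                       "S2\tother\tC"))
  gsc <- read_gmt(f)
  expect_identical(names(gsc), c("S1", "S2"))
  expect_identical(gsc$sets$S1, c("A", "B"))
  expect_identical(gsc$sets$S2, "C")
})

test_that("GMT lines with fewer than three fields fail naming the line", {
  f <- withr::local_tempfile(lines = c("S1\tdesc\tA", "S2\tdesc"))
  expect_error(read_gmt(f), "line 2")
})

test_that("GMT write-then-read preserves the collection", {
  gsc <- gene_set_collection(list(alpha = c("A", "B", "C"), beta = "D"),
                             c("first", "second"))
  f <- withr::local_tempfile()
  write_gmt(gsc, f)
  back <- read_gmt(f)
  expect_identical(back$sets, gsc$sets)
  expect_identical(unname(back$descriptions), c("first", "second"))
})

test_that("cell tables fill missing columns and reject duplicate barcodes", {
  f <- withr::local_tempfile(lines = c("barcode\tcluster",
                                       "bc1\tc1", "bc2\tc1", "bc3\tc2"))
  ct <- read_cell_table(f)
  expect_s3_class(ct, "CellTable")
  expect_identical(ct$genotype, rep("unassigned", 3))
  expect_identical(ct$cluster, c("c1", "c1", "c2"))

  f2 <- withr::local_tempfile(lines = c("barcode", "bc1", "bc1"))
  expect_error(read_cell_table(f2), "bc1")

  f3 <- withr::local_tempfile(lines = "barcode\tcluster")
  expect_identical(nrow(read_cell_table(f3)), 0L)
})

test_that("score tables round trip bit-exactly and degenerate shapes hold", {
  set.seed(42)
  sc <- matrix(runif(10), 5, 2,
               dimnames = list(sprintf("bc%d", 1:5), c("s1", "s2")))
  st <- score_table(sc, c(s1 = 3L, s2 = 8L))
  f <- withr::local_tempfile()
  write_scores(st, f)
  back <- read_scores(f, genes_used = st$genes_used)
  expect_identical(back$scores, st$scores)
  expect_identical(back$genes_used, st$genes_used)

  st1 <- score_table(sc[1:2, 1, drop = FALSE], c(s1 = 3L))
  write_scores(st1, f)
  expect_length(readLines(f), 3L)  # header + one row per cell

  empty <- score_table(matrix(numeric(0), 0, 1,
                              dimnames = list(NULL, "s1")), c(s1 = 1L))
  write_scores(empty, f)
  expect_length(readLines(f), 1L)
  expect_identical(nrow(read_scores(f)$scores), 0L)
})

test_that("constructors enforce the container invariants", {
  m <- matrix(1:4, 2, 2)
  expect_error(expression_matrix(m, c("A", "A"), c("b1", "b2")), "duplicate")
  expect_error(expression_matrix(-m, c("A", "B"), c("b1", "b2")),
               "non-negative")
  expect_error(expression_matrix(m / 3, c("A", "B"), c("b1", "b2")),
               "integer")
  expect_error(gene_set_collection(list(a = character(0))), "empty")
  expect_error(score_table(matrix(2, 1, 1, dimnames = list("b", "s")),
                           c(s = 1L)), "\\[0, 1\\]")
})
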