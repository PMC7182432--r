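#' Score an expression matrix against a gene-set collection, with outputs
#'
#' The scoring stage as a run: normalizes raw counts if needed, computes
#' scGPS for every set, writes `scores.tsv` and a `run_log.json` that
#' records m per set, every dropped set and gene, and all parameter
#' values. Warnings raised during scoring (dropped genes or sets) are
#' captured into the log rather than lost, because m changes the
#' statistic. Files are written atomically (temp file + rename), so a
#' failed run leaves no partial output.
#'
#' @param counts an `ExpressionMatrix` (raw counts or lognorm).
#' @param collection a `GeneSetCollection`.
#' @param out_dir output directory, created if needed.
#' @param scale_total passed to [normalize_log()] when `counts` is raw.
#' @param missing_as_zero passed to [score_collection()].
#' @return The `ScoreTable`, invisibly.
#' @export
run_score <- function(counts, collection, out_dir, scale_total = 1e4,
                      missing_as_zero = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lognorm <- if (layer_tag(counts) == "raw_counts")
    normalize_log(counts, scale_total = scale_total) else counts
  notes <- character(0)
  st <- withCallingHandlers(
    score_collection(lognorm, collection, missing_as_zero = missing_as_zero),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_atomic(function(p) write_scores(st, p), file.path(out_dir, "scores.tsv"))
  log <- list(stage = "score",
              package_version = as.character(utils::packageVersion("scgps")),
              n_genes = nrow(lognorm$values), n_cells = ncol(lognorm$values),
              scale_total = scale_total, missing_as_zero = missing_as_zero,
              genes_used = as.list(st$genes_used),
              dropped_sets = as.list(attr(st, "dropped_sets")),
              warnings = as.list(notes))
  write_atomic(function(p) jsonlite::write_json(log, p, auto_unbox = TRUE,
                                                pretty = TRUE),
               file.path(out_dir, "run_log.json"))
  invisible(st)
}

#' Run the full synthetic pipeline: simulate, score, compare, markers
#'
#' Deterministic end-to-end run from a [sim_config()]: simulates counts,
#' writes them as a Matrix Market trio under `counts/` together with the
#' cell table and the true gene sets as GMT, scores the planted modules,
#' compares scores across clusters (and genotypes, when the config splits
#' them), and scans for markers. Every output is a pure function of the
#' config, so re-running reproduces each file byte for byte.
#'
#' Output layout under `out_dir`: `counts/` (matrix.mtx, genes.tsv,
#' barcodes.tsv), `cells.tsv`, `gene_sets.gmt`, `scores.tsv`,
#' `comparisons.tsv`, `markers.tsv`, `run_log.json`.
#'
#' @param config a `SimConfig` or the path of a YAML/JSON config file.
#' @param out_dir output directory, created if needed.
#' @param scale_total normalization target total.
#' @param min_pct,min_effect marker-scan pre-filters, see [find_markers()].
#' @param exact_threshold rank-sum exact-path threshold.
#' @return list with `scores`, `comparisons`, `markers`, `truth`,
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir, scale_total = 1e4,
                         min_pct = 0.1, min_effect = 0.25,
                         exact_threshold = 16) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "SimConfig"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  sim <- simulate_counts(config)
  sets <- make_true_gene_sets(sim$truth)
  write_mtx_triplet(sim$counts, file.path(out_dir, "counts"))
  write_atomic(function(p) write_cell_table(sim$cells, p),
               file.path(out_dir, "cells.tsv"))
  write_atomic(function(p) write_gmt(sets, p),
               file.path(out_dir, "gene_sets.gmt"))

  lognorm <- normalize_log(sim$counts, scale_total = scale_total)
  st <- score_collection(lognorm, sets)
  write_atomic(function(p) write_scores(st, p),
               file.path(out_dir, "scores.tsv"))

  comparisons <- compare_scores(st, sim$cells,
                                design = "by_cluster_one_vs_rest",
                                exact_threshold = exact_threshold)
  if (length(unique(sim$cells$genotype)) == 2) {
    comparisons <- rbind(comparisons,
                         compare_scores(st, sim$cells,
                                        design = "by_genotype_within_cluster",
                                        exact_threshold = exact_threshold))
  }
  write_atomic(function(p) write_comparisons(comparisons, p),
               file.path(out_dir, "comparisons.tsv"))

  markers <- find_markers(lognorm, sim$cells, min_pct = min_pct,
                          min_effect = min_effect,
                          exact_threshold = exact_threshold)
  write_atomic(function(p) write_comparisons(markers, p),
               file.path(out_dir, "markers.tsv"))

  log <- list(stage = "pipeline",
              package_version = as.character(utils::packageVersion("scgps")),
              seed = config$seed,
              config = unclass(config),
              scale_total = scale_total, min_pct = min_pct,
              min_effect = min_effect, exact_threshold = exact_threshold,
              genes_used = as.list(st$genes_used),
              dropped_sets = as.list(attr(st, "dropped_sets")),
              n_comparisons = nrow(comparisons),
              n_marker_rows = nrow(markers))
  write_atomic(function(p) jsonlite::write_json(log, p, auto_unbox = TRUE,
                                                pretty = TRUE),
               file.path(out_dir, "run_log.json"))
  invisible(list(scores = st, comparisons = comparisons, markers = markers,
                 truth = sim$truth))
}

# write via temp file in the same directory, then rename: no partial files
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("I/O error: could not write ", path, call. = FALSE)
  ok <- TRUE
  invisible(path)
}
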