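#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-group location test used for marker detection and for comparing
#' scores between clusters or genotypes. The p-value comes from exact
#' enumeration of the permutation distribution when the combined sample is
#' small (`n_a + n_b <= exact_threshold`) and tie-free, and otherwise from
#' the tie-corrected normal approximation with continuity correction.
#' A fully tied comparison (zero rank variance) has p = 1 by symmetry.
#'
#' @param values_a,values_b numeric vectors, each non-empty.
#' @param exact_threshold largest combined sample size for the exact path;
#'   16 by default.
#' @param alternative `"two.sided"` (default, matching two-tailed use
#'   throughout), `"greater"` or `"less"` (a is the first sample).
#' @return list with `statistic` (Mann-Whitney U for sample a), `p_value`,
#'   `n_a`, `n_b`, and `exact` (logical, which path was taken).
#' @export
rank_sum_test <- function(values_a, values_b, exact_threshold = 16,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (!length(values_a) || !length(values_b))
    stop("data error: both groups must be non-empty", call. = FALSE)
  if (anyNA(values_a) || anyNA(values_b))
    stop("data error: NA values in rank-sum input", call. = FALSE)
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- !ties && n <= exact_threshold
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = alternative,
                       exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # all observations tied: rank variance is zero
  list(statistic = unname(wt$statistic), p_value = min(p, 1),
       n_a = length(values_a), n_b = length(values_b), exact = exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: sorted p-values are multiplied by
#' m/i, monotonicity is enforced from the largest down, and results are
#' capped at 1 and returned in the original order. Inputs outside `[0, 1]`
#' are rejected.
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("data error: p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Compare gene-set scores between cell groups
#'
#' Runs the rank-sum test on scGPS scores under one of two designs:
#' `"by_cluster_one_vs_rest"` (each cluster against all other cells, the
#' design behind "scores are higher in cluster X" statements) or
#' `"by_genotype_within_cluster"` (e.g. WT vs mutant inside each cluster,
#' the per-state two-group comparison). The effect is the difference of
#' group mean scores (scores share the `[0, 1]` scale); BH adjustment is
#' applied within each gene set across its contrasts. Contrasts with an
#' empty group are skipped with a warning.
#'
#' @param scores a `ScoreTable`.
#' @param cells a `CellTable` covering every scored cell.
#' @param design comparison design, see above.
#' @param exact_threshold passed to [rank_sum_test()].
#' @param alternative passed to [rank_sum_test()]; two-sided by default.
#' @return data.frame with columns unit, group_a, group_b, n_a, n_b,
#'   statistic, effect, p_value, p_adjusted; deterministic row order
#'   (sets in table order, then groups in level order).
#' @export
compare_scores <- function(scores, cells,
                           design = c("by_cluster_one_vs_rest",
                                      "by_genotype_within_cluster"),
                           exact_threshold = 16,
                           alternative = "two.sided") {
  design <- match.arg(design)
  stopifnot(inherits(scores, "ScoreTable"), inherits(cells, "CellTable"))
  idx <- match(scores$cell_ids, cells$barcode)
  if (anyNA(idx))
    stop("data error: scored cells missing from CellTable: ",
         paste(utils::head(scores$cell_ids[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  cluster <- cells$cluster[idx]
  genotype <- cells$genotype[idx]
  contrasts <- list()
  if (design == "by_cluster_one_vs_rest") {
    lev <- sort(unique(cluster))
    if (length(lev) < 2)
      stop("data error: one-vs-rest needs at least 2 clusters", call. = FALSE)
    for (cl in lev)
      contrasts[[length(contrasts) + 1L]] <-
        list(a = which(cluster == cl), b = which(cluster != cl),
             group_a = cl, group_b = "rest")
  } else {
    gl <- sort(unique(genotype))
    if (length(gl) != 2)
      stop("data error: genotype design needs exactly 2 genotype levels, got ",
           length(gl), call. = FALSE)
    for (cl in sort(unique(cluster)))
      contrasts[[length(contrasts) + 1L]] <-
        list(a = which(cluster == cl & genotype == gl[1]),
             b = which(cluster == cl & genotype == gl[2]),
             group_a = paste(cl, gl[1], sep = ":"),
             group_b = paste(cl, gl[2], sep = ":"))
  }
  keep <- vapply(contrasts, function(ct) length(ct$a) > 0 && length(ct$b) > 0,
                 TRUE)
  if (any(!keep))
    warning("skipping contrast(s) with an empty group: ",
            paste(vapply(contrasts[!keep], function(ct)
              paste(ct$group_a, "vs", ct$group_b), ""), collapse = "; "),
            call. = FALSE)
  contrasts <- contrasts[keep]
  if (!length(contrasts))
    stop("data error: no testable contrast under design ", design,
         call. = FALSE)
  out <- do.call(rbind, lapply(scores$set_names, function(s) {
    v <- scores$scores[, s]
    rows <- do.call(rbind, lapply(contrasts, function(ct) {
      rs <- rank_sum_test(v[ct$a], v[ct$b], exact_threshold = exact_threshold,
                          alternative = alternative)
      data.frame(unit = s, group_a = ct$group_a, group_b = ct$group_b,
                 n_a = rs$n_a, n_b = rs$n_b, statistic = rs$statistic,
                 effect = mean(v[ct$a]) - mean(v[ct$b]),
                 p_value = rs$p_value, stringsAsFactors = FALSE)
    }))
    rows$p_adjusted <- bh_adjust(rows$p_value)
    rows
  }))
  rownames(out) <- NULL
  out
}

#' One-vs-rest marker detection
#'
#' For each cluster, tests every gene passing the pre-filters with the
#' rank-sum test against all remaining cells. Pre-filters follow the
#' standard marker-scan convention: the gene must be expressed in at least
#' `min_pct` of either group, and the absolute log-fold-change of group
#' mean de-logged expression, `ln((mean(expm1(a)) + 1) /
#' (mean(expm1(b)) + 1))`, must reach `min_effect`. BH adjustment is
#' applied across the genes tested within each cluster; results are sorted
#' by p-value, then by decreasing effect.
#'
#' @param lognorm an `ExpressionMatrix` with layer `"lognorm"`.
#' @param cells a `CellTable` with at least 2 cluster levels.
#' @param min_pct minimum expressing fraction in either group (default 0.1).
#' @param min_effect minimum absolute log-fold-change (default 0.25).
#' @param exact_threshold passed to [rank_sum_test()].
#' @return data.frame in the [compare_scores()] column layout, `unit`
#'   being the gene.
#' @export
find_markers <- function(lognorm, cells, min_pct = 0.1, min_effect = 0.25,
                         exact_threshold = 16) {
  stopifnot(is_expression_matrix(lognorm), inherits(cells, "CellTable"))
  if (lognorm$layer != "lognorm")
    stop("find_markers expects log-normalized values", call. = FALSE)
  idx <- match(cell_ids(lognorm), cells$barcode)
  if (anyNA(idx))
    stop("data error: cells missing from CellTable", call. = FALSE)
  cluster <- cells$cluster[idx]
  lev <- sort(unique(cluster))
  if (length(lev) < 2)
    stop("data error: marker detection needs at least 2 clusters",
         call. = FALSE)
  m <- lognorm$values
  genes <- rownames(m)
  out <- do.call(rbind, lapply(lev, function(cl) {
    a <- which(cluster == cl)
    b <- which(cluster != cl)
    ma <- m[, a, drop = FALSE]
    mb <- m[, b, drop = FALSE]
    pct_a <- Matrix::rowSums(ma > 0) / length(a)
    pct_b <- Matrix::rowSums(mb > 0) / length(b)
    lfc <- log((Matrix::rowSums(expm1_sparse(ma)) / length(a) + 1) /
               (Matrix::rowSums(expm1_sparse(mb)) / length(b) + 1))
    test_me <- which(pmax(pct_a, pct_b) >= min_pct & abs(lfc) >= min_effect)
    if (!length(test_me)) return(NULL)
    rows <- do.call(rbind, lapply(test_me, function(g) {
      va <- as.numeric(m[g, a])
      vb <- as.numeric(m[g, b])
      rs <- rank_sum_test(va, vb, exact_threshold = exact_threshold)
      data.frame(unit = genes[g], group_a = cl, group_b = "rest",
                 n_a = rs$n_a, n_b = rs$n_b, statistic = rs$statistic,
                 effect = lfc[g], p_value = rs$p_value,
                 stringsAsFactors = FALSE)
    }))
    rows$p_adjusted <- bh_adjust(rows$p_value)
    rows[order(rows$p_value, -rows$effect), ]
  }))
  rownames(out) <- NULL
  out
}

# expm1 applied to the stored nonzeros only (expm1(0) = 0)
expm1_sparse <- function(m) {
  m@x <- expm1(m@x)
  m
}

#' Write comparison or marker results as TSV
#'
#' Fixed column order: unit, group_a, group_b, n_a, n_b, statistic,
#' effect, p_value, p_adjusted.
#'
#' @param results data.frame from [compare_scores()] or [find_markers()].
#' @param path output file.
#' @export
write_comparisons <- function(results, path) {
  cols <- c("unit", "group_a", "group_b", "n_a", "n_b", "statistic",
            "effect", "p_value", "p_adjusted")
  stopifnot(all(cols %in% names(results)))
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
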