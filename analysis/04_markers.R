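#!/usr/bin/env Rscript
# Stage 4: one-vs-rest marker detection, checked against the planted truth.
#
# Every gene expressed in at least 10% of either group with |logFC| >= 0.25
# is rank-sum tested per cluster; BH adjustment within each cluster. The
# top markers of each target cluster should be dominated by its planted
# module genes. Writes results/markers.tsv.

suppressPackageStartupMessages(library(scgps))

counts <- read_mtx_triplet("results/sim/counts/matrix.mtx",
                           "results/sim/counts/genes.tsv",
                           "results/sim/counts/barcodes.tsv")
cells <- read_cell_table("results/sim/cells.tsv")
sets <- read_gmt("results/sim/gene_sets.gmt")

markers <- find_markers(normalize_log(counts), cells)
write_comparisons(markers, "results/markers.tsv")

cat(sprintf("tested rows: %d; significant at adjusted p < 0.01: %d\n",
            nrow(markers), sum(markers$p_adjusted < 0.01)))
for (cl in sort(unique(markers$group_a))) {
  top <- head(markers[markers$group_a == cl & markers$effect > 0, ], 20)
  hits <- vapply(sets$sets, function(g) sum(top$unit %in% g), 0L)
  cat(sprintf("cluster %s: top %d up-markers contain %s\n",
              cl, nrow(top),
              paste(sprintf("%d %s genes", hits, names(hits)),
                    collapse = ", ")))
}
cat("wrote results/markers.tsv\n")
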