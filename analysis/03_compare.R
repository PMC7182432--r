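#!/usr/bin/env Rscript
# Stage 3: compare module scores between clusters and between genotypes.
#
# Two designs: each cluster against the rest (is the module enriched in a
# state?), and WT vs KO inside each cluster (does the knockout lose the
# program where it is active?). Wilcoxon rank-sum, two-sided, BH-adjusted
# within each module. Writes results/comparisons.tsv.

suppressPackageStartupMessages(library(scgps))

st <- read_scores("results/scores.tsv")
cells <- read_cell_table("results/sim/cells.tsv")

by_cluster <- compare_scores(st, cells, design = "by_cluster_one_vs_rest")
by_genotype <- compare_scores(st, cells,
                              design = "by_genotype_within_cluster")
cmp <- rbind(by_cluster, by_genotype)
write_comparisons(cmp, "results/comparisons.tsv")

fmt <- function(df) {
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-11s %-7s vs %-7s effect %+0.3f  adj p %.2e\n",
                df$unit[i], df$group_a[i], df$group_b[i], df$effect[i],
                df$p_adjusted[i]))
}
cat("cluster enrichment (one vs rest):\n")
fmt(by_cluster)
cat("genotype effect within cluster (KO vs WT):\n")
fmt(by_genotype)

sig <- by_genotype[by_genotype$p_adjusted < 0.01, ]
cat(sprintf("%d of %d genotype contrasts significant at adjusted p < 0.01\n",
            nrow(sig), nrow(by_genotype)))
cat("wrote results/comparisons.tsv\n")
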