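#!/usr/bin/env Rscript
# Stage 1: simulate a neonatal-airway-style UMI experiment.
#
# Three cell clusters (think basal, secretory, and a hybrid state), two
# planted co-regulated modules, and a 50/50 wild-type / knockout split in
# which the "disease" module loses its enrichment in KO cells — the
# structure the scoring and comparison stages are meant to detect.
# Outputs land under results/sim/ in the same plain-text formats a 10x
# run would produce (Matrix Market trio, TSV metadata, GMT gene sets).

suppressPackageStartupMessages(library(scgps))

cfg <- sim_config(
  n_genes = 1000,
  n_cells_per_cluster = c(300, 300, 300),
  modules = list(
    list(name = "cell_cycle", n_genes = 50, target_cluster = 2,
         fold_change = 4),
    list(name = "disease", n_genes = 50, target_cluster = 3,
         fold_change = 4, fold_change_ko = 1)),
  genotype_split = 0.5,
  seed = 20260924)

out <- "results/sim"
sim <- simulate_counts(cfg)
write_mtx_triplet(sim$counts, file.path(out, "counts"))
write_cell_table(sim$cells, file.path(out, "cells.tsv"))
write_gmt(make_true_gene_sets(sim$truth), file.path(out, "gene_sets.gmt"))
yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))

cat(sprintf("simulated %d genes x %d cells (%d clusters, %d/%d WT/KO)\n",
            nrow(sim$counts$values), ncol(sim$counts$values),
            length(cfg$n_cells_per_cluster),
            sum(sim$cells$genotype == "WT"),
            sum(sim$cells$genotype == "KO")))
cat(sprintf("median library size: %d UMIs; matrix density: %.1f%%\n",
            as.integer(stats::median(Matrix::colSums(sim$counts$values))),
            100 * length(sim$counts$values@x) /
              prod(dim(sim$counts$values))))
cat("planted modules:",
    paste(sprintf("%s (m=%d -> %s)",
                  names(sim$truth$module_genes),
                  lengths(sim$truth$module_genes),
                  vapply(cfg$modules, `[[`, "", "target_cluster")),
          collapse = ", "), "\n")
cat("wrote", out, "\n")
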