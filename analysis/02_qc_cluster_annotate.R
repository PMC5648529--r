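#!/usr/bin/env Rscript
# Clean up, embed, cluster, and annotate each protocol.
#
# Applies the three clean-up steps (>=1000 UMIs, stressed-cell removal,
# total-count normalization), selects highly variable then principal
# variable genes against a permutation eigenvalue null, embeds with tSNE,
# clusters by density, annotates clusters against the design's marker
# criteria, and tabulates state fractions and motor-neuron efficiency per
# protocol and day. Run 01_simulate.R first.

library(mnpaths)

seed <- 1L
data_dir <- "results/data"
out <- "results"
mito_genes <- readLines(file.path(data_dir, "mito_genes.txt"))
design <- two_protocol_design()
criteria <- design_marker_criteria(design)

all_fractions <- list()
for (p in c("dp", "sp")) {
  cm <- load_counts(file.path(data_dir, p))
  qc <- qc_pipeline(cm, min_umi = 1000, mito_genes = mito_genes)
  message(sprintf(
    "%s: %d cells in, %d below 1000 UMIs, %d stressed, %d retained",
    toupper(p), qc$report$n_input_cells, qc$report$n_below_min_umi,
    qc$report$n_stressed_removed, qc$report$n_retained))

  hvg <- select_variable_genes(qc$normalized, 1000)
  model <- select_principal_variable_genes(qc$normalized, hvg,
                                           n_randomizations = 10,
                                           seed = seed)
  message(sprintf("  %d non-trivial PCs, %d PV genes",
                  model$n_nontrivial, length(model$pv_gene_ids)))

  z <- zscore_transform(qc$normalized, model)
  coords <- embed_tsne(z, max(1, model$n_nontrivial), seed = seed)
  labels <- density_cluster(coords)
  ann <- annotate_clusters(qc$normalized, qc$counts, labels, criteria)
  message(sprintf("  %d clusters: %s", nrow(ann),
                  paste(ann$annotation, collapse = ", ")))

  cells <- cell_annotations(labels, ann)
  fr <- state_fractions(cells, qc$counts$cell_meta)
  all_fractions[[p]] <- fr

  # recovered vs planted states
  truth <- qc$counts$cell_meta$true_state
  message(sprintf("  ARI vs ground truth: %.3f",
                  adjusted_rand_index(labels, truth)))

  utils::write.table(
    data.frame(barcode = qc$counts$cell_ids, cluster = labels,
               annotation = cells),
    file.path(out, sprintf("labels_%s.tsv", p)),
    sep = "\t", quote = FALSE, row.names = FALSE)
}

fr <- do.call(rbind, all_fractions)
utils::write.table(fr, file.path(out, "state_fractions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
eff <- efficiency(fr, c("EMN", "LMN"))
utils::write.table(eff, file.path(out, "mn_efficiency.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(eff)
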