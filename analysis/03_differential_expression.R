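#!/usr/bin/env Rscript
# Marker genes per annotated state, with the study's filter presets.
#
# Welch t-tests of each state versus the rest (>=10 nonzero cells required,
# BH FDR 5% and p < 1e-4 for marker calls) and a demonstration of the two
# transcription-factor screens (fold > 6, p < 1e-3; fold > 4, p < 1e-3,
# mean >= 1 count/cell) using the marker-block genes as a stand-in
# whitelist. Run 01 and 02 first.

library(mnpaths)

data_dir <- "results/data"
out <- "results"
design <- two_protocol_design()
tf_whitelist <- unlist(lapply(design$programs, function(p) p$marker_genes))

for (p in c("dp", "sp")) {
  cm <- load_counts(file.path(data_dir, p))
  qc <- qc_pipeline(cm, min_umi = 1000,
                    mito_genes = readLines(file.path(data_dir,
                                                     "mito_genes.txt")))
  lab <- utils::read.delim(file.path(out, sprintf("labels_%s.tsv", p)))
  lab <- lab[match(qc$counts$cell_ids, lab$barcode), ]
  mk <- marker_genes(qc$normalized, lab$cluster)
  enr <- do.call(rbind, lapply(names(mk), function(k) {
    r <- mk[[k]]
    r <- r[r$enriched, c("gene", "mean_a", "mean_b", "fold_ratio",
                         "p_value", "q_value")]
    if (nrow(r)) cbind(cluster = k, r) else NULL
  }))
  utils::write.table(enr, file.path(out, sprintf("markers_%s.tsv", p)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d enriched marker calls across %d clusters",
                  toupper(p), nrow(enr), length(mk)))

  # TF-style screen between the two intermediate states of this protocol
  states <- unique(lab$annotation[!is.na(lab$annotation)])
  inter <- setdiff(states, design$shared)
  if (length(inter) >= 2) {
    a <- which(lab$annotation == inter[1])
    b <- which(lab$annotation == inter[2])
    r <- de_test(qc$normalized, a, b, restrict_to = tf_whitelist)
    v <- volcano_table(r)
    utils::write.table(
      v, file.path(out, sprintf("tf_volcano_%s_%s_vs_%s.tsv",
                                p, inter[1], inter[2])),
      sep = "\t", quote = FALSE, row.names = FALSE)
    message(sprintf("  %s vs %s: %d pass fold>6 screen, %d pass fold>4",
                    inter[1], inter[2],
                    sum(de_pass(r, "tf6", tf_whitelist)),
                    sum(de_pass(r, "tf4", tf_whitelist))))
  }
}
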