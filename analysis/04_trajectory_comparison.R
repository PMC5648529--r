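#!/usr/bin/env Rscript
# Compare the two differentiation paths.
#
# Pools both protocols into one PV-gene space and asks whether the paths
# bifurcate and reconverge: (i) centroid cosine similarity between all DP
# and SP states, (ii) multinomial maximum-likelihood assignment of every DP
# cell onto the SP states, (iii) a SPRING-style kNN graph with force layout
# over the pooled cells. Run 01 and 02 first.

library(mnpaths)

seed <- 1L
data_dir <- "results/data"
out <- "results"
mito <- readLines(file.path(data_dir, "mito_genes.txt"))

qc <- lapply(c(dp = "dp", sp = "sp"), function(p)
  qc_pipeline(load_counts(file.path(data_dir, p)), min_umi = 1000,
              mito_genes = mito))
lab <- lapply(c(dp = "dp", sp = "sp"), function(p) {
  l <- utils::read.delim(file.path(out, sprintf("labels_%s.tsv", p)))
  l[match(qc[[p]]$counts$cell_ids, l$barcode), ]
})

cmp <- compare_protocols(qc$dp, qc$sp,
                         lab$dp$annotation, lab$sp$annotation, seed = seed)
utils::write.table(round(cmp$similarity, 4),
                   file.path(out, "centroid_cosine_similarity.tsv"),
                   sep = "\t", quote = FALSE)
message("centroid cosine similarity (DP rows x SP columns):")
print(round(cmp$similarity, 3))

jsonlite::write_json(as.list(round(cmp$assignment$tally, 3)),
                     file.path(out, "ml_assignment_tally.json"),
                     auto_unbox = TRUE)
message("DP cells ML-assigned to SP states (%):")
print(round(cmp$assignment$tally, 1))

# pooled kNN graph + force layout for the figure-style view
genes <- intersect(qc$dp$counts$gene_ids, qc$sp$counts$gene_ids)
pooled <- count_matrix(rbind(qc$dp$counts$counts[, genes],
                             qc$sp$counts$counts[, genes]),
                       c(qc$dp$counts$cell_ids, qc$sp$counts$cell_ids),
                       genes)
norm <- total_count_normalize(pooled)
g <- build_knn_graph(norm, k = 20)
xy <- force_layout(g, seed = seed)
utils::write.table(
  data.frame(barcode = rownames(xy), x = xy[, 1], y = xy[, 2],
             protocol = rep(c("DP", "SP"),
                            c(nrow(qc$dp$counts$counts),
                              nrow(qc$sp$counts$counts))),
             state = c(lab$dp$annotation, lab$sp$annotation)),
  file.path(out, "spring_layout.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/spring_layout.tsv")
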