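test_that("tSNE separates planted clusters and is seed-deterministic", {
  spec <- toy_two_state_spec(n_cells = 100, n_genes = 300, depth = 1000,
                             seed = 51)
  cm <- generate_counts(spec)
  norm <- toy_normalized(cm)
  hvg <- select_variable_genes(norm, 150)
  model <- select_principal_variable_genes(norm, hvg, n_randomizations = 3,
                                           seed = 1)
  z <- zscore_transform(norm, model)
  coords <- embed_tsne(z, max(1, model$n_nontrivial), seed = 6)
  expect_equal(dim(coords), c(200, 2))
  expect_identical(coords, embed_tsne(z, max(1, model$n_nontrivial), seed = 6))

  # silhouette of ground truth labels on the embedding
  truth <- cm$cell_meta$true_state
  d <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    a <- mean(d[i, truth == truth[i]][-which(which(truth == truth[i]) == i)])
    b <- min(vapply(setdiff(unique(truth), truth[i]),
                    function(s) mean(d[i, truth == s]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
  expect_error(embed_tsne(z, 0), "n_init_dims")
})

test_that("DBSCAN recovers separated blobs and handles edge cases", {
  set.seed(61)
  blob1 <- matrix(rnorm(100, sd = 0.3), ncol = 2)
  blob2 <- matrix(rnorm(100, sd = 0.3), ncol = 2) + 10
  coords <- rbind(blob1, blob2)
  labels <- density_cluster(coords, eps = 1, min_pts = 5)
  truth <- rep(1:2, each = 50)
  expect_equal(length(unique(labels[labels != -1])), 2)
  expect_equal(adjusted_rand(labels, truth), 1)

  # all points identical -> one cluster
  same <- matrix(1, 20, 2)
  expect_equal(unique(density_cluster(same)), 1L)

  # huge eps -> everything one cluster
  expect_equal(unique(density_cluster(coords, eps = 1e6, min_pts = 5)), 1L)
  expect_error(density_cluster(coords, eps = -1), "eps")

  # sparse outlier far from both blobs is labelled noise
  labels2 <- density_cluster(rbind(coords, c(100, 100)), eps = 1, min_pts = 5)
  expect_equal(labels2[101], -1L)
})

test_that("doublet groups between marker-disjoint states are flagged", {
  # equal library sizes keep cross-state doublets balanced (50/50 mixtures);
  # a doublet dominated by one parent is indistinguishable from that parent
  spec <- toy_two_state_spec(n_cells = 300, n_genes = 400, depth = 1500,
                             doublet_rate = 0.02, seed = 71)
  spec$library_size <- c(meanlog = log(1500), sdlog = 0)
  cm <- generate_counts(spec)
  norm <- toy_normalized(cm)
  hvg <- select_variable_genes(norm, 200)
  model <- select_principal_variable_genes(norm, hvg, n_randomizations = 3,
                                           seed = 1)
  z <- zscore_transform(norm, model)
  graph <- build_knn_graph(NULL, k = 10, coords = z)
  # cluster in the PV space: states + a small intermediate doublet group
  km_labels <- density_cluster(cmdscale(dist(z), k = 2))
  flags <- remove_doublets(graph, km_labels, norm)
  # cross-state doublets are the detectably intermediate ones; same-state
  # doublets are expression-identical to singlets of their state
  cross <- which(cm$cell_meta$doublet_states == "ESC+LMN")
  injected <- which(cm$cell_meta$is_doublet)
  expect_gte(sum(flags[cross]) / length(cross), 0.8)
  expect_lte(sum(flags[-injected]) / (nrow(cm$counts) - length(injected)),
             0.005)
})

test_that("zero doublet rate yields almost no flags", {
  spec <- toy_two_state_spec(n_cells = 250, n_genes = 300, depth = 1200,
                             doublet_rate = 0, seed = 73)
  cm <- generate_counts(spec)
  norm <- toy_normalized(cm)
  hvg <- select_variable_genes(norm, 150)
  model <- select_principal_variable_genes(norm, hvg, n_randomizations = 3,
                                           seed = 1)
  z <- zscore_transform(norm, model)
  graph <- build_knn_graph(NULL, k = 10, coords = z)
  labels <- density_cluster(cmdscale(dist(z), k = 2))
  flags <- remove_doublets(graph, labels, norm)
  expect_lte(mean(flags), 0.005)
})

test_that("a cell at the average of two centroids is flagged as a doublet", {
  spec <- toy_two_state_spec(n_cells = 150, n_genes = 200, depth = 1000,
                             seed = 79)
  cm <- generate_counts(spec)
  norm0 <- toy_normalized(cm)
  avg <- (colMeans(norm0$values[cm$cell_meta$true_state == "ESC", ]) +
            colMeans(norm0$values[cm$cell_meta$true_state == "LMN", ])) / 2
  vals <- rbind(norm0$values, avg * (norm0$target_total / sum(avg)))
  rownames(vals) <- c(rownames(norm0$values), "avg_cell")
  norm <- normalized_matrix(vals, norm0$target_total)
  z <- scale(vals)
  graph <- build_knn_graph(NULL, k = 10, coords = z)
  labels <- c(ifelse(cm$cell_meta$true_state == "ESC", 1L, 2L), 3L)
  flags <- remove_doublets(graph, labels, norm)
  expect_true(flags[length(flags)])
  expect_false(any(flags[-length(flags)]))
})

test_that("clusters are annotated from marker criteria with floor and ties", {
  spec <- toy_two_state_spec(n_cells = 120, n_genes = 200, depth = 1000,
                             seed = 83)
  cm <- generate_counts(spec)
  norm <- toy_normalized(cm)
  labels <- ifelse(cm$cell_meta$true_state == "ESC", 1L, 2L)
  genes <- toy_universe(200)
  crit <- marker_criteria(rbind(
    data.frame(state = "ESC", gene = genes[1:5], level = "Hi"),
    data.frame(state = "ESC", gene = genes[21:25], level = "Absent"),
    data.frame(state = "LMN", gene = genes[21:25], level = "Hi"),
    data.frame(state = "LMN", gene = genes[1:5], level = "Absent")))
  ann <- annotate_clusters(norm, cm, labels, crit)
  expect_equal(ann$annotation[ann$cluster_id == 1], "ESC")
  expect_equal(ann$annotation[ann$cluster_id == 2], "LMN")
  expect_equal(ann$tied, c("", ""))

  # per-cell annotations follow the table; noise gets NA
  labels_n <- labels; labels_n[1] <- -1L
  ann_n <- annotate_clusters(norm, cm, labels_n, crit)
  cells <- cell_annotations(labels_n, ann_n)
  expect_true(is.na(cells[1]))
  expect_equal(cells[2], "ESC")

  # a cluster matching nothing falls back to "other"
  crit_far <- marker_criteria(data.frame(
    state = "Mus", gene = genes[101:105], level = "Hi"))
  ann2 <- annotate_clusters(norm, cm, labels, crit_far)
  expect_true(all(ann2$annotation == "other"))

  # identical centroids (same cells labelled twice) -> identical annotations
  dup <- annotate_clusters(norm, cm, rep(c(5L, 6L), length.out = 240), crit)
  # cells alternate so both clusters mix ESC+LMN equally; equal scores either
  # way, but the two clusters must agree with each other
  expect_equal(dup$annotation[1], dup$annotation[2])

  # criteria genes missing from the data are skipped with a warning
  crit_miss <- marker_criteria(rbind(
    data.frame(state = "ESC", gene = c(genes[1:5], "absent_gene"),
               level = "Hi")))
  expect_warning(annotate_clusters(norm, cm, labels, crit_miss),
                 "absent_gene")
})

test_that("state fractions partition each protocol-day and drive efficiency", {
  meta <- data.frame(protocol = rep(c("DP", "SP"), c(4, 6)),
                     day = c(rep(0, 4), rep(0, 3), rep(11, 3)))
  ann <- c("ESC", "ESC", "EMN", "LMN",
           "ESC", "NP", "NP", "EMN", "LMN", "LMN")
  fr <- state_fractions(ann, meta)
  sums <- aggregate(fraction ~ protocol + day, fr, sum)
  expect_true(all(abs(sums$fraction - 1) < 1e-9))
  expect_equal(fr$fraction[fr$protocol == "DP" & fr$annotation == "ESC"], 0.5)

  eff <- efficiency(fr, c("EMN", "LMN"))
  expect_equal(eff$efficiency[eff$protocol == "DP"], 0.5)
  expect_equal(eff$efficiency[eff$protocol == "SP" & eff$day == 11], 1)
  expect_equal(eff$efficiency[eff$protocol == "SP" & eff$day == 0], 0)

  # the reference worked example: 645 of 874 cells labelled MN -> 73.8%
  meta_p <- data.frame(protocol = rep("primary", 874), day = 0)
  ann_p <- rep(c("LMN", "Gl1"), c(645, 229))
  fr_p <- state_fractions(ann_p, meta_p)
  expect_equal(round(100 * fr_p$fraction[fr_p$annotation == "LMN"], 1), 73.8)

  # single state -> 100%
  fr1 <- state_fractions(rep("ESC", 5),
                         data.frame(protocol = "DP", day = 0)[rep(1, 5), ])
  expect_equal(fr1$fraction, 1)
})
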