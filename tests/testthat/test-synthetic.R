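test_that("state programs and topologies validate their invariants", {
  genes <- toy_universe(10)
  expect_error(state_program("ESC", setNames(rep(0.2, 10), genes)),
               "sum to 1")
  expect_error(state_program("ESC", setNames(numeric(0), character(0))),
               "empty gene universe")
  p <- setNames(rep(0.1, 10), genes)
  expect_error(state_program("ESC", p, marker_genes = "nope"),
               "outside the gene universe")
  a <- state_program("A", p)
  b <- state_program("B", p)
  expect_error(trajectory_topology(list(a, b),
                                   edges = cbind("A", "C")),
               "endpoints")
  # a cycle is rejected
  expect_error(trajectory_topology(list(a, b),
                                   edges = rbind(c("A", "B"), c("B", "A"))),
               "DAG")
})

test_that("degenerate multinomial puts the whole library on one gene", {
  p <- setNames(1, "g001")
  topo <- trajectory_topology(list(state_program("ESC", p)))
  spec <- synthetic_spec(topo, cells_per_state = 10,
                         library_size = c(meanlog = log(100), sdlog = 0),
                         seed = 3)
  cm <- generate_counts(spec)
  expect_equal(dim(cm$counts), c(10, 1))
  expect_true(all(cm$counts == 100))
})

test_that("a fixed seed reproduces the count matrix exactly", {
  spec <- toy_two_state_spec(n_cells = 30, seed = 11)
  cm1 <- generate_counts(spec)
  cm2 <- generate_counts(spec)
  expect_identical(cm1$counts, cm2$counts)
  expect_identical(cm1$cell_meta, cm2$cell_meta)
  # and a different seed does not
  spec2 <- toy_two_state_spec(n_cells = 30, seed = 12)
  expect_false(identical(generate_counts(spec2)$counts, cm1$counts))
})

test_that("per-gene means match library size x gene probability", {
  n <- 1000
  depth <- 800
  prog <- toy_program("ESC", n_genes = 50, marker_idx = 1:5, boost = 20)
  topo <- trajectory_topology(list(prog))
  spec <- synthetic_spec(topo, cells_per_state = n,
                         library_size = c(meanlog = log(depth), sdlog = 0),
                         seed = 5)
  cm <- generate_counts(spec)
  expected <- depth * prog$gene_probs
  observed <- colMeans(cm$counts)
  se <- sqrt(depth * prog$gene_probs * (1 - prog$gene_probs) / n)
  expect_true(all(abs(observed - expected) <= 3 * se + 1e-9))
})

test_that("doublet and stress injection hit their nominal rates", {
  spec <- toy_two_state_spec(n_cells = 500, doublet_rate = 0.05,
                             stress_rate = 0.04,
                             mito_genes = c("mt-01", "mt-02"), seed = 21)
  cm <- generate_counts(spec)
  n <- nrow(cm$counts)
  d <- sum(cm$cell_meta$is_doublet)
  s <- sum(cm$cell_meta$is_stressed)
  expect_true(d >= qbinom(0.005, n, 0.05) && d <= qbinom(0.995, n, 0.05))
  expect_true(s >= qbinom(0.005, n, 0.04) && s <= qbinom(0.995, n, 0.04))
  # stressed cells carry >= 50% mito counts
  mito_frac <- rowSums(cm$counts[, c("mt-01", "mt-02")]) / rowSums(cm$counts)
  expect_true(all(mito_frac[cm$cell_meta$is_stressed] >= 0.45))
  expect_true(all(mito_frac[!cm$cell_meta$is_stressed &
                              !cm$cell_meta$is_doublet] < 0.25))
})

test_that("downstream clustering recovers two planted states", {
  spec <- toy_two_state_spec(n_cells = 200, n_genes = 500, depth = 1000,
                             seed = 8)
  cm <- generate_counts(spec)
  norm <- toy_normalized(cm)
  hvg <- select_variable_genes(norm, 200)
  model <- select_principal_variable_genes(norm, hvg, n_randomizations = 3,
                                           seed = 1)
  z <- zscore_transform(norm, model)
  coords <- embed_tsne(z, max(1, model$n_nontrivial), seed = 2)
  labels <- density_cluster(coords)
  expect_gte(adjusted_rand(labels, cm$cell_meta$true_state), 0.95)
})

test_that("two-protocol generation enforces and uses shared programs", {
  genes <- toy_universe(60)
  mk <- function(idx, name) toy_program(name, 60, idx, boost = 25)
  esc <- mk(1:10, "ESC"); lmn <- mk(11:20, "LMN")
  np <- mk(21:30, "NP"); mnp <- mk(31:40, "MNP")
  dp <- synthetic_spec(trajectory_topology(list(esc, np, lmn)),
                       cells_per_state = 50, seed = 1, protocol = "DP",
                       library_size = c(meanlog = log(800), sdlog = 0.2))
  sp <- synthetic_spec(trajectory_topology(list(esc, mnp, lmn)),
                       cells_per_state = 50, seed = 2, protocol = "SP",
                       library_size = c(meanlog = log(800), sdlog = 0.2))
  ex <- generate_two_protocol_experiment(dp, sp, c("ESC", "LMN"))
  expect_identical(ex$dp$gene_ids, ex$sp$gene_ids)

  # mismatched shared program is rejected
  esc2 <- mk(2:11, "ESC")
  dp2 <- synthetic_spec(trajectory_topology(list(esc2, np, lmn)),
                        cells_per_state = 50, seed = 1)
  expect_error(generate_two_protocol_experiment(dp2, sp, c("ESC", "LMN")),
               "differing programs")

  # disjoint-marker states: cross-protocol similarity of distinct states is
  # below the shared-state similarity
  pooled <- count_matrix(rbind(ex$dp$counts, ex$sp$counts),
                         c(ex$dp$cell_ids, ex$sp$cell_ids))
  norm <- total_count_normalize(pooled, 800)
  hvg <- select_variable_genes(norm, 60)
  model <- select_principal_variable_genes(norm, hvg, n_randomizations = 3,
                                           seed = 3)
  z <- zscore_transform(norm, model)
  st <- c(ex$dp$cell_meta$true_state, ex$sp$cell_meta$true_state)
  n_dp <- nrow(ex$dp$counts)
  ca <- cluster_centroids(z[seq_len(n_dp), ], st[seq_len(n_dp)])
  cb <- cluster_centroids(z[-seq_len(n_dp), ], st[-seq_len(n_dp)])
  sim <- centroid_cosine_similarity(ca, cb)
  expect_gt(sim["ESC", "ESC"], sim["NP", "MNP"])
  expect_gt(sim["LMN", "LMN"], sim["NP", "MNP"])
  # per-row maxima sit on the shared states
  expect_equal(colnames(sim)[which.max(sim["ESC", ])], "ESC")
  expect_equal(colnames(sim)[which.max(sim["LMN", ])], "LMN")
})
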