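# independent oracle: full multinomial log-likelihood including the
# coefficient, computed with dmultinom per cell and cluster
brute_force_loglik <- function(counts, profiles) {
  t(apply(counts, 1, function(x)
    apply(profiles, 1, function(p) stats::dmultinom(x, prob = p, log = TRUE))))
}

test_that("kNN graph respects the SPRING gene filter and recovers states", {
  spec <- toy_two_state_spec(n_cells = 100, n_genes = 300, depth = 1500,
                             seed = 103)
  cm <- generate_counts(spec)
  norm <- total_count_normalize(cm, stats::median(rowSums(cm$counts)))
  g <- build_knn_graph(norm, k = 10)
  # >=99% of neighbors share the cell's ground-truth state
  truth <- cm$cell_meta$true_state
  same <- mean(vapply(seq_len(nrow(g$idx)), function(i)
    mean(truth[g$idx[i, ]] == truth[i]), numeric(1)))
  expect_gte(same, 0.99)
  expect_true(all(diff(t(g$dist)) >= -1e-9))   # distances sorted per cell

  # a gene with mean 0.01 counts/cell cannot pass the expression filter
  vals <- norm$values
  vals[, "g300"] <- 0
  vals[1:2, "g300"] <- c(0.01 * nrow(vals) / 2, 0.01 * nrow(vals) / 2)
  vals <- vals * norm$target_total / rowSums(vals)
  norm2 <- normalized_matrix(vals, norm$target_total)
  g2 <- build_knn_graph(norm2, k = 5)
  expect_false("g300" %in% g2$space$genes)

  # complete graph when k = n - 1
  sub <- subset_cells(cm, 1:12)
  gsub <- build_knn_graph(total_count_normalize(sub, 1000), k = 11)
  expect_equal(sort(unique(as.vector(gsub$idx))), 1:12)
  expect_error(build_knn_graph(norm, k = nrow(norm$values)), "smaller")
})

test_that("force layout is seeded, orders chained clusters, separates components", {
  spec <- toy_two_state_spec(n_cells = 60, n_genes = 200, depth = 1000,
                             seed = 107)
  cm <- generate_counts(spec)
  norm <- toy_normalized(cm)
  g <- build_knn_graph(norm, k = 8)
  xy1 <- force_layout(g, seed = 3)
  xy2 <- force_layout(g, seed = 3)
  expect_identical(xy1, xy2)

  # chain of 3 clusters: middle centroid lies between the ends on PC1
  set.seed(11)
  chain <- rbind(matrix(rnorm(60, 0, 0.4), ncol = 2),
                 matrix(rnorm(60, 0, 0.4), ncol = 2) + c(4, 0),
                 matrix(rnorm(60, 0, 0.4), ncol = 2) + c(8, 0))
  gc <- build_knn_graph(NULL, k = 6, coords = chain)
  xy <- force_layout(gc, seed = 5)
  pc1 <- stats::prcomp(xy)$x[, 1]
  mids <- tapply(pc1, rep(1:3, each = 30), mean)
  expect_true(mids[2] > min(mids[c(1, 3)]) && mids[2] < max(mids[c(1, 3)]))

  # two far-separated blobs disconnect at small k: disjoint bounding boxes
  blobs <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
                 matrix(rnorm(40, 0, 0.1), ncol = 2) + 100)
  gb <- build_knn_graph(NULL, k = 5, coords = blobs)
  xyb <- force_layout(gb, seed = 7)
  r1 <- range(xyb[1:20, 1]); r2 <- range(xyb[21:40, 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
})

test_that("centroid cosine similarity matches hand computations", {
  a <- structure(list(centroids = rbind(x = c(1, 0, 1)), n_cells = 1),
                 class = "centroid_set")
  b <- structure(list(centroids = rbind(y = c(1, 1, 0)), n_cells = 1),
                 class = "centroid_set")
  expect_equal(as.numeric(centroid_cosine_similarity(a, b)), 0.5)
  expect_equal(as.numeric(centroid_cosine_similarity(a, a)), 1.0)
  z <- structure(list(centroids = rbind(z = c(0, 0, 0)), n_cells = 1),
                 class = "centroid_set")
  expect_warning(s <- centroid_cosine_similarity(a, z), "zero-norm")
  expect_true(is.na(s[1, 1]))

  # symmetry and range on a random set
  set.seed(13)
  m <- matrix(rnorm(40), 8, 5)
  cs <- cluster_centroids(m, rep(1:4, each = 2))
  sim <- centroid_cosine_similarity(cs, cs)
  expect_equal(sim, t(sim), tolerance = 1e-12)
  expect_true(all(sim >= -1 - 1e-12 & sim <= 1 + 1e-12))
})

test_that("ml_assign_cells agrees with the brute-force multinomial oracle", {
  set.seed(17)
  genes <- sprintf("g%02d", 1:10)
  counts <- matrix(rpois(100, 3), 10, 10, dimnames = list(NULL, genes))
  cm <- count_matrix(counts, sprintf("c%02d", 1:10))
  profiles <- rbind(A = rep(0.1, 10),
                    B = c(rep(0.19, 5), rep(0.01, 5)))
  colnames(profiles) <- genes
  res <- ml_assign_cells(cm, profiles)
  oracle <- brute_force_loglik(counts, profiles)
  # identical argmax; log-likelihood differences equal the per-cell constant
  expect_equal(colnames(oracle)[apply(oracle, 1, which.max)],
               unname(res$assignment))
  const <- oracle - res$loglik
  expect_equal(const[, "A"], const[, "B"], tolerance = 1e-9)

  # scaling a cell's counts by an integer cannot change its argmax
  cm4 <- count_matrix(counts * 4, sprintf("c%02d", 1:10))
  res4 <- ml_assign_cells(cm4, profiles)
  expect_identical(res4$assignment, res$assignment)
})

test_that("symmetric 3-gene toy produces a reported tie", {
  profiles <- rbind(A = c(0.8, 0.1, 0.1), B = c(0.1, 0.1, 0.8))
  colnames(profiles) <- c("g1", "g2", "g3")
  cm <- count_matrix(matrix(c(5, 0, 5), 1, 3,
                            dimnames = list("c1", c("g1", "g2", "g3"))))
  res <- ml_assign_cells(cm, profiles)
  expect_true(res$tie[1])
  expect_equal(res$loglik[1, "A"], 5 * log(0.8) + 5 * log(0.1))
  expect_equal(res$loglik[1, "A"], res$loglik[1, "B"])
  expect_equal(unname(res$tally), c(50, 50))   # fractional tally

  # single-cluster reference absorbs everything
  res1 <- ml_assign_cells(cm, profiles["A", , drop = FALSE])
  expect_equal(unname(res1$tally), 100)

  # zero-count cell on the comparison genes is unassignable
  cm0 <- count_matrix(matrix(c(0, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE,
                             dimnames = list(c("c1", "c2"),
                                             c("g1", "g2", "g3"))))
  res0 <- ml_assign_cells(cm0, profiles)
  expect_equal(res0$n_unassignable, 1L)
  expect_true(is.na(res0$assignment[1]))
  expect_equal(sum(res0$tally), 100)
})

test_that("reference profiles pool counts and pseudo-fill undetected genes", {
  mat <- matrix(c(8, 2, 0,
                  6, 4, 0,
                  1, 1, 8), 3, 3, byrow = TRUE,
                dimnames = list(paste0("c", 1:3), c("g1", "g2", "g3")))
  cm <- count_matrix(mat)
  prof <- reference_profiles(cm, c("K", "K", "L"))
  expect_equal(unname(rowSums(prof)), c(1, 1))
  # cluster K pooled counts: 14, 6, 0 -> g3 filled with 1e-7 then renormalized
  expect_equal(prof["K", "g1"], 14 / (20 + 1e-7), tolerance = 1e-12)
  expect_gt(prof["K", "g3"], 0)
  expect_lt(prof["K", "g3"], 1e-7)
})

test_that("parameter recovery: query cells map back to their source cluster", {
  spec <- toy_two_state_spec(n_cells = 150, n_genes = 300, depth = 2000,
                             seed = 109)
  cm <- generate_counts(spec)
  prof <- reference_profiles(cm, cm$cell_meta$true_state)
  # fresh cells from the same programs
  cm2 <- generate_counts(toy_two_state_spec(n_cells = 100, n_genes = 300,
                                            depth = 2000, seed = 211))
  res <- ml_assign_cells(cm2, prof)
  acc <- mean(res$assignment == cm2$cell_meta$true_state, na.rm = TRUE)
  expect_gte(acc, 0.95)
})

test_that("label transfer reproduces the 3-of-5 rule and the LMN tie rule", {
  # exhaustive enumeration over all 3^5 neighbor-label vectors vs an
  # independently hand-coded oracle
  lab <- c("EMN", "LMN", "NP")
  grid <- expand.grid(lab, lab, lab, lab, lab, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    v <- unlist(grid[i, ], use.names = FALSE)
    got <- transfer_rule(v)
    e <- sum(v == "EMN"); l <- sum(v == "LMN")
    want_accept <- (e + l) >= 3
    want_label <- if (!want_accept) NA_character_
                  else if (e > l) "EMN" else "LMN"
    expect_identical(got$accepted, want_accept)
    expect_identical(got$label, want_label)
  }
  # worked cases of the acceptance and tie rules
  expect_false(transfer_rule(c("EMN", "LMN", "NP", "NP", "NP"))$accepted)
  r1 <- transfer_rule(c("EMN", "EMN", "LMN", "NP", "NP"))   # 3 of 5 targets
  expect_true(r1$accepted); expect_equal(r1$label, "EMN")
  r2 <- transfer_rule(c("EMN", "LMN", "LMN", "EMN", "LMN"))
  expect_true(r2$accepted); expect_equal(r2$label, "LMN")
  r3 <- transfer_rule(c("EMN", "EMN", "LMN", "LMN", "NP"))
  expect_true(r3$accepted); expect_equal(r3$label, "LMN")   # tie -> LMN
})

test_that("projection-based transfer labels replicate cells by reference neighbors", {
  spec <- toy_two_state_spec(n_cells = 120, n_genes = 200, depth = 1500,
                             seed = 113)
  cm <- generate_counts(spec)
  norm <- toy_normalized(cm)
  hvg <- select_variable_genes(norm, 120)
  model <- select_principal_variable_genes(norm, hvg, n_randomizations = 3,
                                           seed = 1)
  ref_coords <- pca_project(norm, model)
  ref_labels <- ifelse(cm$cell_meta$true_state == "ESC", "NP", "LMN")
  cm_rep <- generate_counts(toy_two_state_spec(n_cells = 40, n_genes = 200,
                                               depth = 1500, seed = 311))
  norm_rep <- toy_normalized(cm_rep)
  tr <- project_and_transfer_labels(norm_rep, model, ref_coords, ref_labels)
  is_lmn <- cm_rep$cell_meta$true_state == "LMN"
  expect_true(all(tr$accepted[is_lmn]))
  expect_true(all(tr$label[is_lmn] == "LMN"))
  expect_true(all(!tr$accepted[!is_lmn]))   # ESC-like cells land near NP

  # invariant to reference cell order
  perm <- sample(nrow(ref_coords))
  tr_p <- project_and_transfer_labels(norm_rep, model,
                                      ref_coords[perm, ], ref_labels[perm])
  expect_identical(tr$accepted, tr_p$accepted)
  expect_identical(tr$label, tr_p$label)
  expect_error(project_and_transfer_labels(norm_rep, model,
                                           ref_coords[1:3, ],
                                           ref_labels[1:3], k = 5),
               "k exceeds")
})

test_that("neighbor fractions count cells with a reference neighbor in k_check", {
  # mixed 1:1 with the reference: fraction ~1; far separated: fraction 0
  set.seed(19)
  mixed <- matrix(rnorm(200 * 5), 200, 5)
  far <- matrix(rnorm(60 * 5), 60, 5) + 50
  coords <- rbind(mixed, far)
  states <- c(rep("LMN", 100), rep(NA, 100), rep("EMN", 60))
  is_ref <- c(rep(FALSE, 100), rep(TRUE, 100), rep(FALSE, 60))
  g <- build_knn_graph(NULL, k = 60, coords = coords)
  fr <- neighbor_fraction(g, states, is_ref, k_check = 50)
  expect_gte(fr[["LMN"]], 0.99)
  expect_equal(fr[["EMN"]], 0)
  expect_error(neighbor_fraction(g, states, is_ref, k_check = 70),
               "k < k_check")
  # no reference cells in the graph -> all zero
  fr0 <- neighbor_fraction(g, states, rep(FALSE, 260), k_check = 50)
  expect_true(all(fr0 == 0))
})
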