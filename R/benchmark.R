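#' Run the two-protocol recovery benchmark
#'
#' Generates the package's reference synthetic study — two protocols over a
#' 2000-gene universe, six state programs (shared ESC start and LMN
#' terminus, distinct intermediates), 200 cells per state at ~2000 UMIs per
#' cell — runs the full pipeline on each protocol, and measures how well the
#' planted structure is recovered:
#' density clustering vs ground truth (adjusted Rand index), cross-protocol
#' maximum-likelihood assignment of shared-state cells, and the
#' bifurcate-reconverge signature in the centroid cosine-similarity matrix.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_genes,n_markers,marker_boost Design of the gene universe.
#' @param cells_per_state Cells simulated per state and protocol.
#' @param depth Median UMIs per cell (lognormal meanlog = log(depth)).
#' @param n_hvg,n_randomizations Feature-selection parameters.
#' @return List: `ari` (named, per protocol), `shared_assign_frac` (fraction
#'   of DP cells from shared states ML-assigned to the matching SP state),
#'   `similarity` (DP x SP centroid cosine matrix in the combined PV space),
#'   `row_max_ok` (shared-state rows peak at their partners),
#'   `max_intermediate_sim` (largest cosine between distinct intermediates),
#'   and the per-protocol cluster labels and truth for reuse.
#' @export
recovery_benchmark <- function(seed = 1, n_genes = 2000, n_markers = 20,
                               marker_boost = 30, cells_per_state = 200,
                               depth = 2000, n_hvg = 1000,
                               n_randomizations = 5) {
  design <- two_protocol_design(n_genes = n_genes, n_markers = n_markers,
                                marker_boost = marker_boost)
  lib <- c(meanlog = log(depth), sdlog = 0.4)
  mk_spec <- function(states, protocol, s)
    synthetic_spec(trajectory_topology(design$programs[states],
                                       shared_states = design$shared),
                   cells_per_state = cells_per_state, library_size = lib,
                   protocol = protocol, seed = s)
  ex <- generate_two_protocol_experiment(
    mk_spec(design$dp_states, "DP", seed),
    mk_spec(design$sp_states, "SP", seed + 1L),
    design$shared)

  per_protocol <- lapply(c(dp = "dp", sp = "sp"), function(p) {
    cm <- ex[[p]]
    norm <- total_count_normalize(cm)
    hvg <- select_variable_genes(norm, n_hvg)
    model <- select_principal_variable_genes(
      norm, hvg, n_randomizations = n_randomizations, seed = seed)
    z <- zscore_transform(norm, model)
    coords <- embed_tsne(z, max(1, model$n_nontrivial), seed = seed)
    labels <- density_cluster(coords)
    list(cm = cm, norm = norm, model = model, labels = labels,
         truth = cm$cell_meta$true_state)
  })
  ari <- vapply(per_protocol, function(r)
    adjusted_rand_index(r$labels, r$truth), numeric(1))

  # cross-protocol ML assignment, parameter-recovery mode: SP ground-truth
  # states define the reference profiles, DP cells are queries
  genes <- ex$dp$gene_ids
  norm_all <- total_count_normalize(
    count_matrix(rbind(ex$dp$counts, ex$sp$counts),
                 c(ex$dp$cell_ids, ex$sp$cell_ids), genes))
  hvg_all <- select_variable_genes(norm_all, n_hvg)
  model_all <- select_principal_variable_genes(
    norm_all, hvg_all, n_randomizations = n_randomizations, seed = seed)
  prof <- reference_profiles(ex$sp, ex$sp$cell_meta$true_state,
                             genes = model_all$pv_gene_ids)
  assign <- ml_assign_cells(ex$dp, prof)
  shared_cells <- ex$dp$cell_meta$true_state %in% design$shared
  shared_assign_frac <- mean(
    assign$assignment[shared_cells] ==
      ex$dp$cell_meta$true_state[shared_cells], na.rm = TRUE)

  # centroid cosine similarity in the combined PV space
  z_all <- zscore_transform(norm_all, model_all)
  n_dp <- nrow(ex$dp$counts)
  cen_dp <- cluster_centroids(z_all[seq_len(n_dp), , drop = FALSE],
                              ex$dp$cell_meta$true_state)
  cen_sp <- cluster_centroids(z_all[-seq_len(n_dp), , drop = FALSE],
                              ex$sp$cell_meta$true_state)
  sim <- centroid_cosine_similarity(cen_dp, cen_sp)
  row_max_ok <- all(vapply(design$shared, function(s)
    colnames(sim)[which.max(sim[s, ])] == s, logical(1)))
  dp_int <- setdiff(rownames(sim), design$shared)
  sp_int <- setdiff(colnames(sim), design$shared)
  max_intermediate_sim <- max(sim[dp_int, sp_int])

  list(ari = ari, shared_assign_frac = shared_assign_frac,
       similarity = sim, row_max_ok = row_max_ok,
       max_intermediate_sim = max_intermediate_sim,
       per_protocol = per_protocol, design = design)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells;
#' 1 means identical partitions, 0 the expectation under random labels.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)
  (sij - expected) / (max_index - expected)
}

#' Null calibration and power of the differential-expression test
#'
#' Runs `n_runs` seeded null splits — each an i.i.d. one-state multinomial
#' dataset split in half — through [de_test()], recording how many eligible
#' genes reach `q < 0.05`, and one power check in which a 10-fold marker is
#' planted and must be detected under all three filter presets.
#'
#' @param n_runs Number of null splits (default 200).
#' @param n_cells,n_genes,depth Size of each null dataset.
#' @param seed Base seed; run r uses `seed + r`.
#' @return List: `total_calls`, `total_eligible`, `call_rate`,
#'   `runs_over_nominal` (runs with more than 5% calls), and
#'   `planted_detected` (named logical per preset).
#' @export
null_calibration <- function(n_runs = 200, n_cells = 60, n_genes = 200,
                             depth = 500, seed = 1) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  p <- stats::setNames(rep(1 / n_genes, n_genes), genes)
  topo <- trajectory_topology(list(state_program("ESC", p)))
  total_calls <- 0L
  total_eligible <- 0L
  runs_over <- 0L
  half <- n_cells %/% 2
  for (r in seq_len(n_runs)) {
    cm <- generate_counts(synthetic_spec(
      topo, cells_per_state = n_cells,
      library_size = c(meanlog = log(depth), sdlog = 0), seed = seed + r))
    norm <- total_count_normalize(cm, depth)
    res <- de_test(norm, seq_len(half), half + seq_len(n_cells - half))
    calls <- sum(res$q_value < 0.05, na.rm = TRUE)
    elig <- sum(res$eligible)
    total_calls <- total_calls + calls
    total_eligible <- total_eligible + elig
    if (calls > 0.05 * elig) runs_over <- runs_over + 1L
  }

  # power: plant a 10-fold marker at 100 cells/group
  set.seed(seed)
  mat <- matrix(stats::rpois(200 * n_genes, 2), 200, n_genes,
                dimnames = list(sprintf("c%03d", 1:200), genes))
  mat[1:100, 1] <- stats::rpois(100, 20)
  normp <- total_count_normalize(count_matrix(mat), 2 * n_genes)
  rp <- de_test(normp, 1:100, 101:200)
  marker <- genes[1]
  detected <- c(
    marker = de_pass(rp, "marker")[rp$gene == marker],
    tf6 = de_pass(rp, "tf6", tf_genes = marker)[rp$gene == marker],
    tf4 = de_pass(rp, "tf4", tf_genes = marker)[rp$gene == marker])

  list(total_calls = total_calls, total_eligible = total_eligible,
       call_rate = total_calls / total_eligible,
       runs_over_nominal = runs_over, planted_detected = detected)
}
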