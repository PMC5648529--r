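# Small synthetic fixtures shared across test files. All are built in code,
# seeded, and kept at sizes where tests run in seconds.

toy_universe <- function(n_genes = 50, prefix = "g") {
  sprintf("%s%03d", prefix, seq_len(n_genes))
}

# A single-state program with `boost`-fold enriched markers on `marker_idx`.
toy_program <- function(name, n_genes = 50, marker_idx = 1:5, boost = 20) {
  genes <- toy_universe(n_genes)
  w <- rep(1, n_genes)
  w[marker_idx] <- boost
  state_program(name, setNames(w / sum(w), genes), genes[marker_idx])
}

# Two well-separated states over disjoint marker blocks.
toy_two_state_spec <- function(n_cells = 100, n_genes = 200, depth = 1000,
                               doublet_rate = 0, stress_rate = 0,
                               mito_genes = character(), seed = 42) {
  k <- min(20, n_genes %/% 2)
  a <- toy_program("ESC", n_genes, seq_len(k), boost = 30)
  b <- toy_program("LMN", n_genes, k + seq_len(k), boost = 30)
  topo <- trajectory_topology(list(a, b))
  synthetic_spec(topo, cells_per_state = n_cells,
                 library_size = c(meanlog = log(depth), sdlog = 0.3),
                 doublet_rate = doublet_rate, stress_rate = stress_rate,
                 mito_genes = mito_genes, seed = seed)
}

# Normalized matrix straight from a count matrix (no filtering).
toy_normalized <- function(cm, target = 1000) {
  total_count_normalize(cm, target)
}

# i.i.d. one-state matrix for null checks.
toy_null_counts <- function(n_cells = 60, n_genes = 200, depth = 500,
                            seed = 7) {
  genes <- toy_universe(n_genes)
  p <- setNames(rep(1 / n_genes, n_genes), genes)
  topo <- trajectory_topology(list(state_program("ESC", p)))
  generate_counts(synthetic_spec(topo, cells_per_state = n_cells,
                                 library_size = c(meanlog = log(depth),
                                                  sdlog = 0),
                                 seed = seed))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
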