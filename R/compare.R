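#' Build a k-nearest-neighbor graph over cells
#'
#' Follows the SPRING recipe: optionally filter to genes with mean
#' expression > 0.02 counts/cell and Fano factor > 2, z-score, reduce to a
#' (at most) 50-dimensional PCA space, and connect each cell to its `k`
#' nearest Euclidean neighbors there.
#'
#' @param m A [normalized_matrix()] on a counts-per-cell scale.
#' @param k Neighbors per cell (`k < n_cells`).
#' @param spring_gene_filter Apply the mean/Fano gene filter (default TRUE).
#' @param n_dims Maximum PCA dimensionality (default 50).
#' @param coords Optional precomputed coordinates (cells x dims); when given
#'   the gene filter and PCA are skipped and neighbors are found in this
#'   space directly.
#' @return An object of class `neighbor_graph`: `k`, `metric`, `idx`
#'   (cells x k neighbor indices, distance-sorted), `dist` (matching
#'   distances), `coords` (the space searched), and `space` (provenance:
#'   genes kept, dimensionality).
#' @export
build_knn_graph <- function(m, k = 20, spring_gene_filter = TRUE,
                            n_dims = 50, coords = NULL) {
  if (is.null(coords)) {
    stopifnot(inherits(m, "normalized_matrix"))
    x <- m$values
    genes <- colnames(x)
    if (spring_gene_filter) {
      mu <- colMeans(x)
      v <- apply(x, 2, stats::var)
      fano <- ifelse(mu > 0, v / mu, 0)
      keep <- mu > 0.02 & fano > 2
      if (!any(keep)) stop("no genes pass the mean/Fano filter")
      x <- x[, keep, drop = FALSE]
      genes <- colnames(x)
    }
    z <- scale(x)
    z[, attr(z, "scaled:scale") == 0] <- 0
    d <- min(n_dims, nrow(z) - 1, ncol(z))
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = d)
    coords <- pc$x
    space <- list(genes = genes, n_dims = d)
  } else {
    coords <- as.matrix(coords)
    space <- list(genes = NULL, n_dims = ncol(coords))
  }
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- FNN::get.knn(coords, k = k)
  structure(list(k = k, metric = "euclidean",
                 idx = nn$nn.index, dist = nn$nn.dist,
                 coords = coords, space = space,
                 cell_ids = rownames(coords)),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d cells, k = %d, %d-dim %s space\n",
              nrow(x$idx), x$k, x$space$n_dims, x$metric))
  invisible(x)
}

#' Force-directed layout of a neighbor graph
#'
#' Fruchterman-Reingold layout of the kNN graph with seeded initialization:
#' edges act as springs pulling similar cells together while nodes repel,
#' revealing the topology of the high-dimensional cell graph. Disconnected
#' components are laid out separately and tiled side by side so their
#' bounding boxes never overlap.
#'
#' @param g A `neighbor_graph`.
#' @param seed Integer seed; fixing it fixes the coordinates.
#' @param niter Iterations of the layout.
#' @return Numeric matrix (cells x 2).
#' @export
force_layout <- function(g, seed = 1L, niter = 500) {
  stopifnot(inherits(g, "neighbor_graph"))
  n <- nrow(g$idx)
  edges <- cbind(rep(seq_len(n), times = g$k), as.vector(g$idx))
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  ig <- igraph::simplify(ig)
  comp <- igraph::components(ig)
  coords <- matrix(0, n, 2)
  offset <- 0
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(ig, vs)
    set.seed(seed + ci)
    init <- matrix(stats::rnorm(2 * length(vs)), ncol = 2)
    xy <- igraph::layout_with_fr(sub, coords = init, niter = niter)
    xy <- sweep(xy, 2, apply(xy, 2, min))          # shift to positive quadrant
    coords[vs, ] <- cbind(xy[, 1] + offset, xy[, 2])
    offset <- offset + max(xy[, 1]) + 0.2 * (diff(range(xy[, 1])) + 1) + 1
  }
  rownames(coords) <- g$cell_ids
  coords
}

#' Cluster centroids in a feature space
#'
#' The centroid — mean position in gene-expression space — averages over
#' single-cell noise and estimates a state's global expression.
#'
#' @param z Numeric matrix (cells x features), typically z-scored PV genes.
#' @param labels Cluster/state label per cell (`NA` or `-1` skipped).
#' @return An object of class `centroid_set`: `centroids` (clusters x
#'   features) and `n_cells` per cluster.
#' @export
cluster_centroids <- function(z, labels) {
  z <- as.matrix(z)
  keep <- !is.na(labels) & labels != -1
  labs <- unique(labels[keep])
  cen <- t(vapply(labs, function(l) colMeans(z[keep & labels == l, ,
                                               drop = FALSE]),
                  numeric(ncol(z))))
  rownames(cen) <- as.character(labs)
  structure(list(centroids = cen,
                 n_cells = stats::setNames(
                   as.integer(table(labels[keep])[as.character(labs)]),
                   as.character(labs))),
            class = "centroid_set")
}

#' Pairwise cosine similarity between two centroid sets
#'
#' @param a,b `centroid_set`s in the same feature space (same columns);
#'   typically built from z-scored PV genes extracted on the combined cells.
#' @return Matrix of cosine similarities in \[-1, 1\], rows = clusters of
#'   `a`, columns = clusters of `b`. Zero-norm centroids yield `NA` entries
#'   with a warning.
#' @export
centroid_cosine_similarity <- function(a, b) {
  stopifnot(inherits(a, "centroid_set"), inherits(b, "centroid_set"),
            ncol(a$centroids) == ncol(b$centroids))
  na <- sqrt(rowSums(a$centroids^2))
  nb <- sqrt(rowSums(b$centroids^2))
  sim <- (a$centroids %*% t(b$centroids)) / outer(na, nb)
  if (any(na == 0) || any(nb == 0))
    warning("zero-norm centroid: undefined similarity entries set to NA")
  sim[!is.finite(sim)] <- NA_real_
  sim
}

#' Reference gene-probability profiles for likelihood assignment
#'
#' For each reference cluster, the probability of observing a gene is its
#' fraction of the cluster's pooled counts over the comparison gene set.
#' Genes undetected in a cluster receive a pseudo-total of `pseudo_total`
#' counts before renormalization, so no gene has probability zero.
#'
#' @param counts A [count_matrix()] of the reference cells.
#' @param labels Reference cluster/state label per cell.
#' @param genes Comparison gene set (default all genes; typically PV genes).
#' @param pseudo_total Pseudo-counts added to undetected genes (1e-07).
#' @return Matrix (clusters x genes) of probabilities, rows summing to 1.
#' @export
reference_profiles <- function(counts, labels, genes = counts$gene_ids,
                               pseudo_total = 1e-07) {
  stopifnot(inherits(counts, "count_matrix"))
  genes <- intersect(genes, counts$gene_ids)
  labs <- unique(labels[!is.na(labels)])
  prof <- t(vapply(labs, function(l)
    colSums(counts$counts[labels == l & !is.na(labels), genes,
                          drop = FALSE]),
    numeric(length(genes))))
  prof[prof == 0] <- pseudo_total
  prof <- prof / rowSums(prof)
  rownames(prof) <- as.character(labs)
  prof
}

#' Maximum-likelihood assignment of cells to reference states
#'
#' Treats each cell's counts as a multinomial sample and computes, per
#' reference cluster k, the log-likelihood `l(c|k) = sum_g x_cg log p_kg`
#' (the multinomial coefficient, constant across clusters for a given
#' cell, is omitted; see Details). Cells are assigned to the argmax cluster;
#' exact ties are reported and contribute fractionally to the tally.
#'
#' @details Because the multinomial coefficient `log(n!/(x_1!...x_g!))`
#' does not depend on the cluster, omitting it changes every cluster's
#' log-likelihood for a cell by the same per-cell constant and leaves the
#' assignment unchanged; reported log-likelihoods are therefore comparable
#' across clusters but not absolute log-probabilities.
#'
#' @param query A [count_matrix()] of cells to classify.
#' @param profiles Reference profile matrix from [reference_profiles()]
#'   (clusters x genes); the gene set defines the comparison space.
#' @return An object of class `likelihood_assignment`: `loglik` (cells x
#'   clusters, nats), `assignment` (argmax cluster per cell, `NA` for
#'   unassignable cells with zero counts on the gene set), `tie` (logical),
#'   `tally` (percentage of assignable cells per cluster, summing to 100;
#'   tied cells split equally), `n_unassignable`.
#' @export
ml_assign_cells <- function(query, profiles) {
  stopifnot(inherits(query, "count_matrix"))
  genes <- colnames(profiles)
  miss <- setdiff(genes, query$gene_ids)
  if (length(miss)) stop("query lacks comparison genes: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  x <- query$counts[, genes, drop = FALSE]
  ll <- x %*% t(log(profiles))          # cells x clusters
  tot <- rowSums(x)
  clusters <- rownames(profiles)
  assignment <- rep(NA_character_, nrow(x))
  tie <- rep(FALSE, nrow(x))
  weights <- matrix(0, nrow(x), nrow(profiles),
                    dimnames = list(NULL, clusters))
  for (i in seq_len(nrow(x))) {
    if (tot[i] == 0) next
    best <- max(ll[i, ])
    winners <- which(ll[i, ] >= best - 1e-9 * abs(best))
    assignment[i] <- clusters[winners[1]]
    tie[i] <- length(winners) > 1
    weights[i, winners] <- 1 / length(winners)
  }
  assignable <- tot > 0
  tally <- if (any(assignable))
    100 * colSums(weights[assignable, , drop = FALSE]) / sum(assignable)
  else stats::setNames(rep(NA_real_, length(clusters)), clusters)
  structure(list(loglik = ll, assignment = assignment, tie = tie,
                 tally = tally, n_unassignable = sum(!assignable),
                 genes = genes),
            class = "likelihood_assignment")
}

#' @export
print.likelihood_assignment <- function(x, ...) {
  cat(sprintf("likelihood_assignment: %d cells over %d clusters (%d ties, %d unassignable)\n",
              nrow(x$loglik), ncol(x$loglik), sum(x$tie), x$n_unassignable))
  print(round(x$tally, 2))
  invisible(x)
}

#' Label-transfer decision rule for one neighbor configuration
#'
#' A query cell is accepted when at least `accept_min` of its `k` reference
#' nearest neighbors carry a target state; accepted cells are labelled
#' `EMN` only on a strict majority of EMN among the target-state neighbors,
#' and `LMN` otherwise (majority LMN, or an EMN/LMN tie). The tie rule
#' deliberately favors LMN.
#'
#' @param neighbor_states Character vector of the k nearest reference
#'   neighbors' states, nearest first (order is irrelevant to the rule).
#' @param target_states States eligible for transfer.
#' @param accept_min Minimum number of target-state neighbors.
#' @return List: `accepted` (logical), `label` (`"EMN"`, `"LMN"`, or `NA`).
#' @export
transfer_rule <- function(neighbor_states, target_states = c("EMN", "LMN"),
                          accept_min = 3) {
  in_target <- neighbor_states %in% target_states
  if (sum(in_target) < accept_min)
    return(list(accepted = FALSE, label = NA_character_))
  n_emn <- sum(neighbor_states == "EMN")
  n_lmn <- sum(neighbor_states == "LMN")
  list(accepted = TRUE, label = if (n_emn > n_lmn) "EMN" else "LMN")
}

#' Project query cells into a reference PC space and transfer labels
#'
#' Query cells are z-scored with the reference model's stored per-gene
#' parameters, projected with the reference PC loadings, and labelled by
#' their `k` nearest reference cells under [transfer_rule()]: integrate
#' replicate cells by accepting those with at least `accept_min` of `k`
#' neighbors in the target states.
#'
#' @param query A [normalized_matrix()] of replicate cells sharing the
#'   reference gene universe.
#' @param model The reference `pv_gene_model`.
#' @param reference_coords Reference cells' coordinates in the model's PC
#'   space (as from [pca_project()] on the reference).
#' @param reference_labels State label per reference cell.
#' @param k Nearest neighbors consulted (default 5).
#' @param accept_min Acceptance threshold (default 3).
#' @param target_states States transferred (default EMN/LMN).
#' @return Data frame per query cell: `accepted`, `label`, and
#'   `n_target_neighbors`.
#' @export
project_and_transfer_labels <- function(query, model, reference_coords,
                                        reference_labels, k = 5,
                                        accept_min = 3,
                                        target_states = c("EMN", "LMN")) {
  reference_coords <- as.matrix(reference_coords)
  if (k > nrow(reference_coords)) stop("k exceeds the reference size")
  qc <- pca_project(query, model, n_dims = ncol(reference_coords))
  nn <- FNN::get.knnx(reference_coords, qc, k = k)
  out <- data.frame(accepted = logical(nrow(qc)),
                    label = NA_character_,
                    n_target_neighbors = integer(nrow(qc)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(qc))) {
    st <- reference_labels[nn$nn.index[i, ]]
    r <- transfer_rule(st, target_states, accept_min)
    out$accepted[i] <- r$accepted
    out$label[i] <- r$label
    out$n_target_neighbors[i] <- sum(st %in% target_states)
  }
  rownames(out) <- rownames(query$values)
  out
}

#' Fraction of cells with a reference cell among their nearest neighbors
#'
#' For each named cell state, the fraction of its cells that have at least
#' one reference cell (e.g. a primary motor neuron) among their `k_check`
#' most similar cells in the pooled graph space — a single-cell measure of
#' similarity to the reference population.
#'
#' @param graph A `neighbor_graph` over the pooled cells (terminal states
#'   plus reference) with `k >= k_check`.
#' @param states Character label per pooled cell (the state grouping).
#' @param is_reference Logical per pooled cell: member of the reference set.
#' @param k_check Neighborhood size checked (default 50; must be below the
#'   pooled cell count).
#' @return Named numeric vector: per state, the fraction in \[0, 1\].
#' @export
neighbor_fraction <- function(graph, states, is_reference, k_check = 50) {
  stopifnot(inherits(graph, "neighbor_graph"),
            length(states) == nrow(graph$idx),
            length(is_reference) == nrow(graph$idx))
  if (k_check >= nrow(graph$idx)) stop("k_check must be below the pooled size")
  if (k_check > graph$k) stop("graph was built with k < k_check")
  hit <- vapply(seq_len(nrow(graph$idx)), function(i)
    any(is_reference[graph$idx[i, seq_len(k_check)]]), logical(1))
  query_states <- setdiff(unique(states[!is_reference]), NA)
  vapply(stats::setNames(query_states, query_states), function(s)
    mean(hit[!is.na(states) & states == s & !is_reference]), numeric(1))
}
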