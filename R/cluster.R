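#' Embed cells in two dimensions with tSNE
#'
#' Runs Barnes-Hut tSNE on a z-scored matrix, asking for an initial PCA to a
#' number of dimensions equal to the number of non-trivial principal
#' components, which focuses the embedding on statistically supported
#' structure.
#'
#' @param z Numeric matrix (cells x features), typically z-scored PV genes.
#' @param n_init_dims Initial PCA dimensionality (>= 1).
#' @param seed Integer seed; fixing it fixes the coordinates.
#' @param perplexity tSNE perplexity; shrunk automatically for small inputs.
#' @return Numeric matrix (cells x 2) of coordinates.
#' @export
embed_tsne <- function(z, n_init_dims, seed = 1L, perplexity = 30) {
  z <- as.matrix(z)
  if (nrow(z) < 3) stop("need at least 3 cells to embed")
  if (n_init_dims < 1) stop("n_init_dims must be >= 1")
  n_init_dims <- min(n_init_dims, ncol(z), nrow(z) - 1)
  perplexity <- min(perplexity, floor((nrow(z) - 1) / 3))
  set.seed(seed)
  fit <- Rtsne::Rtsne(z, dims = 2, initial_dims = n_init_dims,
                      pca = TRUE, perplexity = perplexity,
                      check_duplicates = FALSE, verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- rownames(z)
  coords
}

#' Density-based clustering of a 2-D embedding
#'
#' Standard DBSCAN: points with at least `min_pts` neighbors within `eps`
#' are core points; clusters are the connected components of core points
#' under eps-reachability plus their border points; remaining sparse points
#' are labelled noise (`-1`). Defaults are scale-free: `eps` is 5% of the
#' bounding-box diagonal and `min_pts` is `max(5, 0.2%)` of the cells.
#'
#' @param coords Numeric matrix (cells x 2) of finite coordinates.
#' @param eps Neighborhood radius (> 0).
#' @param min_pts Core-point neighbor threshold (neighborhood includes the
#'   point itself).
#' @return Integer vector of cluster ids (1, 2, ...), `-1` for noise.
#' @export
density_cluster <- function(coords, eps = NULL, min_pts = NULL) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  n <- nrow(coords)
  if (is.null(eps)) {
    span <- apply(coords, 2, function(v) diff(range(v)))
    eps <- 0.05 * sqrt(sum(span^2))
    if (eps == 0) eps <- 1e-9  # all points identical
  }
  if (eps <= 0) stop("eps must be > 0")
  if (is.null(min_pts)) min_pts <- max(5, ceiling(0.002 * n))

  d <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts

  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == -1L])
      }
    }
  }
  labels
}

#' Flag doublet cell groups on a neighbor graph
#'
#' Doublets — droplets that captured two cells — are recognized by three
#' criteria: (1) they are rare; (2) they form long-range connections between
#' large cell groups in the same protocol and timepoint; (3) they have no
#' unique marker genes, because their expression is a combination of two
#' other states. Operationally a cluster is flagged when (a) it holds less
#' than `rare_frac` of the cells, (b) its kNN edges connect at least two
#' clusters each at least `size_factor` times its size (within the same
#' protocol/day when metadata is available), and (c) every gene enriched in
#' it (Welch t-test vs the rest, BH `q < 0.05`, higher mean) is expressed in
#' one of the connected clusters at `>= explain_frac` of the flagged group's
#' mean.
#'
#' @param graph A `neighbor_graph` (see [build_knn_graph()]) over the cells.
#' @param labels Integer cluster ids per cell. Noise cells (`-1`) are grouped
#'   by their connected components in the kNN subgraph and those groups are
#'   screened by the same criteria — doublets between well-separated states
#'   typically fall outside any dense cluster.
#' @param norm A [normalized_matrix()] over the same cells, used for the
#'   marker criterion.
#' @param cell_meta Optional data frame with `protocol` and `day` to restrict
#'   criterion (b) to same-sample connections.
#' @param rare_frac Maximum cluster fraction considered rare (default 0.03,
#'   the scale of doublet rates in droplet data).
#' @param size_factor Minimum size ratio of the connected clusters.
#' @param explain_frac Fraction of the group mean a connected cluster must
#'   reach for an enriched gene to count as explained.
#' @return Logical doublet flag per cell.
#' @export
remove_doublets <- function(graph, labels, norm, cell_meta = NULL,
                            rare_frac = 0.03, size_factor = 10,
                            explain_frac = 0.5) {
  stopifnot(inherits(graph, "neighbor_graph"),
            inherits(norm, "normalized_matrix"),
            length(labels) == nrow(norm$values))
  n <- length(labels)
  flags <- rep(FALSE, n)
  sizes <- table(labels[labels != -1L])

  # candidate groups: every cluster, plus connected components of noise
  # cells in the kNN subgraph
  groups <- lapply(as.integer(names(sizes)), function(cl) which(labels == cl))
  noise <- which(labels == -1L)
  if (length(noise) > 1) {
    edges <- cbind(rep(seq_len(n), times = ncol(graph$idx)),
                   as.vector(graph$idx))
    edges <- edges[edges[, 1] %in% noise & edges[, 2] %in% noise, ,
                   drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(match(edges, noise), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(noise) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    groups <- c(groups, split(noise, comp))
  } else if (length(noise) == 1) {
    groups <- c(groups, list(noise))
  }

  for (members in groups) {
    if (length(members) >= rare_frac * n) next          # (1) not rare
    cl_id <- labels[members[1]]

    # (2) kNN edges into other, much larger clusters
    nbr <- graph$idx[members, , drop = FALSE]
    nbr_lab <- labels[as.vector(nbr)]
    ok_sample <- rep(TRUE, length(nbr_lab))
    if (!is.null(cell_meta) && all(c("protocol", "day") %in% names(cell_meta))) {
      src <- rep(members, times = ncol(nbr))
      dst <- as.vector(nbr)
      ok_sample <- cell_meta$protocol[src] == cell_meta$protocol[dst] &
        cell_meta$day[src] == cell_meta$day[dst]
    }
    ext <- nbr_lab[ok_sample & nbr_lab != cl_id & nbr_lab != -1L]
    if (!length(ext)) next
    connected <- as.integer(names(table(ext)))
    connected <- connected[sizes[as.character(connected)] >=
                             size_factor * length(members)]
    if (length(connected) < 2) next

    # keep the two most-connected qualifying clusters
    tab <- table(ext)
    tab <- tab[as.character(connected)]
    parents <- as.integer(names(sort(tab, decreasing = TRUE)))[1:2]

    # (3) no unique markers: every enriched gene explained by a parent
    enr <- character()
    if (length(members) >= 2) {
      de <- de_test(norm, members, setdiff(seq_len(n), members))
      enr <- de$gene[!is.na(de$q_value) & de$q_value < 0.05 &
                       de$mean_a > de$mean_b]
    }
    if (length(enr)) {
      grp_mean <- colMeans(norm$values[members, enr, drop = FALSE])
      p_mean <- sapply(parents, function(p)
        colMeans(norm$values[labels == p, enr, drop = FALSE]))
      p_mean <- matrix(p_mean, nrow = length(enr))
      explained <- apply(p_mean, 1, max) >= explain_frac * grp_mean
      if (!all(explained)) next
    }
    flags[members] <- TRUE
  }
  flags
}
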