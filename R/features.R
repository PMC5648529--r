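#' Rank and select highly variable genes
#'
#' Genes are ranked by excess variability: the Fano factor (variance/mean) of
#' their normalized expression relative to the typical Fano factor of genes
#' with a matched mean. Means are split into `n_bins` quantile bins and each
#' gene's Fano factor is divided by its bin's baseline — the bin median,
#' capped at the dataset-wide median so that bins filled with genuinely
#' variable genes cannot mask each other — so the purely technical
#' mean-variance trend cancels and genes that vary between cell populations
#' rise to the top. Deterministic given the input.
#'
#' @param m A [normalized_matrix()].
#' @param n_top Number of genes to return (default 1000). If larger than the
#'   gene universe, all genes are returned with a warning.
#' @param n_bins Number of mean-expression bins for the baseline.
#' @return Character vector of gene ids, ordered by decreasing excess
#'   variability.
#' @export
select_variable_genes <- function(m, n_top = 1000, n_bins = 20) {
  stopifnot(inherits(m, "normalized_matrix"))
  x <- m$values
  if (nrow(x) < 2) stop("need at least 2 cells")
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  v <- v * nrow(x) / (nrow(x) - 1)
  fano <- ifelse(mu > 0, v / mu, 0)
  expressed <- mu > 0
  score <- rep(-Inf, ncol(x))
  if (any(expressed)) {
    qs <- unique(stats::quantile(mu[expressed],
                                 probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- cut(mu[expressed], breaks = qs, include.lowest = TRUE)
    # After total-count normalization the technical Fano baseline is nearly
    # flat in the mean, so a bin median far above the dataset-wide median
    # signals a bin dominated by genuinely variable genes (e.g. a shared
    # marker block); cap the baseline there so such genes are not masked.
    global_med <- stats::median(fano[expressed])
    base <- stats::ave(fano[expressed], bin,
                       FUN = function(z) max(min(stats::median(z),
                                                 global_med), 1e-12))
    score[expressed] <- fano[expressed] / base
  }
  genes <- colnames(x)
  if (n_top > length(genes)) {
    warning(sprintf("n_top = %d exceeds gene count %d; returning all genes",
                    n_top, length(genes)))
    n_top <- length(genes)
  }
  genes[order(-score)][seq_len(n_top)]
}

zscore_columns <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  list(z = sweep(sweep(x, 2, mu, "-"), 2, sd, "/"), mean = mu, sd = sd)
}

#' Select principal variable genes
#'
#' Fits PCA to the z-scored highly-variable-gene matrix and keeps only the
#' statistically non-trivial components: the leading components whose
#' eigenvalues exceed the maximum same-rank eigenvalue observed over
#' `n_randomizations` datasets in which each gene's values are independently
#' permuted across cells (a null that preserves per-gene marginals exactly
#' while destroying gene-gene covariation); retention stops at the first
#' component inside the null band. The principal variable (PV)
#' genes are those whose absolute loading on any non-trivial component
#' exceeds that component's `loading_quantile` quantile of absolute
#' loadings.
#'
#' @param m A [normalized_matrix()].
#' @param hvg Character vector of highly variable gene ids (see
#'   [select_variable_genes()]).
#' @param n_randomizations Number of permutation null datasets (default 10;
#'   taking the max over more randomizations can only shrink the retained
#'   set).
#' @param loading_quantile Per-component quantile for the loading threshold
#'   (default 0.90).
#' @param seed Seed for the permutations.
#' @return An object of class `pv_gene_model`: `hvg_ids`, `zscore_params`
#'   (per-gene mean and sd over cells), `pc_loadings` (genes x components),
#'   `eigenvalues`, `null_eigenvalues` (max per rank), `n_nontrivial`,
#'   `loading_quantile`, `pv_gene_ids`.
#' @export
select_principal_variable_genes <- function(m, hvg, n_randomizations = 10,
                                            loading_quantile = 0.90,
                                            seed = 1L) {
  stopifnot(inherits(m, "normalized_matrix"),
            length(hvg) > 0, n_randomizations >= 1)
  miss <- setdiff(hvg, colnames(m$values))
  if (length(miss)) stop("hvg genes absent from matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  x <- m$values[, hvg, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance genes before z-scoring",
                    sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  zs <- zscore_columns(x)
  z <- zs$z
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  k_max <- length(ev)

  set.seed(seed)
  null_ev <- matrix(0, nrow = n_randomizations, ncol = k_max)
  for (r in seq_len(n_randomizations)) {
    zp <- apply(z, 2, sample)
    sv <- svd(zp, nu = 0, nv = 0)
    null_ev[r, ] <- (sv$d^2 / (nrow(z) - 1))[seq_len(k_max)]
  }
  null_max <- apply(null_ev, 2, max)
  # Components are ordered by eigenvalue, so the statistically supported set
  # is the leading block: stop at the first component that falls within the
  # permutation null band. (Testing every rank in isolation would flag
  # ~1/(n_randomizations+1) of the deep, pure-noise ranks by exchangeability.)
  exceeds <- ev > null_max
  n_nontrivial <- if (all(exceeds)) length(ev) else which(!exceeds)[1] - 1L
  nontrivial <- seq_len(n_nontrivial)

  pv <- character()
  if (n_nontrivial > 0) {
    for (k in nontrivial) {
      ld <- abs(pc$rotation[, k])
      pv <- union(pv, names(ld)[ld > stats::quantile(ld, loading_quantile)])
    }
    pv <- colnames(z)[colnames(z) %in% pv]   # stable gene order
  }
  structure(list(hvg_ids = colnames(z),
                 zscore_params = list(mean = zs$mean, sd = zs$sd),
                 pc_loadings = pc$rotation,
                 eigenvalues = ev, null_eigenvalues = null_max,
                 nontrivial_components = nontrivial,
                 n_nontrivial = as.integer(n_nontrivial),
                 loading_quantile = loading_quantile,
                 pv_gene_ids = pv),
            class = "pv_gene_model")
}

#' @export
print.pv_gene_model <- function(x, ...) {
  cat(sprintf("pv_gene_model: %d HVGs, %d non-trivial PCs, %d PV genes\n",
              length(x$hvg_ids), x$n_nontrivial, length(x$pv_gene_ids)))
  invisible(x)
}

#' Z-score a matrix with a fitted model's parameters
#'
#' Applies the per-gene means and standard deviations stored in a
#' [select_principal_variable_genes()] model. Using the training parameters
#' on new cells projects them into the reference feature space.
#'
#' @param m A [normalized_matrix()] sharing the model's gene universe.
#' @param model A `pv_gene_model`.
#' @param genes Genes to return (default the model's PV genes; use
#'   `model$hvg_ids` for the full fitted set).
#' @return Numeric matrix (cells x genes) of z-scores.
#' @export
zscore_transform <- function(m, model, genes = model$pv_gene_ids) {
  stopifnot(inherits(m, "normalized_matrix"), inherits(model, "pv_gene_model"))
  miss <- setdiff(genes, colnames(m$values))
  if (length(miss))
    stop("genes missing from matrix: ", paste(miss, collapse = ", "))
  miss_fit <- setdiff(genes, model$hvg_ids)
  if (length(miss_fit))
    stop("genes not covered by the fitted model: ",
         paste(miss_fit, collapse = ", "))
  x <- m$values[, genes, drop = FALSE]
  sweep(sweep(x, 2, model$zscore_params$mean[genes], "-"),
        2, model$zscore_params$sd[genes], "/")
}

#' Project cells onto a model's principal components
#'
#' Z-scores `m` over the model's fitted gene set with the stored training
#' parameters and multiplies by the stored loadings, yielding coordinates in
#' the reference PC space (used e.g. for label transfer of replicate cells).
#'
#' @inheritParams zscore_transform
#' @param n_dims Number of leading components (default: the non-trivial
#'   count, or all components if none are non-trivial).
#' @return Numeric matrix (cells x `n_dims`).
#' @export
pca_project <- function(m, model, n_dims = NULL) {
  if (is.null(n_dims))
    n_dims <- if (model$n_nontrivial > 0) model$n_nontrivial
              else ncol(model$pc_loadings)
  n_dims <- min(n_dims, ncol(model$pc_loadings))
  z <- zscore_transform(m, model, genes = model$hvg_ids)
  z %*% model$pc_loadings[, seq_len(n_dims), drop = FALSE]
}
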