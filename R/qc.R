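#' Remove cells below a minimum UMI total
#'
#' Droplet experiments include barcodes whose few counts come from ambient
#' RNA rather than a cell; requiring a minimum number of UMIs per cell
#' removes that signal. Default threshold: 1000 UMIs.
#'
#' @param m A [count_matrix()].
#' @param min_umi Minimum total UMIs for a cell to be retained.
#' @return A [count_matrix()] with exactly the cells whose totals are
#'   `>= min_umi`; the gene set is unchanged. Idempotent.
#' @export
filter_min_counts <- function(m, min_umi = 1000) {
  stopifnot(inherits(m, "count_matrix"), min_umi >= 0)
  subset_cells(m, rowSums(m$counts) >= min_umi)
}

#' Total-count normalize a matrix
#'
#' Scales every cell to a common total so that differences between cells do
#' not reflect capture efficiency or cell size. The target is the median
#' library size by default, which keeps values on a counts-per-cell scale.
#'
#' @param m A [count_matrix()].
#' @param target_total Positive scalar, or `"median"` (median of cell totals).
#' @return A [normalized_matrix()] whose rows each sum to `target_total`.
#' @export
total_count_normalize <- function(m, target_total = "median") {
  stopifnot(inherits(m, "count_matrix"))
  totals <- rowSums(m$counts)
  if (any(totals == 0))
    stop("zero-total cell present; run filter_min_counts first")
  if (identical(target_total, "median")) target_total <- stats::median(totals)
  stopifnot(is.numeric(target_total), target_total > 0)
  vals <- m$counts * (target_total / totals)
  normalized_matrix(vals, target_total,
                    provenance = list(n_cells = nrow(vals),
                                      cell_meta = m$cell_meta,
                                      target = target_total))
}

#' Remove stressed cells by mitochondrial signature
#'
#' Stressed cells express very high levels of a mitochondrial gene set and,
#' in droplet data, appear as a small (<10%) population clustering apart from
#' everything else. A cell is flagged stressed when its mitochondrial count
#' fraction exceeds `mito_threshold`, or — when cluster labels are supplied —
#' when its cluster's median mitochondrial fraction exceeds
#' `cluster_factor` times the dataset median.
#'
#' @param m A [count_matrix()].
#' @param mito_genes Non-empty character vector of mitochondrial gene ids
#'   (intersected with the gene universe).
#' @param cluster_labels Optional integer vector of per-cell cluster ids.
#' @param mito_threshold Per-cell mitochondrial fraction above which a cell
#'   is stressed.
#' @param cluster_factor Multiplier on the dataset median for the
#'   cluster-level rule.
#' @return List with `matrix` (the filtered [count_matrix()]) and `report`,
#'   a `qc_report` recording `n_input_cells`, `n_stressed_removed`,
#'   `n_retained` and the per-cell mito fractions. If more than 10% of cells
#'   are flagged a warning is emitted (stress populations are expected to be
#'   small); removal is still applied.
#' @export
remove_stressed_cells <- function(m, mito_genes, cluster_labels = NULL,
                                  mito_threshold = 0.25, cluster_factor = 3) {
  stopifnot(inherits(m, "count_matrix"))
  if (!length(mito_genes)) stop("empty mitochondrial gene panel")
  present <- intersect(mito_genes, m$gene_ids)
  if (!length(present)) stop("no mitochondrial panel gene found in the data")
  totals <- rowSums(m$counts)
  mito <- rowSums(m$counts[, present, drop = FALSE])
  frac <- ifelse(totals > 0, mito / totals, 0)
  stressed <- frac > mito_threshold
  if (!is.null(cluster_labels)) {
    stopifnot(length(cluster_labels) == nrow(m$counts))
    med_all <- stats::median(frac)
    for (cl in unique(cluster_labels)) {
      in_cl <- cluster_labels == cl
      if (med_all > 0 && stats::median(frac[in_cl]) > cluster_factor * med_all)
        stressed[in_cl] <- TRUE
    }
  }
  if (mean(stressed) > 0.10)
    warning(sprintf("%.1f%% of cells flagged stressed (>10%% expected ceiling)",
                    100 * mean(stressed)))
  report <- qc_report(n_input_cells = nrow(m$counts), n_below_min_umi = 0L,
                      n_stressed_removed = sum(stressed),
                      n_retained = sum(!stressed),
                      mito_fraction_per_cell = frac)
  list(matrix = subset_cells(m, !stressed), report = report)
}

#' QC accounting report
#'
#' @param n_input_cells,n_below_min_umi,n_stressed_removed,n_retained
#'   Integers partitioning the input cells
#'   (`n_input = n_below_min_umi + n_stressed_removed + n_retained`).
#' @param mito_fraction_per_cell Numeric vector in \[0, 1\].
#' @return An object of class `qc_report`.
#' @export
qc_report <- function(n_input_cells, n_below_min_umi, n_stressed_removed,
                      n_retained, mito_fraction_per_cell = numeric()) {
  if (n_input_cells != n_below_min_umi + n_stressed_removed + n_retained)
    stop("qc_report partition identity violated")
  if (length(mito_fraction_per_cell) &&
      (any(mito_fraction_per_cell < 0) || any(mito_fraction_per_cell > 1)))
    stop("mito fractions must lie in [0, 1]")
  structure(list(n_input_cells = n_input_cells,
                 n_below_min_umi = n_below_min_umi,
                 n_stressed_removed = n_stressed_removed,
                 n_retained = n_retained,
                 mito_fraction_per_cell = mito_fraction_per_cell),
            class = "qc_report")
}

#' Run the full clean-up: UMI filter, stressed-cell removal, normalization
#'
#' Applies the three clean-up steps in the fixed order minimum-UMI filter,
#' stressed-cell removal, total-count normalization, so that normalization
#' sees the final cell set.
#'
#' @inheritParams filter_min_counts
#' @inheritParams remove_stressed_cells
#' @inheritParams total_count_normalize
#' @return List with `counts` (filtered [count_matrix()]), `normalized`
#'   (a [normalized_matrix()]), and `report` (a `qc_report` whose
#'   partition covers the original input).
#' @export
qc_pipeline <- function(m, min_umi = 1000, mito_genes = NULL,
                        target_total = "median", mito_threshold = 0.25) {
  n0 <- nrow(m$counts)
  filtered <- filter_min_counts(m, min_umi)
  n_low <- n0 - nrow(filtered$counts)
  if (!is.null(mito_genes) && length(intersect(mito_genes, m$gene_ids))) {
    st <- remove_stressed_cells(filtered, mito_genes,
                                mito_threshold = mito_threshold)
    filtered <- st$matrix
    n_st <- st$report$n_stressed_removed
    frac <- st$report$mito_fraction_per_cell
  } else {
    n_st <- 0L
    frac <- numeric()
  }
  report <- qc_report(n0, n_low, n_st, nrow(filtered$counts), frac)
  list(counts = filtered,
       normalized = total_count_normalize(filtered, target_total),
       report = report)
}
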