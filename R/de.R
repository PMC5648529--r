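#' Differential expression between two cell groups
#'
#' Per-gene two-tailed Welch (unequal-variance) t-tests on normalized
#' expression, with Benjamini-Hochberg FDR correction. Only genes where at
#' least one group has `min_nonzero` (default 10) cells with non-zero
#' expression are eligible; ineligible genes are reported with `NA`
#' p/q-values and never called. Fold ratios use a pseudocount of
#' `pseudocount` counts/cell so genes silent in one group stay finite;
#' such genes carry a `capped` flag.
#'
#' @param m A [normalized_matrix()].
#' @param group_a,group_b Disjoint cell index vectors (integer, logical, or
#'   barcode character), each with at least 2 cells.
#' @param restrict_to Optional gene panel (character) to test within, e.g. a
#'   transcription-factor whitelist.
#' @param min_nonzero Eligibility threshold on non-zero cells.
#' @param pseudocount Added to both means in the fold ratio.
#' @return Data frame of class `de_result` with columns `gene`, `mean_a`,
#'   `mean_b`, `fold_ratio` (a over b), `p_value`, `q_value`,
#'   `n_nonzero_a`, `n_nonzero_b`, `eligible`, `capped`.
#' @export
de_test <- function(m, group_a, group_b, restrict_to = NULL,
                    min_nonzero = 10, pseudocount = 0.01) {
  stopifnot(inherits(m, "normalized_matrix"))
  ga <- resolve_cells(group_a, m)
  gb <- resolve_cells(group_b, m)
  if (length(intersect(ga, gb))) stop("groups must be disjoint")
  if (length(ga) < 2 || length(gb) < 2) stop("each group needs >= 2 cells")
  x <- m$values
  if (!is.null(restrict_to)) {
    keep <- intersect(colnames(x), restrict_to)
    if (!length(keep)) stop("no genes left after restricting to the panel")
    x <- x[, keep, drop = FALSE]
  }
  a <- x[ga, , drop = FALSE]
  b <- x[gb, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- (colSums(a^2) - na * ma^2) / (na - 1)
  vb <- (colSums(b^2) - nb * mb^2) / (nb - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- ifelse(ma[se2 == 0] == mb[se2 == 0], 1, 0)

  nza <- colSums(a > 0); nzb <- colSums(b > 0)
  eligible <- pmax(nza, nzb) >= min_nonzero
  q <- rep(NA_real_, ncol(x))
  q[eligible] <- stats::p.adjust(p[eligible], method = "BH")
  p[!eligible] <- NA_real_

  out <- data.frame(gene = colnames(x), mean_a = ma, mean_b = mb,
                    fold_ratio = (ma + pseudocount) / (mb + pseudocount),
                    p_value = p, q_value = q,
                    n_nonzero_a = nza, n_nonzero_b = nzb,
                    eligible = eligible, capped = ma == 0 | mb == 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

resolve_cells <- function(idx, m) {
  n <- nrow(m$values)
  if (is.logical(idx)) return(which(idx))
  if (is.character(idx)) {
    pos <- match(idx, rownames(m$values))
    if (anyNA(pos)) stop("unknown cell ids in group")
    return(pos)
  }
  if (any(idx < 1 | idx > n)) stop("cell index out of range")
  as.integer(idx)
}

#' Apply a named differential-expression filter preset
#'
#' Three presets mirror the study's call rules:
#' * `"marker"` — conservative marker calls: BH FDR 5% and `p < 1e-4`.
#' * `"tf6"` — intermediate-state transcription-factor screen: fold ratio
#'   (higher over lower) `> 6` and `p < 1e-3`, within the TF whitelist.
#' * `"tf4"` — terminal-state TF screen: fold ratio `> 4`, `p < 1e-3`, and
#'   mean of the higher-expressing group `>= 1` count/cell, within the TF
#'   whitelist.
#' Eligibility (`min_nonzero`) is enforced upstream by [de_test()].
#'
#' @param r A `de_result`.
#' @param preset `"marker"`, `"tf6"`, or `"tf4"`.
#' @param tf_genes TF whitelist (required for the TF presets).
#' @return Logical vector: whether each gene passes the preset.
#' @export
de_pass <- function(r, preset = c("marker", "tf6", "tf4"), tf_genes = NULL) {
  preset <- match.arg(preset)
  fr <- pmax(r$fold_ratio, 1 / r$fold_ratio)
  mean_high <- pmax(r$mean_a, r$mean_b)
  ok <- switch(preset,
    marker = !is.na(r$q_value) & r$q_value < 0.05 & r$p_value < 1e-4,
    tf6 = !is.na(r$p_value) & fr > 6 & r$p_value < 1e-3,
    tf4 = !is.na(r$p_value) & fr > 4 & r$p_value < 1e-3 & mean_high >= 1)
  if (preset %in% c("tf6", "tf4")) {
    if (is.null(tf_genes)) stop("TF presets require a tf_genes whitelist")
    ok <- ok & r$gene %in% tf_genes
  }
  ok
}

#' Marker genes of each cluster (cluster versus rest)
#'
#' @param m A [normalized_matrix()].
#' @param labels Integer cluster ids per cell (`-1` = noise, excluded from
#'   both sides).
#' @param ... Passed to [de_test()].
#' @return Named list (by cluster id) of `de_result`s with an extra
#'   `enriched` column: higher in the cluster and passing the `"marker"`
#'   preset. Singleton clusters are skipped with a warning.
#' @export
marker_genes <- function(m, labels, ...) {
  cl <- sort(unique(labels[labels != -1L]))
  if (length(cl) < 2) {
    warning("fewer than 2 clusters; no marker comparison possible")
    return(list())
  }
  out <- list()
  for (k in cl) {
    members <- which(labels == k)
    rest <- which(labels != k & labels != -1L)
    if (length(members) < 2) {
      warning("singleton cluster skipped: ", k)
      next
    }
    r <- de_test(m, members, rest, ...)
    r$enriched <- r$mean_a > r$mean_b & de_pass(r, "marker")
    out[[as.character(k)]] <- r
  }
  out
}

#' Volcano-plot table
#'
#' @param r A `de_result`.
#' @return Data frame (`gene`, `log2_ratio`, `neg_log10_q`, `mean_high`,
#'   `capped`), sorted by `q_value` ascending with ties in input order;
#'   `mean_high` is the mean of the higher-expressing group.
#' @export
volcano_table <- function(r) {
  out <- data.frame(gene = r$gene,
                    log2_ratio = log2(r$fold_ratio),
                    neg_log10_q = -log10(r$q_value),
                    mean_high = pmax(r$mean_a, r$mean_b),
                    capped = r$capped, stringsAsFactors = FALSE)
  out[order(r$q_value), ]
}
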