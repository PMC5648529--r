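#' Controlled vocabulary of cell-state annotations
#'
#' Embryonic stem cells through late motor neurons, plus off-target and
#' support populations, and `"other"` for clusters matching no state.
#'
#' @return Character vector of allowed annotation labels.
#' @export
state_vocabulary <- function() {
  c("ESC", "NP", "PNP", "PVNP", "MNP", "EMN", "LMN", "CN", "DSCN",
    "Gl1", "Gl2", "Mus", "Meso", "Endo", "Oligo", "Astro", "Stro", "other")
}

#' Read a marker-criteria table
#'
#' A marker-criteria table records, per cell state and gene, whether the
#' gene is expected highly expressed (`Hi`), lowly expressed (`Lo`), or not
#' expressed (`Absent`, written `-` in some sources). TSV columns:
#' `state`, `gene`, `level`.
#'
#' @param path TSV file path.
#' @return A data frame of class `marker_criteria` with columns
#'   `state`, `gene`, `level`.
#' @export
read_marker_criteria <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  marker_criteria(df)
}

#' Construct a marker-criteria table from a data frame
#'
#' @param df Data frame with columns `state`, `gene`, `level`; `level` in
#'   `Hi`, `Lo`, `Absent` (`-` is read as `Absent`).
#' @return A validated `marker_criteria` data frame.
#' @export
marker_criteria <- function(df) {
  stopifnot(all(c("state", "gene", "level") %in% names(df)))
  df$level[df$level == "-"] <- "Absent"
  if (!all(df$level %in% c("Hi", "Lo", "Absent")))
    stop("levels must be Hi, Lo, or Absent")
  bad <- setdiff(unique(df$state), state_vocabulary())
  if (length(bad))
    stop("states outside the controlled vocabulary: ",
         paste(bad, collapse = ", "))
  structure(df[, c("state", "gene", "level")],
            class = c("marker_criteria", "data.frame"))
}

#' Annotate clusters against a marker-criteria table
#'
#' Each cluster's centroid is compared with every state's Hi/Lo/Absent
#' pattern and assigned the best-matching state. The match score over a
#' state's criteria genes awards +1 for `Hi` genes whose centroid z-score
#' exceeds `hi_z`, +1 for `Absent` genes detected in fewer than
#' `absent_detect` of the cluster's cells, and +0.5 for `Lo` genes with
#' centroid z-score in `(-hi_z, +hi_z)`; the total is divided by the number
#' of criteria genes. Clusters whose best score falls below `floor` are
#' annotated `"other"`. Ties are reported, never silently broken.
#'
#' @param m A [normalized_matrix()].
#' @param counts The source [count_matrix()] (for detection fractions).
#' @param labels Integer cluster ids per cell (`-1` = noise, skipped).
#' @param criteria A `marker_criteria` table.
#' @param hi_z Centroid z-score above which a gene counts as high.
#' @param absent_detect Maximum detection fraction for an absent gene.
#' @param floor Minimum score for assignment.
#' @return Data frame with one row per cluster: `cluster_id`, `annotation`,
#'   `score`, `tied` (comma-separated states within 1e-9 of the best score,
#'   empty when unique), plus a `scores` attribute (cluster x state matrix).
#'   Criteria genes absent from the data are skipped with a warning.
#' @export
annotate_clusters <- function(m, counts, labels, criteria,
                              hi_z = 0.5, absent_detect = 0.05, floor = 0.5) {
  stopifnot(inherits(m, "normalized_matrix"),
            inherits(counts, "count_matrix"),
            inherits(criteria, "marker_criteria"),
            length(labels) == nrow(m$values))
  missing_genes <- setdiff(unique(criteria$gene), colnames(m$values))
  if (length(missing_genes)) {
    warning("criteria genes absent from data, skipped: ",
            paste(missing_genes, collapse = ", "))
    criteria <- criteria[!criteria$gene %in% missing_genes, ]
  }
  if (!nrow(criteria)) stop("no criteria genes present in the data")

  genes <- unique(criteria$gene)
  z <- scale(m$values[, genes, drop = FALSE])   # dataset-wide z per gene
  z[, attr(z, "scaled:scale") == 0] <- 0
  det <- counts$counts[, genes, drop = FALSE] > 0

  clusters <- sort(unique(labels[labels != -1L]))
  states <- unique(criteria$state)
  scores <- matrix(NA_real_, length(clusters), length(states),
                   dimnames = list(as.character(clusters), states))
  for (ci in seq_along(clusters)) {
    members <- labels == clusters[ci]
    cz <- colMeans(z[members, , drop = FALSE])
    cd <- colMeans(det[members, , drop = FALSE])
    for (s in states) {
      cr <- criteria[criteria$state == s, ]
      pts <- 0
      for (r in seq_len(nrow(cr))) {
        g <- cr$gene[r]
        pts <- pts + switch(cr$level[r],
          Hi = as.numeric(cz[g] > hi_z),
          Absent = as.numeric(cd[g] < absent_detect),
          Lo = 0.5 * as.numeric(cz[g] > -hi_z && cz[g] < hi_z))
      }
      scores[ci, s] <- pts / nrow(cr)
    }
  }
  best <- apply(scores, 1, max)
  annotation <- character(length(clusters))
  tied <- character(length(clusters))
  for (ci in seq_along(clusters)) {
    winners <- states[scores[ci, ] > best[ci] - 1e-9]
    annotation[ci] <- if (best[ci] < floor) "other" else winners[1]
    tied[ci] <- if (length(winners) > 1 && best[ci] >= floor)
      paste(winners, collapse = ",") else ""
  }
  out <- data.frame(cluster_id = clusters, annotation = annotation,
                    score = best, tied = tied, stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  out
}

#' Per-cell annotations from a cluster annotation table
#'
#' @param labels Integer cluster ids per cell.
#' @param annotation_table Output of [annotate_clusters()].
#' @return Character vector per cell; noise cells get `NA`.
#' @export
cell_annotations <- function(labels, annotation_table) {
  idx <- match(labels, annotation_table$cluster_id)
  out <- annotation_table$annotation[idx]
  out[labels == -1L] <- NA_character_
  out
}

#' State fractions per protocol and timepoint
#'
#' Counts the percentage of cells in each annotated state at each
#' (protocol, day), the quantity used to follow differentiation progress
#' and compute protocol efficficiencies over time.
#'
#' @param annotations Character vector of per-cell state annotations
#'   (`NA` = unassigned, excluded).
#' @param meta Data frame with `protocol` and `day` per cell.
#' @return Data frame (`protocol`, `day`, `annotation`, `n_cells`,
#'   `fraction`); fractions sum to 1 within each (protocol, day).
#' @export
state_fractions <- function(annotations, meta) {
  stopifnot(length(annotations) == nrow(meta),
            all(c("protocol", "day") %in% names(meta)))
  keep <- !is.na(annotations)
  df <- data.frame(protocol = meta$protocol[keep], day = meta$day[keep],
                   annotation = annotations[keep], stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n_cells = rep(1L, nrow(df))),
                          df[, c("protocol", "day", "annotation")], sum)
  tot <- stats::aggregate(list(total = agg$n_cells),
                          agg[, c("protocol", "day")], sum)
  agg <- merge(agg, tot, by = c("protocol", "day"))
  agg$fraction <- agg$n_cells / agg$total
  agg$total <- NULL
  agg[order(agg$protocol, agg$day, agg$annotation), ]
}

#' Differentiation efficiency toward a set of states
#'
#' @param fractions Output of [state_fractions()].
#' @param states States of interest (default the motor-neuron states
#'   `EMN` and `LMN`).
#' @return Data frame (`protocol`, `day`, `efficiency`) where efficiency is
#'   the summed fraction of cells in the named states.
#' @export
efficiency <- function(fractions, states = c("EMN", "LMN")) {
  sel <- fractions[fractions$annotation %in% states, ]
  days <- unique(fractions[, c("protocol", "day")])
  if (nrow(sel)) {
    agg <- stats::aggregate(list(efficiency = sel$fraction),
                            sel[, c("protocol", "day")], sum)
    out <- merge(days, agg, by = c("protocol", "day"), all.x = TRUE)
  } else {
    out <- days
    out$efficiency <- NA_real_
  }
  out$efficiency[is.na(out$efficiency)] <- 0
  out[order(out$protocol, out$day), ]
}
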