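#' Gene-expression program of one cell state
#'
#' A state is modelled as a multinomial distribution over the gene universe:
#' every transcript in a cell of this state is drawn independently from
#' `gene_probs`. Marker genes are the subset designated highly expressed
#' ("Hi") for the state.
#'
#' @param state_name Label for the state (e.g. `"ESC"`, `"LMN"`).
#' @param gene_probs Named non-negative numeric vector over the gene universe,
#'   summing to 1 (tolerance 1e-9).
#' @param marker_genes Character vector, subset of `names(gene_probs)`.
#' @return An object of class `state_program`.
#' @export
state_program <- function(state_name, gene_probs, marker_genes = character()) {
  if (is.null(names(gene_probs))) stop("gene_probs must be named by gene")
  if (length(gene_probs) == 0) stop("empty gene universe")
  if (any(gene_probs < 0)) stop("gene probabilities must be non-negative")
  if (abs(sum(gene_probs) - 1) > 1e-9)
    stop("gene_probs must sum to 1 (got ", format(sum(gene_probs)), ")")
  if (!all(marker_genes %in% names(gene_probs)))
    stop("marker_genes outside the gene universe")
  structure(list(state_name = state_name, gene_probs = gene_probs,
                 marker_genes = marker_genes),
            class = "state_program")
}

#' Trajectory topology over cell-state programs
#'
#' @param states List of [state_program()]s sharing one gene universe, in
#'   trajectory order.
#' @param edges Two-column character matrix/data.frame of directed
#'   (from, to) state-name pairs; must form a connected DAG. Defaults to the
#'   linear chain over `states`.
#' @param shared_states State names shared with a partner protocol (start and
#'   terminal states in the two-protocol design).
#' @return An object of class `trajectory_topology`.
#' @export
trajectory_topology <- function(states, edges = NULL,
                                shared_states = character()) {
  nm <- vapply(states, function(s) s$state_name, character(1))
  if (anyDuplicated(nm)) stop("duplicate state names")
  universe <- names(states[[1]]$gene_probs)
  for (s in states)
    if (!identical(names(s$gene_probs), universe))
      stop("all states must share one gene universe")
  if (is.null(edges)) {
    edges <- if (length(nm) > 1)
      cbind(from = nm[-length(nm)], to = nm[-1])
    else matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to")))
  }
  edges <- as.matrix(edges)
  if (length(edges) && !all(edges %in% nm)) stop("edge endpoints must be states")
  if (length(nm) > 1) {
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g)) stop("edges must form a DAG")
    if (igraph::components(g, mode = "weak")$no != 1 ||
        igraph::vcount(g) != length(nm))
      stop("edges must connect all states")
  }
  if (!all(shared_states %in% nm)) stop("shared_states must name states")
  names(states) <- nm
  structure(list(states = states, edges = edges,
                 shared_states = shared_states),
            class = "trajectory_topology")
}

#' Specification for one synthetic droplet experiment
#'
#' Describes everything needed to simulate a seeded UMI count matrix: the
#' state programs and their cell numbers per timepoint, the library-size law
#' (lognormal total UMIs per cell), and the doublet / stressed-cell injection
#' rates.
#'
#' @param topology A [trajectory_topology()].
#' @param cells_per_state Named integer vector (state name -> cell count), or
#'   a single count recycled over states.
#' @param days Named integer vector assigning a collection day to each state;
#'   defaults to the state's 0-based position in the topology order.
#' @param library_size `c(meanlog=, sdlog=)` of the lognormal law for total
#'   UMIs per cell. Defaults emulate typical droplet depth (median ~2000).
#' @param doublet_rate,stress_rate Fractions in \[0, 1\] of cells replaced by
#'   injected doublets / stressed cells.
#' @param mito_genes Genes that stressed cells reallocate counts into. May be
#'   outside the state programs' support.
#' @param protocol Protocol tag recorded in cell metadata.
#' @param seed Integer; fixing it fixes the generated matrix exactly.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(topology, cells_per_state,
                           days = NULL,
                           library_size = c(meanlog = log(2000), sdlog = 0.4),
                           doublet_rate = 0, stress_rate = 0,
                           mito_genes = character(),
                           protocol = "synthetic", seed = 1L) {
  stopifnot(inherits(topology, "trajectory_topology"))
  nm <- names(topology$states)
  if (length(cells_per_state) == 1 && is.null(names(cells_per_state)))
    cells_per_state <- stats::setNames(rep(cells_per_state, length(nm)), nm)
  if (!all(nm %in% names(cells_per_state)))
    stop("cells_per_state must cover every state")
  cells_per_state <- cells_per_state[nm]
  if (any(cells_per_state < 0)) stop("cells_per_state must be >= 0")
  if (is.null(days)) days <- stats::setNames(seq_along(nm) - 1L, nm)
  if (doublet_rate < 0 || doublet_rate > 1) stop("doublet_rate must be in [0,1]")
  if (stress_rate < 0 || stress_rate > 1) stop("stress_rate must be in [0,1]")
  if (length(library_size) != 2 || is.null(names(library_size)))
    stop("library_size must be c(meanlog=, sdlog=)")
  structure(list(topology = topology, cells_per_state = cells_per_state,
                 days = days[nm], library_size = library_size,
                 doublet_rate = doublet_rate, stress_rate = stress_rate,
                 mito_genes = as.character(mito_genes),
                 protocol = protocol, seed = as.integer(seed)),
            class = "synthetic_spec")
}

draw_library_sizes <- function(n, library_size) {
  if (library_size[["sdlog"]] == 0)
    rep(max(1, round(exp(library_size[["meanlog"]]))), n)
  else
    pmax(1, round(stats::rlnorm(n, library_size[["meanlog"]],
                                library_size[["sdlog"]])))
}

#' Simulate a UMI count matrix from a synthetic specification
#'
#' Each cell's counts are a multinomial sample from its state's gene
#' distribution, with total UMIs drawn from the lognormal library-size law.
#' A `doublet_rate` fraction of cells are replaced by doublets: the pooled
#' draw of two randomly chosen singlet profiles, downsampled back to a single
#' library-size draw. A `stress_rate` fraction are replaced by stressed
#' cells, which reallocate a uniform 50-90% share of their counts into the
#' mitochondrial gene set. Ground truth (state, doublet flag, stress flag)
#' is recorded in the cell metadata.
#'
#' @param spec A [synthetic_spec()].
#' @return A [count_matrix()] whose `cell_meta` carries `true_state`,
#'   `is_doublet`, `doublet_states` (the sorted parent states of a doublet,
#'   `NA` for singlets), and `is_stressed` columns. The gene universe is the state
#'   programs' genes followed by any `mito_genes` not already present.
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  states <- spec$topology$states
  universe <- names(states[[1]]$gene_probs)
  genes <- union(universe, spec$mito_genes)
  n_per <- spec$cells_per_state
  n <- sum(n_per)
  if (n == 0) stop("no cells requested")

  set.seed(spec$seed)
  state_of <- rep(names(n_per), n_per)
  lib <- draw_library_sizes(n, spec$library_size)
  counts <- matrix(0, nrow = n, ncol = length(genes),
                   dimnames = list(NULL, genes))
  for (s in names(states)) {
    idx <- which(state_of == s)
    if (!length(idx)) next
    p <- states[[s]]$gene_probs
    draws <- vapply(idx, function(i) {
      stats::rmultinom(1, lib[i], p)[, 1]
    }, numeric(length(p)))
    counts[idx, universe] <- t(draws)
  }

  is_doublet <- as.logical(stats::rbinom(n, 1, spec$doublet_rate))
  doublet_states <- rep(NA_character_, n)
  for (i in which(is_doublet)) {
    pair <- sample(setdiff(seq_len(n), i), 2)
    pooled <- counts[pair[1], ] + counts[pair[2], ]
    tot <- sum(pooled)
    if (tot > 0)
      counts[i, ] <- stats::rmultinom(1, lib[i], pooled / tot)[, 1]
    doublet_states[i] <- paste(sort(state_of[pair]), collapse = "+")
  }

  is_stressed <- as.logical(stats::rbinom(n, 1, spec$stress_rate))
  if (any(is_stressed) && !length(spec$mito_genes))
    stop("stress_rate > 0 requires mito_genes")
  for (i in which(is_stressed)) {
    f <- stats::runif(1, 0.5, 0.9)
    tot <- sum(counts[i, ])
    n_mito <- round(f * tot)
    keep <- tot - n_mito
    row <- counts[i, ]
    if (sum(row) > 0 && keep > 0)
      row <- stats::rmultinom(1, keep, row / sum(row))[, 1]
    else row <- rep(0, length(row))
    mito_add <- stats::rmultinom(1, n_mito,
                                 rep(1 / length(spec$mito_genes),
                                     length(spec$mito_genes)))[, 1]
    row[match(spec$mito_genes, genes)] <-
      row[match(spec$mito_genes, genes)] + mito_add
    counts[i, ] <- row
  }

  barcodes <- sprintf("%s_bc%05d", spec$protocol, seq_len(n))
  meta <- data.frame(barcode = barcodes, protocol = spec$protocol,
                     day = as.integer(spec$days[state_of]),
                     true_state = state_of, is_doublet = is_doublet,
                     doublet_states = doublet_states,
                     is_stressed = is_stressed, stringsAsFactors = FALSE)
  count_matrix(counts, barcodes, genes, meta)
}

#' Simulate a paired two-protocol experiment
#'
#' Generates two count matrices over the same gene universe, for designs
#' where two protocols start and end in identical states (identical gene
#' programs) but pass through distinct intermediates — the
#' bifurcate-and-reconverge topology.
#'
#' @param spec_dp,spec_sp [synthetic_spec()]s for the two protocols.
#' @param shared Character vector of state names present in both topologies;
#'   their programs must be identical.
#' @return List with elements `dp` and `sp`, each a [count_matrix()].
#' @export
generate_two_protocol_experiment <- function(spec_dp, spec_sp, shared) {
  st_dp <- spec_dp$topology$states
  st_sp <- spec_sp$topology$states
  if (!identical(names(st_dp[[1]]$gene_probs), names(st_sp[[1]]$gene_probs)))
    stop("the two protocols must share one gene universe")
  for (s in shared) {
    if (!(s %in% names(st_dp)) || !(s %in% names(st_sp)))
      stop("shared state absent from a topology: ", s)
    if (!isTRUE(all.equal(st_dp[[s]]$gene_probs, st_sp[[s]]$gene_probs,
                          tolerance = 1e-12)))
      stop("shared state has differing programs: ", s)
  }
  list(dp = generate_counts(spec_dp), sp = generate_counts(spec_sp))
}

#' Build a block-marker two-protocol design
#'
#' Convenience constructor for the synthetic study design used throughout the
#' package: a gene universe of `n_genes`, each state expressing a disjoint
#' block of `n_markers` marker genes at `marker_boost`-fold the baseline
#' probability, with the DP and SP protocols sharing the start (`ESC`) and
#' terminal (`LMN`) programs but using distinct intermediates.
#'
#' @param n_genes Size of the gene universe (marker blocks are carved from
#'   its head; the default 2000 keeps runtimes in seconds).
#' @param n_markers Markers per state.
#' @param marker_boost Fold increase of marker probability over baseline.
#' @param offmarker_weight Relative weight of other states' marker genes
#'   (default 0.02 of baseline): marker genes are state-specific, nearly
#'   silent outside their own state, as real lineage markers are.
#' @param dp_states,sp_states Ordered state names per protocol.
#' @param shared States whose programs are common to both protocols.
#' @return List with `programs` (named list of [state_program()]),
#'   `dp_states`, `sp_states`, `shared`, and `genes`.
#' @export
two_protocol_design <- function(n_genes = 2000, n_markers = 20,
                                marker_boost = 30, offmarker_weight = 0.02,
                                dp_states = c("ESC", "NP", "EMN", "LMN"),
                                sp_states = c("ESC", "PVNP", "MNP", "LMN"),
                                shared = c("ESC", "LMN")) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  all_states <- union(dp_states, sp_states)
  if (n_markers * length(all_states) > n_genes)
    stop("gene universe too small for the marker blocks")
  all_blocks <- seq_len(n_markers * length(all_states))
  programs <- list()
  for (i in seq_along(all_states)) {
    w <- rep(1, n_genes)
    w[all_blocks] <- offmarker_weight
    block <- seq.int((i - 1) * n_markers + 1, i * n_markers)
    w[block] <- marker_boost
    programs[[all_states[i]]] <- state_program(
      all_states[i], stats::setNames(w / sum(w), genes), genes[block])
  }
  list(programs = programs, dp_states = dp_states, sp_states = sp_states,
       shared = shared, genes = genes)
}

#' Marker-criteria table implied by a synthetic design
#'
#' Builds the Hi/Absent criteria that annotation should recover on data from
#' a [two_protocol_design()]: each state's own marker genes are `Hi`, and the
#' other states' markers are `Absent`.
#'
#' @param design A [two_protocol_design()].
#' @param n_per_state Criteria genes taken from each state's marker block.
#' @return A [marker_criteria()] table.
#' @export
design_marker_criteria <- function(design, n_per_state = 5) {
  states <- names(design$programs)
  rows <- list()
  for (s in states) {
    own <- utils::head(design$programs[[s]]$marker_genes, n_per_state)
    rows[[length(rows) + 1]] <-
      data.frame(state = s, gene = own, level = "Hi")
    for (o in setdiff(states, s)) {
      other <- utils::head(design$programs[[o]]$marker_genes, n_per_state)
      rows[[length(rows) + 1]] <-
        data.frame(state = s, gene = other, level = "Absent")
    }
  }
  marker_criteria(do.call(rbind, rows))
}
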