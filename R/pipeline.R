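#' Default pipeline configuration
#'
#' @return Nested list of every stage parameter with its default. See
#'   [run_pipeline()] for the stage semantics.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "pipeline_out",
    input = list(path = NULL),           # NULL -> simulate the demo design
    simulate = list(n_genes = 2000L, n_markers = 20L, marker_boost = 30,
                    cells_per_state = 200L, meanlog = log(2000), sdlog = 0.4,
                    doublet_rate = 0.02, stress_rate = 0.02,
                    n_mito_genes = 10L),
    qc = list(min_umi = 1000L, target_total = "median",
              mito_threshold = 0.25),
    features = list(n_hvg = 1000L, n_randomizations = 10L,
                    loading_quantile = 0.9),
    cluster = list(eps = "auto", min_pts = "auto", perplexity = 30),
    de = list(min_nonzero = 10L),
    compare = list(k = 20L),
    scores = list(zscore = FALSE)
  )
}

validate_config <- function(config, template = default_config(),
                            path = "config") {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown))
    stop(sprintf("unknown %s key(s): %s", path, paste(unknown, collapse = ", ")))
  merged <- template
  for (key in names(config)) {
    if (is.list(template[[key]]) && !is.null(names(template[[key]]))) {
      merged[[key]] <- validate_config(config[[key]], template[[key]],
                                       paste(path, key, sep = "$"))
    } else {
      merged[key] <- config[key]
    }
  }
  numeric_keys <- c("seed", "min_umi", "n_hvg", "n_randomizations", "k",
                    "cells_per_state", "min_nonzero")
  for (key in numeric_keys) {
    hit <- find_key(merged, key)
    if (!is.null(hit) && !is.numeric(hit))
      stop(sprintf("config field '%s' must be numeric, got '%s'", key,
                   as.character(hit)))
  }
  merged
}

find_key <- function(x, key) {
  if (key %in% names(x)) return(x[[key]])
  for (el in x) if (is.list(el)) {
    hit <- find_key(el, key)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order: simulate/load, quality control,
#' feature selection, embedding and clustering, annotation, marker
#' differential expression, cross-protocol comparison (centroid cosine
#' similarity and maximum-likelihood assignment), and panel scores. Stage
#' artifacts are written under `output_dir` along with the echoed
#' configuration and a run manifest (package version, seed, file
#' checksums). Any stage failure aborts with the stage name; artifacts
#' written so far are preserved.
#'
#' @param config Path to a YAML configuration file, or a nested list (see
#'   [default_config()]). Unknown keys are rejected.
#' @return Invisibly, a list with the principal in-memory results
#'   (`qc`, `model`, `labels`, `annotations`, `fractions`, `similarity`,
#'   `tally`, `manifest`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(msg)
    cat(msg, "\n", file = file.path(out, "run.log"), append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- simulate or load -----------------------------------------------------
  sim <- cfg$simulate
  mito_genes <- sprintf("mt-%02d", seq_len(sim$n_mito_genes))
  data <- stage("input", {
    if (!is.null(cfg$input$path)) {
      list(dp = load_counts(cfg$input$path))
    } else {
      design <- two_protocol_design(n_genes = sim$n_genes,
                                    n_markers = sim$n_markers,
                                    marker_boost = sim$marker_boost)
      lib <- c(meanlog = sim$meanlog, sdlog = sim$sdlog)
      mk_spec <- function(states, protocol, seed)
        synthetic_spec(trajectory_topology(design$programs[states],
                                           shared_states = design$shared),
                       cells_per_state = sim$cells_per_state,
                       library_size = lib, doublet_rate = sim$doublet_rate,
                       stress_rate = sim$stress_rate, mito_genes = mito_genes,
                       protocol = protocol, seed = seed)
      ex <- generate_two_protocol_experiment(
        mk_spec(design$dp_states, "DP", cfg$seed),
        mk_spec(design$sp_states, "SP", cfg$seed + 1L),
        design$shared)
      ex$design <- design
      ex
    }
  })

  results <- list()
  for (prot in intersect(names(data), c("dp", "sp"))) {
    m0 <- data[[prot]]
    qc <- stage(paste0("qc_", prot),
                qc_pipeline(m0, min_umi = cfg$qc$min_umi,
                            mito_genes = intersect(mito_genes, m0$gene_ids),
                            target_total = cfg$qc$target_total,
                            mito_threshold = cfg$qc$mito_threshold))
    jsonlite::write_json(unclass(qc$report)[1:4],
                         file.path(out, sprintf("qc_report_%s.json", prot)),
                         auto_unbox = TRUE)
    model <- stage(paste0("features_", prot), {
      hvg <- select_variable_genes(qc$normalized, cfg$features$n_hvg)
      select_principal_variable_genes(
        qc$normalized, hvg,
        n_randomizations = cfg$features$n_randomizations,
        loading_quantile = cfg$features$loading_quantile,
        seed = cfg$seed)
    })
    labels <- stage(paste0("cluster_", prot), {
      z <- zscore_transform(qc$normalized, model)
      coords <- embed_tsne(z, max(1, model$n_nontrivial), seed = cfg$seed,
                           perplexity = cfg$cluster$perplexity)
      eps <- if (identical(cfg$cluster$eps, "auto")) NULL else cfg$cluster$eps
      mp <- if (identical(cfg$cluster$min_pts, "auto")) NULL
            else cfg$cluster$min_pts
      density_cluster(coords, eps, mp)
    })
    ann <- NULL
    if (!is.null(data$design)) {
      ann <- stage(paste0("annotate_", prot), {
        crit <- design_marker_criteria(data$design)
        annotate_clusters(qc$normalized, qc$counts, labels, crit)
      })
      utils::write.table(ann, file.path(out, sprintf("annotation_%s.tsv", prot)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    markers <- stage(paste0("de_", prot),
                     marker_genes(qc$normalized, labels,
                                  min_nonzero = cfg$de$min_nonzero))
    results[[prot]] <- list(qc = qc, model = model, labels = labels,
                            annotation = ann, markers = markers)
  }

  fractions <- similarity <- tally <- NULL
  if (all(c("dp", "sp") %in% names(results))) {
    fractions <- stage("fractions", {
      f <- do.call(rbind, lapply(c("dp", "sp"), function(prot) {
        r <- results[[prot]]
        state_fractions(cell_annotations(r$labels, r$annotation),
                        r$qc$counts$cell_meta)
      }))
      utils::write.table(f, file.path(out, "state_fractions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      f
    })
    comparison <- stage("compare", {
      compare_protocols(results$dp$qc, results$sp$qc,
                        cell_annotations(results$dp$labels,
                                         results$dp$annotation),
                        cell_annotations(results$sp$labels,
                                         results$sp$annotation),
                        n_hvg = cfg$features$n_hvg,
                        n_randomizations = cfg$features$n_randomizations,
                        seed = cfg$seed)
    })
    similarity <- comparison$similarity
    tally <- comparison$assignment$tally
    utils::write.table(round(similarity, 4),
                       file.path(out, "centroid_cosine_similarity.tsv"),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(as.list(round(tally, 3)),
                         file.path(out, "ml_assignment_tally.json"),
                         auto_unbox = TRUE)
  }

  scores <- stage("scores", {
    first <- results[[1]]$qc$normalized
    panel <- intersect(proliferation_panel(), colnames(first$values))
    if (length(panel)) panel_score(first, panel, zscore = cfg$scores$zscore)
    else NULL
  })

  manifest <- stage("manifest", {
    files <- list.files(out, full.names = TRUE)
    files <- files[!grepl("manifest.json$|run.log$", files)]
    mf <- list(package = "mnpaths",
               version = as.character(utils::packageVersion("mnpaths")),
               seed = cfg$seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               checksums = as.list(tools::md5sum(files)))
    jsonlite::write_json(mf, file.path(out, "manifest.json"),
                         auto_unbox = TRUE)
    mf
  })
  log_line("pipeline complete")
  invisible(list(results = results, fractions = fractions,
                 similarity = similarity, tally = tally, scores = scores,
                 manifest = manifest))
}

#' Cross-protocol comparison in a shared PV-gene space
#'
#' Pools the cells of both protocols, extracts PV genes on the combined
#' data, and computes (i) the pairwise cosine similarity between each
#' protocol's state centroids in the z-scored PV space, and (ii) the
#' multinomial maximum-likelihood assignment of every first-protocol cell
#' to the second protocol's states.
#'
#' @param qc_a,qc_b [qc_pipeline()] results for the two protocols.
#' @param labels_a,labels_b Per-cell state labels (character).
#' @param n_hvg,n_randomizations,seed Feature-selection parameters.
#' @return List: `similarity` (states of a x states of b), `assignment`
#'   (a `likelihood_assignment` of a's cells onto b's states), `model`.
#' @export
compare_protocols <- function(qc_a, qc_b, labels_a, labels_b,
                              n_hvg = 1000, n_randomizations = 10,
                              seed = 1L) {
  genes <- intersect(qc_a$counts$gene_ids, qc_b$counts$gene_ids)
  pooled_counts <- rbind(qc_a$counts$counts[, genes, drop = FALSE],
                         qc_b$counts$counts[, genes, drop = FALSE])
  pooled <- count_matrix(pooled_counts,
                         c(qc_a$counts$cell_ids, qc_b$counts$cell_ids), genes)
  norm <- total_count_normalize(pooled)
  hvg <- select_variable_genes(norm, n_hvg)
  model <- select_principal_variable_genes(norm, hvg,
                                           n_randomizations = n_randomizations,
                                           seed = seed)
  z <- zscore_transform(norm, model)
  na <- length(labels_a)
  cen_a <- cluster_centroids(z[seq_len(na), , drop = FALSE], labels_a)
  cen_b <- cluster_centroids(z[na + seq_along(labels_b), , drop = FALSE],
                             labels_b)
  sim <- centroid_cosine_similarity(cen_a, cen_b)
  prof <- reference_profiles(qc_b$counts, labels_b,
                             genes = model$pv_gene_ids)
  assignment <- ml_assign_cells(qc_a$counts, prof)
  list(similarity = sim, assignment = assignment, model = model)
}
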