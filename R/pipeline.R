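# End-to-end orchestration: simulate a study to disk, compute the
# clustering-index tables, and run the full network analysis, each stage
# reading and writing the package's documented text formats so any stage
# can be rerun in isolation from the files plus the manifest.

#' Pipeline configuration
#'
#' Collects paths and parameters for the pipeline stages. Defaults mirror
#' the study configuration: 46 objects, pruning threshold 1, 3000 sigma
#' null graphs, primacy/recency regions of 7 and 3 positions, a 10-recall
#' probe window, and exact path search up to 13 objects.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed, mandatory for every stochastic stage.
#' @param inventory,protocols,taxonomy input file paths (defaults point
#'   into `outdir`, matching what [run_simulate()] writes).
#' @param n_objects,prune_threshold,sigma_samples,primacy_len,recency_len,probe_k,exact_tsp_limit
#'   analysis parameters.
#' @param groups group labels expected in the data.
#' @param strict intrusion handling mode for protocol loading.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "recallnet_out", seed = 1L,
                            inventory = file.path(outdir, "inventory.csv"),
                            protocols = file.path(outdir, "protocols.csv"),
                            taxonomy = file.path(outdir, "taxonomy.json"),
                            n_objects = 46L, prune_threshold = 1,
                            sigma_samples = 3000L, primacy_len = 7L,
                            recency_len = 3L, probe_k = 10L,
                            exact_tsp_limit = 13L,
                            groups = c("HOA", "YA"), strict = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  for (v in c(n_objects, prune_threshold, sigma_samples, primacy_len,
              recency_len, probe_k, exact_tsp_limit)) {
    if (!is.numeric(v) || v <= 0) stop("all parameters must be positive")
  }
  structure(
    list(outdir = outdir, seed = as.integer(seed), inventory = inventory,
         protocols = protocols, taxonomy = taxonomy,
         n_objects = as.integer(n_objects), prune_threshold = prune_threshold,
         sigma_samples = as.integer(sigma_samples),
         primacy_len = as.integer(primacy_len),
         recency_len = as.integer(recency_len), probe_k = as.integer(probe_k),
         exact_tsp_limit = as.integer(exact_tsp_limit), groups = groups,
         strict = isTRUE(strict)),
    class = "pipeline_config")
}

.ensure_outdir <- function(config) {
  if (!dir.exists(config$outdir)) {
    message("creating output directory ", config$outdir)
    dir.create(config$outdir, recursive = TRUE)
  }
  config$outdir
}

.stage_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Simulate a study to disk
#'
#' Writes `inventory.csv`, `taxonomy.json`, `protocols.csv` and
#' `ground_truth.json` into the configured output directory. Rerunning with
#' the same config reproduces identical files.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config) {
  out <- .ensure_outdir(config)
  study <- make_paper_like_study(seed = config$seed)
  .stage_log("simulate", length(study$dataset$protocols), " protocols, ",
             n_objects(study$inventory), " objects, groups ",
             paste(study$dataset$groups, collapse = ", "))
  paths <- list(inventory = config$inventory, taxonomy = config$taxonomy,
                protocols = config$protocols,
                ground_truth = file.path(out, "ground_truth.json"))
  write_inventory(study$inventory, paths$inventory)
  save_taxonomy(study$taxonomy, paths$taxonomy)
  write_protocols(study$dataset, paths$protocols)
  write_ground_truth(study$truth, paths$ground_truth)
  invisible(paths)
}

.load_stage_inputs <- function(config) {
  tax <- load_taxonomy(config$taxonomy)
  inventory <- load_inventory(config$inventory, tax = tax)
  dataset <- load_protocols(config$protocols, inventory,
                            mode = if (config$strict) "strict" else "lenient")
  list(tax = tax, inventory = inventory, dataset = dataset)
}

#' Compute reference lists, clustering records and group comparisons
#'
#' Writes the two start-constrained reference lists, the per-protocol
#' clustering records (tidy long format) and, when two groups are present,
#' the per-trial comparison table.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results.
#' @export
run_indices <- function(config) {
  out <- .ensure_outdir(config)
  inp <- .load_stage_inputs(config)
  .stage_log("indices", length(inp$dataset$protocols), " protocols read")
  sim <- similarity_matrix(inp$inventory, inp$tax)
  refs <- build_reference_lists(sim, inp$inventory,
                                exact_limit = config$exact_tsp_limit)
  write_reference_list(refs$first, file.path(out, "reference_first.csv"))
  write_reference_list(refs$last, file.path(out, "reference_last.csv"))
  records <- index_table(inp$dataset, refs)
  export_tidy_tables(inp$dataset, records,
                     file.path(out, "clustering_records.csv"))
  comparisons <- NULL
  if (length(inp$dataset$groups) >= 2) {
    comparisons <- comparison_table(records)
    utils::write.csv(comparisons, file.path(out, "group_comparisons.csv"),
                     row.names = FALSE)
  } else {
    .stage_log("indices", "single group; comparisons skipped")
  }
  .stage_log("indices", nrow(records), " clustering records written")
  invisible(list(sim = sim, references = refs, records = records,
                 comparisons = comparisons))
}

#' Run the association-network analysis
#'
#' Builds per-group pruned association graphs (GraphML + edge CSV), their
#' metric tables and sigma samples; with two groups, also the comparison
#' table, intersection cliques, within/between likelihood contrast,
#' clique-attribute chi-squares, validity regression and primacy/recency
#' probe. A manifest JSON records seed, parameters and package version.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results.
#' @export
run_networks <- function(config) {
  out <- .ensure_outdir(config)
  inp <- .load_stage_inputs(config)
  groups <- inp$dataset$groups
  .stage_log("networks", length(inp$dataset$protocols), " protocols, groups ",
             paste(groups, collapse = ", "))
  sim <- similarity_matrix(inp$inventory, inp$tax)
  graphs <- list(); metrics <- list(); sigmas <- list()
  metric_rows <- list()
  for (k in seq_along(groups)) {
    g <- association_graph(inp$dataset, groups[k],
                           threshold = config$prune_threshold)
    m <- compute_metrics(g)
    s <- sample_sigma(g, n_samples = config$sigma_samples,
                      seed = config$seed + k)
    graphs[[groups[k]]] <- g; metrics[[groups[k]]] <- m
    sigmas[[groups[k]]] <- s
    .stage_log("networks", groups[k], ": ", m$graph_level$n_edges,
               " edges retained, mean sigma ",
               format(s$mean_sigma, digits = 4))
    gl <- m$graph_level
    metric_rows[[k]] <- data.frame(
      group = groups[k], n_vertices = gl$n_vertices, n_edges = gl$n_edges,
      mean_degree = gl$mean_degree, mean_clustering = gl$mean_clustering,
      mean_path_length = gl$mean_path_length,
      serial_edge_count = gl$serial_edge_count,
      serial_fraction = gl$serial_fraction, median_weight = gl$median_weight,
      mean_sigma = s$mean_sigma, sd_sigma = s$sd_sigma,
      stringsAsFactors = FALSE)
    utils::write.csv(data.frame(sigma = s$sigmas),
                     file.path(out, paste0("sigma_", groups[k], ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, metric_rows),
                   file.path(out, "graph_metrics.csv"), row.names = FALSE)
  results <- list(graphs = graphs, metrics = metrics, sigmas = sigmas)
  if (length(groups) >= 2) {
    g1 <- graphs[[1]]; g2 <- graphs[[2]]
    cmp <- compare_graphs(g1, g2, metrics[[1]], metrics[[2]],
                          sigmas[[1]], sigmas[[2]])
    utils::write.csv(cmp, file.path(out, "graph_comparisons.csv"),
                     row.names = FALSE)
    inter <- intersection_graph(g1, g2)
    cliques <- extract_cliques(inter)
    .stage_log("networks", length(cliques$cliques), " cliques found")
    utils::write.csv(
      data.frame(object_id = names(cliques$assignment),
                 clique_id = unname(cliques$assignment)),
      file.path(out, "cliques.csv"), row.names = FALSE)
    wb <- tryCatch(within_between_likelihood(cliques, g1, g2),
                   error = function(e) NULL)
    chi <- list()
    for (attrib in c("context", "zone")) {
      chi[[attrib]] <- tryCatch(
        suppressWarnings(
          clique_attribute_association(cliques, inp$inventory, attrib)),
        error = function(e) NULL)
    }
    reg <- tryCatch(
      likelihood_similarity_regression(
        g1, g2, sim, inp$inventory,
        exclude_primacy = config$primacy_len,
        exclude_recency = config$recency_len),
      error = function(e) NULL)
    probe <- primacy_recency_probe(inp$dataset, k = config$probe_k,
                                   primacy_len = config$primacy_len,
                                   recency_len = config$recency_len)
    utils::write.csv(probe$summary, file.path(out, "primacy_recency.csv"),
                     row.names = FALSE)
    for (k in seq_along(groups)) {
      export_graph(graphs[[k]], inp$inventory,
                   file.path(out, paste0("graph_", groups[k], ".graphml")),
                   clique_assignment = cliques$assignment)
    }
    results <- c(results, list(comparison = cmp, intersection = inter,
                               cliques = cliques, within_between = wb,
                               attribute_tests = chi, regression = reg,
                               probe = probe))
  } else {
    .stage_log("networks", "single group; intersection stages skipped")
    export_graph(graphs[[1]], inp$inventory,
                 file.path(out, paste0("graph_", groups[1], ".graphml")))
  }
  manifest <- list(
    package = "recallnet",
    version = as.character(utils::packageVersion("recallnet")),
    seed = config$seed,
    parameters = config[c("n_objects", "prune_threshold", "sigma_samples",
                          "primacy_len", "recency_len", "probe_k",
                          "exact_tsp_limit")],
    counts = list(protocols = length(inp$dataset$protocols),
                  groups = as.list(stats::setNames(
                    vapply(groups, function(g) sum(vapply(
                      inp$dataset$protocols,
                      function(p) p$group == g, TRUE)), 0L), groups))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Quick plot of an association graph
#'
#' Minimal convenience plot: edge width scales with association strength
#' (inverse weight), serial edges drawn in red, vertices coloured by clique
#' when an assignment is given.
#'
#' @param graph a pruned association graph.
#' @param clique_assignment optional named clique vector.
#' @param ... passed to `plot.igraph`.
#' @return The graph, invisibly.
#' @export
plot_association_graph <- function(graph, clique_assignment = NULL, ...) {
  deg <- igraph::degree(graph)
  g <- igraph::induced_subgraph(graph, which(deg > 0))
  w <- igraph::edge_attr(g, "weight")
  ew <- 0.5 + 2.5 * (max(w) - w) / max(max(w) - min(w), 1e-9)
  is_serial <- igraph::edge_attr(g, "is_serial")
  ecol <- if (is.null(is_serial)) "grey40" else ifelse(is_serial, "red", "grey40")
  vcol <- "lightsteelblue"
  if (!is.null(clique_assignment)) {
    cl <- clique_assignment[igraph::V(g)$name]
    pal <- grDevices::hcl.colors(max(cl, na.rm = TRUE), "Set 2")
    vcol <- ifelse(is.na(cl), "grey85", pal[cl])
  }
  igraph::plot.igraph(g, edge.width = ew, edge.color = ecol,
                      vertex.color = vcol, vertex.size = 9,
                      vertex.label.cex = 0.6, ...)
  invisible(graph)
}
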