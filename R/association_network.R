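# Group-level object-association networks. Consecutive recalls of two
# objects, pooled over all trials and participants of a group, are counted
# as undirected co-occurrences. Each observed pair becomes an edge whose
# weight is the expected/observed frequency ratio under an independence
# (chi-square style) model: small weights mark associations far above
# chance. Pruning then removes weak edges, weakest first, as long as the
# graph stays connected -- which maximizes the summed -log(weight) of the
# retained backbone.

#' Consecutive-recall co-occurrence counts for one group
#'
#' For each protocol of the group (all five trials), every consecutive
#' recall pair increments the count of that unordered object pair. The sum
#' over distinct pairs equals the total number of transitions,
#' sum over protocols of `max(r - 1, 0)`.
#'
#' @param dataset a [study_dataset].
#' @param group group label present in the dataset.
#' @return A symmetric integer matrix (zero diagonal) over all inventory
#'   objects, class `cooccurrence_matrix`, with attribute `group`.
#' @export
cooccurrence_counts <- function(dataset, group) {
  stopifnot(inherits(dataset, "study_dataset"))
  sel <- Filter(function(p) p$group == group, dataset$protocols)
  if (length(sel) == 0) stop("no protocols for group '", group, "'")
  ids <- dataset$inventory$object_id
  n <- length(ids)
  counts <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (p in sel) {
    if (p$r < 2) next
    i <- match(p$recalls[-p$r], ids)
    j <- match(p$recalls[-1], ids)
    for (k in seq_along(i)) {
      counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
      counts[j[k], i[k]] <- counts[j[k], i[k]] + 1L
    }
  }
  structure(counts, class = c("cooccurrence_matrix", class(counts)), group = group)
}

#' Expected co-occurrence counts under independence
#'
#' Chi-square style non-contingency model on the symmetric co-occurrence
#' table: `expected(i, j) = m_i * m_j / M` where `m_i` is object i's total
#' transition involvement (its row sum) and `M` the full-table sum.
#'
#' @param counts a [cooccurrence_counts()] matrix.
#' @return A symmetric numeric matrix of expectations over all pairs.
#' @export
expected_counts <- function(counts) {
  m <- rowSums(counts)
  total <- sum(counts)
  if (total <= 0) stop("co-occurrence matrix is all zero; expectations undefined")
  expected <- outer(m, m) / total
  diag(expected) <- 0
  expected
}

#' Build the (unpruned) association graph with likelihood weights
#'
#' Every pair observed at least once becomes an undirected edge with
#' attributes `count`, `expected`, and `weight = expected / count` -- the
#' association likelihood, where a small value indicates a pairing unlikely
#' to arise by chance.
#'
#' @param counts a [cooccurrence_counts()] matrix.
#' @param expected matching [expected_counts()] matrix (computed when `NULL`).
#' @return An `igraph` object over all inventory objects (isolated vertices
#'   kept), with graph attribute `group`.
#' @export
likelihood_weights <- function(counts, expected = NULL) {
  if (is.null(expected)) expected <- expected_counts(counts)
  if (!identical(dim(counts), dim(expected))) {
    stop("counts and expected matrices are not aligned")
  }
  ids <- rownames(counts)
  ut <- upper.tri(counts)
  sel <- which(ut & counts > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[sel[, 1]], to = ids[sel[, 2]],
    count = counts[sel], expected = expected[sel],
    weight = expected[sel] / counts[sel], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g <- igraph::set_graph_attr(g, "group", attr(counts, "group"))
  g
}

#' Flag serial edges
#'
#' An edge is serial when its two objects were presented in consecutive
#' positions (no wraparound: positions 1 and N are not neighbours).
#'
#' @param graph an association graph.
#' @param inventory the [object_inventory].
#' @return The graph with logical edge attribute `is_serial`; graph
#'   attributes `serial_count` and `serial_fraction` record the summary.
#' @export
label_serial_edges <- function(graph, inventory) {
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  pos <- function(v) inventory$position[match(v, inventory$object_id)]
  is_serial <- abs(pos(ends[, 1]) - pos(ends[, 2])) == 1L
  graph <- igraph::set_edge_attr(graph, "is_serial", value = is_serial)
  graph <- igraph::set_graph_attr(graph, "serial_count", sum(is_serial))
  igraph::set_graph_attr(graph, "serial_fraction",
                         if (length(is_serial)) mean(is_serial) else NA_real_)
}

# number of connected components among vertices that still carry an edge
.edge_bearing_components <- function(graph) {
  deg <- igraph::degree(graph)
  sub <- igraph::induced_subgraph(graph, which(deg > 0))
  if (igraph::vcount(sub) == 0) return(0L)
  igraph::count_components(sub)
}

# components among a fixed vertex set (the pruning connectivity check)
.components_on <- function(graph, vertices) {
  if (length(vertices) == 0) return(0L)
  igraph::count_components(igraph::induced_subgraph(graph, vertices))
}

#' Prune an association graph to its connected backbone
#'
#' Edges are visited in decreasing weight order (least important first; ties
#' broken by the object-id pair). An edge is removed iff its weight is at or
#' above `threshold` and the removal does not disconnect any vertex of the
#' input's edge-bearing vertex set from the rest (vertices that never had an
#' edge are outside the check). Because every removed edge has
#' `-log(weight) <= 0` and the procedure is reverse-delete over the
#' removable edges with all edge-bearing vertices kept spanned, the result
#' maximizes the retained backbone's summed `-log(weight)` among
#' connectivity-preserving threshold prunings.
#'
#' @param graph an association graph with edge attribute `weight`.
#' @param threshold removal threshold on the weight (default 1: remove
#'   edges at or below chance-level association strength).
#' @param per_component if the edge-bearing subgraph is disconnected,
#'   `TRUE` prunes within components (with a warning); `FALSE` errors.
#' @return The pruned graph; graph attributes `retained_fraction_pairs`
#'   (edges kept / N(N-1)/2) and `retained_fraction_observed` (edges kept /
#'   edges in) report retention.
#' @export
prune_graph <- function(graph, threshold = 1, per_component = FALSE) {
  ncomp0 <- .edge_bearing_components(graph)
  if (ncomp0 > 1) {
    if (!per_component) {
      stop("edge-bearing subgraph is disconnected (", ncomp0,
           " components); use per_component = TRUE to prune within components")
    }
    warning("pruning a disconnected graph per component (", ncomp0, " components)")
  }
  m_in <- igraph::ecount(graph)
  w <- igraph::edge_attr(graph, "weight")
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  key <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]))
  ord <- order(-w, key)
  v0 <- igraph::V(graph)$name[igraph::degree(graph) > 0]
  g <- graph
  for (e in ord) {
    if (w[e] < threshold) break  # remaining edges are all below threshold
    eid <- igraph::get_edge_ids(g, c(ends[e, 1], ends[e, 2]))
    if (eid == 0) next
    g2 <- igraph::delete_edges(g, eid)
    # every vertex that carried an edge on input must stay attached
    if (.components_on(g2, v0) <= ncomp0) g <- g2
  }
  n <- igraph::vcount(g)
  g <- igraph::set_graph_attr(g, "retained_fraction_pairs",
                              igraph::ecount(g) / (n * (n - 1) / 2))
  g <- igraph::set_graph_attr(g, "retained_fraction_observed",
                              if (m_in > 0) igraph::ecount(g) / m_in else NA_real_)
  g
}

#' Export an association graph
#'
#' Writes GraphML with vertex attributes (label, position, zone,
#' is_context_typical, and clique_id when present) and edge attributes
#' (count, expected, weight, is_serial), plus a flat edge-list CSV.
#'
#' @param graph an association graph.
#' @param inventory the [object_inventory] (vertex attributes).
#' @param path output GraphML path; the edge list goes to `<path>.csv`.
#' @param clique_assignment optional named vector mapping object ids to
#'   clique ids (see [extract_cliques()]).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, inventory, path, clique_assignment = NULL) {
  idx <- match(igraph::V(graph)$name, inventory$object_id)
  graph <- igraph::set_vertex_attr(graph, "label", value = inventory$label[idx])
  graph <- igraph::set_vertex_attr(graph, "position", value = inventory$position[idx])
  graph <- igraph::set_vertex_attr(graph, "zone", value = inventory$zone[idx])
  graph <- igraph::set_vertex_attr(graph, "is_context_typical",
                                   value = inventory$is_context_typical[idx])
  if (!is.null(clique_assignment)) {
    cl <- clique_assignment[igraph::V(graph)$name]
    graph <- igraph::set_vertex_attr(graph, "clique_id",
                                     value = ifelse(is.na(cl), "unassigned", cl))
  }
  igraph::write_graph(graph, path, format = "graphml")
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  df <- data.frame(from = ends[, 1], to = ends[, 2],
                   count = igraph::edge_attr(graph, "count"),
                   expected = igraph::edge_attr(graph, "expected"),
                   weight = igraph::edge_attr(graph, "weight"),
                   stringsAsFactors = FALSE)
  if (!is.null(igraph::edge_attr(graph, "is_serial"))) {
    df$is_serial <- igraph::edge_attr(graph, "is_serial")
  }
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' One-call association graph for a group
#'
#' Counts, expectations, likelihood weights, serial labelling and pruning in
#' one step.
#'
#' @inheritParams cooccurrence_counts
#' @inheritParams prune_graph
#' @param prune prune the graph (default `TRUE`).
#' @return A pruned, serial-labelled association graph.
#' @export
association_graph <- function(dataset, group, threshold = 1, prune = TRUE,
                              per_component = FALSE) {
  counts <- cooccurrence_counts(dataset, group)
  g <- likelihood_weights(counts)
  g <- label_serial_edges(g, dataset$inventory)
  if (prune) {
    g <- prune_graph(g, threshold = threshold, per_component = per_component)
    g <- label_serial_edges(g, dataset$inventory)  # refresh summary attrs
  }
  g
}
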