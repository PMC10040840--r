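# Shared fixtures and independent oracles. Everything is built in code; the
# oracles (exhaustive enumeration, brute-force subset search) are kept free
# of the package's solver internals so they can certify them.

# small fixed taxonomy: root -> (animals -> (dog, cat), tools -> (hammer, saw))
toy_taxonomy <- function() {
  taxonomy(
    id = c("root", "animals", "tools", "dog", "cat", "hammer", "saw"),
    parent = c(NA, "root", "root", "animals", "animals", "tools", "tools"),
    frequency = c(0, 10, 20, 30, 40, 25, 25)
  )
}

# inventory of 4 objects mapped to the toy taxonomy leaves
toy_inventory <- function() {
  object_inventory(data.frame(
    object_id = c("A", "B", "C", "D"),
    label = c("dog", "cat", "hammer", "saw"),
    position = 1:4,
    zone = c("z1", "z1", "z2", "z2"),
    is_context_typical = c(TRUE, TRUE, FALSE, FALSE),
    taxonomy_leaf = c("dog", "cat", "hammer", "saw"),
    stringsAsFactors = FALSE
  ))
}

# inventory of n generic objects, identity positions
generic_inventory <- function(n, positions = seq_len(n)) {
  object_inventory(data.frame(
    object_id = sprintf("o%02d", seq_len(n)),
    label = sprintf("object %d", seq_len(n)),
    position = positions,
    zone = rep_len(c("z1", "z2", "z3"), n),
    is_context_typical = rep_len(c(TRUE, FALSE), n),
    taxonomy_leaf = sprintf("leaf%02d", seq_len(n)),
    stringsAsFactors = FALSE
  ))
}

# protocol straight from object ids without file round-trip
make_protocol <- function(recalls, inventory, group = "G1", pid = "p01",
                          trial = 1) {
  recall_protocol(group, pid, trial, recalls, inventory)
}

# random symmetric similarity matrix in [0, 1], unit diagonal
random_sim_matrix <- function(n, ids = sprintf("v%02d", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m <- m + t(m)
  diag(m) <- 1
  m
}

# all permutations of a vector (small n only)
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1) return(matrix(v, ncol = n))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# exhaustive maximum-similarity open path; returns best total
brute_force_path_total <- function(sim, start = NULL) {
  ids <- rownames(sim)
  perms <- if (is.null(start)) {
    all_perms(ids)
  } else {
    rest <- all_perms(setdiff(ids, start))
    cbind(start, rest)
  }
  best <- -Inf
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    tot <- sum(sim[cbind(p[-length(p)], p[-1])])
    if (tot > best) best <- tot
  }
  best
}

# brute-force pruning oracle: over all subsets of removable edges (weight >=
# threshold), keep those whose removal leaves every input edge-bearing
# vertex attached (component count on that fixed vertex set must not
# exceed the input's), and maximize the retained sum of -log(weight).
# Returns the optimal objective value.
brute_force_prune_objective <- function(graph, threshold = 1) {
  w <- igraph::edge_attr(graph, "weight")
  m <- igraph::ecount(graph)
  removable <- which(w >= threshold)
  v0 <- igraph::V(graph)$name[igraph::degree(graph) > 0]
  comps_on_v0 <- function(g) {
    igraph::count_components(igraph::induced_subgraph(g, v0))
  }
  comps_in <- comps_on_v0(graph)
  best <- -Inf
  for (code in 0:(2^length(removable) - 1)) {
    drop <- removable[bitwAnd(code, 2^(seq_along(removable) - 1)) > 0]
    g2 <- igraph::delete_edges(graph, drop)
    if (comps_on_v0(g2) > comps_in) next
    obj <- sum(-log(w[setdiff(seq_len(m), drop)]))
    if (obj > best) best <- obj
  }
  best
}

edge_bearing_components <- function(g) {
  deg <- igraph::degree(g)
  sub <- igraph::induced_subgraph(g, which(deg > 0))
  if (igraph::vcount(sub) == 0) return(0L)
  igraph::count_components(sub)
}

# small weighted graph from an edge data frame (from, to, weight)
graph_from_edges <- function(edges, vertices = NULL) {
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

retained_objective <- function(g) {
  sum(-log(igraph::edge_attr(g, "weight")))
}
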