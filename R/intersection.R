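# Shared structure between the two group graphs: the intersection graph,
# its "cliques" (connected components with >= 2 vertices -- shared
# association subgraphs, not complete subgraphs), coherence and attribute
# tests on those cliques, the primacy/recency probe of early recalls, and
# the validity regression of edge likelihoods on semantic similarity.

#' Intersection of two association graphs
#'
#' An edge is present iff the unordered pair is an edge in both pruned
#' graphs; it carries both weights as `weight_1` and `weight_2`.
#'
#' @param g1,g2 pruned association graphs over the same vertex universe.
#' @return An `igraph` over the shared vertex universe.
#' @export
intersection_graph <- function(g1, g2) {
  ids <- sort(igraph::V(g1)$name)
  if (!setequal(ids, igraph::V(g2)$name)) {
    stop("graphs do not share the same vertex universe")
  }
  k1 <- .edge_keys(g1); k2 <- .edge_keys(g2)
  common <- sort(intersect(k1, k2))
  if (length(common)) {
    parts <- do.call(rbind, strsplit(common, " ", fixed = TRUE))
    edges <- data.frame(from = parts[, 1], to = parts[, 2],
                        weight_1 = igraph::edge_attr(g1, "weight")[match(common, k1)],
                        weight_2 = igraph::edge_attr(g2, "weight")[match(common, k2)],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight_1 = numeric(), weight_2 = numeric())
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Extract cliques (shared connected components) from an intersection graph
#'
#' Cliques are the connected components of the intersection graph with at
#' least two vertices, numbered by decreasing size (ties by the smallest
#' member id); singletons stay unassigned.
#'
#' @param intersection an [intersection_graph()] result.
#' @return An object of class `clique_partition`: `cliques` (named list of
#'   character vectors) and `assignment` (named integer vector over all
#'   vertices, `NA` = unassigned).
#' @export
extract_cliques <- function(intersection) {
  comp <- igraph::components(intersection)
  ids <- igraph::V(intersection)$name
  groups <- split(ids, comp$membership)
  groups <- Filter(function(g) length(g) >= 2, groups)
  groups <- lapply(groups, sort)
  if (length(groups)) {
    ord <- order(-vapply(groups, length, 0L),
                 vapply(groups, function(g) g[1], ""))
    groups <- groups[ord]
  }
  names(groups) <- if (length(groups)) paste0("clique", seq_along(groups)) else NULL
  assignment <- stats::setNames(rep(NA_integer_, length(ids)), sort(ids))
  for (k in seq_along(groups)) assignment[groups[[k]]] <- k
  structure(list(cliques = groups, assignment = assignment),
            class = "clique_partition")
}

#' @export
print.clique_partition <- function(x, ...) {
  cat("<clique_partition> ", length(x$cliques), " cliques, ",
      sum(!is.na(x$assignment)), "/", length(x$assignment),
      " vertices assigned\n", sep = "")
  for (k in seq_along(x$cliques)) {
    cat("  ", names(x$cliques)[k], " (", length(x$cliques[[k]]), "): ",
        paste(x$cliques[[k]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Within- vs between-clique association likelihood
#'
#' Pools the edge weights of both pruned graphs and classifies each edge as
#' within-clique (both endpoints in the same clique) or between-clique
#' (endpoints in two different cliques). Edges touching an unassigned vertex
#' are excluded by default (`unassigned = "between"` counts them as
#' between-clique instead). Reports group means/sds, a one-way F test of the
#' within/between contrast, and the graph-1 vs graph-2 comparison among
#' within-clique edges.
#'
#' @param partition a [extract_cliques()] result.
#' @param g1,g2 the pruned association graphs.
#' @param unassigned `"exclude"` or `"between"`.
#' @return A list of class `within_between`: `edges` (data frame),
#'   `mean_within`, `sd_within`, `mean_between`, `sd_between`, `F`, `df`,
#'   `p`, `graph_F`, `graph_p`, `degenerate`.
#' @export
within_between_likelihood <- function(partition, g1, g2,
                                      unassigned = c("exclude", "between")) {
  unassigned <- match.arg(unassigned)
  stopifnot(inherits(partition, "clique_partition"))
  if (length(partition$cliques) == 0) stop("partition has no cliques")
  asg <- partition$assignment
  edge_rows <- function(g, tag) {
    e <- igraph::ends(g, igraph::E(g), names = TRUE)
    if (nrow(e) == 0) return(NULL)
    c1 <- asg[e[, 1]]; c2 <- asg[e[, 2]]
    cls <- ifelse(!is.na(c1) & !is.na(c2) & c1 == c2, "within",
                  ifelse(!is.na(c1) & !is.na(c2), "between",
                         if (unassigned == "between") "between" else NA))
    data.frame(graph = tag, from = e[, 1], to = e[, 2],
               weight = igraph::edge_attr(g, "weight"), class = cls,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(edge_rows(g1, "graph1"), edge_rows(g2, "graph2"))
  edges <- edges[!is.na(edges$class), , drop = FALSE]
  wn <- edges$weight[edges$class == "within"]
  bt <- edges$weight[edges$class == "between"]
  degenerate <- length(bt) == 0 || length(wn) == 0
  if (degenerate) {
    warning("within/between contrast is degenerate (an edge class is empty)")
    fit <- list(F = NA_real_, df = c(NA_real_, NA_real_), p = NA_real_)
  } else {
    fit <- .oneway_F(edges$weight, edges$class)
  }
  wedges <- edges[edges$class == "within", , drop = FALSE]
  gfit <- if (length(unique(wedges$graph)) == 2) {
    .oneway_F(wedges$weight, wedges$graph)
  } else {
    list(F = NA_real_, df = c(NA_real_, NA_real_), p = NA_real_)
  }
  structure(
    list(edges = edges,
         mean_within = mean(wn), sd_within = stats::sd(wn),
         mean_between = if (length(bt)) mean(bt) else NA_real_,
         sd_between = if (length(bt)) stats::sd(bt) else NA_real_,
         F = fit$F, df = fit$df, p = fit$p,
         graph_F = gfit$F, graph_df = gfit$df, graph_p = gfit$p,
         degenerate = degenerate),
    class = "within_between")
}

.oneway_F <- function(y, g) {
  fit <- stats::anova(stats::lm(y ~ factor(g)))
  list(F = fit$`F value`[1], df = fit$Df, p = fit$`Pr(>F)`[1])
}

#' Clique x attribute association (chi-square)
#'
#' Contingency table of clique membership against an object attribute
#' (context typicality or spatial zone) over assigned vertices; Pearson
#' chi-square without continuity correction, with a warning when expected
#' cell counts fall below 5 (an exact test option is provided).
#'
#' @param partition a [extract_cliques()] result with >= 2 cliques.
#' @param inventory the [object_inventory].
#' @param attribute `"context"` (the `is_context_typical` flag) or `"zone"`.
#' @param exact use Fisher's exact test instead (small tables).
#' @return A list: `table`, `statistic`, `df`, `p`, `method`.
#' @export
clique_attribute_association <- function(partition, inventory,
                                         attribute = c("context", "zone"),
                                         exact = FALSE) {
  attribute <- match.arg(attribute)
  stopifnot(inherits(partition, "clique_partition"))
  if (length(partition$cliques) < 2) stop("need at least 2 cliques")
  asg <- partition$assignment
  assigned <- names(asg)[!is.na(asg)]
  vals <- if (attribute == "context") {
    inventory$is_context_typical[match(assigned, inventory$object_id)]
  } else {
    inventory$zone[match(assigned, inventory$object_id)]
  }
  if (length(unique(vals)) < 2) {
    stop("attribute '", attribute, "' is constant over assigned vertices")
  }
  tab <- table(clique = asg[assigned], attribute = vals)
  if (exact) {
    ft <- stats::fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 10,
                             B = 1e4)
    return(list(table = tab, statistic = NA_real_, df = NA_real_,
                p = ft$p.value, method = "fisher_exact"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    warning("expected cell counts below 5; chi-square approximation is rough ",
            "(consider exact = TRUE)")
  }
  list(table = tab, statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, method = "chisq_no_correction")
}

#' Primacy/recency probe of early recalls
#'
#' Among the first `k` recalls of every protocol, counts how many objects
#' come from the primacy region (presentation positions `1..primacy_len`)
#' and the recency region (last `recency_len` positions), then compares the
#' two groups by rank-sum on each count.
#'
#' @param dataset a [study_dataset].
#' @param k number of initial recalls probed (default 10).
#' @param primacy_len,recency_len region lengths (defaults 7 and 3).
#' @return A list of class `primacy_recency`: `per_protocol` (data frame),
#'   `summary` (group means/sds), and rank-sum results `primacy_test`,
#'   `recency_test` (when two groups are present).
#' @export
primacy_recency_probe <- function(dataset, k = 10L, primacy_len = 7L,
                                  recency_len = 3L) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (k < 1) stop("k must be >= 1")
  N <- n_objects(dataset$inventory)
  inv <- dataset$inventory
  rows <- lapply(dataset$protocols, function(p) {
    first <- p$recalls[seq_len(min(k, p$r))]
    pos <- inv$position[match(first, inv$object_id)]
    data.frame(group = p$group, participant_id = p$participant_id,
               trial = p$trial,
               primacy = sum(pos <= primacy_len),
               recency = sum(pos > N - recency_len),
               stringsAsFactors = FALSE)
  })
  pp <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  agg <- do.call(rbind, lapply(split(pp, pp$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               primacy_mean = mean(d$primacy), primacy_sd = stats::sd(d$primacy),
               recency_mean = mean(d$recency), recency_sd = stats::sd(d$recency),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  out <- list(per_protocol = pp, summary = agg,
              k = k, primacy_len = primacy_len, recency_len = recency_len)
  groups <- sort(unique(pp$group))
  if (length(groups) == 2) {
    sp <- split(pp, factor(pp$group, levels = groups))
    out$primacy_test <- .rank_sum(sp[[1]]$primacy, sp[[2]]$primacy)
    out$recency_test <- .rank_sum(sp[[1]]$recency, sp[[2]]$recency)
  }
  class(out) <- "primacy_recency"
  out
}

#' Validity regression of edge likelihoods on semantic similarity
#'
#' Pools the edges of both pruned graphs (weight, Lin similarity of the two
#' endpoints' leaves, serial flag, source group), excludes edges touching
#' the primacy/recency regions, and fits OLS
#' `weight ~ similarity_z + is_serial + group` with the similarity
#' standardized over the pooled edges. On study-like data the similarity
#' coefficient is negative: semantically closer pairs carry smaller
#' (stronger) association likelihoods.
#'
#' @param g1,g2 pruned association graphs with `is_serial` edge attributes.
#' @param sim a [similarity_matrix] over the same objects.
#' @param inventory the [object_inventory] (positions for the exclusions).
#' @param exclude_primacy,exclude_recency region lengths to drop (defaults
#'   7 and 3; 0 disables).
#' @return A list of class `validity_regression`: `coefficients`, `R2`,
#'   `F`, `df`, `p`, `n_edges`, `model` (the `lm` fit), `edges`.
#' @export
likelihood_similarity_regression <- function(g1, g2, sim, inventory,
                                             exclude_primacy = 7L,
                                             exclude_recency = 3L) {
  N <- n_objects(inventory)
  excluded_pos <- c(seq_len(exclude_primacy),
                    if (exclude_recency > 0) (N - exclude_recency + 1L):N)
  excluded <- inventory$object_id[inventory$position %in% excluded_pos]
  edge_rows <- function(g, tag) {
    e <- igraph::ends(g, igraph::E(g), names = TRUE)
    if (nrow(e) == 0) return(NULL)
    data.frame(graph = tag, from = e[, 1], to = e[, 2],
               weight = igraph::edge_attr(g, "weight"),
               similarity = sim[cbind(e[, 1], e[, 2])],
               is_serial = igraph::edge_attr(g, "is_serial"),
               stringsAsFactors = FALSE)
  }
  edges <- rbind(edge_rows(g1, "graph1"), edge_rows(g2, "graph2"))
  edges <- edges[!(edges$from %in% excluded | edges$to %in% excluded), ,
                 drop = FALSE]
  if (nrow(edges) < 10) {
    stop("fewer than 10 usable edges after exclusions (", nrow(edges), ")")
  }
  if (stats::sd(edges$similarity) == 0) {
    warning("similarity is constant across usable edges; term dropped")
    edges$similarity_z <- NULL
    form <- weight ~ is_serial + graph
  } else {
    edges$similarity_z <- as.numeric(scale(edges$similarity))
    form <- weight ~ similarity_z + is_serial + graph
  }
  fit <- stats::lm(form, data = edges)
  sm <- summary(fit)
  structure(
    list(coefficients = stats::coef(sm), R2 = sm$r.squared,
         F = unname(sm$fstatistic[1]),
         df = unname(sm$fstatistic[2:3]),
         p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                       lower.tail = FALSE),
         n_edges = nrow(edges), model = fit, edges = edges),
    class = "validity_regression")
}

#' @export
print.validity_regression <- function(x, ...) {
  cat("<validity_regression> ", x$n_edges, " edges, R2 = ",
      format(x$R2, digits = 3), ", F(", x$df[1], ",", x$df[2], ") = ",
      format(x$F, digits = 3), ", p = ", format(x$p, digits = 3), "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}
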