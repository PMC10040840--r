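# Graph-level and per-vertex metrics of pruned association networks, and
# the small-world index sigma = (C/C_rand)/(L/L_rand) estimated against
# connected Erdos-Renyi null graphs with matched vertex and edge counts.
# C is the mean local (triangle-based) clustering coefficient, L the mean
# shortest-path length; sigma uses their unweighted versions, while the
# descriptive metrics table also reports likelihood-weighted path lengths.

# mean local clustering, 0 for degree < 2
.mean_local_clustering <- function(g) {
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(lc)
}

# per-vertex mean shortest-path distance to all reachable others;
# weights = NA means topological (unweighted) distances
.mean_path_lengths <- function(g, weights = NA) {
  d <- igraph::distances(g, weights = weights)
  diag(d) <- NA
  d[is.infinite(d)] <- NA
  rowMeans(d, na.rm = TRUE)
}

#' Descriptive metrics of a pruned association graph
#'
#' Per-vertex: unweighted degree, local (triangle) clustering coefficient
#' (0 for degree < 2), and mean weighted shortest-path distance to every
#' other vertex, using the likelihood weight as edge length. Graph level:
#' edge count, mean degree, mean clustering `C`, mean weighted path length
#' `L`, serial-edge count/fraction and median weight. Metrics are computed
#' on the edge-bearing subgraph (isolated vertices drop out at pruning).
#'
#' @param graph a pruned association graph.
#' @param per_component allow a disconnected graph (metrics per component,
#'   with a flag); default errors on disconnected input.
#' @return A list of class `graph_metrics` with `per_vertex` (data frame)
#'   and `graph_level` (list); unweighted `C` and `L` are carried along for
#'   the small-world index.
#' @export
compute_metrics <- function(graph, per_component = FALSE) {
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
  }
  deg_all <- igraph::degree(graph)
  g <- igraph::induced_subgraph(graph, which(deg_all > 0))
  ncomp <- if (igraph::vcount(g)) igraph::count_components(g) else 0L
  if (ncomp > 1 && !per_component) {
    stop("graph is disconnected (", ncomp,
         " components); pass per_component = TRUE for per-component metrics")
  }
  deg <- igraph::degree(g)
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  w <- igraph::edge_attr(g, "weight")
  pv <- data.frame(
    vertex = igraph::V(g)$name, degree = deg, local_clustering = lc,
    mean_path_length_weighted = .mean_path_lengths(g, weights = w),
    stringsAsFactors = FALSE)
  rownames(pv) <- NULL
  is_serial <- igraph::edge_attr(g, "is_serial")
  gl <- list(
    n_vertices = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_components = ncomp,
    mean_degree = if (igraph::vcount(g)) 2 * igraph::ecount(g) / igraph::vcount(g) else NA_real_,
    mean_clustering = mean(lc),
    mean_path_length = mean(pv$mean_path_length_weighted, na.rm = TRUE),
    serial_edge_count = if (is.null(is_serial)) NA_integer_ else sum(is_serial),
    serial_fraction = if (is.null(is_serial)) NA_real_ else mean(is_serial),
    median_weight = if (length(w)) stats::median(w) else NA_real_)
  structure(
    list(per_vertex = pv, graph_level = gl,
         C_unweighted = mean(lc),
         L_unweighted = mean(.mean_path_lengths(g), na.rm = TRUE)),
    class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  gl <- x$graph_level
  cat("<graph_metrics> ", gl$n_vertices, " vertices, ", gl$n_edges, " edges\n",
      "  mean degree ", format(gl$mean_degree, digits = 3),
      ", C ", format(gl$mean_clustering, digits = 3),
      ", weighted L ", format(gl$mean_path_length, digits = 3),
      ", median weight ", format(gl$median_weight, digits = 3), "\n", sep = "")
  if (!is.na(gl$serial_edge_count)) {
    cat("  serial edges ", gl$serial_edge_count, " (",
        format(100 * gl$serial_fraction, digits = 3), "%)\n", sep = "")
  }
  invisible(x)
}

#' Small-world index sample against connected ER nulls
#'
#' For each of `n_samples` draws, a G(n, m) Erdos-Renyi graph with the
#' observed vertex and edge counts is sampled, redrawing until it is
#' connected and contains at least one triangle (otherwise the index is
#' undefined). Each draw yields a per-draw ratio
#' `sigma_k = (C/C_k) / (L/L_k)` with the observed graph's unweighted mean
#' local clustering `C` and mean path length `L`; the point estimate
#' `mean_sigma` is the ratio-of-means form
#' `(C / mean(C_k)) / (L / mean(L_k))`. The two differ: the mean of the
#' per-draw ratios is upward-biased (Jensen's inequality on `1/C_k`) in
#' exactly the sparse regime these networks occupy, and only the
#' ratio-of-means form is centred at 1 when the observed graph is itself an
#' ER draw. The per-draw ratios are kept for dispersion (`sd_sigma`) and
#' distributional comparison between groups.
#'
#' @param graph a pruned, connected association graph.
#' @param n_samples number of null graphs (the study default is 3000).
#' @param seed integer RNG seed; recorded in the result.
#' @param max_retries redraw budget per sample before giving up.
#' @return An object of class `sigma_sample`: `sigmas` (per-draw ratios),
#'   `n_samples`, `seed`, `mean_sigma` (ratio-of-means point estimate),
#'   `sd_sigma` (sd of the per-draw ratios), null ensemble means
#'   `C_null`, `L_null`, and the observed `C`, `L`, `n`, `m`.
#' @export
sample_sigma <- function(graph, n_samples = 3000L, seed, max_retries = 1000L) {
  stopifnot(n_samples >= 1)
  if (missing(seed)) stop("a seed is required for the random-graph sampling")
  deg <- igraph::degree(graph)
  g <- igraph::induced_subgraph(graph, which(deg > 0))
  if (igraph::count_components(g) != 1) {
    stop("sigma requires a connected graph")
  }
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  C <- .mean_local_clustering(g)
  L <- mean(.mean_path_lengths(g), na.rm = TRUE)
  set.seed(as.integer(seed))
  Ck <- numeric(n_samples)
  Lk <- numeric(n_samples)
  for (k in seq_len(n_samples)) {
    tries <- 0L
    repeat {
      gk <- igraph::sample_gnm(n, m)
      tries <- tries + 1L
      if (igraph::is_connected(gk)) {
        c_k <- .mean_local_clustering(gk)
        if (c_k > 0) break
      }
      if (tries >= max_retries) {
        stop("could not draw a connected, triangle-bearing ER graph with n = ",
             n, ", m = ", m, " within ", max_retries, " retries")
      }
    }
    Ck[k] <- c_k
    Lk[k] <- igraph::mean_distance(gk)
  }
  sigmas <- (C / Ck) / (L / Lk)
  structure(
    list(sigmas = sigmas, n_samples = n_samples, seed = as.integer(seed),
         mean_sigma = (C / mean(Ck)) / (L / mean(Lk)),
         sd_sigma = stats::sd(sigmas),
         C_null = mean(Ck), L_null = mean(Lk),
         C = C, L = L, n = n, m = m),
    class = "sigma_sample")
}

#' @export
print.sigma_sample <- function(x, ...) {
  cat("<sigma_sample> n = ", x$n, ", m = ", x$m, ", ", x$n_samples,
      " null graphs (seed ", x$seed, ")\n  sigma ",
      format(x$mean_sigma, digits = 4), " (per-draw sd ",
      format(x$sd_sigma, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Fold change of observed small-worldness over a calibration expectation
#'
#' Small-worldness and edge counts scale log-linearly with vertex count, so
#' an observed mean sigma is judged against the sigma expected for a network
#' of that size. The calibration (e.g., a user-fitted log-linear model
#' evaluated at the observed vertex count) is supplied, not assumed.
#'
#' @param sample a [sample_sigma()] result.
#' @param expected_sigma positive calibration value.
#' @return `mean_sigma / expected_sigma`.
#' @export
sigma_fold_change <- function(sample, expected_sigma) {
  stopifnot(inherits(sample, "sigma_sample"))
  if (!is.numeric(expected_sigma) || expected_sigma <= 0) {
    stop("expected_sigma must be positive")
  }
  sample$mean_sigma / expected_sigma
}

# Wilcoxon signed-rank z (paired), normal approximation, zero differences
# dropped, tie correction on |d| ranks; z > 0 means x tends above y
.signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  nz <- length(d)
  if (nz == 0) return(list(z = 0, p = 1, n_nonzero = 0L))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- nz * (nz + 1) / 4
  ties <- table(rk)
  v <- nz * (nz + 1) * (2 * nz + 1) / 24 - sum(ties^3 - ties) / 48
  if (v <= 0) return(list(z = 0, p = 1, n_nonzero = nz))
  z <- (W - mu) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n_nonzero = nz)
}

# phi coefficient of a 2x2 table (no continuity correction)
.phi_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  den <- sqrt(prod(c(a + b, c + d, a + c, b + d)))
  if (den == 0) return(0)
  (a * d - b * c) / den
}

#' Compare two group graphs
#'
#' Per-vertex metrics (degree, local clustering, weighted path length) are
#' compared pairwise across the shared vertex set by Wilcoxon signed rank
#' with effect size `z/sqrt(n)`; edge weights by rank-sum over the two edge
#' weight collections (unpaired by default, `paired_edges = TRUE` restricts
#' to common edges and pairs them); serial-edge proportions by Fisher's
#' exact test on the 2x2 table with the phi coefficient; sigma by rank-sum
#' on the two sigma samples.
#'
#' @param g1,g2 pruned association graphs over the same vertex universe.
#' @param m1,m2 their [compute_metrics()] results.
#' @param s1,s2 their [sample_sigma()] results.
#' @param paired_edges pair the edge-weight comparison on common edges.
#' @return A data frame with one row per comparison: `metric`, `value1`,
#'   `value2`, `statistic`, `effect_size`, `p`, `test`.
#' @export
compare_graphs <- function(g1, g2, m1, m2, s1, s2, paired_edges = FALSE) {
  if (!setequal(igraph::V(g1)$name, igraph::V(g2)$name)) {
    stop("graphs do not share the same vertex universe")
  }
  rows <- list()
  shared <- sort(union(m1$per_vertex$vertex, m2$per_vertex$vertex))
  per_vertex_of <- function(m, col) {
    v <- m$per_vertex[[col]][match(shared, m$per_vertex$vertex)]
    # vertices isolated in one graph contribute degree 0 / clustering 0
    if (col != "mean_path_length_weighted") v[is.na(v)] <- 0
    v
  }
  for (col in c("degree", "local_clustering", "mean_path_length_weighted")) {
    x <- per_vertex_of(m1, col); y <- per_vertex_of(m2, col)
    keep <- !(is.na(x) | is.na(y))
    sr <- .signed_rank(x[keep], y[keep])
    rows[[length(rows) + 1L]] <- data.frame(
      metric = col, value1 = mean(x[keep]), value2 = mean(y[keep]),
      statistic = sr$z, effect_size = sr$z / sqrt(sum(keep)), p = sr$p,
      test = "wilcoxon_signed_rank", stringsAsFactors = FALSE)
  }
  w1 <- igraph::edge_attr(g1, "weight")
  w2 <- igraph::edge_attr(g2, "weight")
  if (paired_edges) {
    k1 <- .edge_keys(g1); k2 <- .edge_keys(g2)
    common <- intersect(k1, k2)
    sr <- .signed_rank(w1[match(common, k1)], w2[match(common, k2)])
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "weight", value1 = stats::median(w1), value2 = stats::median(w2),
      statistic = sr$z, effect_size = sr$z / sqrt(length(common)), p = sr$p,
      test = "wilcoxon_signed_rank_common_edges", stringsAsFactors = FALSE)
  } else {
    rs <- .rank_sum(w1, w2)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "weight", value1 = stats::median(w1), value2 = stats::median(w2),
      statistic = rs$z, effect_size = rs$z / sqrt(length(w1) + length(w2)),
      p = rs$p, test = "wilcoxon_rank_sum", stringsAsFactors = FALSE)
  }
  sc <- c(m1$graph_level$serial_edge_count, m2$graph_level$serial_edge_count)
  me <- c(m1$graph_level$n_edges, m2$graph_level$n_edges)
  if (!anyNA(sc)) {
    tab <- rbind(serial = sc, non_serial = me - sc)
    fish <- stats::fisher.test(tab)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "serial_fraction", value1 = sc[1] / me[1], value2 = sc[2] / me[2],
      statistic = NA_real_, effect_size = .phi_2x2(tab), p = fish$p.value,
      test = "fisher_exact_phi", stringsAsFactors = FALSE)
  }
  rs <- .rank_sum(s1$sigmas, s2$sigmas)
  rows[[length(rows) + 1L]] <- data.frame(
    metric = "sigma", value1 = s1$mean_sigma, value2 = s2$mean_sigma,
    statistic = rs$z, effect_size = rs$z / sqrt(s1$n_samples + s2$n_samples),
    p = rs$p, test = "wilcoxon_rank_sum", stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.edge_keys <- function(g) {
  e <- igraph::ends(g, igraph::E(g), names = TRUE)
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}
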