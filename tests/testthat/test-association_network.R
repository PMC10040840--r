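# Co-occurrence counting, independence expectations, likelihood weights,
# serial labelling and connectivity-preserving pruning (with a brute-force
# subset oracle).

test_that("co-occurrence counts accumulate consecutive pairs symmetrically", {
  inv <- generic_inventory(5)
  p1 <- make_protocol(c("o01", "o02", "o03"), inv, group = "G", pid = "a", trial = 1)
  p2 <- make_protocol(c("o01", "o02"), inv, group = "G", pid = "b", trial = 1)
  ds <- study_dataset(inv, list(p1, p2))
  cm <- cooccurrence_counts(ds, "G")
  expect_equal(cm["o01", "o02"], 2)
  expect_equal(cm["o02", "o01"], 2)
  expect_equal(cm["o02", "o03"], 1)
  expect_equal(cm["o01", "o03"], 0)
  expect_equal(unname(diag(cm)), rep(0, 5))
  # conservation: upper-triangle mass equals total transitions
  expect_equal(sum(cm[upper.tri(cm)]), (3 - 1) + (2 - 1))
  expect_error(cooccurrence_counts(ds, "nope"), "no protocols")
})

test_that("transition mass is conserved over a simulated group", {
  set.seed(91)
  inv <- generic_inventory(12)
  protos <- list()
  for (pid in 1:6) {
    for (tr in 1:5) {
      protos[[length(protos) + 1L]] <- make_protocol(
        sample(inv$object_id, sample(0:12, 1)), inv, group = "G",
        pid = sprintf("p%02d", pid), trial = tr)
    }
  }
  ds <- study_dataset(inv, protos)
  cm <- cooccurrence_counts(ds, "G")
  expect_equal(sum(cm[upper.tri(cm)]),
               sum(vapply(protos, function(p) max(p$r - 1, 0), 0)))
})

test_that("independence expectations use involvement margins over the table sum", {
  inv <- generic_inventory(3)
  ds <- study_dataset(inv, list(
    make_protocol(c("o01", "o02"), inv, pid = "a", trial = 1),
    make_protocol(c("o01", "o02"), inv, pid = "a", trial = 2),
    make_protocol(c("o01", "o02"), inv, pid = "a", trial = 3),
    make_protocol(c("o01", "o02"), inv, pid = "a", trial = 4)))
  cm <- cooccurrence_counts(ds, "G1")
  # counts: AB = 4 only; margins m_A = m_B = 4, table sum = 8
  expected <- expected_counts(cm)
  expect_equal(expected["o01", "o02"], 4 * 4 / 8)
  expect_equal(expected["o01", "o03"], 0)
  # observed exceeds expected for the only observed pair
  expect_gt(cm["o01", "o02"], expected["o01", "o02"])
  expect_error(expected_counts(cm * 0L), "all zero")
})

test_that("likelihood weights are expected over observed", {
  inv <- generic_inventory(4)
  counts <- matrix(0L, 4, 4, dimnames = list(inv$object_id, inv$object_id))
  counts["o01", "o02"] <- counts["o02", "o01"] <- 8L
  counts["o02", "o03"] <- counts["o03", "o02"] <- 2L
  class(counts) <- c("cooccurrence_matrix", class(counts))
  attr(counts, "group") <- "G"
  expected <- expected_counts(counts)
  g <- likelihood_weights(counts, expected)
  expect_equal(igraph::ecount(g), 2)
  w <- igraph::edge_attr(g, "weight")
  k <- recallnet:::.edge_keys(g)
  expect_equal(w[k == "o01 o02"], expected["o01", "o02"] / 8)
  expect_equal(w[k == "o02 o03"], expected["o02", "o03"] / 2)
  # observed = 4 * expected -> weight 0.25
  cm2 <- counts
  cm2[] <- 0L
  cm2["o01", "o02"] <- cm2["o02", "o01"] <- 4L
  exp2 <- cm2; exp2[] <- 0; exp2["o01", "o02"] <- exp2["o02", "o01"] <- 1
  g2 <- likelihood_weights(cm2, exp2)
  expect_equal(igraph::edge_attr(g2, "weight"), 0.25)
})

test_that("serial edges are flagged without wraparound", {
  set.seed(92)
  n <- 10
  inv <- generic_inventory(n, positions = sample(n))
  ids_at <- function(pos) inv$object_id[match(pos, inv$position)]
  edges <- data.frame(from = ids_at(c(7, 1, 3)), to = ids_at(c(8, n, 5)),
                      weight = c(0.5, 0.5, 0.5))
  g <- graph_from_edges(edges, vertices = data.frame(name = inv$object_id))
  g <- label_serial_edges(g, inv)
  k <- recallnet:::.edge_keys(g)
  key_of <- function(a, b) paste(min(ids_at(a), ids_at(b)), max(ids_at(a), ids_at(b)))
  is_serial <- igraph::edge_attr(g, "is_serial")
  expect_true(is_serial[k == key_of(7, 8)])
  expect_false(is_serial[k == key_of(1, n)])  # no wraparound
  expect_false(is_serial[k == key_of(3, 5)])
  expect_equal(igraph::graph_attr(g, "serial_count"), 1)
})

test_that("pruning removes weak edges while preserving connectivity", {
  # triangle with one above-threshold edge: becomes a path
  tri <- graph_from_edges(data.frame(from = c("a", "b", "a"),
                                     to = c("b", "c", "c"),
                                     weight = c(0.2, 0.3, 1.5)))
  pr <- prune_graph(tri)
  expect_equal(igraph::ecount(pr), 2)
  expect_false("a c" %in% recallnet:::.edge_keys(pr))
  expect_equal(edge_bearing_components(pr), 1)

  # all weights below 1: nothing removed
  ok <- graph_from_edges(data.frame(from = c("a", "b"), to = c("b", "c"),
                                    weight = c(0.4, 0.9)))
  expect_equal(igraph::ecount(prune_graph(ok)), 2)

  # a weight-2 bridge in a tree is retained (connectivity constraint)
  tree <- graph_from_edges(data.frame(from = c("a", "b", "c"),
                                      to = c("b", "c", "d"),
                                      weight = c(0.5, 2.0, 0.5)))
  expect_equal(igraph::ecount(prune_graph(tree)), 3)

  # a pendant above-threshold edge is retained: its leaf may not be cut off
  pend <- graph_from_edges(data.frame(from = c("a", "b", "c"),
                                      to = c("b", "c", "d"),
                                      weight = c(0.5, 0.5, 3.0)))
  pr2 <- prune_graph(pend)
  expect_equal(igraph::ecount(pr2), 3)
  expect_equal(edge_bearing_components(pr2), 1)

  # above-threshold chord of a cycle goes, even off a pendant-bearing core
  cyc <- graph_from_edges(data.frame(from = c("a", "b", "c", "a"),
                                     to = c("b", "c", "a", "d"),
                                     weight = c(0.5, 0.5, 3.0, 2.0)))
  pr2b <- prune_graph(cyc)
  expect_setequal(recallnet:::.edge_keys(pr2b), c("a b", "b c", "a d"))

  # disconnected input errors unless per_component
  disc <- graph_from_edges(data.frame(from = c("a", "c"), to = c("b", "d"),
                                      weight = c(1.5, 0.2)))
  expect_error(prune_graph(disc), "disconnected")
  expect_warning(pr3 <- prune_graph(disc, per_component = TRUE), "disconnected")
  expect_equal(igraph::ecount(pr3), 2)  # each edge is its component's bridge
})

test_that("pruning matches the brute-force subset oracle on small graphs", {
  set.seed(93)
  for (rep in 1:40) {
    n <- sample(4:6, 1)
    ids <- letters[seq_len(n)]
    # random connected graph with <= 7 edges
    all_pairs <- t(utils::combn(ids, 2))
    m <- sample(n - 1 + 0:3, 1)
    m <- min(m, nrow(all_pairs), 7)
    repeat {
      pick <- all_pairs[sample.int(nrow(all_pairs), m), , drop = FALSE]
      g <- graph_from_edges(data.frame(from = pick[, 1], to = pick[, 2],
                                       weight = stats::runif(m, 0.1, 2.5)))
      if (edge_bearing_components(g) == 1) break
    }
    pr <- prune_graph(g)
    expect_equal(retained_objective(pr), brute_force_prune_objective(g),
                 tolerance = 1e-9)
    expect_lte(edge_bearing_components(pr), 1)
    # no removable (weight >= 1) edge could still be dropped legally without
    # lowering the objective below the oracle optimum: oracle equality covers it
  }
})

test_that("pruning is deterministic and reports retention fractions", {
  set.seed(94)
  inv <- generic_inventory(8)
  protos <- list()
  for (pid in 1:5) {
    for (tr in 1:5) {
      protos[[length(protos) + 1L]] <- make_protocol(
        sample(inv$object_id, 6), inv, group = "G",
        pid = sprintf("p%02d", pid), trial = tr)
    }
  }
  ds <- study_dataset(inv, protos)
  g1 <- association_graph(ds, "G")
  g2 <- association_graph(ds, "G")
  expect_identical(recallnet:::.edge_keys(g1), recallnet:::.edge_keys(g2))
  rf <- igraph::graph_attr(g1, "retained_fraction_pairs")
  expect_equal(rf, igraph::ecount(g1) / choose(8, 2))
  expect_lte(igraph::graph_attr(g1, "retained_fraction_observed"), 1)
})

test_that("graph export writes GraphML and edge CSV with attributes", {
  set.seed(95)
  inv <- generic_inventory(6)
  protos <- lapply(1:5, function(tr) make_protocol(
    sample(inv$object_id, 5), inv, group = "G", pid = "p1", trial = tr))
  ds <- study_dataset(inv, protos)
  g <- association_graph(ds, "G")
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, inv, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_true("position" %in% igraph::vertex_attr_names(back))
  el <- utils::read.csv(paste0(path, ".csv"))
  expect_equal(nrow(el), igraph::ecount(g))
  expect_true(all(c("count", "expected", "weight", "is_serial") %in% names(el)))
})
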