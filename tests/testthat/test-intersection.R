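# Intersection graph, clique extraction, within/between coherence,
# attribute association, primacy/recency probe, and the validity
# regression's parameter recovery.

ids6 <- sprintf("o%02d", 1:6)

mkgraph <- function(edges, vertices = ids6) {
  graph_from_edges(edges, vertices = data.frame(name = vertices))
}

test_that("intersection keeps only shared unordered pairs with both weights", {
  g1 <- mkgraph(data.frame(from = c("o01", "o02", "o04"),
                           to = c("o02", "o03", "o05"),
                           weight = c(0.1, 0.2, 0.3)))
  g2 <- mkgraph(data.frame(from = c("o01", "o03", "o04"),
                           to = c("o02", "o04", "o05"),
                           weight = c(0.15, 0.25, 0.35)))
  gi <- intersection_graph(g1, g2)
  expect_setequal(recallnet:::.edge_keys(gi), c("o01 o02", "o04 o05"))
  k <- recallnet:::.edge_keys(gi)
  expect_equal(igraph::edge_attr(gi, "weight_1")[k == "o01 o02"], 0.1)
  expect_equal(igraph::edge_attr(gi, "weight_2")[k == "o01 o02"], 0.15)

  # idempotence and commutativity
  expect_setequal(recallnet:::.edge_keys(intersection_graph(g1, g1)),
                  recallnet:::.edge_keys(g1))
  expect_setequal(recallnet:::.edge_keys(intersection_graph(g2, g1)),
                  recallnet:::.edge_keys(gi))
  expect_lte(igraph::ecount(gi), min(igraph::ecount(g1), igraph::ecount(g2)))

  # disjoint edge sets -> empty intersection, zero cliques
  g3 <- mkgraph(data.frame(from = "o03", to = "o06", weight = 0.5))
  gi0 <- intersection_graph(g1, g3)
  expect_equal(igraph::ecount(gi0), 0)
  expect_length(extract_cliques(gi0)$cliques, 0)
})

test_that("cliques are connected components of size >= 2, largest first", {
  g1 <- mkgraph(data.frame(from = c("o01", "o02", "o04"),
                           to = c("o02", "o03", "o05"),
                           weight = 0.1))
  g2 <- mkgraph(data.frame(from = c("o01", "o02", "o04"),
                           to = c("o02", "o03", "o05"),
                           weight = 0.2))
  part <- extract_cliques(intersection_graph(g1, g2))
  expect_length(part$cliques, 2)
  expect_equal(part$cliques[[1]], c("o01", "o02", "o03"))  # chain = one clique
  expect_equal(part$cliques[[2]], c("o04", "o05"))
  expect_equal(unname(part$assignment["o06"]), NA_integer_)
  # partition property: assigned + unassigned covers all, no overlap
  expect_setequal(names(part$assignment), ids6)
  expect_equal(sum(!is.na(part$assignment)), 5)
})

test_that("within-clique edges are stronger than between-clique edges", {
  # constructed contrast: within weights near 0.1, between near 0.2
  g1 <- mkgraph(data.frame(from = c("o01", "o03", "o02"),
                           to = c("o02", "o04", "o03"),
                           weight = c(0.10, 0.12, 0.20)))
  g2 <- mkgraph(data.frame(from = c("o01", "o03", "o02"),
                           to = c("o02", "o04", "o03"),
                           weight = c(0.11, 0.13, 0.22)))
  # intersection is the full shared structure; force two cliques by hand
  part <- structure(list(
    cliques = list(clique1 = c("o01", "o02"), clique2 = c("o03", "o04")),
    assignment = setNames(c(1L, 1L, 2L, 2L, NA, NA), ids6)),
    class = "clique_partition")
  wb <- within_between_likelihood(part, g1, g2)
  expect_equal(wb$mean_within, mean(c(0.10, 0.12, 0.11, 0.13)))
  expect_equal(wb$mean_between, 0.21)
  expect_false(wb$degenerate)
  expect_lt(wb$p, 0.05)
  # graph1-vs-graph2 within-clique contrast is null here
  expect_gt(wb$graph_p, 0.3)

  # all edges within one clique -> degenerate flag
  part1 <- structure(list(
    cliques = list(clique1 = c("o01", "o02", "o03", "o04")),
    assignment = setNames(c(1L, 1L, 1L, 1L, NA, NA), ids6)),
    class = "clique_partition")
  expect_warning(wb1 <- within_between_likelihood(part1, g1, g2), "degenerate")
  expect_true(wb1$degenerate)
})

test_that("clique-attribute association matches hand chi-square", {
  inv <- generic_inventory(6)
  part <- structure(list(
    cliques = list(clique1 = c("o01", "o03", "o05"),
                   clique2 = c("o02", "o04", "o06")),
    assignment = setNames(c(1L, 2L, 1L, 2L, 1L, 2L),
                          sprintf("o%02d", 1:6))),
    class = "clique_partition")
  # is_context_typical alternates TRUE/FALSE with position, so cliques split
  # it perfectly: table {{3,0},{0,3}} -> chi-square = 6 without correction
  res <- suppressWarnings(
    clique_attribute_association(part, inv, "context"))
  expect_equal(res$statistic, 6)
  expect_equal(res$df, 1)

  # degenerate constant attribute
  inv2 <- as.data.frame(inv)
  inv2$is_context_typical <- TRUE
  expect_error(
    clique_attribute_association(part, object_inventory(inv2), "context"),
    "constant")

  # independence null: p approximately uniform over simulated partitions
  set.seed(111)
  inv3 <- generic_inventory(24)
  pvals <- replicate(60, {
    ids <- sample(inv3$object_id)
    part3 <- structure(list(
      cliques = list(clique1 = ids[1:8], clique2 = ids[9:16],
                     clique3 = ids[17:24]),
      assignment = setNames(rep(1:3, each = 8), ids)),
      class = "clique_partition")
    suppressWarnings(
      clique_attribute_association(part3, inv3, "context"))$p
  })
  # not systematically small under the null (p is discrete, so only a
  # coarse calibration check is meaningful)
  expect_gt(mean(pvals), 0.3)
  expect_lte(mean(pvals < 0.05), 0.15)
})

test_that("primacy/recency probe counts early-region recalls", {
  n <- 46
  inv <- generic_inventory(n)
  ids_at <- function(pos) inv$object_id[match(pos, inv$position)]
  p1 <- make_protocol(ids_at(1:10), inv, group = "A", pid = "a1")
  p2 <- make_protocol(ids_at(c(44, 45, 46, 20, 21)), inv, group = "B", pid = "b1")
  ds <- study_dataset(inv, list(p1, p2))
  probe <- primacy_recency_probe(ds)
  pp <- probe$per_protocol
  expect_equal(pp$primacy[pp$group == "A"], 7)
  expect_equal(pp$recency[pp$group == "A"], 0)
  expect_equal(pp$recency[pp$group == "B"], 3)
  expect_error(primacy_recency_probe(ds, k = 0), "k must be")
})

test_that("validity regression recovers planted slopes", {
  set.seed(112)
  n <- 46
  inv <- generic_inventory(n)
  ids <- inv$object_id
  sim <- random_sim_matrix(n, ids = ids)
  # usable vertices: positions 8..43 (outside primacy 7 / recency 3)
  usable <- ids[inv$position >= 8 & inv$position <= 43]
  mkedges <- function(n_edges) {
    pairs <- t(replicate(n_edges, sample(usable, 2)))
    simz <- scale(sim[pairs])
    is_serial <- stats::runif(n_edges) < 0.25
    w <- 0.15 - 0.05 * as.numeric(simz) - 0.02 * is_serial +
      stats::rnorm(n_edges, 0, 0.02)
    data.frame(from = pairs[, 1], to = pairs[, 2], weight = w,
               is_serial = is_serial)
  }
  e1 <- mkedges(150); e2 <- mkedges(150)
  g1 <- mkgraph(e1, vertices = ids)
  g2 <- mkgraph(e2, vertices = ids)
  reg <- likelihood_similarity_regression(g1, g2, sim, inv)
  co <- reg$coefficients
  expect_lt(co["similarity_z", "Estimate"], 0)
  expect_equal(unname(co["similarity_z", "Estimate"]), -0.05, tolerance = 0.1)
  expect_equal(unname(co["is_serialTRUE", "Estimate"]), -0.02, tolerance = 0.25)
  expect_equal(reg$n_edges, 300)

  # constant similarity: term dropped with a warning
  sim_const <- sim; sim_const[] <- 0.4; diag(sim_const) <- 1
  expect_warning(
    reg2 <- likelihood_similarity_regression(g1, g2, sim_const, inv),
    "constant")
  expect_false("similarity_z" %in% rownames(reg2$coefficients))

  # too few edges after exclusions
  tiny1 <- mkgraph(mkedges(4), vertices = ids)
  tiny2 <- mkgraph(mkedges(4), vertices = ids)
  expect_error(likelihood_similarity_regression(tiny1, tiny2, sim, inv),
               "fewer than 10")
})

test_that("planted shared structure is recovered as cliques", {
  # both groups share strong pairs (o01-o02-o03) and (o05-o06); each also has
  # private edges that must not survive the intersection
  shared <- data.frame(from = c("o01", "o02", "o05"),
                       to = c("o02", "o03", "o06"),
                       weight = 0.1)
  g1 <- mkgraph(rbind(shared, data.frame(from = "o03", to = "o04", weight = 0.2)))
  g2 <- mkgraph(rbind(shared, data.frame(from = "o04", to = "o05", weight = 0.2)))
  part <- extract_cliques(intersection_graph(g1, g2))
  expect_length(part$cliques, 2)
  expect_equal(part$cliques[[1]], c("o01", "o02", "o03"))
  expect_equal(part$cliques[[2]], c("o05", "o06"))
})
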