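two_triangles <- function() {
  igraph::graph_from_data_frame(data.frame(
    from = c("a", "b", "c", "d", "e", "f", "c"),
    to   = c("b", "c", "a", "e", "f", "d", "d")), directed = FALSE)
}

test_that("orthogroups are placed by strict plurality", {
  anns <- list(
    S = make_annotation("S", list(c("og1", "og1b", "og2"),
                                  c("og2b", "og3", "og4"))))
  tab <- orthogroup_table(list(
    og_multi = list(S = c("S_og1", "S_og1b", "S_og2b")),  # 2 chr1, 1 chr2
    og_tie = list(S = c("S_og2", "S_og3")),               # 1 chr1, 1 chr2
    og_single = list(S = "S_og4")), "S")
  pl <- place_orthogroups(tab, anns)
  expect_equal(pl["og_multi", "S"], "chr1")
  expect_true(is.na(pl["og_tie", "S"]))
  expect_equal(pl["og_single", "S"], "chr2")
  bad <- orthogroup_table(list(og = list(S = "S_missing")), "S")
  expect_error(place_orthogroups(bad, anns), "S_missing")
})

test_that("linkage edges count supporting species and honour min_support", {
  # og1, og2 together in all 3 species; og1, og3 together in only 1
  anns <- list(
    A = make_annotation("A", list(c("og1", "og2", "og3"))),
    B = make_annotation("B", list(c("og1", "og2"), "og3")),
    C = make_annotation("C", list(c("og1", "og2"), "og3")))
  tab <- make_og_table(anns)
  g <- build_linkage_graph(place_orthogroups(tab, anns), min_support = 2)
  el <- igraph::as_data_frame(g)
  key <- paste(pmin(el$from, el$to), pmax(el$from, el$to))
  expect_equal(el$weight[key == "og1 og2"], 3)
  expect_false("og1 og3" %in% key)
  expect_true(all(el$weight >= 2))
  # isolated placed orthogroups stay as vertices
  expect_setequal(igraph::V(g)$name, c("og1", "og2", "og3"))
})

test_that("modularity matches hand-computed and igraph values", {
  tt <- two_triangles()
  part <- stats::setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(modularity_score(tt, part), 6 / 7 - 1 / 2)
  expect_equal(modularity_score(tt, stats::setNames(rep(1, 6),
                                                    letters[1:6])), 0)
  tri <- igraph::graph_from_data_frame(data.frame(
    from = c("a", "b", "c"), to = c("b", "c", "a")), directed = FALSE)
  expect_equal(modularity_score(tri, stats::setNames(1:3, letters[1:3])),
               -1 / 3)
  # weighted cross-check against igraph's implementation
  set.seed(12)
  g <- igraph::sample_gnp(12, 0.4)
  igraph::V(g)$name <- paste0("v", 1:12)
  igraph::E(g)$weight <- sample(1:5, igraph::ecount(g), replace = TRUE)
  mem <- sample(1:3, 12, replace = TRUE)
  expect_equal(modularity_score(g, stats::setNames(mem, paste0("v", 1:12))),
               igraph::modularity(g, mem, weights = igraph::E(g)$weight))
  expect_error(modularity_score(tt, part[1:5]), "missing")
})

test_that("consensus splits the two-triangle graph and is deterministic", {
  tt <- two_triangles()
  p <- consensus_communities(tt, resolution = 1, n_runs = 10, seed = 4)
  expect_equal(p$n_communities, 2)
  expect_equal(p$membership[c("a", "b", "c")],
               rep(p$membership["a"], 3), ignore_attr = TRUE)
  expect_equal(p$modularity, 6 / 7 - 1 / 2)
  expect_equal(p$stability, 1)
  p2 <- consensus_communities(tt, resolution = 1, n_runs = 10, seed = 4)
  expect_identical(p$membership, p2$membership)
  expect_error(consensus_communities(tt, n_runs = 1), "n_runs")
})

test_that("an edgeless graph yields singleton communities", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:4)
  p <- consensus_communities(g, n_runs = 5, seed = 1)
  expect_equal(p$n_communities, 4)
})

test_that("consensus is invariant to node insertion order", {
  set.seed(77)
  el <- data.frame(from = paste0("v", sample(1:9, 20, replace = TRUE)),
                   to = paste0("v", sample(1:9, 20, replace = TRUE)))
  el <- el[el$from != el$to, ]
  mk <- function(order) {
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
      vertices = data.frame(name = paste0("v", order)))
    igraph::simplify(g, edge.attr.comb = "first")
  }
  p1 <- consensus_communities(mk(1:9), n_runs = 10, seed = 2)
  p2 <- consensus_communities(mk(9:1), n_runs = 10, seed = 2)
  nm <- names(p1$membership)
  expect_equal(adjusted_rand_index(p1$membership[nm], p2$membership[nm]), 1)
})

test_that("the scenario sweep recovers three planted cliques", {
  # three 6-cliques joined by single bridging edges
  edges <- NULL
  for (c in 0:2) {
    v <- paste0("c", c, "n", 1:6)
    idx <- t(utils::combn(6, 2))
    edges <- rbind(edges, data.frame(from = v[idx[, 1]], to = v[idx[, 2]]))
  }
  edges <- rbind(edges,
                 data.frame(from = c("c0n1", "c1n1"),
                            to = c("c1n2", "c2n2")))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  sw <- scenario_sweep(g, c(0.5, 1, 2), n_runs = 10, seed = 6)
  expect_equal(sw$best$n_communities, 3)
  for (c in 0:2) {
    mem <- sw$best$membership[paste0("c", c, "n", 1:6)]
    expect_equal(length(unique(mem)), 1)
  }
  expect_equal(nrow(sw$summary), 3)
  one <- scenario_sweep(g, 1, n_runs = 5, seed = 1)
  expect_equal(length(one$partitions), 1)
})

test_that("adjusted Rand index agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(5)
  for (i in 1:5) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
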