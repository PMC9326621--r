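test_that("degree tables count stars, paths, and satisfy the handshake identity", {
  star <- figure1_fixtures()$star_hub
  tab <- degree_table(star)
  hub <- tab[tab$node == "hub", ]
  expect_identical(hub$out_degree, 5L)
  expect_identical(hub$in_degree, 0L)
  expect_identical(hub$rank_degree, 1L)
  expect_true(all(tab$degree[tab$node != "hub"] == 1L))

  path <- chain_network(3)
  mid <- degree_table(path)
  expect_identical(mid$in_degree[mid$node == "n02"], 1L)
  expect_identical(mid$out_degree[mid$node == "n02"], 1L)

  for (seed in 0:4) {
    net <- random_digraph(30, 0.1, seed)
    tab <- degree_table(net)
    expect_identical(sum(tab$degree), 2L * nrow(net$edges))
  }
})

test_that("interior nodes of a directed chain have betweenness (k-1)(n-k)", {
  for (n in c(4, 5, 8)) {
    net <- chain_network(n)
    bet <- betweenness(net)
    bet <- bet[order(bet$node), ]
    for (k in seq_len(n)) {
      expected <- if (k == 1 || k == n) 0 else (k - 1) * (n - k)
      expect_equal(bet$betweenness[k], expected,
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("equal-length path splitting and adjacent pairs behave as defined", {
  bet <- betweenness(diamond_network())
  expect_equal(bet$betweenness[bet$node %in% c("b", "c")], c(0.5, 0.5))
  expect_equal(bet$betweenness[bet$node %in% c("a", "d")], c(0, 0))

  # every pair adjacent: no interior nodes anywhere
  complete <- complete_digraph(4)
  expect_true(all(betweenness(complete)$betweenness == 0))
  expect_true(all(betweenness_oracle(complete)$betweenness == 0))

  single <- build_network(assertion_table(
    "OSA", "sleep_disturbance", "leptin", "adipokine"))$network
  expect_true(all(betweenness(single)$betweenness == 0))
})

test_that("Brandes agrees with the enumeration oracle on random graphs", {
  for (seed in 0:14) {
    net <- generated_network(small_config(seed))
    b <- betweenness(net)
    o <- betweenness_oracle(net)
    expect_identical(b$node, o$node)
    expect_lt(max(abs(b$betweenness - o$betweenness)), 1e-9)
  }
  for (seed in 0:4) {
    net <- random_digraph(40, 0.08, seed)
    b <- betweenness(net)
    o <- betweenness_oracle(net)
    expect_lt(max(abs(b$betweenness - o$betweenness)), 1e-9)
  }
  for (net in figure1_fixtures()) {
    b <- betweenness(net)
    o <- betweenness_oracle(net)
    expect_lt(max(abs(b$betweenness - o$betweenness)), 1e-9)
  }
})

test_that("betweenness matches an independent library implementation", {
  skip_if_not_installed("igraph")
  for (seed in 0:2) {
    net <- generated_network(small_config(seed))
    b <- betweenness(net)
    g <- igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                       vertices = net$nodes$name)
    ib <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
    expect_lt(max(abs(b$betweenness - ib[b$node])), 1e-9)
  }
})

test_that("relabeling nodes permutes but does not change centrality values", {
  net <- generated_network(small_config(11))
  rename <- setNames(paste0("zz", rev(seq_len(nrow(net$nodes))),
                            "_", net$nodes$name),
                     net$nodes$name)
  relabeled <- typed_network(
    nodes = data.frame(name = unname(rename[net$nodes$name]),
                       category = net$nodes$category),
    edges = data.frame(source = unname(rename[net$edges$source]),
                       target = unname(rename[net$edges$target]),
                       sign = net$edges$sign))
  a <- sort(centrality_table(net)$betweenness)
  b <- sort(centrality_table(relabeled)$betweenness)
  expect_equal(a, b)
  expect_equal(sort(degree_table(net)$degree),
               sort(degree_table(relabeled)$degree))
})

test_that("pure sources and sinks always have zero betweenness", {
  for (seed in 0:9) {
    net <- generated_network(small_config(seed))
    tab <- centrality_table(net)
    boundary <- tab$category %in% c("physiologic_perturbation",
                                    "sleep_disturbance", "disease_process")
    expect_true(all(tab$betweenness[boundary] == 0))
  }
})

test_that("undirected and normalized variants are consistent", {
  net <- diamond_network()
  und <- betweenness(net, directed = FALSE)
  # undirected diamond: b and c each carry half of the single a-d geodesic
  # pair in both directions
  expect_equal(und$betweenness[und$node %in% c("b", "c")], c(1, 1))
  norm <- betweenness(net, normalized = TRUE)
  raw <- betweenness(net)
  n <- nrow(net$nodes)
  expect_equal(norm$betweenness, raw$betweenness / ((n - 1) * (n - 2)))
})
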