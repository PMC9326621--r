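test_that("star center is a hub and a bridge is a nonhub bottleneck", {
  star <- figure1_fixtures()$star_hub
  cl <- classify(centrality_table(star))
  expect_identical(cl$hubs, "hub")
  expect_identical(cl$bottlenecks, character(0))
  expect_identical(cl$nonhub_bottlenecks, character(0))

  # double star joined by one low-degree bridge: expectation derived from
  # the enumeration oracle, not from the Brandes path
  ds <- figure1_fixtures()$bridged_bottleneck
  deg <- degree_table(ds)
  bet <- betweenness_oracle(ds)
  tab <- data.frame(deg[c("node", "category", "in_degree", "out_degree",
                          "degree")],
                    betweenness = bet$betweenness,
                    rank_degree = deg$rank_degree,
                    rank_betweenness = bet$rank_betweenness)
  expect_identical(tab$node[which.max(tab$betweenness)], "b")
  expect_identical(tab$degree[tab$node == "b"], 2L)
  cl <- classify(tab)
  expect_true("b" %in% cl$nonhub_bottlenecks)
  expect_true(all(c("h1", "h2") %in% cl$hubs))
})

test_that("an edgeless network classifies to empty sets", {
  net <- typed_network(
    nodes = data.frame(name = c("leptin", "AMPK"),
                       category = c("adipokine", "molecular_target")),
    edges = data.frame(source = character(), target = character(),
                       sign = character()))
  cl <- classify(centrality_table(net))
  expect_identical(cl$hubs, character(0))
  expect_identical(cl$bottlenecks, character(0))
  expect_identical(cl$nonhub_bottlenecks, character(0))
})

test_that("classify validates its inputs", {
  tab <- centrality_table(figure1_fixtures()$star_hub)
  expect_error(classify(tab[0, ]), "nonempty")
  expect_error(classify(tab, hub_quantile = 1.5), "quantiles")
  expect_error(classify(tab, low_degree_quantile = 0), "quantiles")
})

test_that("raising the hub quantile never enlarges the hub set", {
  for (seed in 0:4) {
    tab <- centrality_table(generated_network(small_config(seed)))
    previous <- NULL
    for (q in c(0.5, 0.7, 0.9, 0.97)) {
      hubs <- classify(tab, hub_quantile = q)$hubs
      if (!is.null(previous)) expect_true(all(hubs %in% previous))
      previous <- hubs
    }
  }
})

test_that("class memberships satisfy the subset and disjointness invariants", {
  for (seed in 0:9) {
    tab <- centrality_table(generated_network(small_config(seed)))
    cl <- classify(tab)
    expect_true(all(cl$nonhub_bottlenecks %in% cl$bottlenecks))
    expect_length(intersect(cl$nonhub_bottlenecks, cl$hubs), 0)
  }
})

test_that("rank_by_type orders each category and checks node sets", {
  net <- generated_network(small_config(7))
  tab <- centrality_table(net)
  ranks <- rank_by_type(tab, net, by = "degree")
  expect_named(ranks, node_categories())
  for (d in ranks) {
    expect_true(all(diff(d$degree) <= 0))
  }
  bet_ranks <- rank_by_type(tab, net, by = "betweenness")
  for (d in bet_ranks) {
    expect_true(all(diff(d$betweenness) <= 0))
  }
  expect_identical(sum(vapply(ranks, nrow, integer(1))), nrow(net$nodes))
  expect_error(rank_by_type(tab[-1, ], net), "different node sets")

  lone <- build_network(assertion_table(
    "OSA", "sleep_disturbance", "leptin", "adipokine"))$network
  lone_ranks <- rank_by_type(centrality_table(lone), lone)
  expect_identical(nrow(lone_ranks$sleep_disturbance), 1L)
  expect_identical(nrow(lone_ranks$molecular_target), 0L)
})

test_that("degree distributions summarize regular and star graphs correctly", {
  cycle <- typed_network(
    nodes = data.frame(name = c("a", "b", "c", "d"),
                       category = rep("molecular_target", 4)),
    edges = data.frame(source = c("a", "b", "c", "d"),
                       target = c("b", "c", "d", "a"),
                       sign = "uncertain"))
  dd <- degree_distribution(centrality_table(cycle))
  expect_identical(dd$histogram,
                   data.frame(degree = 2L, count = 4L))
  expect_false(dd$heavy_tail_flag)
  expect_true(is.na(dd$tail_slope))

  star9 <- typed_network(
    nodes = data.frame(name = c("h", paste0("l", 1:9)),
                       category = c("adipokine",
                                    rep("molecular_target", 9))),
    edges = data.frame(source = "h", target = paste0("l", 1:9),
                       sign = "uncertain"))
  dd9 <- degree_distribution(centrality_table(star9))
  expect_identical(dd9$histogram,
                   data.frame(degree = c(1L, 9L), count = c(9L, 1L)))
  expect_equal(dd9$tail_slope, -1)
  expect_true(dd9$heavy_tail_flag)
})

test_that("the default synthetic network registers as heavy-tailed", {
  net <- generated_network(synthetic_config(seed = 42))
  dd <- degree_distribution(centrality_table(net))
  expect_true(dd$heavy_tail_flag)
  expect_identical(sum(dd$histogram$count), nrow(net$nodes))
})
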