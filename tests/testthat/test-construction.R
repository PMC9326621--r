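test_that("a single curated relation builds the expected two-node network", {
  a <- assertion_table("OSA", "sleep_disturbance", "leptin", "adipokine",
                       sign = "negative")
  out <- build_network(a)
  expect_identical(nrow(out$network$nodes), 2L)
  expect_identical(nrow(out$network$edges), 1L)
  expect_identical(out$network$edges$source, "OSA")
  expect_identical(out$network$edges$target, "leptin")
  expect_identical(out$network$edges$sign, "negative")
  expect_identical(nrow(out$conflicts), 0L)
  expect_identical(validate_network(out$network), character(0))
})

test_that("empty input gives an empty network and no conflicts", {
  out <- build_network(assertion_table())
  expect_identical(nrow(out$network$nodes), 0L)
  expect_identical(nrow(out$network$edges), 0L)
  expect_identical(nrow(out$conflicts), 0L)
})

test_that("duplicate assertions collapse and definite signs beat uncertain", {
  a <- assertion_table(rep("leptin", 3), "adipokine",
                       rep("AMPK", 3), "molecular_target",
                       sign = c("uncertain", "positive", "positive"))
  out <- build_network(a)
  expect_identical(nrow(out$network$edges), 1L)
  expect_identical(out$network$edges$sign, "positive")
  expect_identical(nrow(out$conflicts), 0L)
})

test_that("contradictory signs are resolved per policy and logged", {
  a <- assertion_table(c("leptin", "leptin"), "adipokine",
                       c("AMPK", "AMPK"), "molecular_target",
                       sign = c("positive", "negative"))
  dropped <- build_network(a, conflict_policy = "drop_edge")
  expect_identical(nrow(dropped$network$nodes), 2L)
  expect_identical(nrow(dropped$network$edges), 0L)
  expect_identical(dropped$conflicts$resolution, "edge_dropped")
  expect_identical(dropped$conflicts$signs_seen, "negative+positive")

  excluded <- build_network(a, conflict_policy = "exclude_node")
  expect_identical(excluded$network$nodes$name, "leptin")
  expect_identical(excluded$conflicts$resolution, "node_excluded")

  both <- build_network(a, conflict_policy = "exclude_node",
                        exclude_side = "both")
  expect_identical(nrow(both$network$nodes), 0L)
})

test_that("exclude_node removes all edges incident to the excluded node", {
  a <- rbind(
    assertion_table("leptin", "adipokine", "AMPK", "molecular_target",
                    sign = "positive"),
    assertion_table("leptin", "adipokine", "AMPK", "molecular_target",
                    sign = "negative"),
    assertion_table("adiponectin", "adipokine", "AMPK", "molecular_target",
                    sign = "positive"),
    assertion_table("leptin", "adipokine", "food intake",
                    "physiologic_function", sign = "positive"))
  out <- build_network(a, conflict_policy = "exclude_node")
  expect_false("AMPK" %in% out$network$nodes$name)
  # the unrelated leptin -> food intake edge survives
  expect_identical(nrow(out$network$edges), 1L)
  expect_identical(out$network$edges$target, "food intake")
})

test_that("schema errors name the offending record", {
  bad <- assertion_table("metabolic syndrome", "disease_process",
                         "leptin", "adipokine", sign = "positive")
  expect_error(build_network(bad), "record 1.*disallowed transition")
  dup_cat <- rbind(
    assertion_table("leptin", "adipokine", "AMPK", "molecular_target"),
    assertion_table("AMPK", "adipokine", "insulin signaling",
                    "physiologic_function"))
  expect_error(build_network(dup_cat), "entity 'AMPK' used with categories")
})

test_that("build_network is order-invariant", {
  gen <- generate_network(small_config(3))
  a <- gen$assertions
  ref <- build_network(a)
  for (seed in 1:5) {
    set.seed(seed)
    perm <- a[sample(nrow(a)), ]
    out <- build_network(perm)
    expect_identical(out$network, ref$network)
    expect_identical(out$conflicts, ref$conflicts)
  }
})

test_that("adding a fresh assertion grows the edge set by exactly one", {
  gen <- generate_network(small_config(4))
  a <- gen$assertions
  base <- build_network(a)$network
  extra <- assertion_table("a brand new kinase", "molecular_target",
                           a$target[a$target_category ==
                                      "physiologic_function"][1],
                           "physiologic_function", sign = "positive")
  grown <- build_network(rbind(a, extra))$network
  expect_identical(nrow(grown$edges), nrow(base$edges) + 1L)
  expect_identical(nrow(grown$nodes), nrow(base$nodes) + 1L)
})

test_that("to_assertions round-trips any conflict-free network", {
  for (seed in 0:4) {
    net <- generated_network(small_config(seed))
    rebuilt <- build_network(to_assertions(net))$network
    expect_identical(rebuilt$nodes, net$nodes)
    expect_identical(rebuilt$edges, net$edges)
  }
})

test_that("assert_chain expands mechanism chains link by link", {
  recs <- assert_chain("leptin", data.frame(
    name = c("JAK-STAT3", "food intake"),
    category = c("molecular_target", "physiologic_function")))
  expect_identical(nrow(recs), 2L)
  expect_identical(recs$source, c("leptin", "JAK-STAT3"))
  expect_identical(recs$target, c("JAK-STAT3", "food intake"))
  expect_identical(unique(recs$sign), "uncertain")

  shortcut <- assert_chain("leptin", data.frame(
    name = "insulin signaling", category = "physiologic_function"))
  expect_identical(nrow(shortcut), 1L)
  expect_identical(shortcut$source_category, "adipokine")

  expect_identical(nrow(assert_chain("leptin", data.frame(
    name = character(), category = character()))), 0L)

  expect_error(assert_chain("leptin", data.frame(
    name = c("metabolic syndrome", "AMPK"),
    category = c("disease_process", "molecular_target"))),
    "broken chain")
})
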