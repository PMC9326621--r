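# Fixture builders shared across test files. Everything is generated in
# code; no fixture files.

# directed chain n1 -> n2 -> ... -> nk on schema-legal categories when
# k <= 5, generic molecular_target categories otherwise (centrality does
# not consult the schema)
chain_network <- function(k) {
  cats <- if (k <= 5) {
    c("sleep_disturbance", "adipokine", "molecular_target",
      "physiologic_function", "disease_process")[seq_len(k)]
  } else {
    rep("molecular_target", k)
  }
  names <- sprintf("n%02d", seq_len(k))
  typed_network(nodes = data.frame(name = names, category = cats),
                edges = data.frame(source = names[-k], target = names[-1],
                                   sign = "uncertain"))
}

# a -> {b, c} -> d: two equal shortest paths
diamond_network <- function() {
  typed_network(
    nodes = data.frame(name = c("a", "b", "c", "d"),
                       category = c("adipokine", "molecular_target",
                                    "molecular_target",
                                    "physiologic_function")),
    edges = data.frame(source = c("a", "a", "b", "c"),
                       target = c("b", "c", "d", "d"),
                       sign = "uncertain"))
}

# complete digraph on k nodes (every ordered pair adjacent)
complete_digraph <- function(k) {
  names <- sprintf("v%02d", seq_len(k))
  pairs <- expand.grid(source = names, target = names,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  typed_network(nodes = data.frame(name = names,
                                   category = "molecular_target"),
                edges = data.frame(pairs, sign = "uncertain"))
}

# Erdos-Renyi style random digraph; ignores the layered schema on purpose
# (category uniform) to exercise the metrics on unstructured graphs
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  names <- sprintf("v%03d", seq_len(n))
  pairs <- expand.grid(source = names, target = names,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p
  typed_network(nodes = data.frame(name = names,
                                   category = "molecular_target"),
                edges = data.frame(pairs[keep, ], sign = "uncertain"))
}

# small layered config for fast property loops
small_config <- function(seed, edge_budget = 70L, ...) {
  synthetic_config(
    layer_sizes = c(physiologic_perturbation = 3L, sleep_disturbance = 2L,
                    adipokine = 4L, molecular_target = 10L,
                    physiologic_function = 8L, disease_process = 8L),
    edge_budget = edge_budget, seed = seed, ...)
}

generated_network <- function(config) {
  build_network(generate_network(config)$assertions)$network
}
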