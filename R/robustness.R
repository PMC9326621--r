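# all schema-legal ordered node pairs absent from the network
legal_absent_pairs <- function(net, transitions = allowed_transitions()) {
  nodes <- net$nodes
  pairs <- do.call(rbind, lapply(seq_len(nrow(transitions)), function(i) {
    s <- nodes$name[nodes$category == transitions$from[i]]
    t <- nodes$name[nodes$category == transitions$to[i]]
    if (!length(s) || !length(t)) return(NULL)
    expand.grid(source = s, target = t, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    return(data.frame(source = character(), target = character()))
  }
  existing <- paste(name_key(net$edges$source), name_key(net$edges$target),
                    sep = "\r")
  keys <- paste(name_key(pairs$source), name_key(pairs$target), sep = "\r")
  out <- pairs[!keys %in% existing & name_key(pairs$source) !=
                 name_key(pairs$target), , drop = FALSE]
  out <- out[order(name_key(out$source), name_key(out$target),
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resample the edge set of a network once
#'
#' One replicate of the curation-noise model used by [stability()]: each
#' existing edge is deleted independently with `edge_drop_prob`, and
#' `Binomial(|E|, edge_add_prob)` schema-legal absent edges (drawn without
#' replacement, sign `uncertain`) are added. The node set is unchanged, so
#' perturbed networks stay comparable to the baseline.
#'
#' @param net A validated [typed_network()].
#' @param edge_drop_prob,edge_add_prob Probabilities in [0, 1).
#' @param transitions Transition table; defaults to [allowed_transitions()].
#' @return A [typed_network()] on the same node set.
#' @export
perturb_edges <- function(net, edge_drop_prob, edge_add_prob,
                          transitions = allowed_transitions()) {
  stopifnot(edge_drop_prob >= 0, edge_drop_prob < 1,
            edge_add_prob >= 0, edge_add_prob < 1)
  m <- nrow(net$edges)
  keep <- if (m) stats::runif(m) >= edge_drop_prob else logical(0)
  edges <- net$edges[keep, , drop = FALSE]
  n_add <- if (m) stats::rbinom(1L, m, edge_add_prob) else 0L
  if (n_add > 0) {
    pool <- legal_absent_pairs(net, transitions)
    n_add <- min(n_add, nrow(pool))
    if (n_add > 0) {
      ix <- sample(nrow(pool), n_add)
      edges <- rbind(edges,
                     data.frame(source = pool$source[ix],
                                target = pool$target[ix],
                                sign = "uncertain",
                                stringsAsFactors = FALSE))
    }
  }
  typed_network(nodes = net$nodes, edges = edges)
}

#' Stability of centrality classifications under edge resampling
#'
#' Literature-curated networks inherit publication bias: edges reflect
#' what has been studied, and node roles may shift as evidence
#' accumulates. This procedure quantifies how fragile the hub /
#' bottleneck / nonhub-bottleneck calls are under that uncertainty. For
#' each of `replicates` resampled networks ([perturb_edges()]) the
#' centrality table is recomputed and [classify()] is re-applied with the
#' numeric thresholds frozen at their baseline values (set
#' `reclassify = TRUE` to re-derive quantile cutoffs per replicate), and
#' each node's membership frequency in the three classes is reported.
#'
#' @inheritParams perturb_edges
#' @param replicates Number of resampled networks (>= 1).
#' @param seed Integer seed; the report is deterministic given it.
#' @param reclassify Recompute quantile cutoffs per replicate instead of
#'   freezing the baseline thresholds.
#' @param hub_quantile,bottleneck_quantile,low_degree_quantile Passed to
#'   [classify()] for the baseline (and for replicates when
#'   `reclassify = TRUE`).
#' @return Object of class `stability_report`: list with `frequencies`
#'   (data.frame `node`, `category`, `hub`, `bottleneck`,
#'   `nonhub_bottleneck` — frequencies in [0, 1]), `baseline` (the
#'   baseline `classification`), and `parameters`.
#' @export
#' @examples
#' net <- build_network(generate_network(synthetic_config(seed = 1))$
#'   assertions)$network
#' stability(net, edge_drop_prob = 0.1, edge_add_prob = 0.05,
#'           replicates = 20, seed = 7)
stability <- function(net, edge_drop_prob, edge_add_prob, replicates,
                      seed, reclassify = FALSE,
                      hub_quantile = 0.90, bottleneck_quantile = 0.90,
                      low_degree_quantile = 0.50,
                      transitions = allowed_transitions()) {
  stopifnot(inherits(net, "typed_network"), replicates >= 1)
  baseline_table <- centrality_table(net)
  baseline <- classify(baseline_table, hub_quantile, bottleneck_quantile,
                       low_degree_quantile)
  frozen <- as.list(stats::setNames(baseline$thresholds$value,
                                    baseline$thresholds$threshold))
  nodes <- baseline_table$node
  counts <- matrix(0, nrow = length(nodes), ncol = 3,
                   dimnames = list(nodes,
                                   c("hub", "bottleneck",
                                     "nonhub_bottleneck")))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(replicates)) {
    rep_net <- perturb_edges(net, edge_drop_prob, edge_add_prob, transitions)
    tab <- centrality_table(rep_net)
    cl <- classify(tab, hub_quantile, bottleneck_quantile,
                   low_degree_quantile,
                   cutoffs = if (reclassify) NULL else frozen)
    counts[cl$hubs, "hub"] <- counts[cl$hubs, "hub"] + 1
    counts[cl$bottlenecks, "bottleneck"] <-
      counts[cl$bottlenecks, "bottleneck"] + 1
    counts[cl$nonhub_bottlenecks, "nonhub_bottleneck"] <-
      counts[cl$nonhub_bottlenecks, "nonhub_bottleneck"] + 1
  }
  structure(list(
    frequencies = data.frame(node = nodes,
                             category = baseline_table$category,
                             counts / replicates,
                             stringsAsFactors = FALSE, row.names = NULL),
    baseline = baseline,
    parameters = list(edge_drop_prob = edge_drop_prob,
                      edge_add_prob = edge_add_prob,
                      replicates = as.integer(replicates),
                      seed = as.integer(seed),
                      reclassify = reclassify)
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(paste0("<stability_report> %d replicates, drop %.3g, ",
                     "add %.3g, seed %d\n"),
              p$replicates, p$edge_drop_prob, p$edge_add_prob, p$seed))
  interesting <- x$frequencies[rowSums(x$frequencies[, 3:5]) > 0, ,
                               drop = FALSE]
  print(utils::head(interesting[order(-interesting$hub,
                                      -interesting$nonhub_bottleneck), ],
                    10), row.names = FALSE)
  invisible(x)
}
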