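# Nearest-rank quantile: the ceiling(q * n)-th smallest value. Chosen over
# interpolating quantile types for bit-identical results across platforms.
nearest_rank_quantile <- function(x, q) {
  s <- sort(x)
  s[min(length(s), max(1L, as.integer(ceiling(q * length(s)))))]
}

#' Classify hubs, bottlenecks and nonhub bottlenecks
#'
#' Hubs are nodes with much higher degree than the rest of the network;
#' bottlenecks are nodes with high betweenness; nonhub bottlenecks combine
#' low degree with high betweenness and often mark key regulatory points.
#' The qualitative definitions are made operational with quantile cutoffs
#' (nearest-rank method), which are reported alongside the memberships:
#' \itemize{
#'   \item hubs: `degree >=` the `hub_quantile` quantile of all node
#'     degrees (and `degree > 0`);
#'   \item bottlenecks: `betweenness >=` the `bottleneck_quantile`
#'     quantile of the positive-betweenness distribution;
#'   \item nonhub bottlenecks: bottlenecks that are not hubs and whose
#'     degree is `<=` the `low_degree_quantile` quantile of the degrees of
#'     positive-betweenness nodes (the population the "low degree"
#'     judgement is made against).
#' }
#'
#' @param table A centrality table from [centrality_table()] (or a merge
#'   of [degree_table()] and [betweenness()] sharing the `node` column).
#' @param hub_quantile,bottleneck_quantile,low_degree_quantile Quantile
#'   cutoffs in (0, 1); defaults 0.90, 0.90, 0.50.
#' @param cutoffs Optional list with elements `hub_degree_cutoff`,
#'   `bottleneck_betweenness_cutoff`, `low_degree_cutoff` that freezes the
#'   numeric thresholds (used by [stability()] so replicate frequencies
#'   measure network, not threshold, instability).
#' @return Object of class `classification`: list with character-vector
#'   elements `hubs`, `bottlenecks`, `nonhub_bottlenecks` and a
#'   `thresholds` data.frame recording each numeric cutoff and the rule
#'   that produced it.
#' @export
#' @examples
#' net <- figure1_fixtures()$star_hub
#' classify(centrality_table(net))
classify <- function(table, hub_quantile = 0.90, bottleneck_quantile = 0.90,
                     low_degree_quantile = 0.50, cutoffs = NULL) {
  if (is.null(table) || nrow(table) == 0) {
    stop("classification requires a nonempty centrality table")
  }
  for (q in c(hub_quantile, bottleneck_quantile, low_degree_quantile)) {
    if (!is.numeric(q) || q <= 0 || q >= 1) {
      stop("quantiles must lie in (0, 1)")
    }
  }
  pos <- table[table$betweenness > 0, , drop = FALSE]
  if (is.null(cutoffs)) {
    cutoffs <- list(
      hub_degree_cutoff = nearest_rank_quantile(table$degree, hub_quantile),
      bottleneck_betweenness_cutoff =
        if (nrow(pos)) nearest_rank_quantile(pos$betweenness,
                                             bottleneck_quantile) else Inf,
      low_degree_cutoff =
        if (nrow(pos)) nearest_rank_quantile(pos$degree,
                                             low_degree_quantile) else -Inf)
    rules <- c(
      sprintf("degree >= %s-quantile of all degrees (nearest rank)",
              format(hub_quantile)),
      sprintf("betweenness >= %s-quantile of positive betweenness",
              format(bottleneck_quantile)),
      sprintf("degree <= %s-quantile of positive-betweenness node degrees",
              format(low_degree_quantile)))
  } else {
    rules <- rep("frozen baseline cutoff", 3)
  }
  hubs <- table$node[table$degree >= cutoffs$hub_degree_cutoff &
                       table$degree > 0]
  bottlenecks <- table$node[table$betweenness > 0 &
    table$betweenness >= cutoffs$bottleneck_betweenness_cutoff]
  low <- table$node[table$degree <= cutoffs$low_degree_cutoff]
  nonhub <- setdiff(intersect(bottlenecks, low), hubs)
  structure(list(
    hubs = sort(hubs, method = "radix"),
    bottlenecks = sort(bottlenecks, method = "radix"),
    nonhub_bottlenecks = sort(nonhub, method = "radix"),
    thresholds = data.frame(
      threshold = c("hub_degree_cutoff", "bottleneck_betweenness_cutoff",
                    "low_degree_cutoff"),
      value = c(cutoffs$hub_degree_cutoff,
                cutoffs$bottleneck_betweenness_cutoff,
                cutoffs$low_degree_cutoff),
      rule = rules, stringsAsFactors = FALSE)
  ), class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat("<classification>\n")
  cat("  hubs:               ", paste(x$hubs, collapse = ", "), "\n")
  cat("  bottlenecks:        ", paste(x$bottlenecks, collapse = ", "), "\n")
  cat("  nonhub bottlenecks: ", paste(x$nonhub_bottlenecks, collapse = ", "),
      "\n")
  for (i in seq_len(nrow(x$thresholds))) {
    cat(sprintf("  %-30s %s  [%s]\n", x$thresholds$threshold[i],
                format(x$thresholds$value[i]), x$thresholds$rule[i]))
  }
  invisible(x)
}

#' Per-category centrality rankings
#'
#' Splits the centrality table by node category and sorts each slice by
#' the chosen metric (descending, ties broken lexicographically by node
#' name) — the tabular analogue of per-category degree and betweenness
#' bar charts.
#'
#' @param table Centrality table from [centrality_table()].
#' @param net The [typed_network()] the table was computed on (node sets
#'   must match).
#' @param by `"degree"` or `"betweenness"`.
#' @return Named list with one data.frame per category (all six, possibly
#'   empty), columns `node`, `in_degree`, `out_degree`, `degree`,
#'   `betweenness`.
#' @export
rank_by_type <- function(table, net, by = c("degree", "betweenness")) {
  by <- match.arg(by)
  stopifnot(inherits(net, "typed_network"))
  if (!setequal(name_key(table$node), name_key(net$nodes$name))) {
    stop("centrality table and network cover different node sets")
  }
  cols <- c("node", "in_degree", "out_degree", "degree", "betweenness")
  out <- lapply(node_categories(), function(cat_i) {
    d <- table[table$category == cat_i, cols, drop = FALSE]
    d <- d[order(-d[[by]], name_key(d$node), method = "radix"), ,
           drop = FALSE]
    rownames(d) <- NULL
    d
  })
  names(out) <- node_categories()
  out
}

#' Degree distribution summary
#'
#' Exact histogram of total degrees plus a heavy-tail heuristic: the
#' log-log least-squares slope of node count against degree (degrees >= 1),
#' flagged heavy-tailed when the slope is at most -1 and the maximum degree
#' is at least four times the median degree. This is a screening heuristic
#' in the spirit of scale-free descriptions of small curated networks, not
#' a maximum-likelihood power-law fit.
#'
#' @param table Centrality table with a `degree` column (nonempty).
#' @return Object of class `degree_distribution`: list with `histogram`
#'   (data.frame `degree`, `count`), `tail_slope` (NA when fewer than two
#'   distinct positive degrees) and `heavy_tail_flag`.
#' @export
degree_distribution <- function(table) {
  if (is.null(table) || nrow(table) == 0) {
    stop("degree distribution requires a nonempty centrality table")
  }
  tab <- table(table$degree)
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab))
  pos <- hist[hist$degree >= 1, , drop = FALSE]
  tail_slope <- NA_real_
  if (nrow(pos) >= 2) {
    fit <- stats::lm(log(count) ~ log(degree), data = pos)
    tail_slope <- unname(stats::coef(fit)[2])
  }
  med <- stats::median(table$degree)
  # tolerance keeps exact boundary cases (analytic slope of -1) heavy
  heavy <- !is.na(tail_slope) && tail_slope <= -1 + 1e-9 &&
    med > 0 && max(table$degree) >= 4 * med
  structure(list(histogram = hist, tail_slope = tail_slope,
                 heavy_tail_flag = heavy),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("<degree_distribution> %d distinct degrees; tail slope %s; %s\n",
              nrow(x$histogram),
              ifelse(is.na(x$tail_slope), "NA", format(round(x$tail_slope, 3))),
              if (x$heavy_tail_flag) "heavy-tailed" else "not heavy-tailed"))
  invisible(x)
}
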