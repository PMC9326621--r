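# Internal indexed representation: nodes sorted by normalized name so that
# floating-point accumulation order, and hence every reported value, is
# reproducible across runs and platforms.
graph_index <- function(net, directed = TRUE) {
  keys <- sort(name_key(net$nodes$name), method = "radix")
  ord <- match(keys, name_key(net$nodes$name))
  names <- net$nodes$name[ord]
  categories <- net$nodes$category[ord]
  n <- length(keys)
  adj <- rep(list(integer(0)), n)
  radj <- rep(list(integer(0)), n)
  if (nrow(net$edges)) {
    s <- match(name_key(net$edges$source), keys)
    t <- match(name_key(net$edges$target), keys)
    if (!directed) {
      tmp <- c(s, t); t <- c(t, s); s <- tmp
      dup <- duplicated(paste(s, t))
      s <- s[!dup]; t <- t[!dup]
    }
    sp <- split(t, factor(s, levels = seq_len(n)))
    rp <- split(s, factor(t, levels = seq_len(n)))
    adj <- lapply(sp, function(v) sort(unname(v)))
    radj <- lapply(rp, function(v) sort(unname(v)))
  }
  list(n = n, names = names, categories = categories, adj = adj, radj = radj)
}

bfs_dist <- function(n, adj, s) {
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  queue <- integer(n)
  queue[1] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  dist
}

# Brandes (2001): one BFS per source plus reverse dependency accumulation.
brandes_betweenness <- function(n, adj) {
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- rep(list(integer(0)), n)
    queue <- integer(n)
    queue[1] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      dv1 <- dist[v] + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv1
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dv1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(tail))) {
      w <- queue[i]
      coef <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc
}

# Explicit enumeration oracle: BFS distances, then depth-first enumeration
# of every shortest path per ordered pair, counting interior passages.
enumeration_betweenness <- function(n, adj, radj) {
  distf <- vapply(seq_len(n), function(s) bfs_dist(n, adj, s), integer(n))
  distr <- vapply(seq_len(n), function(t) bfs_dist(n, radj, t), integer(n))
  # distf[v, s] = d(s, v); distr[v, t] = d(v, t)
  bc <- numeric(n)
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      if (x == y || is.na(distf[y, x])) next
      d <- distf[y, x]
      if (d < 2L) next   # adjacent pairs have no interior node
      through <- numeric(n)
      npaths <- 0L
      path <- integer(d + 1L)
      path[1] <- x
      walk <- function(v, len) {
        if (v == y) {
          # path[1] = x and path[len] = y; only interior nodes count
          npaths <<- npaths + 1L
          inner <- path[2:(len - 1L)]
          through[inner] <<- through[inner] + 1
          return(invisible())
        }
        for (w in adj[[v]]) {
          # stay on the shortest-path DAG and keep y reachable in budget
          if (!is.na(distf[w, x]) && distf[w, x] == len &&
              !is.na(distr[w, y]) && distr[w, y] == d - len) {
            path[len + 1L] <<- w
            walk(w, len + 1L)
          }
        }
      }
      walk(x, 1L)
      if (npaths > 0L) bc <- bc + through / npaths
    }
  }
  bc
}

centrality_frame <- function(gi) {
  data.frame(node = gi$names, category = gi$categories,
             stringsAsFactors = FALSE)
}

# ordinal 1..n ranks, metric descending, ties broken by node name
ordinal_rank <- function(metric, names) {
  ord <- order(-metric, name_key(names), method = "radix")
  rank <- integer(length(metric))
  rank[ord] <- seq_along(metric)
  rank
}

#' Degree centrality table
#'
#' In-, out- and total degree (C_i = in + out) for every node of a
#' directed network, with ordinal ranks (degree descending, ties broken
#' lexicographically by node name).
#'
#' @param net A validated [typed_network()].
#' @return data.frame with columns `node`, `category`, `in_degree`,
#'   `out_degree`, `degree`, `rank_degree`.
#' @export
#' @examples
#' net <- figure1_fixtures()$star_hub
#' degree_table(net)
degree_table <- function(net) {
  gi <- graph_index(net)
  out <- centrality_frame(gi)
  out$in_degree <- vapply(gi$radj, length, integer(1))
  out$out_degree <- vapply(gi$adj, length, integer(1))
  out$degree <- out$in_degree + out$out_degree
  out$rank_degree <- ordinal_rank(out$degree, out$node)
  out
}

#' Betweenness centrality (shortest-path counting)
#'
#' For every node i, C_bet(i) = sum over ordered pairs (x, y) with
#' x != y != i of sigma_xy(i) / sigma_xy, where sigma_xy counts shortest
#' directed paths from x to y and sigma_xy(i) those passing through i as
#' an interior node. Endpoints are excluded; unreachable pairs contribute
#' nothing; paths are unweighted (signs are labels, not weights). Computed
#' by Brandes' single-source BFS with dependency accumulation in
#' O(|V| * |E|).
#'
#' @param net A validated [typed_network()].
#' @param directed Treat edges as directed (default `TRUE`); `FALSE`
#'   symmetrizes for cross-tool comparison.
#' @param normalized Divide by the number of ordered interior pairs,
#'   (n-1)(n-2) (halved for undirected). Default `FALSE`: the raw
#'   path-count sum.
#' @return data.frame with columns `node`, `category`, `betweenness`,
#'   `rank_betweenness`.
#' @seealso [betweenness_oracle()] for the independently coded
#'   enumeration oracle, [centrality_table()] for the combined table.
#' @export
#' @examples
#' net <- figure1_fixtures()$bridged_bottleneck
#' betweenness(net)
betweenness <- function(net, directed = TRUE, normalized = FALSE) {
  gi <- graph_index(net, directed = directed)
  bc <- brandes_betweenness(gi$n, gi$adj)
  finish_betweenness(gi, bc, directed, normalized)
}

#' Betweenness centrality by brute-force path enumeration
#'
#' Independent oracle with the same contract as [betweenness()]: BFS per
#' source for distances, then depth-first enumeration of all shortest
#' paths for each ordered pair, counting interior-node passages directly.
#' Exponential in the number of shortest paths — intended for networks of
#' at most a few hundred nodes, where it cross-checks the Brandes
#' implementation.
#'
#' @inheritParams betweenness
#' @return data.frame with columns `node`, `category`, `betweenness`,
#'   `rank_betweenness`.
#' @export
betweenness_oracle <- function(net, directed = TRUE, normalized = FALSE) {
  gi <- graph_index(net, directed = directed)
  bc <- enumeration_betweenness(gi$n, gi$adj, gi$radj)
  finish_betweenness(gi, bc, directed, normalized)
}

finish_betweenness <- function(gi, bc, directed, normalized) {
  if (normalized && gi$n > 2) {
    denom <- (gi$n - 1) * (gi$n - 2)
    if (!directed) denom <- denom / 2
    bc <- bc / denom
  }
  out <- centrality_frame(gi)
  out$betweenness <- bc
  out$rank_betweenness <- ordinal_rank(bc, out$node)
  out
}

#' Combined centrality table
#'
#' Merges [degree_table()] and [betweenness()] into one per-node table.
#'
#' @inheritParams betweenness
#' @return data.frame with columns `node`, `category`, `in_degree`,
#'   `out_degree`, `degree`, `betweenness`, `rank_degree`,
#'   `rank_betweenness`.
#' @export
centrality_table <- function(net, directed = TRUE, normalized = FALSE) {
  deg <- degree_table(net)
  bet <- betweenness(net, directed = directed, normalized = normalized)
  stopifnot(identical(deg$node, bet$node))
  data.frame(deg[c("node", "category", "in_degree", "out_degree", "degree")],
             betweenness = bet$betweenness,
             rank_degree = deg$rank_degree,
             rank_betweenness = bet$rank_betweenness,
             stringsAsFactors = FALSE)
}
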