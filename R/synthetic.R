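#' Configuration of the synthetic layered-network generator
#'
#' Defaults emulate the headline statistics of the curated adipokine
#' network: 94 nodes over six categories (6 physiologic perturbations,
#' 4 sleep disturbances, 6 adipokines, 28 molecular targets,
#' 25 physiologic functions, 25 disease processes), 264 directed signed
#' edges, a heavy-tailed degree profile dominated by 2 planted adipokine
#' hubs (leptin/adiponectin analogues), and one low-degree bridge
#' molecular target fed by both hubs (AMPK analogue). Only the total node
#' count and the adipokine count are pinned down by the study design; the
#' per-layer split is an informed default and fully configurable.
#'
#' @param layer_sizes Named integer vector, nodes per category.
#' @param edge_budget Total number of edges (exactly met).
#' @param hub_skew Zipf exponent (>= 1) of the adipokine attachment
#'   weights; larger values concentrate edges on the planted hubs.
#' @param planted_hub_count Number of adipokines given the top attachment
#'   weights (>= 1).
#' @param shortcut_edge_fraction Fraction of randomly placed edges that
#'   run straight from an adipokine to a function or disease, bypassing
#'   molecular targets, in [0, 1].
#' @param sign_probs Probabilities of positive/negative/uncertain signs;
#'   must sum to 1.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(layer_sizes = c(physiologic_perturbation = 6L,
                                             sleep_disturbance = 4L,
                                             adipokine = 6L,
                                             molecular_target = 28L,
                                             physiologic_function = 25L,
                                             disease_process = 25L),
                             edge_budget = 264L,
                             hub_skew = 1.6,
                             planted_hub_count = 2L,
                             shortcut_edge_fraction = 0.2,
                             sign_probs = c(positive = 0.5, negative = 0.3,
                                            uncertain = 0.2),
                             seed = 1L) {
  stopifnot(setequal(names(layer_sizes), node_categories()),
            all(layer_sizes >= 0), hub_skew >= 1,
            planted_hub_count >= 1,
            planted_hub_count <= layer_sizes[["adipokine"]],
            shortcut_edge_fraction >= 0, shortcut_edge_fraction <= 1,
            length(sign_probs) == 3, all(sign_probs >= 0))
  if (abs(sum(sign_probs) - 1) > 1e-12) {
    stop("sign_probs must sum to 1")
  }
  if (layer_sizes[["molecular_target"]] < 1 ||
      layer_sizes[["physiologic_function"]] < 2 ||
      layer_sizes[["disease_process"]] < 1) {
    stop("planted bridge motif needs >= 1 molecular target, >= 2 functions",
         " and >= 1 disease process")
  }
  ls <- vapply(node_categories(), function(k) as.integer(layer_sizes[[k]]),
               integer(1))
  capacity <- transition_capacity(ls)
  if (edge_budget > capacity) {
    stop(sprintf("edge_budget %d exceeds the %d ordered pairs allowed by %s",
                 edge_budget, capacity, "the transition schema"))
  }
  structure(list(layer_sizes = ls, edge_budget = as.integer(edge_budget),
                 hub_skew = hub_skew,
                 planted_hub_count = as.integer(planted_hub_count),
                 shortcut_edge_fraction = shortcut_edge_fraction,
                 sign_probs = stats::setNames(as.numeric(sign_probs),
                                              edge_signs()),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# number of ordered pairs the transition schema allows for given layer sizes
transition_capacity <- function(ls, transitions = allowed_transitions()) {
  sum(ls[transitions$from] * ls[transitions$to])
}

layer_names <- function(ls) {
  prefix <- c(physiologic_perturbation = "PP", sleep_disturbance = "SD",
              adipokine = "ADK", molecular_target = "MT",
              physiologic_function = "PF", disease_process = "DP")
  out <- lapply(node_categories(), function(k) {
    n <- ls[[k]]
    if (n == 0) return(character(0))
    sprintf("%s%0*d", prefix[[k]], max(2L, nchar(n)), seq_len(n))
  })
  names(out) <- node_categories()
  out
}

#' Generate a synthetic layered signed network
#'
#' Seeded stand-in for the curated network, produced in three
#' deterministic phases. (1) Planted motif: every planted hub adipokine
#' points at a designated bridge molecular target, which feeds a small
#' set of functions wired onward to diseases of their own; that
#' downstream chain takes no other incoming edges, so the bridge's
#' degree stays fixed and low while both hubs route shortest paths
#' through it. (2) Coverage: every remaining node receives one
#' schema-legal incident edge (upstream nodes are wired to the planted
#' hubs), so the node count is exact. (3) Fill: edges are sampled from
#' the allowed transitions (adipokine endpoints drawn with
#' Zipf(`hub_skew`) weights, other endpoints with within-layer Zipf rank
#' weights, duplicates resampled) until the edge budget is exactly met.
#' Signs are drawn independently from `sign_probs`.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `assertions` (data.frame ready for
#'   [build_network()]), `planted_hubs` (character), `bridge` (character
#'   scalar), and `config`.
#' @export
#' @examples
#' gen <- generate_network(synthetic_config(seed = 42))
#' net <- build_network(gen$assertions)$network
#' net
generate_network <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  ls <- config$layer_sizes
  nm <- layer_names(ls)
  category_of <- stats::setNames(
    rep(node_categories(), times = vapply(nm, length, integer(1))),
    unlist(nm, use.names = FALSE))
  adks <- nm$adipokine
  hubs <- adks[seq_len(config$planted_hub_count)]
  bridge <- nm$molecular_target[1]
  free_targets <- setdiff(nm$molecular_target, bridge)
  # the bridge's downstream chain (its functions and their diseases, the
  # AMPK -> fatty-acid-oxidation pattern) is reachable only through it:
  # those nodes take no other incoming edges
  n_bf <- if (ls[["physiologic_function"]] >= 4L) 3L else 2L
  bridge_funs <- nm$physiologic_function[seq_len(n_bf)]
  free_funs <- setdiff(nm$physiologic_function, bridge_funs)
  dis_per_fun <- max(1L, min(3L, (ls[["disease_process"]] - 4L) %/% n_bf))
  bridge_dis <- nm$disease_process[seq_len(min(n_bf * dis_per_fun,
                                               ls[["disease_process"]]))]
  free_dis <- setdiff(nm$disease_process, bridge_dis)

  edges <- new.env(parent = emptyenv())
  src <- character(config$edge_budget)
  dst <- character(config$edge_budget)
  n_edges <- 0L
  deg <- stats::setNames(numeric(length(category_of)), names(category_of))
  add_edge <- function(s, t) {
    key <- paste(s, t, sep = "\r")
    if (!is.null(edges[[key]])) return(FALSE)
    edges[[key]] <- TRUE
    n_edges <<- n_edges + 1L
    src[n_edges] <<- s
    dst[n_edges] <<- t
    deg[s] <<- deg[s] + 1
    deg[t] <<- deg[t] + 1
    TRUE
  }
  covered <- function(x) deg[x] > 0
  # Zipf rank weights within every layer: the first-listed nodes of each
  # category dominate (the obesity / insulin-signaling analogues), giving
  # the within-layer degree profile its heavy tail. Adipokine ranks
  # 1..planted_hub_count are the planted hubs.
  # rank-weight exponent for the non-adipokine layers; 1.3 spreads the
  # within-layer degrees smoothly (degree roughly proportional to inverse
  # rank), which is what gives the aggregate histogram its decay
  wl_exponent <- 1.3
  pick <- function(pool, exponent = wl_exponent) {
    if (length(pool) == 1L) return(pool)
    sample(pool, 1L, prob = seq_along(pool)^(-exponent))
  }
  pick_fun <- function() pick(free_funs)
  pick_dis <- function() pick(free_dis)
  pick_adk <- function() {
    sample(adks, 1L, prob = seq_along(adks)^(-config$hub_skew))
  }

  # phase 1: planted motif (hub -> bridge -> function -> disease)
  for (h in hubs) add_edge(h, bridge)
  for (i in seq_len(n_bf)) {
    add_edge(bridge, bridge_funs[i])
    for (j in seq_len(dis_per_fun)) {
      d_ix <- min((i - 1L) * dis_per_fun + j, ls[["disease_process"]])
      add_edge(bridge_funs[i], nm$disease_process[d_ix])
    }
  }

  # phase 2: coverage — one incident edge for every untouched node;
  # upstream nodes are wired to the dominant adipokines first, as the
  # best-studied adipokines are the ones perturbations are reported
  # against
  upstream <- c(nm$physiologic_perturbation, nm$sleep_disturbance)
  for (i in seq_along(upstream)) {
    add_edge(upstream[i], hubs[(i - 1L) %% length(hubs) + 1L])
  }
  for (t in free_targets) add_edge(pick_adk(), t)
  for (a in adks[!covered(adks)]) add_edge(a, pick(free_targets))
  for (f in nm$physiologic_function[!covered(nm$physiologic_function)]) {
    s <- if (stats::runif(1) < config$shortcut_edge_fraction ||
             !length(free_targets)) pick_adk() else pick(free_targets)
    add_edge(s, f)
  }
  for (d in free_dis[!covered(free_dis)]) {
    s <- if (stats::runif(1) < config$shortcut_edge_fraction ||
             !length(free_funs)) pick_adk() else pick(free_funs)
    add_edge(s, d)
  }
  if (n_edges > config$edge_budget) {
    stop(sprintf("edge_budget %d too small: %d edges needed to cover %s",
                 config$edge_budget, n_edges, "all layers"))
  }

  # phase 3: fill to the exact budget; the bridge takes no further edges
  s_frac <- config$shortcut_edge_fraction
  fill_types <- c("pert_adk", "sleep_adk", "adk_mt", "mt_pf", "pf_dp",
                  "adk_pf", "adk_dp")
  # the small upstream layers saturate quickly, so most random edges are
  # placed in the large downstream layers
  fill_probs <- c((1 - s_frac) * c(0.05, 0.03, 0.22, 0.40, 0.30),
                  s_frac * c(0.6, 0.4))
  attempts <- 0L
  while (n_edges < config$edge_budget) {
    attempts <- attempts + 1L
    if (attempts > 1e6L) {
      stop("edge budget infeasible: exceeded 1e6 sampling attempts")
    }
    type <- sample(fill_types, 1L, prob = fill_probs)
    ok <- switch(type,
      pert_adk = ls[["physiologic_perturbation"]] > 0 &&
        add_edge(pick(nm$physiologic_perturbation), pick_adk()),
      sleep_adk = ls[["sleep_disturbance"]] > 0 &&
        add_edge(pick(nm$sleep_disturbance), pick_adk()),
      adk_mt = length(free_targets) > 0 &&
        add_edge(pick_adk(), pick(free_targets)),
      mt_pf = length(free_targets) > 0 && length(free_funs) > 0 &&
        add_edge(pick(free_targets), pick_fun()),
      pf_dp = length(free_funs) > 0 &&
        add_edge(pick(free_funs), pick_dis()),
      adk_pf = length(free_funs) > 0 &&
        add_edge(pick_adk(), pick_fun()),
      adk_dp = add_edge(pick_adk(), pick_dis()))
  }

  ord <- order(src, dst, method = "radix")
  src <- src[ord]
  dst <- dst[ord]
  signs <- sample(edge_signs(), config$edge_budget, replace = TRUE,
                  prob = config$sign_probs)
  assertions <- assertion_table(
    source = src, source_category = unname(category_of[src]),
    target = dst, target_category = unname(category_of[dst]),
    sign = signs,
    provenance = sprintf("synthetic (seed %d)", config$seed))
  list(assertions = assertions, planted_hubs = hubs, bridge = bridge,
       config = config)
}

#' Pedagogical toy networks
#'
#' Small named fixtures illustrating the network concepts the analysis
#' rests on, for use in tests and documentation:
#' \describe{
#'   \item{gene_regulatory}{directed two-regulator toy (TF1, TF2 each
#'     driving downstream genes).}
#'   \item{ppi}{5-protein interaction toy; undirected associations stored
#'     as symmetric directed pairs, so it deliberately ignores the layered
#'     schema.}
#'   \item{random_like}{sparse graph with near-uniform degrees — no hubs.}
#'   \item{star_hub}{one high-degree center, the canonical hub.}
#'   \item{bridged_bottleneck}{two 4-node stars joined by a single
#'     low-degree bridge node carrying every cross-star shortest path —
#'     the canonical nonhub bottleneck.}
#' }
#'
#' @return Named list of [typed_network()] objects.
#' @export
#' @examples
#' betweenness(figure1_fixtures()$bridged_bottleneck)
figure1_fixtures <- function() {
  tn <- function(names, cats, s, t) {
    typed_network(nodes = data.frame(name = names, category = cats),
                  edges = data.frame(source = s, target = t,
                                     sign = "uncertain"))
  }
  gene_regulatory <- tn(
    c("TF1", "TF2", "G1", "G2", "G3"),
    c("adipokine", "adipokine", rep("molecular_target", 3)),
    s = c("TF1", "TF1", "TF2", "TF2"),
    t = c("G1", "G2", "G2", "G3"))
  ppi_pairs <- rbind(c("P0", "P1"), c("P1", "P2"), c("P2", "P3"),
                     c("P3", "P4"), c("P4", "P0"), c("P0", "P2"))
  ppi <- tn(paste0("P", 0:4), rep("molecular_target", 5),
            s = c(ppi_pairs[, 1], ppi_pairs[, 2]),
            t = c(ppi_pairs[, 2], ppi_pairs[, 1]))
  random_like <- tn(
    c("R1", "R2", "A1", "A2", "M1", "M2", "F1", "D1"),
    c("physiologic_perturbation", "sleep_disturbance",
      "adipokine", "adipokine", "molecular_target", "molecular_target",
      "physiologic_function", "disease_process"),
    s = c("R1", "R2", "A1", "A2", "M1", "M2", "F1"),
    t = c("A1", "A2", "M1", "M2", "F1", "F1", "D1"))
  star_hub <- tn(
    c("hub", paste0("leaf", 1:5)),
    c("adipokine", rep("molecular_target", 5)),
    s = rep("hub", 5), t = paste0("leaf", 1:5))
  bridged_bottleneck <- tn(
    c(paste0("in", 1:3), "h1", "b", "h2", paste0("out", 1:3)),
    c(rep("physiologic_perturbation", 3), "adipokine", "molecular_target",
      "physiologic_function", rep("disease_process", 3)),
    s = c(paste0("in", 1:3), "h1", "b", rep("h2", 3)),
    t = c(rep("h1", 3), "b", "h2", paste0("out", 1:3)))
  list(gene_regulatory = gene_regulatory, ppi = ppi,
       random_like = random_like, star_hub = star_hub,
       bridged_bottleneck = bridged_bottleneck)
}
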