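#' Node categories of the layered adipokine network
#'
#' The network schema distinguishes six node categories. Information flows
#' from physiologic perturbations and sleep disturbances through adipokines
#' and their molecular targets to physiologic functions and, finally,
#' disease processes.
#'
#' @return Character vector of the six category labels, in layer order.
#' @export
#' @examples
#' node_categories()
node_categories <- function() {
  c("physiologic_perturbation", "sleep_disturbance", "adipokine",
    "molecular_target", "physiologic_function", "disease_process")
}

#' Edge sign labels
#'
#' Every edge carries exactly one sign: a positive, negative, or uncertain
#' association between source and target.
#'
#' @return Character vector of the three sign labels.
#' @export
edge_signs <- function() {
  c("positive", "negative", "uncertain")
}

#' Allowed category transitions
#'
#' The schema is closed-world: a directed edge is legal only if its
#' (source category, target category) pair appears in this table, which is
#' derived from the five edge-creation rules used to curate the network:
#' perturbation/sleep -> adipokine, adipokine -> molecular target,
#' target -> physiologic function, function -> disease process, and the
#' "shortcut" edges adipokine -> function and adipokine -> disease for
#' relations whose molecular mechanism is not pinned down.
#'
#' Functions that validate or build networks accept a `transitions`
#' argument, so a curator can extend the table (e.g. with
#' molecular_target -> disease_process) without touching package code.
#'
#' @return A data.frame with columns `from` and `to` (category labels).
#' @export
#' @examples
#' allowed_transitions()
allowed_transitions <- function() {
  data.frame(
    from = c("physiologic_perturbation", "sleep_disturbance",
             "adipokine", "adipokine", "adipokine",
             "molecular_target", "physiologic_function"),
    to   = c("adipokine", "adipokine",
             "molecular_target", "physiologic_function", "disease_process",
             "physiologic_function", "disease_process"),
    stringsAsFactors = FALSE
  )
}

#' Test whether a category transition is schema-legal
#'
#' @param src,dst Category labels (see [node_categories()]).
#' @param transitions Transition table; defaults to [allowed_transitions()].
#' @return `TRUE` iff an edge from a `src`-category node to a
#'   `dst`-category node is allowed.
#' @export
#' @examples
#' allowed_transition("sleep_disturbance", "adipokine")   # TRUE
#' allowed_transition("disease_process", "adipokine")     # FALSE
allowed_transition <- function(src, dst, transitions = allowed_transitions()) {
  if (!src %in% node_categories() || !dst %in% node_categories()) {
    stop("unknown node category: ",
         paste(setdiff(c(src, dst), node_categories()), collapse = ", "))
  }
  any(transitions$from == src & transitions$to == dst)
}

# Whitespace-normalized display form; comparison key is its casefold.
# "AMPK " and "ampk" collapse to one node; the first-seen spelling is kept.
normalize_name <- function(x) {
  gsub("[[:space:]]+", " ", trimws(x))
}

name_key <- function(x) {
  tolower(normalize_name(x))
}

#' Construct a typed network
#'
#' A typed network is a directed graph whose nodes carry one of the six
#' categories and whose edges carry a sign. Node weights (used for display
#' sizing on export) always equal the node's total degree. The constructor
#' canonicalizes node and edge order so that structurally equal networks
#' are identical objects; it does not check the transition schema — use
#' [validate_network()] for that.
#'
#' @param nodes data.frame with columns `name`, `category`.
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (names refer to `nodes$name`; matching is case-insensitive after
#'   whitespace normalization).
#' @return An object of class `typed_network` with elements `nodes`,
#'   `edges` and `weights` (named integer vector, total degree).
#' @seealso [validate_network()], [build_network()]
#' @export
typed_network <- function(nodes = data.frame(name = character(),
                                             category = character()),
                          edges = data.frame(source = character(),
                                             target = character(),
                                             sign = character())) {
  nodes <- data.frame(name = normalize_name(as.character(nodes$name)),
                      category = as.character(nodes$category),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = normalize_name(as.character(edges$source)),
                      target = normalize_name(as.character(edges$target)),
                      sign = as.character(edges$sign),
                      stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(name_key(nodes$name)), , drop = FALSE]
  nodes <- nodes[order(name_key(nodes$name), method = "radix"), , drop = FALSE]
  edges <- edges[order(name_key(edges$source), name_key(edges$target),
                       method = "radix"), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  net <- structure(list(nodes = nodes, edges = edges), class = "typed_network")
  net$weights <- node_weights(net)
  net
}

# total degree per node, in nodes-table order
node_weights <- function(net) {
  keys <- name_key(net$nodes$name)
  w <- integer(length(keys))
  names(w) <- net$nodes$name
  if (nrow(net$edges)) {
    tab <- table(factor(c(name_key(net$edges$source),
                          name_key(net$edges$target)), levels = keys))
    w[] <- as.integer(tab)
  }
  w
}

#' @export
print.typed_network <- function(x, ...) {
  cat(sprintf("<typed_network> %d nodes, %d directed signed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  tab <- table(factor(x$nodes$category, levels = node_categories()))
  for (cat_i in names(tab)) {
    if (tab[[cat_i]] > 0) cat(sprintf("  %-24s %d\n", cat_i, tab[[cat_i]]))
  }
  invisible(x)
}

#' Validate a typed network against the layered schema
#'
#' Checks every structural invariant: known categories and signs, edge
#' endpoints present in the node table, no self-loops, at most one edge per
#' ordered pair, every edge on an allowed category transition, and node
#' weights equal to total degree. Violations are described and returned,
#' never thrown.
#'
#' @param net A [typed_network()].
#' @param transitions Transition table; defaults to [allowed_transitions()].
#' @return Character vector of human-readable violations; `character(0)`
#'   when the network is valid.
#' @export
#' @examples
#' net <- typed_network(
#'   nodes = data.frame(name = c("OSA", "leptin"),
#'                      category = c("sleep_disturbance", "adipokine")),
#'   edges = data.frame(source = "OSA", target = "leptin", sign = "negative"))
#' validate_network(net)  # character(0)
validate_network <- function(net, transitions = allowed_transitions()) {
  stopifnot(inherits(net, "typed_network"))
  v <- character(0)
  nodes <- net$nodes
  edges <- net$edges

  bad_cat <- !nodes$category %in% node_categories()
  if (any(bad_cat)) {
    v <- c(v, sprintf("node '%s': unknown category '%s'",
                      nodes$name[bad_cat], nodes$category[bad_cat]))
  }
  dup_node <- duplicated(name_key(nodes$name))
  if (any(dup_node)) {
    v <- c(v, sprintf("node '%s': duplicate node name", nodes$name[dup_node]))
  }
  if (nrow(edges)) {
    bad_sign <- !edges$sign %in% edge_signs()
    if (any(bad_sign)) {
      v <- c(v, sprintf("edge %s->%s: unknown sign '%s'",
                        edges$source[bad_sign], edges$target[bad_sign],
                        edges$sign[bad_sign]))
    }
    keys <- name_key(nodes$name)
    s_ix <- match(name_key(edges$source), keys)
    t_ix <- match(name_key(edges$target), keys)
    miss <- is.na(s_ix) | is.na(t_ix)
    if (any(miss)) {
      v <- c(v, sprintf("edge %s->%s: endpoint not in node table",
                        edges$source[miss], edges$target[miss]))
    }
    loops <- !miss & s_ix == t_ix
    if (any(loops)) {
      v <- c(v, sprintf("edge %s->%s: self-loop",
                        edges$source[loops], edges$target[loops]))
    }
    dup <- duplicated(paste(name_key(edges$source), name_key(edges$target),
                            sep = "\r"))
    if (any(dup)) {
      v <- c(v, sprintf("edge %s->%s: duplicate ordered pair",
                        edges$source[dup], edges$target[dup]))
    }
    ok <- !miss
    if (any(ok)) {
      from_cat <- nodes$category[s_ix[ok]]
      to_cat <- nodes$category[t_ix[ok]]
      legal <- mapply(function(f, t) any(transitions$from == f &
                                           transitions$to == t),
                      from_cat, to_cat)
      if (any(!legal)) {
        v <- c(v, sprintf("edge %s->%s: disallowed transition %s->%s",
                          edges$source[ok][!legal], edges$target[ok][!legal],
                          from_cat[!legal], to_cat[!legal]))
      }
    }
  }
  w <- node_weights(net)
  if (!is.null(net$weights) &&
      (length(net$weights) != length(w) ||
       any(net$weights[names(w)] != w, na.rm = TRUE) ||
       anyNA(net$weights[names(w)]))) {
    v <- c(v, "node weights do not equal total degree")
  }
  unname(v)
}
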