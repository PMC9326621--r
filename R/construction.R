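#' Build an assertion table
#'
#' An assertion is one curated directed signed relation between two named,
#' typed entities — the raw material of the network. This helper builds the
#' canonical six-column data.frame and recycles scalar arguments.
#'
#' @param source,target Entity names.
#' @param source_category,target_category Category labels
#'   (see [node_categories()]).
#' @param sign Edge sign; defaults to `"uncertain"`.
#' @param provenance Free-text citation note; may be empty.
#' @return data.frame with columns `source`, `source_category`, `target`,
#'   `target_category`, `sign`, `provenance`.
#' @export
#' @examples
#' assertion_table("OSA", "sleep_disturbance", "leptin", "adipokine",
#'                 sign = "negative")
assertion_table <- function(source = character(), source_category = character(),
                            target = character(), target_category = character(),
                            sign = "uncertain", provenance = "") {
  n <- max(length(source), length(target))
  data.frame(source = as.character(source),
             source_category = rep_len(as.character(source_category), n),
             target = as.character(target),
             target_category = rep_len(as.character(target_category), n),
             sign = rep_len(as.character(sign), n),
             provenance = rep_len(as.character(provenance), n),
             stringsAsFactors = FALSE)
}

assertion_columns <- function() {
  c("source", "source_category", "target", "target_category",
    "sign", "provenance")
}

# row-level checks shared by build_network() and read_assertions();
# returns character(0) or messages mentioning the 1-based record number
check_assertion_rows <- function(a, transitions = allowed_transitions()) {
  msgs <- character(0)
  for (i in seq_len(nrow(a))) {
    rec <- sprintf("record %d (%s -> %s)", i, a$source[i], a$target[i])
    if (!a$source_category[i] %in% node_categories()) {
      msgs <- c(msgs, sprintf("%s: unknown source_category '%s'",
                              rec, a$source_category[i]))
      next
    }
    if (!a$target_category[i] %in% node_categories()) {
      msgs <- c(msgs, sprintf("%s: unknown target_category '%s'",
                              rec, a$target_category[i]))
      next
    }
    if (!a$sign[i] %in% edge_signs()) {
      msgs <- c(msgs, sprintf("%s: unknown sign '%s'", rec, a$sign[i]))
    }
    if (name_key(a$source[i]) == name_key(a$target[i])) {
      msgs <- c(msgs, sprintf("%s: source equals target", rec))
    } else if (!allowed_transition(a$source_category[i], a$target_category[i],
                                   transitions)) {
      msgs <- c(msgs, sprintf("%s: disallowed transition %s->%s", rec,
                              a$source_category[i], a$target_category[i]))
    }
  }
  msgs
}

#' Build a typed network from an assertion table
#'
#' Applies the curation procedure: one node per distinct (name, category),
#' one edge per distinct ordered pair. Duplicate identical assertions
#' collapse to one edge; an `uncertain` sign is overridden by a definite
#' (`positive`/`negative`) sign on deduplication. An ordered pair asserted
#' with both `positive` and `negative` sign is contradictory and resolved
#' by `conflict_policy`:
#' \describe{
#'   \item{`drop_edge`}{(default) only the contradictory edge is removed;
#'     both endpoint nodes stay.}
#'   \item{`exclude_node`}{mirrors the stricter curation rule that nodes
#'     with inconsistent relations are excluded: the node on
#'     `exclude_side` of each conflicting pair is removed with all its
#'     incident edges.}
#' }
#' Every resolution is logged as a conflict record.
#'
#' @param assertions data.frame as produced by [assertion_table()] or
#'   [read_assertions()].
#' @param conflict_policy `"drop_edge"` or `"exclude_node"`.
#' @param exclude_side For `exclude_node`: which endpoint(s) of a
#'   conflicting pair to remove (`"target"`, `"source"`, or `"both"`).
#' @param transitions Transition table; defaults to [allowed_transitions()].
#' @return List with elements `network` (a validated [typed_network()])
#'   and `conflicts` (data.frame: `source`, `target`, `signs_seen`,
#'   `resolution`).
#' @export
#' @examples
#' a <- assertion_table("OSA", "sleep_disturbance", "leptin", "adipokine",
#'                      sign = "negative")
#' build_network(a)$network
build_network <- function(assertions,
                          conflict_policy = c("drop_edge", "exclude_node"),
                          exclude_side = c("target", "source", "both"),
                          transitions = allowed_transitions()) {
  conflict_policy <- match.arg(conflict_policy)
  exclude_side <- match.arg(exclude_side)
  a <- as.data.frame(assertions, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(assertion_columns(), "provenance"),
                          names(a))
  if (length(missing_cols)) {
    stop("assertion table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(a$provenance)) a$provenance <- ""
  for (col in assertion_columns()) a[[col]] <- as.character(a[[col]])

  no_conflicts <- data.frame(source = character(), target = character(),
                             signs_seen = character(),
                             resolution = character(),
                             stringsAsFactors = FALSE)
  if (nrow(a) == 0) {
    return(list(network = typed_network(), conflicts = no_conflicts))
  }

  msgs <- check_assertion_rows(a, transitions)
  if (length(msgs)) stop(paste(msgs, collapse = "\n"))

  # one category per entity name
  ent <- data.frame(name = c(a$source, a$target),
                    category = c(a$source_category, a$target_category),
                    stringsAsFactors = FALSE)
  ent$key <- name_key(ent$name)
  by_key <- split(ent, ent$key)
  cat_conf <- vapply(by_key, function(d) length(unique(d$category)) > 1,
                     logical(1))
  if (any(cat_conf)) {
    bad <- by_key[cat_conf]
    stop(paste(vapply(bad, function(d) {
      sprintf("entity '%s' used with categories: %s", d$name[1],
              paste(sort(unique(d$category)), collapse = ", "))
    }, character(1)), collapse = "\n"))
  }
  ent <- ent[!duplicated(ent$key), , drop = FALSE]

  # deduplicate ordered pairs; definite sign beats uncertain
  pair_key <- paste(name_key(a$source), name_key(a$target), sep = "\r")
  groups <- split(seq_len(nrow(a)), pair_key)
  edge_rows <- lapply(groups, function(ix) {
    signs <- unique(a$sign[ix])
    definite <- setdiff(signs, "uncertain")
    conflict <- all(c("positive", "negative") %in% definite)
    data.frame(source = a$source[ix[1]], target = a$target[ix[1]],
               sign = if (conflict) NA_character_
                      else if (length(definite)) definite else "uncertain",
               signs_seen = paste(sort(signs), collapse = "+"),
               conflict = conflict, stringsAsFactors = FALSE)
  })
  ed <- do.call(rbind, edge_rows)
  rownames(ed) <- NULL

  conflicts <- no_conflicts
  drop_keys <- character(0)
  if (any(ed$conflict)) {
    cf <- ed[ed$conflict, , drop = FALSE]
    resolution <- if (conflict_policy == "drop_edge") "edge_dropped"
                  else "node_excluded"
    conflicts <- data.frame(source = cf$source, target = cf$target,
                            signs_seen = cf$signs_seen,
                            resolution = resolution,
                            stringsAsFactors = FALSE)
    if (conflict_policy == "exclude_node") {
      drop_keys <- switch(exclude_side,
        target = name_key(cf$target),
        source = name_key(cf$source),
        both   = c(name_key(cf$source), name_key(cf$target)))
      drop_keys <- unique(drop_keys)
    }
  }
  keep <- !ed$conflict &
    !(name_key(ed$source) %in% drop_keys) &
    !(name_key(ed$target) %in% drop_keys)
  nodes <- ent[!ent$key %in% drop_keys, c("name", "category"), drop = FALSE]
  net <- typed_network(nodes = nodes,
                       edges = ed[keep, c("source", "target", "sign"),
                                  drop = FALSE])
  conflicts <- conflicts[order(name_key(conflicts$source),
                               name_key(conflicts$target),
                               method = "radix"), , drop = FALSE]
  rownames(conflicts) <- NULL
  list(network = net, conflicts = conflicts)
}

#' Expand a mechanism chain into assertions
#'
#' Convenience for curating a chain such as
#' adipokine -> molecular target -> physiologic function -> disease
#' process: each consecutive pair becomes one assertion. The first link
#' starts at the adipokine, so a one-element path encodes a "shortcut"
#' edge (adipokine straight to a function or disease).
#'
#' @param adipokine Adipokine entity name.
#' @param path data.frame with columns `name` and `category`, in chain
#'   order (may be empty), or a list of `c(name, category)` pairs.
#' @param sign Sign(s) for the generated records, recycled along the
#'   chain; defaults to `"uncertain"`.
#' @param provenance Provenance note, recycled.
#' @param transitions Transition table; defaults to [allowed_transitions()].
#' @return Assertion data.frame with one row per chain link.
#' @export
#' @examples
#' assert_chain("leptin", data.frame(
#'   name = c("JAK-STAT3", "food intake"),
#'   category = c("molecular_target", "physiologic_function")))
assert_chain <- function(adipokine, path, sign = "uncertain",
                         provenance = "",
                         transitions = allowed_transitions()) {
  if (is.list(path) && !is.data.frame(path)) {
    path <- data.frame(name = vapply(path, `[`, character(1), 1),
                       category = vapply(path, `[`, character(1), 2),
                       stringsAsFactors = FALSE)
  }
  if (is.null(path) || nrow(path) == 0) {
    return(assertion_table())
  }
  src <- c(adipokine, path$name[-nrow(path)])
  src_cat <- c("adipokine", path$category[-nrow(path)])
  out <- assertion_table(source = src, source_category = src_cat,
                         target = path$name, target_category = path$category,
                         sign = sign, provenance = provenance)
  msgs <- check_assertion_rows(out, transitions)
  if (length(msgs)) {
    stop("broken chain:\n", paste(msgs, collapse = "\n"))
  }
  out
}

#' Convert a typed network back to an assertion table
#'
#' Inverse of [build_network()] for conflict-free networks: each edge
#' becomes one assertion carrying the endpoint categories; provenance is
#' empty.
#'
#' @param net A [typed_network()].
#' @return Assertion data.frame with one row per edge.
#' @export
to_assertions <- function(net) {
  stopifnot(inherits(net, "typed_network"))
  if (nrow(net$edges) == 0) return(assertion_table())
  keys <- name_key(net$nodes$name)
  s_ix <- match(name_key(net$edges$source), keys)
  t_ix <- match(name_key(net$edges$target), keys)
  assertion_table(source = net$nodes$name[s_ix],
                  source_category = net$nodes$category[s_ix],
                  target = net$nodes$name[t_ix],
                  target_category = net$nodes$category[t_ix],
                  sign = net$edges$sign,
                  provenance = "")
}
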