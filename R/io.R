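#' Read an assertion table from CSV
#'
#' Expects the dialect written by [write_assertions()]: header exactly
#' `source,source_category,target,target_category,sign,provenance`,
#' UTF-8, comma-separated, quoted fields allowed. Fields are trimmed and
#' category/sign tokens are validated per row; errors name the 1-based
#' file line and the offending field.
#'
#' @param path Path to a CSV file.
#' @return Assertion data.frame (see [assertion_table()]).
#' @export
read_assertions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  a <- utils::read.csv(path, colClasses = "character",
                       check.names = FALSE, fileEncoding = "UTF-8")
  expected <- assertion_columns()
  if (!identical(names(a), expected)) {
    stop(sprintf("line 1: header must be exactly '%s' (got '%s')",
                 paste(expected, collapse = ","),
                 paste(names(a), collapse = ",")))
  }
  for (col in expected) a[[col]] <- trimws(a[[col]])
  msgs <- character(0)
  for (i in seq_len(nrow(a))) {
    line <- i + 1L
    if (!nzchar(a$source[i])) {
      msgs <- c(msgs, sprintf("line %d: field 'source' is empty", line))
    }
    if (!nzchar(a$target[i])) {
      msgs <- c(msgs, sprintf("line %d: field 'target' is empty", line))
    }
    if (!a$source_category[i] %in% node_categories()) {
      msgs <- c(msgs, sprintf(
        "line %d: field 'source_category' has unknown value '%s'",
        line, a$source_category[i]))
    }
    if (!a$target_category[i] %in% node_categories()) {
      msgs <- c(msgs, sprintf(
        "line %d: field 'target_category' has unknown value '%s'",
        line, a$target_category[i]))
    }
    if (!a$sign[i] %in% edge_signs()) {
      msgs <- c(msgs, sprintf("line %d: field 'sign' has unknown value '%s'",
                              line, a$sign[i]))
    }
  }
  if (length(msgs)) stop(paste(msgs, collapse = "\n"))
  a
}

#' Write an assertion table to CSV
#'
#' @param assertions Assertion data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assertions <- function(assertions, path) {
  a <- as.data.frame(assertions)[assertion_columns()]
  utils::write.csv(a, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

GEXF_NS <- "http://gexf.net/1.3"
GEXF_VIZ_NS <- "http://gexf.net/1.3/viz"

#' Write a network to GEXF 1.3
#'
#' Gephi-native export. Nodes carry `category`, `degree` and
#' `betweenness` attributes plus a viz size equal to their degree (nodes
#' weighted proportionally to degree); edges carry their `sign` and the
#' graph is marked directed.
#'
#' @param net A [typed_network()].
#' @param path Output path.
#' @param table Optional [centrality_table()] over the same nodes;
#'   computed on the fly when `NULL`.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(net, path, table = NULL) {
  stopifnot(inherits(net, "typed_network"))
  if (is.null(table)) table <- centrality_table(net)
  if (!setequal(name_key(table$node), name_key(net$nodes$name))) {
    stop("centrality table and network cover different node sets")
  }
  ix <- match(name_key(net$nodes$name), name_key(table$node))

  doc <- xml2::xml_new_root("gexf", xmlns = GEXF_NS,
                            "xmlns:viz" = GEXF_VIZ_NS, version = "1.3")
  meta <- xml2::xml_add_child(doc, "meta")
  xml2::xml_add_child(meta, "creator", "adiponet")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  nattr <- xml2::xml_add_child(graph, "attributes", class = "node")
  for (def in list(c("0", "category", "string"),
                   c("1", "degree", "integer"),
                   c("2", "betweenness", "double"))) {
    xml2::xml_add_child(nattr, "attribute", id = def[1], title = def[2],
                        type = def[3])
  }
  eattr <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattr, "attribute", id = "0", title = "sign",
                      type = "string")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(net$nodes))) {
    node <- xml2::xml_add_child(nodes_el, "node",
                                id = net$nodes$name[i],
                                label = net$nodes$name[i])
    av <- xml2::xml_add_child(node, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = net$nodes$category[i])
    xml2::xml_add_child(av, "attvalue", "for" = "1",
                        value = as.character(table$degree[ix[i]]))
    xml2::xml_add_child(av, "attvalue", "for" = "2",
                        value = format_number(table$betweenness[ix[i]]))
    xml2::xml_add_child(node, "viz:size",
                        value = as.character(table$degree[ix[i]]))
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(net$edges))) {
    edge <- xml2::xml_add_child(edges_el, "edge",
                                id = as.character(i - 1L),
                                source = net$edges$source[i],
                                target = net$edges$target[i])
    av <- xml2::xml_add_child(edge, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0",
                        value = net$edges$sign[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a typed network back from GEXF written by [write_gexf()]
#'
#' @param path Path to a GEXF file.
#' @return A [typed_network()].
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = GEXF_NS)
  node_el <- xml2::xml_find_all(doc, ".//g:nodes/g:node", ns)
  edge_el <- xml2::xml_find_all(doc, ".//g:edges/g:edge", ns)
  get_att <- function(els, id) {
    vapply(els, function(e) {
      v <- xml2::xml_find_first(
        e, sprintf("./g:attvalues/g:attvalue[@for='%s']", id), ns)
      xml2::xml_attr(v, "value")
    }, character(1))
  }
  nodes <- data.frame(name = xml2::xml_attr(node_el, "id"),
                      category = get_att(node_el, "0"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = xml2::xml_attr(edge_el, "source"),
                      target = xml2::xml_attr(edge_el, "target"),
                      sign = get_att(edge_el, "0"),
                      stringsAsFactors = FALSE)
  typed_network(nodes = nodes, edges = edges)
}

#' Write a network to GraphML
#'
#' Alternate export for tools that do not read GEXF; same attributes as
#' [write_gexf()].
#'
#' @inheritParams write_gexf
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, table = NULL) {
  stopifnot(inherits(net, "typed_network"))
  if (is.null(table)) table <- centrality_table(net)
  ix <- match(name_key(net$nodes$name), name_key(table$node))
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- list(c("d0", "node", "category", "string"),
               c("d1", "node", "degree", "int"),
               c("d2", "node", "betweenness", "double"),
               c("d3", "edge", "sign", "string"))
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1], "for" = k[2],
                        "attr.name" = k[3], "attr.type" = k[4])
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "directed")
  for (i in seq_len(nrow(net$nodes))) {
    node <- xml2::xml_add_child(graph, "node", id = net$nodes$name[i])
    xml2::xml_add_child(node, "data", key = "d0", net$nodes$category[i])
    xml2::xml_add_child(node, "data", key = "d1",
                        as.character(table$degree[ix[i]]))
    xml2::xml_add_child(node, "data", key = "d2",
                        format_number(table$betweenness[ix[i]]))
  }
  for (i in seq_len(nrow(net$edges))) {
    edge <- xml2::xml_add_child(graph, "edge",
                                source = net$edges$source[i],
                                target = net$edges$target[i])
    xml2::xml_add_child(edge, "data", key = "d3", net$edges$sign[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# 9 significant digits in all serialized reports, for stable diffs
format_number <- function(x) {
  formatC(signif(x, 9), format = "g", digits = 9)
}

#' Write a centrality table as TSV
#'
#' @param table Centrality table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centrality_tsv <- function(table, path) {
  out <- table
  out$betweenness <- format_number(out$betweenness)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a classification report as JSON
#'
#' @param result A `classification` from [classify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(result, path) {
  stopifnot(inherits(result, "classification"))
  jsonlite::write_json(list(
    hubs = result$hubs,
    bottlenecks = result$bottlenecks,
    nonhub_bottlenecks = result$nonhub_bottlenecks,
    thresholds = data.frame(
      threshold = result$thresholds$threshold,
      value = signif(result$thresholds$value, 9),
      rule = result$thresholds$rule)
  ), path, pretty = TRUE, digits = NA)
  invisible(path)
}
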