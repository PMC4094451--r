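# Machine-readable graph exports. Both writers emit nodes with kind
# (species|reaction) and category, and edges with role, anchor site index
# and occurrence index, so a reader can reconstruct a graph isomorphic to
# the input.

dot_quote <- function(x) {
  sprintf('"%s"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)))
}

#' Export a reaction graph as Graphviz DOT
#'
#' @param graph a `reaction_graph`.
#' @return a single DOT `digraph` string; node attributes `kind` and
#'   `category`, edge attributes `role`, `category`, `anchor_site`
#'   (absent for center-anchored edges) and `occurrence`.
#' @export
export_dot <- function(graph) {
  stopifnot(inherits(graph, "reaction_graph"))
  lines <- c("digraph reaction_network {")
  for (i in seq_len(nrow(graph$nodes))) {
    n <- graph$nodes[i, ]
    attrs <- sprintf('kind=%s', dot_quote(n$kind))
    if (!is.na(n$category))
      attrs <- paste0(attrs, sprintf(', category=%s', dot_quote(n$category)))
    lines <- c(lines, sprintf("  %s [%s];", dot_quote(n$id), attrs))
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    attrs <- sprintf('role=%s, category=%s, occurrence="%d"',
                     dot_quote(e$role), dot_quote(e$category),
                     e$occurrence_index)
    if (!is.na(e$anchor_site))
      attrs <- paste0(attrs, sprintf(', anchor_site="%d"', e$anchor_site))
    lines <- c(lines, sprintf("  %s -> %s [%s];", dot_quote(e$from),
                              dot_quote(e$to), attrs))
  }
  paste(c(lines, "}", ""), collapse = "\n")
}

#' Export a reaction graph as GraphML
#'
#' @param graph a `reaction_graph`.
#' @return a single GraphML XML string with the same node/edge attributes
#'   as [export_dot()].
#' @export
export_graphml <- function(graph) {
  stopifnot(inherits(graph, "reaction_graph"))
  keys <- c(
    '<key id="kind" for="node" attr.name="kind" attr.type="string"/>',
    '<key id="category" for="node" attr.name="category" attr.type="string"/>',
    '<key id="role" for="edge" attr.name="role" attr.type="string"/>',
    '<key id="ecategory" for="edge" attr.name="category" attr.type="string"/>',
    '<key id="anchor_site" for="edge" attr.name="anchor_site" attr.type="int"/>',
    '<key id="occurrence" for="edge" attr.name="occurrence" attr.type="int"/>')
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             keys, '<graph id="reaction_network" edgedefault="directed">')
  for (i in seq_len(nrow(graph$nodes))) {
    n <- graph$nodes[i, ]
    lines <- c(lines, sprintf('<node id="%s">', xml_escape(n$id)),
               sprintf('<data key="kind">%s</data>', n$kind))
    if (!is.na(n$category))
      lines <- c(lines, sprintf('<data key="category">%s</data>',
                                n$category))
    lines <- c(lines, "</node>")
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    lines <- c(lines,
               sprintf('<edge id="%s" source="%s" target="%s">',
                       xml_escape(e$id), xml_escape(e$from),
                       xml_escape(e$to)),
               sprintf('<data key="role">%s</data>', e$role),
               sprintf('<data key="ecategory">%s</data>', e$category))
    if (!is.na(e$anchor_site))
      lines <- c(lines, sprintf('<data key="anchor_site">%d</data>',
                                e$anchor_site))
    lines <- c(lines,
               sprintf('<data key="occurrence">%d</data>',
                       e$occurrence_index),
               "</edge>")
  }
  paste(c(lines, "</graph>", "</graphml>", ""), collapse = "\n")
}
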