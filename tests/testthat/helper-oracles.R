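# Independent oracles and small construction helpers shared by the tests.
# Oracles deliberately avoid the package's own code paths: brute-force
# scans, a hand-rolled BFS, and export readers written against the format
# documentation rather than the writers.

tiny_association_model <- function() {
  # one association rule over three single-molecule species A + B -> AB
  mols <- list(
    molecule("A", list(mol_component("core", binding_sites = "a1"))),
    molecule("B", list(mol_component("core", binding_sites = "b1"))))
  species <- list(
    complex_species("A", c(m = "A"), complexes = list(species_complex("A"))),
    complex_species("B", c(m = "B"), complexes = list(species_complex("B"))),
    complex_species("AB", c(a = "A", b = "B"),
                    structural_bonds = list(c(1L, 2L)),
                    complexes = list(species_complex("AB"))))
  rule <- reaction_rule("bind", "association",
                        c(A = "A", B = "B"), c(AB = "AB"),
                        bond_sites = list(binding_site_ref("A", 1L),
                                          binding_site_ref("B", 1L)))
  reaction_model(mols, species, list(rule))
}

random_models_for_tests <- function(n, base_seed = 100L,
                                    n_species = 4L, n_rules = 6L) {
  lapply(seq_len(n), function(i)
    random_model(random_model_spec(n_species, n_rules,
                                   seed = base_seed + i)))
}

# brute-force: rules a (species, complex) pair occurs in
oracle_rules_of_complex <- function(model, species, complex) {
  hits <- character()
  for (r in model$rules) {
    refs <- rbind(r$reactants, r$products)
    if (any(refs$species == species & refs$complex == complex))
      hits <- c(hits, r$name)
  }
  hits
}

# brute-force lowercase substring scan over species/complex names
oracle_name_filter <- function(model, term) {
  out <- list()
  for (sp in model$species) {
    cx_names <- vapply(sp$complexes, `[[`, "", "name")
    cx_hit <- grepl(tolower(term), tolower(cx_names), fixed = TRUE)
    sp_hit <- grepl(tolower(term), tolower(sp$name), fixed = TRUE)
    out[[sp$name]] <- list(
      species = if (sp_hit) "match"
                else if (any(cx_hit)) "child_match" else "none",
      complexes = stats::setNames(ifelse(cx_hit, "match", "none"), cx_names))
  }
  out
}

# exhaustive 3x3-per-variable tri-state matching oracle
oracle_tri_match <- function(a, b) {
  table <- c("on/on" = TRUE, "on/off" = FALSE, "on/dont_care" = TRUE,
             "off/on" = FALSE, "off/off" = TRUE, "off/dont_care" = TRUE,
             "dont_care/on" = TRUE, "dont_care/off" = TRUE,
             "dont_care/dont_care" = TRUE)
  unname(table[paste(a, b, sep = "/")])
}

# hand-rolled undirected BFS over a reaction_graph's edge list
oracle_bfs_levels <- function(graph, ref_id) {
  adj <- list()
  link <- function(a, b) adj[[a]] <<- unique(c(adj[[a]], b))
  for (i in seq_len(nrow(graph$edges))) {
    link(graph$edges$from[i], graph$edges$to[i])
    link(graph$edges$to[i], graph$edges$from[i])
  }
  dist <- stats::setNames(rep(Inf, nrow(graph$nodes)), graph$nodes$id)
  dist[ref_id] <- 0
  frontier <- ref_id
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
  }
  dist
}

# --- export readers (format-level, independent of the writers) -----------

read_graphml_export <- function(text) {
  doc <- xml2::read_xml(text)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf("./g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  nodes <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  edges <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  list(
    nodes = data.frame(
      id = xml2::xml_attr(nodes, "id"),
      kind = vapply(nodes, get_data, "", "kind"),
      category = vapply(nodes, get_data, "", "category"),
      stringsAsFactors = FALSE),
    edges = data.frame(
      from = xml2::xml_attr(edges, "source"),
      to = xml2::xml_attr(edges, "target"),
      role = vapply(edges, get_data, "", "role"),
      category = vapply(edges, get_data, "", "ecategory"),
      anchor_site = vapply(edges, get_data, "", "anchor_site"),
      occurrence = vapply(edges, get_data, "", "occurrence"),
      stringsAsFactors = FALSE))
}

read_dot_export <- function(text) {
  unquote <- function(x) gsub('\\\\"', '"',
                              gsub("\\\\\\\\", "\\\\", x))
  lines <- strsplit(text, "\n")[[1]]
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexec(sprintf('%s="((\\\\.|[^"\\\\])*)"', key),
                                   attrs))[[1]]
    if (length(m) < 2L) NA_character_ else unquote(m[2])
  }
  node_rows <- list()
  edge_rows <- list()
  for (ln in lines) {
    em <- regmatches(ln, regexec(
      '^  "((\\\\.|[^"\\\\])*)" -> "((\\\\.|[^"\\\\])*)" \\[(.*)\\];$',
      ln))[[1]]
    if (length(em)) {
      attrs <- em[6]
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        from = unquote(em[2]), to = unquote(em[4]),
        role = attr_val(attrs, "role"),
        category = attr_val(attrs, "category"),
        anchor_site = attr_val(attrs, "anchor_site"),
        occurrence = attr_val(attrs, "occurrence"),
        stringsAsFactors = FALSE)
      next
    }
    nm <- regmatches(ln, regexec(
      '^  "((\\\\.|[^"\\\\])*)" \\[(.*)\\];$', ln))[[1]]
    if (length(nm)) {
      attrs <- nm[4]
      node_rows[[length(node_rows) + 1L]] <- data.frame(
        id = unquote(nm[2]), kind = attr_val(attrs, "kind"),
        category = attr_val(attrs, "category"), stringsAsFactors = FALSE)
    }
  }
  list(nodes = do.call(rbind, node_rows), edges = do.call(rbind, edge_rows))
}

# canonical signatures for graph-isomorphism-by-identity comparison
graph_signature <- function(nodes, edges) {
  nodes$category[is.na(nodes$category)] <- ""
  n <- sort(sprintf("%s|%s|%s", nodes$id, nodes$kind, nodes$category))
  anchor <- if ("anchor_site" %in% names(edges)) {
    a <- as.character(edges$anchor_site)
    a[is.na(a)] <- ""
    a
  } else ""
  occ <- if ("occurrence" %in% names(edges)) edges$occurrence
         else edges$occurrence_index
  e <- sort(sprintf("%s|%s|%s|%s|%s|%s", edges$from, edges$to, edges$role,
                    edges$category, anchor, occ))
  list(nodes = n, edges = e)
}

reaction_graph_signature <- function(graph) {
  graph_signature(graph$nodes, graph$edges)
}
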