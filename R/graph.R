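# Directed bipartite species-reaction graph. Species nodes get ids
# "s:<name>", reaction (intermediate) nodes "r:<name>", so the two
# namespaces can never collide.

#' Node ids of species and reaction nodes
#' @param name species or rule name.
#' @return the node id string.
#' @export
species_node_id <- function(name) {
  if (length(name) == 0L) return(character())
  paste0("s:", name)
}

#' @rdname species_node_id
#' @export
reaction_node_id <- function(name) {
  if (length(name) == 0L) return(character())
  paste0("r:", name)
}

node_label <- function(id) sub("^[sr]:", "", id)

#' Build the bipartite species-reaction graph of a model
#'
#' Creates one species node per complex species and one reaction
#' (intermediate) node per rule. Every reactant occurrence contributes a
#' species-to-reaction edge and every product occurrence a
#' reaction-to-species edge, so a rule of category association or
#' dissociation contributes 3 edges and a transformation 2. Homotypic
#' occurrences (the same species twice on one side) yield parallel edges
#' distinguished by `occurrence_index`.
#'
#' Association and dissociation edges are anchored at the binding site the
#' rule's `bond_sites` name in that species; product-side edges are
#' anchored at the product species' copy of the bonded site (matched by
#' molecule/component/site name, lowest matching index). Transformation
#' edges, and edges whose site cannot be resolved, anchor at the node
#' center.
#'
#' @param model a valid [reaction_model()].
#' @return an object of class `reaction_graph` with components `nodes`
#'   (data frame: `id`, `name`, `kind`, `category`), `edges` (data frame:
#'   `id`, `from`, `to`, `role`, `category`, `species`, `rule`,
#'   `occurrence_index`, `anchor_species`, `anchor_site`,
#'   `anchor_molecule`, `anchor_component`, `anchor_site_name`,
#'   `rate_constant`) and `site_tables` (per-species site index tables).
#' @export
#' @examples
#' g <- build_network_graph(egfr_model())
#' graph_stats(g)
build_network_graph <- function(model) {
  assert_valid_model(model)
  sp_names <- names(model$species)
  rule_names <- names(model$rules)
  nodes <- rbind(
    data.frame(id = species_node_id(sp_names), name = sp_names,
               kind = rep("species", length(sp_names)),
               category = rep(NA_character_, length(sp_names)),
               stringsAsFactors = FALSE),
    data.frame(id = reaction_node_id(rule_names), name = rule_names,
               kind = rep("reaction", length(rule_names)),
               category = unname(vapply(model$rules, `[[`, "", "category")),
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL

  site_tables <- lapply(sp_names, function(s) species_site_table(model, s))
  names(site_tables) <- sp_names
  site_sig <- function(species, index) {
    tab <- site_tables[[species]]
    row <- tab[tab$site_index == index, , drop = FALSE]
    if (nrow(row) != 1L) return(NULL)
    c(molecule = row$molecule, component = row$component,
      site_name = row$site_name)
  }
  # lowest site index in `species` whose molecular identity matches any of
  # the given signatures
  match_sig <- function(species, sigs) {
    tab <- site_tables[[species]]
    for (i in seq_len(nrow(tab))) {
      for (sig in sigs) {
        if (is.null(sig)) next
        if (tab$molecule[i] == sig[["molecule"]] &&
            tab$component[i] == sig[["component"]] &&
            tab$site_name[i] == sig[["site_name"]])
          return(tab$site_index[i])
      }
    }
    NA_integer_
  }

  edge_rows <- list()
  add_edge <- function(rule, role, species, occ, anchor_species, anchor_site) {
    sig <- if (!is.na(anchor_site)) site_sig(anchor_species, anchor_site)
    edge_rows[[length(edge_rows) + 1L]] <<- data.frame(
      id = sprintf("%s#%s#%s#%d", rule$name, role, species, occ),
      from = if (role == "reactant") species_node_id(species)
             else reaction_node_id(rule$name),
      to = if (role == "reactant") reaction_node_id(rule$name)
           else species_node_id(species),
      role = role, category = rule$category, species = species,
      rule = rule$name, occurrence_index = occ,
      anchor_species = if (is.na(anchor_site)) NA_character_
                       else anchor_species,
      anchor_site = anchor_site,
      anchor_molecule = if (is.null(sig)) NA_character_ else sig[["molecule"]],
      anchor_component = if (is.null(sig)) NA_character_
                         else sig[["component"]],
      anchor_site_name = if (is.null(sig)) NA_character_
                         else sig[["site_name"]],
      rate_constant = rule$rate_constant, stringsAsFactors = FALSE)
  }

  for (rule in model$rules) {
    has_bonds <- !is.null(rule$bond_sites) &&
      rule$category != "transformation"
    bond_species <- if (has_bonds)
      vapply(rule$bond_sites, `[[`, "", "species_name") else character()
    bond_sigs <- if (has_bonds)
      lapply(rule$bond_sites, function(b) site_sig(b$species_name,
                                                   b$site_index))
    else list()

    for (role in c("reactant", "product")) {
      side <- if (role == "reactant") rule$reactants else rule$products
      occ_count <- integer()
      for (i in seq_len(nrow(side))) {
        sp <- side$species[i]
        occ_count[sp] <- if (is.na(occ_count[sp] + 0L)) 1L
                         else occ_count[[sp]] + 1L
        occ <- occ_count[[sp]]
        anchor <- NA_integer_
        if (has_bonds) {
          if (role == "reactant") {
            mine <- which(bond_species == sp)
            if (rule$category == "dissociation") {
              # both dissolved sites live in the single reactant species
              if (length(mine))
                anchor <- min(vapply(rule$bond_sites[mine],
                                     `[[`, 0L, "site_index"))
            } else if (length(mine) >= occ) {
              anchor <- rule$bond_sites[[mine[occ]]]$site_index
            }
          } else {
            # map the bonded site(s) into the product species by molecular
            # identity; lowest matching index wins
            anchor <- match_sig(sp, bond_sigs)
          }
        }
        add_edge(rule, role, sp, occ,
                 anchor_species = sp, anchor_site = anchor)
      }
    }
  }

  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(id = character(), from = character(), to = character(),
               role = character(), category = character(),
               species = character(), rule = character(),
               occurrence_index = integer(), anchor_species = character(),
               anchor_site = integer(), anchor_molecule = character(),
               anchor_component = character(), anchor_site_name = character(),
               rate_constant = numeric(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, site_tables = site_tables),
            class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  s <- graph_stats(x)
  cat(sprintf(
    "<reaction_graph: %d nodes (%d species + %d reactions), %d edges>\n",
    s$n_nodes, s$n_species_nodes, s$n_reaction_nodes, s$n_edges))
  invisible(x)
}

#' Convert to an igraph object
#'
#' @param graph a [build_network_graph()] result.
#' @return a directed `igraph` graph whose vertices carry `kind` and
#'   `category`, and edges `role`, `anchor_site` and `occurrence_index`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "reaction_graph"))
  igraph::graph_from_data_frame(
    graph$edges[, c("from", "to", "role", "category", "anchor_site",
                    "occurrence_index"), drop = FALSE],
    directed = TRUE,
    vertices = graph$nodes[, c("id", "kind", "category"), drop = FALSE])
}

#' Summary statistics of a bipartite reaction graph
#'
#' @param graph a `reaction_graph`.
#' @return list of class `graph_stats`: `n_species_nodes`,
#'   `n_reaction_nodes`, `n_nodes` (their sum), `n_edges`, and
#'   `per_category` (named association/dissociation/transformation rule
#'   counts). The edge count always satisfies
#'   `n_edges = 3 * (A + D) + 2 * T`.
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "reaction_graph"))
  kind <- graph$nodes$kind
  per_cat <- vapply(rule_categories(), function(cat)
    sum(graph$nodes$category == cat, na.rm = TRUE), 0L)
  structure(list(
    n_species_nodes = sum(kind == "species"),
    n_reaction_nodes = sum(kind == "reaction"),
    n_nodes = nrow(graph$nodes),
    n_edges = nrow(graph$edges),
    per_category = per_cat), class = "graph_stats")
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "nodes: %d (%d species + %d reactions)\nedges: %d\n",
    "rules: %d association, %d dissociation, %d transformation\n"),
    x$n_nodes, x$n_species_nodes, x$n_reaction_nodes, x$n_edges,
    x$per_category[["association"]], x$per_category[["dissociation"]],
    x$per_category[["transformation"]]))
  invisible(x)
}

#' Reactions a complex participates in
#'
#' @param model the model the graph was built from.
#' @param graph the `reaction_graph`.
#' @param complex_ref `c(species = ..., complex = ...)` (or a length-2
#'   character vector species, complex).
#' @return character vector of rule names, in model order.
#' @export
#' @examples
#' m <- gprotein_model()
#' g <- build_network_graph(m)
#' reactions_of_complex(m, g, c("Receptor", "Rec inactive"))
reactions_of_complex <- function(model, graph, complex_ref) {
  complex_ref <- as.character(unlist(complex_ref, use.names = FALSE))
  stopifnot(length(complex_ref) == 2L)
  model_complex(model, complex_ref[1], complex_ref[2])  # lookup error if absent
  hit <- vapply(model$rules, function(r) {
    refs <- rbind(r$reactants, r$products)
    any(refs$species == complex_ref[1] & refs$complex == complex_ref[2])
  }, logical(1))
  names(model$rules)[hit]
}

#' Edges anchored at a binding site
#'
#' Returns, in stable insertion order, every edge whose anchor resolves to
#' the same molecular site (molecule, component, site name) as the given
#' reference. Because a bond's product-side anchor is the product species'
#' copy of the reactant site, querying a reactant-species site returns
#' both sides of the bond's edges. Transformation edges anchor at node
#' centers and are never returned.
#'
#' @param graph a `reaction_graph`.
#' @param site a [binding_site_ref()]; the species and index must exist in
#'   the graph.
#' @return the matching rows of `graph$edges`.
#' @export
edges_at_site <- function(graph, site) {
  stopifnot(inherits(graph, "reaction_graph"),
            inherits(site, "binding_site_ref"))
  tab <- graph$site_tables[[site$species_name]]
  if (is.null(tab))
    stop(sprintf("unknown species '%s'", site$species_name), call. = FALSE)
  row <- tab[tab$site_index == site$site_index, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("species '%s' has no site with index %d",
                 site$species_name, site$site_index), call. = FALSE)
  e <- graph$edges
  keep <- !is.na(e$anchor_site) &
    e$anchor_molecule == row$molecule &
    e$anchor_component == row$component &
    e$anchor_site_name == row$site_name
  e[keep, , drop = FALSE]
}
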