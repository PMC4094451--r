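# Filtering, tri-state pattern search and selection semantics. These
# operations compute the data behind highlighting: which entities match a
# filter, which rules/edges a selection lights up, and which complex each
# species node should display in detail.

#' Highlight states
#' @return `c("match", "child_match", "none")`. `child_match` applies only
#'   to species whose own name misses a name filter while some child
#'   complex matches (rendered light blue); `match` is rendered yellow.
#' @export
highlight_states <- function() c("match", "child_match", "none")

highlight_frame <- function(model) {
  rows <- list()
  for (sp in model$species) {
    rows[[length(rows) + 1L]] <- data.frame(
      entity = "species", species = sp$name, complex = NA_character_,
      stringsAsFactors = FALSE)
    for (cx in sp$complexes)
      rows[[length(rows) + 1L]] <- data.frame(
        entity = "complex", species = sp$name, complex = cx$name,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entity = character(), species = character(),
               complex = character(), stringsAsFactors = FALSE)
  out$highlight <- rep("none", nrow(out))
  out
}

#' Filter species and complexes by name
#'
#' Case-insensitive substring test on entity names. A species whose own
#' name contains the term is a `match`; a species whose name does not but
#' that has a matching child complex is a `child_match`; complexes are
#' `match` or `none`.
#'
#' @param model a [reaction_model()].
#' @param term non-empty search string (no regular expressions).
#' @return data frame with columns `entity` (`"species"`/`"complex"`),
#'   `species`, `complex` (`NA` for species rows) and `highlight`.
#' @export
#' @examples
#' f <- filter_by_name(gprotein_model(), "gdp")
#' subset(f, highlight != "none")
filter_by_name <- function(model, term) {
  stopifnot(inherits(model, "reaction_model"))
  if (!is.character(term) || length(term) != 1L || !nzchar(term))
    stop("filter term must be a non-empty string", call. = FALSE)
  out <- highlight_frame(model)
  hit <- function(name) grepl(tolower(term), tolower(name), fixed = TRUE)
  is_cx <- out$entity == "complex"
  out$highlight[is_cx & vapply(out$complex, function(n)
    !is.na(n) && hit(n), logical(1))] <- "match"
  for (i in which(!is_cx)) {
    if (hit(out$species[i])) {
      out$highlight[i] <- "match"
    } else if (any(is_cx & out$species == out$species[i] &
                   out$highlight == "match")) {
      out$highlight[i] <- "child_match"
    }
  }
  out
}

#' Filter species and complexes by contained molecule
#'
#' Molecule containment is structural, so it is hereditary: every complex
#' shares its species' answer, and `child_match` never occurs. An unknown
#' molecule name highlights nothing.
#'
#' @param model a [reaction_model()].
#' @param molecule_name molecule name (case-sensitive, like all model
#'   cross-references).
#' @return data frame as in [filter_by_name()].
#' @export
filter_by_molecule <- function(model, molecule_name) {
  stopifnot(inherits(model, "reaction_model"))
  out <- highlight_frame(model)
  for (sp in model$species) {
    if (species_contains_molecule(sp, molecule_name))
      out$highlight[out$species == sp$name] <- "match"
  }
  out
}

#' Tri-state search pattern over one species' complexes
#'
#' @param species_name the species whose complexes are searched.
#' @param constraints named tri-state vector; names are
#'   `"instance_id/component/state_variable"` keys. Variables not listed
#'   are unconstrained (`"dont_care"`), mirroring untouched state squares
#'   in an interactive search.
#' @return an object of class `state_pattern`.
#' @export
#' @examples
#' state_pattern("Receptor", c("rec/intracellular/active" = "off"))
state_pattern <- function(species_name, constraints = character()) {
  stopifnot(is.character(species_name), length(species_name) == 1L)
  constraints <- unlist(constraints)
  if (length(constraints)) {
    stopifnot(!is.null(names(constraints)),
              all(vapply(constraints, is_tri_state, logical(1))))
  }
  structure(list(species_name = species_name,
                 constraints = constraints), class = "state_pattern")
}

#' Match a complex against a tri-state pattern
#'
#' A complex matches when every constrained state variable overlaps the
#' pattern's value: equal values match, and `"dont_care"` on either side
#' (an unconstrained query square, or a stored rule-pattern complex)
#' matches anything.
#'
#' @param pattern a [state_pattern()].
#' @param complex a [species_complex()] of the same species.
#' @param model the model declaring the species (used to check that
#'   constrained variables exist).
#' @return `TRUE` or `FALSE`.
#' @export
match_state_pattern <- function(pattern, complex, model = NULL) {
  stopifnot(inherits(pattern, "state_pattern"),
            inherits(complex, "species_complex"))
  if (!is.null(model)) {
    decl <- species_state_table(model, pattern$species_name)
    decl_keys <- state_key(decl$instance_id, decl$component,
                           decl$state_variable)
    bad <- setdiff(names(pattern$constraints), decl_keys)
    if (length(bad))
      stop(sprintf("pattern constrains unknown state variable(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  got <- complex_state_vector(complex)
  for (k in names(pattern$constraints)) {
    stored <- got[[k]]
    if (is.null(stored))
      stop(sprintf("complex '%s' does not carry state variable '%s'",
                   complex$name, k), call. = FALSE)
    if (!tri_match(pattern$constraints[[k]], stored)) return(FALSE)
  }
  TRUE
}

new_selection <- function(highlighted_rules = character(),
                          highlighted_edges = character(),
                          overlays = list(), searched_species = NULL,
                          matching_complexes = character()) {
  structure(list(highlighted_rules = highlighted_rules,
                 highlighted_edges = highlighted_edges,
                 overlays = overlays, searched_species = searched_species,
                 matching_complexes = matching_complexes),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection: %d rule(s), %d edge(s), %d overlay(s)%s>\n",
              length(x$highlighted_rules), length(x$highlighted_edges),
              length(x$overlays),
              if (is.null(x$searched_species)) ""
              else sprintf(", searched '%s'", x$searched_species)))
  invisible(x)
}

rule_edge_ids <- function(graph, rule_names) {
  graph$edges$id[graph$edges$rule %in% rule_names]
}

#' Search a species for complexes matching a state pattern
#'
#' Finds every complex of the pattern's species that matches, then
#' highlights every rule having one of those complexes as reactant or
#' product, plus all edges incident to those rules. The searched species
#' is recorded for its red-border rendering.
#'
#' @param model a [reaction_model()].
#' @param graph its `reaction_graph`.
#' @param pattern a [state_pattern()].
#' @return a `selection_result`; `matching_complexes` holds the matching
#'   complex names.
#' @export
#' @examples
#' m <- gprotein_model(); g <- build_network_graph(m)
#' p <- state_pattern("Receptor", c("rec/intracellular/active" = "off"))
#' search_species(m, g, p)$matching_complexes
search_species <- function(model, graph, pattern) {
  stopifnot(inherits(pattern, "state_pattern"))
  sp <- model_species(model, pattern$species_name)
  matches <- vapply(sp$complexes, function(cx)
    match_state_pattern(pattern, cx, model), logical(1))
  match_names <- vapply(sp$complexes, `[[`, "", "name")[matches]
  hit <- vapply(model$rules, function(r) {
    refs <- rbind(r$reactants, r$products)
    any(refs$species == sp$name & refs$complex %in% match_names)
  }, logical(1))
  rules <- names(model$rules)[hit]
  new_selection(highlighted_rules = rules,
                highlighted_edges = rule_edge_ids(graph, rules),
                searched_species = sp$name,
                matching_complexes = match_names)
}

#' Select a reaction for detail display
#'
#' For an association or dissociation, every involved species node is
#' overlaid with its rule-side complex (reactant complexes on reactant
#' species, the product complex on product species), including the bond
#' status at the rule's bond sites. For a transformation, the overlay is
#' a detached before/after complex pair for side-panel rendering. All of
#' the rule's edges are highlighted.
#'
#' @param model a [reaction_model()].
#' @param graph its `reaction_graph`.
#' @param rule_name name of a rule in the model.
#' @return a `selection_result`; `overlays` is a list keyed by species
#'   node id with entries `list(species, complex, role)` (association /
#'   dissociation) or a single `list(species, before, after)` entry
#'   (transformation).
#' @export
select_reaction <- function(model, graph, rule_name) {
  rule <- model_rule(model, rule_name)
  overlays <- list()
  if (rule$category == "transformation") {
    sp <- rule$reactants$species[1]
    overlays[[species_node_id(sp)]] <- list(
      species = sp, before = rule$reactants$complex[1],
      after = rule$products$complex[1], role = "transformation")
  } else {
    for (role in c("reactant", "product")) {
      side <- if (role == "reactant") rule$reactants else rule$products
      for (i in seq_len(nrow(side))) {
        # bond status at the rule's bond sites: shown as bound in the
        # selected view (an association links its previously-unbound sites)
        rule_sites <- integer()
        if (!is.null(rule$bond_sites))
          rule_sites <- vapply(
            Filter(function(b) b$species_name == side$species[i],
                   rule$bond_sites),
            `[[`, 0L, "site_index")
        overlays[[species_node_id(side$species[i])]] <- list(
          species = side$species[i], complex = side$complex[i], role = role,
          rule_sites = rule_sites)
      }
    }
  }
  new_selection(highlighted_rules = rule$name,
                highlighted_edges = rule_edge_ids(graph, rule$name),
                overlays = overlays)
}

#' Select a complex: highlight the reactions it participates in
#'
#' @inheritParams reactions_of_complex
#' @return a `selection_result` with the complex's rules and their
#'   incident edges highlighted, and no overlays.
#' @export
#' @examples
#' m <- gprotein_model(); g <- build_network_graph(m)
#' select_complex(m, g, c("Receptor", "Rec inactive"))$highlighted_rules
select_complex <- function(model, graph, complex_ref) {
  rules <- reactions_of_complex(model, graph, complex_ref)
  new_selection(highlighted_rules = rules,
                highlighted_edges = rule_edge_ids(graph, rules))
}

#' Rules grouped by category
#'
#' @param model a [reaction_model()].
#' @return named list `association` / `dissociation` / `transformation`,
#'   each a character vector of rule names in stable model order; the
#'   three groups partition the rule set.
#' @export
reactions_by_category <- function(model) {
  stopifnot(inherits(model, "reaction_model"))
  cats <- vapply(model$rules, `[[`, "", "category")
  out <- lapply(stats::setNames(nm = rule_categories()), function(cat)
    unname(names(model$rules)[cats == cat]))
  out
}
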