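# S3 constructors for the rule-based model domain. Constructors do cheap
# argument checking only; whole-model consistency lives in validate_model().

radix_sort <- function(x) sort(x, method = "radix")

#' Molecule component
#'
#' A component (sub-domain) of a molecule, carrying ordered state variables
#' (drawn as squares) and ordered binding sites (drawn as indexed circles).
#'
#' @param name component name, unique within its molecule.
#' @param state_variables character vector of state-variable names (may be
#'   empty); unique within the component.
#' @param binding_sites character vector of binding-site names (may be
#'   empty). Site *indices* are not assigned here: they are 1-based per
#'   complex species, in declaration order across the species' molecule
#'   instances and components (see [species_site_table()]).
#' @return an object of class `mol_component`.
#' @export
#' @examples
#' mol_component("intracellular", state_variables = "active",
#'               binding_sites = "gprotein")
mol_component <- function(name, state_variables = character(),
                          binding_sites = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(name = name,
         state_variables = as.character(state_variables),
         binding_sites = as.character(binding_sites)),
    class = "mol_component")
}

#' Molecule
#'
#' @param name molecule name, unique within the model.
#' @param components list of [mol_component()] objects, in declaration order.
#' @return an object of class `molecule`.
#' @export
molecule <- function(name, components = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(all(vapply(components, inherits, logical(1), "mol_component")))
  structure(list(name = name, components = components), class = "molecule")
}

#' Reference to a binding site within a complex species
#'
#' Sites are addressed by their 1-based index within the species (assigned
#' in declaration order across the species' molecule instances and their
#' components), matching the indices displayed inside site circles.
#'
#' @param species_name name of the complex species the site belongs to.
#' @param site_index positive integer site index within that species.
#' @return an object of class `binding_site_ref`.
#' @export
binding_site_ref <- function(species_name, site_index) {
  stopifnot(is.character(species_name), length(species_name) == 1L)
  site_index <- as.integer(site_index)
  stopifnot(length(site_index) == 1L, !is.na(site_index), site_index >= 1L)
  structure(list(species_name = species_name, site_index = site_index),
            class = "binding_site_ref")
}

#' Complex: a state-specific instance of a complex species
#'
#' A complex assigns a tri-state value to every state variable declared by
#' its species' molecules (a total state map). Complexes referenced by
#' reaction rules are patterns and may use `"dont_care"`.
#'
#' @param name complex name, unique within its species.
#' @param states either a data frame with columns `instance_id`,
#'   `component`, `state_variable`, `value`, or a named character vector
#'   whose names are `"instance_id/component/state_variable"` keys.
#' @return an object of class `species_complex`; `states` is stored as a
#'   data frame.
#' @export
#' @examples
#' species_complex("Rec inactive", c("rec/intracellular/active" = "off"))
species_complex <- function(name, states = data.frame()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.character(states)) {
    if (length(states) == 0L) {
      states <- data.frame(instance_id = character(), component = character(),
                           state_variable = character(), value = character(),
                           stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(names(states), "/", fixed = TRUE)
      stopifnot(all(lengths(parts) == 3L))
      states <- data.frame(
        instance_id = vapply(parts, `[`, "", 1L),
        component = vapply(parts, `[`, "", 2L),
        state_variable = vapply(parts, `[`, "", 3L),
        value = unname(states), stringsAsFactors = FALSE)
    }
  }
  stopifnot(is.data.frame(states))
  if (nrow(states) == 0L) {
    states <- data.frame(instance_id = character(), component = character(),
                         state_variable = character(), value = character(),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("instance_id", "component", "state_variable", "value")
                %in% names(states)))
  states <- states[, c("instance_id", "component", "state_variable", "value")]
  rownames(states) <- NULL
  structure(list(name = name, states = states), class = "species_complex")
}

#' Complex species: a structural prototype and its declared complexes
#'
#' A complex species fixes the molecular composition and bond topology; its
#' complexes differ only in component states. Complexes are explicitly
#' declared (a curated list), not enumerated combinatorially.
#'
#' @param name species name, unique within the model.
#' @param molecule_instances data frame with columns `instance_id`,
#'   `molecule` (ordered), or a named character vector
#'   `c(instance_id = molecule_name, ...)`.
#' @param structural_bonds list of length-2 integer vectors of species site
#'   indices; each unordered pair is stored sorted, and the set of pairs is
#'   stored sorted. A site may take part in at most one bond.
#' @param complexes list of [species_complex()] objects; stored sorted by
#'   name.
#' @return an object of class `complex_species`.
#' @export
complex_species <- function(name, molecule_instances,
                            structural_bonds = list(), complexes = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.character(molecule_instances) && !is.null(names(molecule_instances))) {
    molecule_instances <- data.frame(
      instance_id = names(molecule_instances),
      molecule = unname(molecule_instances), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(molecule_instances),
            all(c("instance_id", "molecule") %in% names(molecule_instances)))
  molecule_instances <-
    molecule_instances[, c("instance_id", "molecule"), drop = FALSE]
  rownames(molecule_instances) <- NULL
  bonds <- lapply(structural_bonds, function(b) sort(as.integer(b)))
  stopifnot(all(lengths(bonds) == 2L))
  if (length(bonds) > 1L) {
    key <- vapply(bonds, function(b) sprintf("%09d-%09d", b[1], b[2]), "")
    bonds <- bonds[order(key)]
  }
  stopifnot(all(vapply(complexes, inherits, logical(1), "species_complex")))
  if (length(complexes) > 1L) {
    complexes <- complexes[order(vapply(complexes, `[[`, "", "name"),
                                 method = "radix")]
  }
  structure(
    list(name = name, molecule_instances = molecule_instances,
         structural_bonds = bonds, complexes = complexes),
    class = "complex_species")
}

#' Rule categories
#' @return character vector `c("association", "dissociation", "transformation")`.
#' @export
rule_categories <- function() c("association", "dissociation", "transformation")

#' Reaction rule
#'
#' A categorized rewrite of complexes. Associations take two reactant
#' complexes and produce one (forming a bond); dissociations take one and
#' produce two (dissolving a bond); transformations take one and produce
#' one, changing only component states and therefore never involving
#' binding sites.
#'
#' @param name rule name, unique within the model.
#' @param category one of [rule_categories()].
#' @param reactants,products data frames with columns `species`, `complex`
#'   (ordered), or character vectors `c(species = complex, ...)`.
#' @param bond_sites optional list of two [binding_site_ref()]s: for an
#'   association, one site per reactant species (the sites that become
#'   bonded); for a dissociation, the two sites of the reactant species
#'   whose bond is dissolved; must be absent for a transformation.
#' @param rate_constant single non-negative number; stored for reporting
#'   (edge tool-tips), never integrated.
#' @return an object of class `reaction_rule`.
#' @export
reaction_rule <- function(name, category, reactants, products,
                          bond_sites = NULL, rate_constant = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(category), length(category) == 1L)
  as_pairs <- function(x) {
    if (is.character(x) && !is.null(names(x))) {
      x <- data.frame(species = names(x), complex = unname(x),
                      stringsAsFactors = FALSE)
    }
    stopifnot(is.data.frame(x), all(c("species", "complex") %in% names(x)))
    x <- x[, c("species", "complex"), drop = FALSE]
    rownames(x) <- NULL
    x
  }
  if (!is.null(bond_sites)) {
    stopifnot(is.list(bond_sites),
              all(vapply(bond_sites, inherits, logical(1), "binding_site_ref")))
  }
  stopifnot(is.numeric(rate_constant), length(rate_constant) == 1L)
  structure(
    list(name = name, category = category,
         reactants = as_pairs(reactants), products = as_pairs(products),
         bond_sites = bond_sites, rate_constant = as.numeric(rate_constant)),
    class = "reaction_rule")
}

#' Rule-based model container
#'
#' Holds molecules, complex species and reaction rules. Entity lists are
#' normalized to C-locale name order at construction, which makes
#' serialization canonical: two constructions of the same content in
#' different insertion orders are identical models.
#'
#' @param molecules list of [molecule()]s.
#' @param species list of [complex_species()].
#' @param rules list of [reaction_rule()]s.
#' @param metadata free-form named list.
#' @param format_version model document format version string.
#' @return an object of class `reaction_model`.
#' @seealso [validate_model()], [parse_model()], [serialize_model()]
#' @export
reaction_model <- function(molecules = list(), species = list(),
                           rules = list(), metadata = list(),
                           format_version = "1.0") {
  stopifnot(all(vapply(molecules, inherits, logical(1), "molecule")),
            all(vapply(species, inherits, logical(1), "complex_species")),
            all(vapply(rules, inherits, logical(1), "reaction_rule")))
  by_name <- function(xs) {
    if (length(xs) > 1L)
      xs <- xs[order(vapply(xs, `[[`, "", "name"), method = "radix")]
    names(xs) <- vapply(xs, `[[`, "", "name")
    xs
  }
  structure(
    list(format_version = as.character(format_version),
         molecules = by_name(molecules), species = by_name(species),
         rules = by_name(rules), metadata = metadata),
    class = "reaction_model")
}

#' @export
print.reaction_model <- function(x, ...) {
  cat(sprintf("<reaction_model v%s: %d molecules, %d species, %d rules>\n",
              x$format_version, length(x$molecules), length(x$species),
              length(x$rules)))
  invisible(x)
}

#' @export
print.reaction_rule <- function(x, ...) {
  side <- function(p) paste(sprintf("%s:%s", p$species, p$complex),
                            collapse = " + ")
  cat(sprintf("<%s rule '%s': %s -> %s>\n", x$category, x$name,
              side(x$reactants), side(x$products)))
  invisible(x)
}

model_rule <- function(model, rule_name) {
  r <- model$rules[[rule_name]]
  if (is.null(r)) stop(sprintf("unknown rule '%s'", rule_name), call. = FALSE)
  r
}

model_species <- function(model, species_name) {
  s <- model$species[[species_name]]
  if (is.null(s))
    stop(sprintf("unknown species '%s'", species_name), call. = FALSE)
  s
}

model_complex <- function(model, species_name, complex_name) {
  s <- model_species(model, species_name)
  idx <- match(complex_name, vapply(s$complexes, `[[`, "", "name"))
  if (is.na(idx))
    stop(sprintf("unknown complex '%s' in species '%s'",
                 complex_name, species_name), call. = FALSE)
  s$complexes[[idx]]
}
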