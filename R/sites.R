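#' Binding-site table of a complex species
#'
#' Assigns the species' 1-based site indices: sites are numbered in
#' declaration order across the species' molecule instances, each
#' instance's components, and each component's binding sites. These are
#' the indices displayed inside site circles and referenced by
#' [binding_site_ref()].
#'
#' @param model a [reaction_model()].
#' @param species_name name of a species in `model`.
#' @return data frame with one row per site: `site_index`, `instance_id`,
#'   `molecule`, `component`, `site_name`, and `bonded` (whether the site
#'   takes part in one of the species' structural bonds).
#' @export
#' @examples
#' m <- gprotein_model()
#' species_site_table(m, "Receptor")
species_site_table <- function(model, species_name) {
  sp <- model_species(model, species_name)
  rows <- list()
  for (i in seq_len(nrow(sp$molecule_instances))) {
    inst <- sp$molecule_instances$instance_id[i]
    mol_name <- sp$molecule_instances$molecule[i]
    mol <- model$molecules[[mol_name]]
    if (is.null(mol)) next  # dangling reference; validate_model reports it
    for (comp in mol$components) {
      for (site in comp$binding_sites) {
        rows[[length(rows) + 1L]] <- data.frame(
          instance_id = inst, molecule = mol_name, component = comp$name,
          site_name = site, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(instance_id = character(), molecule = character(),
               component = character(), site_name = character(),
               stringsAsFactors = FALSE)
  tab <- cbind(site_index = seq_len(nrow(tab)), tab)
  bonded_idx <- unlist(sp$structural_bonds)
  tab$bonded <- tab$site_index %in% bonded_idx
  rownames(tab) <- NULL
  tab
}

#' State-variable table of a complex species
#'
#' Enumerates every state variable declared by the species' molecules, in
#' declaration order. A complex of the species must assign a tri-state
#' value to exactly this set (its state map is total).
#'
#' @inheritParams species_site_table
#' @return data frame with columns `instance_id`, `molecule`, `component`,
#'   `state_variable`.
#' @export
species_state_table <- function(model, species_name) {
  sp <- model_species(model, species_name)
  rows <- list()
  for (i in seq_len(nrow(sp$molecule_instances))) {
    inst <- sp$molecule_instances$instance_id[i]
    mol_name <- sp$molecule_instances$molecule[i]
    mol <- model$molecules[[mol_name]]
    if (is.null(mol)) next
    for (comp in mol$components) {
      for (sv in comp$state_variables) {
        rows[[length(rows) + 1L]] <- data.frame(
          instance_id = inst, molecule = mol_name, component = comp$name,
          state_variable = sv, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    tab
  } else {
    data.frame(instance_id = character(), molecule = character(),
               component = character(), state_variable = character(),
               stringsAsFactors = FALSE)
  }
}

state_key <- function(instance_id, component, state_variable) {
  paste(instance_id, component, state_variable, sep = "/")
}

# Named tri-state vector keyed "instance/component/variable".
complex_state_vector <- function(cx) {
  st <- cx$states
  stats::setNames(st$value,
                  state_key(st$instance_id, st$component, st$state_variable))
}

#' Does a species (and hence each of its complexes) contain a molecule?
#'
#' Molecule containment is structural and hereditary: a complex contains a
#' molecule exactly when its species does, because all complexes of a
#' species share the species' molecular composition.
#'
#' @param species a [complex_species()] object.
#' @param molecule_name molecule name; an unknown name simply yields `FALSE`.
#' @return `TRUE` or `FALSE`.
#' @export
species_contains_molecule <- function(species, molecule_name) {
  stopifnot(inherits(species, "complex_species"))
  molecule_name %in% species$molecule_instances$molecule
}
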