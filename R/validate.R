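# Whole-model validation. Violations are data, not exceptions: every
# invariant breach in the model is reported, not just the first.

violation_row <- function(code, path, message, severity = "error") {
  data.frame(code = code, severity = severity, path = path, message = message,
             stringsAsFactors = FALSE)
}

empty_violations <- function() {
  data.frame(code = character(), severity = character(), path = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate a rule-based model
#'
#' Checks every model invariant: name uniqueness at each scope, resolvable
#' cross-references, bond-site index ranges and single-bond-per-site,
#' totality of complex state maps, legal tri-state values, rule category
#' arities (association 2 to 1, dissociation 1 to 2, transformation 1 to 1),
#' absence of bond sites on transformations, and non-negative rate
#' constants. Two complexes of one species with identical state maps are
#' flagged as a warning (`DUP_COMPLEX_STATES`), not an error.
#'
#' @param model a [reaction_model()].
#' @return data frame of violations with columns `code`, `severity`
#'   (`"error"` or `"warning"`), `path` (JSON-pointer-style location) and
#'   `message`; zero rows iff the model is valid (warnings aside).
#' @export
#' @examples
#' validate_model(egfr_model())
validate_model <- function(model) {
  stopifnot(inherits(model, "reaction_model"))
  v <- list()
  add <- function(code, path, message, severity = "error")
    v[[length(v) + 1L]] <<- violation_row(code, path, message, severity)

  dup_check <- function(nms, code, path_fmt) {
    for (d in unique(nms[duplicated(nms)]))
      add(code, sprintf(path_fmt, d), sprintf("duplicate name '%s'", d))
  }
  dup_check(vapply(model$molecules, `[[`, "", "name"), "DUP_MOLECULE",
            "/molecules/%s")
  dup_check(vapply(model$species, `[[`, "", "name"), "DUP_SPECIES",
            "/species/%s")
  dup_check(vapply(model$rules, `[[`, "", "name"), "DUP_RULE", "/rules/%s")

  for (mol in model$molecules) {
    mpath <- sprintf("/molecules/%s", mol$name)
    comp_names <- vapply(mol$components, `[[`, "", "name")
    dup_check(comp_names, "DUP_COMPONENT", paste0(mpath, "/components/%s"))
    for (comp in mol$components) {
      dup_check(comp$state_variables, "DUP_STATE_VAR",
                paste0(mpath, "/components/", comp$name, "/state_variables/%s"))
      dup_check(comp$binding_sites, "DUP_SITE",
                paste0(mpath, "/components/", comp$name, "/binding_sites/%s"))
    }
  }

  for (sp in model$species) {
    spath <- sprintf("/species/%s", sp$name)
    dup_check(sp$molecule_instances$instance_id, "DUP_INSTANCE",
              paste0(spath, "/molecule_instances/%s"))
    missing_mol <- setdiff(sp$molecule_instances$molecule,
                           names(model$molecules))
    for (m in missing_mol)
      add("UNKNOWN_MOLECULE", spath,
          sprintf("molecule '%s' is not declared in the model", m))
    if (length(missing_mol) == 0L) {
      sites <- species_site_table(model, sp$name)
      n_sites <- nrow(sites)
      all_bond_idx <- unlist(sp$structural_bonds)
      for (b in sp$structural_bonds) {
        if (any(b < 1L | b > n_sites))
          add("BOND_SITE_RANGE", paste0(spath, "/structural_bonds"),
              sprintf("bond (%d,%d) references a site index beyond the %d sites of '%s'",
                      b[1], b[2], n_sites, sp$name))
        if (b[1] == b[2])
          add("BOND_SELF", paste0(spath, "/structural_bonds"),
              sprintf("bond joins site %d to itself", b[1]))
      }
      for (idx in unique(all_bond_idx[duplicated(all_bond_idx)]))
        add("BOND_SITE_REUSED", paste0(spath, "/structural_bonds"),
            sprintf("site %d appears in more than one bond", idx))

      decl <- species_state_table(model, sp$name)
      decl_keys <- state_key(decl$instance_id, decl$component,
                             decl$state_variable)
      cx_names <- vapply(sp$complexes, `[[`, "", "name")
      dup_check(cx_names, "DUP_COMPLEX", paste0(spath, "/complexes/%s"))
      seen_state_sigs <- character()
      for (cx in sp$complexes) {
        cpath <- paste0(spath, "/complexes/", cx$name)
        got <- complex_state_vector(cx)
        for (k in setdiff(decl_keys, names(got)))
          add("STATE_COVERAGE", cpath,
              sprintf("state map omits declared state variable '%s'", k))
        for (k in setdiff(names(got), decl_keys))
          add("STATE_UNKNOWN", cpath,
              sprintf("state map assigns undeclared state variable '%s'", k))
        for (k in names(got))
          if (!is_tri_state(got[[k]]))
            add("BAD_TRISTATE", cpath,
                sprintf("'%s' has illegal value '%s'", k, got[[k]]))
        sig <- paste(radix_sort(paste0(names(got), "=", got)), collapse = ";")
        if (sig %in% seen_state_sigs && length(got) > 0L)
          add("DUP_COMPLEX_STATES", cpath,
              sprintf("complex '%s' duplicates the state map of an earlier complex",
                      cx$name),
              severity = "warning")
        seen_state_sigs <- c(seen_state_sigs, sig)
      }
    }
  }

  arity <- list(association = c(2L, 1L), dissociation = c(1L, 2L),
                transformation = c(1L, 1L))
  for (rule in model$rules) {
    rpath <- sprintf("/rules/%s", rule$name)
    if (!rule$category %in% rule_categories()) {
      add("BAD_CATEGORY", rpath,
          sprintf("unknown category '%s'", rule$category))
      next
    }
    want <- arity[[rule$category]]
    if (nrow(rule$reactants) != want[1] || nrow(rule$products) != want[2])
      add("ARITY", rpath,
          sprintf("%s rule must have %d reactant(s) and %d product(s), found %d/%d",
                  rule$category, want[1], want[2],
                  nrow(rule$reactants), nrow(rule$products)))
    if (rule$category == "transformation" && !is.null(rule$bond_sites))
      add("BOND_ON_TRANSFORM", rpath,
          "transformations do not involve binding sites; bond_sites must be absent")
    refs <- rbind(rule$reactants, rule$products)
    for (i in seq_len(nrow(refs))) {
      spn <- refs$species[i]
      cxn <- refs$complex[i]
      if (!spn %in% names(model$species)) {
        add("UNKNOWN_SPECIES", rpath,
            sprintf("species '%s' is not declared", spn))
      } else {
        sp <- model$species[[spn]]
        if (!cxn %in% vapply(sp$complexes, `[[`, "", "name"))
          add("UNKNOWN_COMPLEX", rpath,
              sprintf("complex '%s' is not declared in species '%s'",
                      cxn, spn))
      }
    }
    if (!is.null(rule$bond_sites) && rule$category != "transformation") {
      if (length(rule$bond_sites) != 2L) {
        add("BOND_COUNT", rpath, "bond_sites must name exactly two sites")
      } else {
        ref_species <- vapply(rule$bond_sites, `[[`, "", "species_name")
        legal <- if (rule$category == "association")
          identical(radix_sort(ref_species), radix_sort(rule$reactants$species))
        else all(ref_species == rule$reactants$species[1])
        if (!legal)
          add("BOND_SPECIES_MISMATCH", rpath,
              sprintf("bond_sites name species (%s) inconsistent with reactants (%s)",
                      paste(ref_species, collapse = ", "),
                      paste(rule$reactants$species, collapse = ", ")))
        for (bs in rule$bond_sites) {
          if (bs$species_name %in% names(model$species)) {
            sp <- model$species[[bs$species_name]]
            ok_mols <- all(sp$molecule_instances$molecule %in%
                             names(model$molecules))
            if (ok_mols) {
              n_sites <- nrow(species_site_table(model, bs$species_name))
              if (bs$site_index > n_sites)
                add("BOND_SITE_RANGE", rpath,
                    sprintf("site index %d exceeds the %d sites of species '%s'",
                            bs$site_index, n_sites, bs$species_name))
            }
          }
        }
      }
    }
    if (is.na(rule$rate_constant) || rule$rate_constant < 0)
      add("RATE_NEGATIVE", rpath, "rate constant must be a non-negative number")
  }

  if (length(v)) do.call(rbind, v) else empty_violations()
}

#' Stop unless a model validates cleanly
#'
#' @param model a [reaction_model()].
#' @return the model, invisibly; otherwise an error whose message aggregates
#'   every error-severity violation.
#' @export
assert_valid_model <- function(model) {
  viol <- validate_model(model)
  viol <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(viol) > 0L) {
    stop(sprintf("invalid model (%d violation%s):\n%s", nrow(viol),
                 if (nrow(viol) == 1L) "" else "s",
                 paste(sprintf("  [%s] %s: %s", viol$code, viol$path,
                               viol$message), collapse = "\n")),
         call. = FALSE)
  }
  invisible(model)
}
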