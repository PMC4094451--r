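# Reference models built programmatically: an EGFR adaptor-binding model,
# a heterotrimeric G-protein signaling model, and a seeded random-model
# generator for property tests.

#' EGFR adaptor-binding model
#'
#' A rule-based model of adaptor binding to the phosphorylated EGFR
#' cytoplasmic domain. The domain carries five binding sites; sites 1-4
#' are the phosphotyrosines pY992, pY1068, pY1148 and pY1173 (site 5 is an
#' unused membrane anchor). Stat5 binds pY992 and Grb2 binds pY1068,
#' unconditionally. PLCgamma1 binds pY992 or pY1173, and Shc binds pY1148
#' or pY1173, under mutual-exclusion constraints expressed through three
#' EGFR state variables: `bndPLCg992` and `bndPLCg1173` record a bound
#' PLCgamma1 (either blocks the other PLCgamma1 site), and `bndSHC1148`
#' records a bound Shc at pY1148 (mutually exclusive with PLCgamma1 at
#' pY1173). The model has 11 complex species (5 unbound, 6 bound) and 6
#' association rules, one per binding possibility.
#'
#' @return a validated [reaction_model()].
#' @export
#' @examples
#' m <- egfr_model()
#' length(m$species)
#' graph_stats(build_network_graph(m))
egfr_model <- function() {
  egfr_states <- c("bndPLCg992", "bndPLCg1173", "bndSHC1148")
  molecules <- list(
    molecule("EGFR", list(mol_component(
      "cytoplasmic",
      state_variables = egfr_states,
      binding_sites = c("pY992", "pY1068", "pY1148", "pY1173", "anchor")))),
    molecule("Grb2", list(mol_component("SH2", binding_sites = "sh2"))),
    molecule("PLCg1", list(mol_component("SH2", binding_sites = "sh2"))),
    molecule("Stat5", list(mol_component("SH2", binding_sites = "sh2"))),
    molecule("Shc", list(mol_component("PTB", binding_sites = "ptb"))))

  egfr_cx <- function(name, v992, v1173, v1148) {
    species_complex(name, stats::setNames(
      c(v992, v1173, v1148),
      state_key("egfr", "cytoplasmic", egfr_states)))
  }
  adaptor_species <- function(mol) {
    inst <- stats::setNames(mol, tolower(mol))
    complex_species(mol, inst, complexes = list(species_complex(mol)))
  }

  site_idx <- c(pY992 = 1L, pY1068 = 2L, pY1148 = 3L, pY1173 = 4L)
  bound_species <- function(adaptor, site, v992, v1173, v1148) {
    name <- sprintf("EGFR_%s_%s", adaptor, site)
    inst <- data.frame(instance_id = c("egfr", tolower(adaptor)),
                       molecule = c("EGFR", adaptor),
                       stringsAsFactors = FALSE)
    complex_species(
      name, inst,
      structural_bonds = list(c(site_idx[[site]], 6L)),  # adaptor site is 6th
      complexes = list(egfr_cx(name, v992, v1173, v1148)))
  }

  species <- list(
    complex_species(
      "EGFR", c(egfr = "EGFR"),
      complexes = list(
        egfr_cx("EGFR unconstrained", "dont_care", "dont_care", "dont_care"),
        egfr_cx("EGFR PLC-free", "off", "off", "dont_care"),
        egfr_cx("EGFR adaptor-free", "off", "off", "off"),
        egfr_cx("EGFR Shc-free", "dont_care", "off", "off"))),
    adaptor_species("Grb2"), adaptor_species("PLCg1"),
    adaptor_species("Stat5"), adaptor_species("Shc"),
    bound_species("Stat5", "pY992", "dont_care", "dont_care", "dont_care"),
    bound_species("Grb2", "pY1068", "dont_care", "dont_care", "dont_care"),
    bound_species("PLCg1", "pY992", "on", "off", "dont_care"),
    bound_species("PLCg1", "pY1173", "off", "on", "off"),
    bound_species("Shc", "pY1148", "dont_care", "off", "on"),
    bound_species("Shc", "pY1173", "dont_care", "dont_care", "dont_care"))

  bind_rule <- function(adaptor, site, egfr_complex) {
    product <- sprintf("EGFR_%s_%s", adaptor, site)
    r <- c(egfr_complex, adaptor)
    names(r) <- c("EGFR", adaptor)
    reaction_rule(
      sprintf("%s binds EGFR %s", adaptor, site), "association",
      reactants = r,
      products = stats::setNames(product, product),
      bond_sites = list(binding_site_ref("EGFR", site_idx[[site]]),
                        binding_site_ref(adaptor, 1L)),
      rate_constant = 1)
  }
  rules <- list(
    bind_rule("Stat5", "pY992", "EGFR unconstrained"),
    bind_rule("Grb2", "pY1068", "EGFR unconstrained"),
    bind_rule("PLCg1", "pY992", "EGFR PLC-free"),
    bind_rule("PLCg1", "pY1173", "EGFR adaptor-free"),
    bind_rule("Shc", "pY1148", "EGFR Shc-free"),
    bind_rule("Shc", "pY1173", "EGFR unconstrained"))

  reaction_model(molecules, species, rules,
                 metadata = list(fixture = "egfr"))
}

gp_rule_provenance <- function() {
  list(`receptor ligation` = "model-verbatim",
       `ligand dissociation` = "model-verbatim",
       `Receptor mediated Galpha GDP GTP exchange` = "model-verbatim",
       `G-protein receptor coupling` = "fixture-completion",
       `G-protein release` = "fixture-completion",
       `G-protein precoupling release` = "fixture-completion",
       `G-protein trimer dissociation` = "fixture-completion",
       `G-protein trimer reformation` = "fixture-completion",
       `Galpha GTP hydrolysis` = "fixture-completion",
       `receptor desensitization` = "fixture-completion",
       `effector deactivation` = "fixture-completion")
}

#' G-protein receptor signaling model
#'
#' A ligand/receptor/heterotrimeric-G-protein model with 8 complex species
#' and 11 reaction rules (3 associations, 4 dissociations, 4
#' transformations; its bipartite graph therefore has 19 nodes and 29
#' edges). The core rules are receptor ligation (Ligand + Rec inactive ->
#' Ligated Receptor, intracellular activity off -> on), ligand dissociation
#' (the reverse, on -> off) and the receptor-mediated GDP/GTP exchange
#' transformation (LigRec_Gab_GDP -> LigRec_Gabg_GTP). The remaining rules
#' complete a canonical G-protein cycle (receptor/G-protein coupling and
#' release, trimer dissociation into Galpha-GTP and Gbetagamma, trimer
#' reformation, GTP hydrolysis, receptor desensitization, effector
#' deactivation) and are tagged `"fixture-completion"` in
#' `metadata$rule_provenance` to separate them from the core rules.
#'
#' @return a validated [reaction_model()].
#' @export
#' @examples
#' graph_stats(build_network_graph(gprotein_model()))
gprotein_model <- function() {
  molecules <- list(
    molecule("Ligand", list(mol_component("body", binding_sites = "rec"))),
    molecule("Receptor", list(
      mol_component("extracellular", binding_sites = "lig"),
      mol_component("intracellular", state_variables = c("active",
                                                         "desensitized"),
                    binding_sites = "gprot"))),
    molecule("Galpha", list(mol_component("Galpha",
                                          state_variables = "GTP",
                                          binding_sites = c("receptor",
                                                            "gbeta")))),
    molecule("Gbeta", list(mol_component("Gbeta",
                                         binding_sites = c("galpha",
                                                           "ggamma")))),
    molecule("Ggamma", list(mol_component("Ggamma", binding_sites = "gbeta"))),
    molecule("Effector", list(mol_component("catalytic",
                                            state_variables = "active"))))

  rec_cx <- function(name, active, desens) species_complex(
    name, stats::setNames(c(active, desens),
                          state_key("rec", "intracellular",
                                    c("active", "desensitized"))))
  lr_states <- function(active, desens) stats::setNames(
    c(active, desens), state_key("rec", "intracellular",
                                 c("active", "desensitized")))
  lrg_cx <- function(name, gtp) species_complex(
    name, c(lr_states("on", "off"),
            stats::setNames(gtp, state_key("ga", "Galpha", "GTP"))))

  species <- list(
    complex_species("Ligand", c(lig = "Ligand"),
                    complexes = list(species_complex("Ligand"))),
    complex_species("Receptor", c(rec = "Receptor"),
                    complexes = list(
                      rec_cx("Rec inactive", "off", "off"),
                      rec_cx("Receptor_2", "off", "on"),
                      rec_cx("Rec inactive unbound", "off", "dont_care"))),
    complex_species("Ligated Receptor",
                    c(lig = "Ligand", rec = "Receptor"),
                    structural_bonds = list(c(1L, 2L)),
                    complexes = list(species_complex("Ligated Receptor",
                                                     lr_states("on", "off")))),
    complex_species("Gabg",
                    c(ga = "Galpha", gb = "Gbeta", gg = "Ggamma"),
                    structural_bonds = list(c(2L, 3L), c(4L, 5L)),
                    complexes = list(
                      species_complex("Gabg_GDP",
                                      c("ga/Galpha/GTP" = "off")),
                      species_complex("Gabg_GTP",
                                      c("ga/Galpha/GTP" = "on")))),
    complex_species("LigRec_Gabg",
                    c(lig = "Ligand", rec = "Receptor", ga = "Galpha",
                      gb = "Gbeta", gg = "Ggamma"),
                    structural_bonds = list(c(1L, 2L), c(3L, 4L),
                                            c(5L, 6L), c(7L, 8L)),
                    complexes = list(lrg_cx("LigRec_Gab_GDP", "off"),
                                     lrg_cx("LigRec_Gabg_GTP", "on"))),
    complex_species("Galpha", c(ga = "Galpha"),
                    complexes = list(
                      species_complex("Galpha_GTP", c("ga/Galpha/GTP" = "on")),
                      species_complex("Galpha_GDP",
                                      c("ga/Galpha/GTP" = "off")))),
    complex_species("Gbg", c(gb = "Gbeta", gg = "Ggamma"),
                    structural_bonds = list(c(2L, 3L)),
                    complexes = list(species_complex("Gbg"))),
    complex_species("Effector", c(eff = "Effector"),
                    complexes = list(
                      species_complex("Effector active",
                                      c("eff/catalytic/active" = "on")),
                      species_complex("Effector inactive",
                                      c("eff/catalytic/active" = "off")))))

  pair <- function(...) {
    x <- c(...)
    data.frame(species = names(x), complex = unname(x),
               stringsAsFactors = FALSE)
  }
  bsr <- binding_site_ref
  rules <- list(
    reaction_rule("receptor ligation", "association",
                  pair(Ligand = "Ligand", Receptor = "Rec inactive"),
                  pair(`Ligated Receptor` = "Ligated Receptor"),
                  bond_sites = list(bsr("Ligand", 1L), bsr("Receptor", 1L)),
                  rate_constant = 1),
    reaction_rule("ligand dissociation", "dissociation",
                  pair(`Ligated Receptor` = "Ligated Receptor"),
                  pair(Ligand = "Ligand", Receptor = "Rec inactive"),
                  bond_sites = list(bsr("Ligated Receptor", 1L),
                                    bsr("Ligated Receptor", 2L)),
                  rate_constant = 1),
    reaction_rule("Receptor mediated Galpha GDP GTP exchange",
                  "transformation",
                  pair(LigRec_Gabg = "LigRec_Gab_GDP"),
                  pair(LigRec_Gabg = "LigRec_Gabg_GTP"),
                  rate_constant = 1),
    reaction_rule("G-protein receptor coupling", "association",
                  pair(`Ligated Receptor` = "Ligated Receptor",
                       Gabg = "Gabg_GDP"),
                  pair(LigRec_Gabg = "LigRec_Gab_GDP"),
                  bond_sites = list(bsr("Ligated Receptor", 3L),
                                    bsr("Gabg", 1L)),
                  rate_constant = 1),
    reaction_rule("G-protein release", "dissociation",
                  pair(LigRec_Gabg = "LigRec_Gabg_GTP"),
                  pair(`Ligated Receptor` = "Ligated Receptor",
                       Gabg = "Gabg_GTP"),
                  bond_sites = list(bsr("LigRec_Gabg", 3L),
                                    bsr("LigRec_Gabg", 4L)),
                  rate_constant = 1),
    reaction_rule("G-protein precoupling release", "dissociation",
                  pair(LigRec_Gabg = "LigRec_Gab_GDP"),
                  pair(`Ligated Receptor` = "Ligated Receptor",
                       Gabg = "Gabg_GDP"),
                  bond_sites = list(bsr("LigRec_Gabg", 3L),
                                    bsr("LigRec_Gabg", 4L)),
                  rate_constant = 1),
    reaction_rule("G-protein trimer dissociation", "dissociation",
                  pair(Gabg = "Gabg_GTP"),
                  pair(Galpha = "Galpha_GTP", Gbg = "Gbg"),
                  bond_sites = list(bsr("Gabg", 2L), bsr("Gabg", 3L)),
                  rate_constant = 1),
    reaction_rule("G-protein trimer reformation", "association",
                  pair(Galpha = "Galpha_GDP", Gbg = "Gbg"),
                  pair(Gabg = "Gabg_GDP"),
                  bond_sites = list(bsr("Galpha", 2L), bsr("Gbg", 1L)),
                  rate_constant = 1),
    reaction_rule("Galpha GTP hydrolysis", "transformation",
                  pair(Galpha = "Galpha_GTP"), pair(Galpha = "Galpha_GDP"),
                  rate_constant = 1),
    reaction_rule("receptor desensitization", "transformation",
                  pair(Receptor = "Rec inactive unbound"),
                  pair(Receptor = "Receptor_2"),
                  rate_constant = 1),
    reaction_rule("effector deactivation", "transformation",
                  pair(Effector = "Effector active"),
                  pair(Effector = "Effector inactive"),
                  rate_constant = 1))

  reaction_model(molecules, species, rules,
                 metadata = list(fixture = "gprotein",
                                 rule_provenance = gp_rule_provenance()))
}

#' Specification for the random-model generator
#'
#' @param n_species number of complex species (each built on its own
#'   molecule).
#' @param n_rules number of reaction rules.
#' @param category_weights non-negative sampling weights for
#'   association/dissociation/transformation; not all zero.
#' @param max_sites_per_species maximum binding sites per species (>= 1).
#' @param max_state_vars maximum state variables per species (>= 0).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return an object of class `random_model_spec`.
#' @export
random_model_spec <- function(n_species, n_rules,
                              category_weights = c(1, 1, 1),
                              max_sites_per_species = 3L,
                              max_state_vars = 2L, seed = 1L) {
  stopifnot(n_species >= 0, n_rules >= 0,
            length(category_weights) == 3L, all(category_weights >= 0),
            sum(category_weights) > 0,
            max_sites_per_species >= 1L, max_state_vars >= 0L)
  structure(list(n_species = as.integer(n_species),
                 n_rules = as.integer(n_rules),
                 category_weights = as.numeric(category_weights),
                 max_sites_per_species = as.integer(max_sites_per_species),
                 max_state_vars = as.integer(max_state_vars),
                 seed = as.integer(seed)),
            class = "random_model_spec")
}

with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a seeded random model
#'
#' Builds a valid model for property testing: one single-molecule species
#' per `n_species` (with random site and state-variable counts and 1-3
#' complexes with distinct state maps), then `n_rules` rules sampled by
#' `category_weights` over existing (species, complex) pairs, with category
#' arity respected and bond sites drawn from the reactant species' sites
#' where available. Identical specs give identical models.
#'
#' @param spec a [random_model_spec()].
#' @return a validated [reaction_model()].
#' @export
#' @examples
#' m <- random_model(random_model_spec(n_species = 4, n_rules = 6, seed = 7))
#' nrow(validate_model(m))
random_model <- function(spec) {
  stopifnot(inherits(spec, "random_model_spec"))
  if (spec$n_rules > 0L && spec$n_species == 0L)
    stop("infeasible spec: rules require at least one species", call. = FALSE)
  with_preserved_rng(spec$seed, {
    molecules <- list()
    species <- list()
    n_sites <- integer(spec$n_species)
    complex_names <- vector("list", spec$n_species)
    for (i in seq_len(spec$n_species)) {
      sname <- sprintf("S%02d", i)
      mname <- sprintf("M%02d", i)
      k_sites <- sample.int(spec$max_sites_per_species, 1L)
      k_vars <- if (spec$max_state_vars > 0L)
        sample.int(spec$max_state_vars + 1L, 1L) - 1L else 0L
      molecules[[i]] <- molecule(mname, list(mol_component(
        "core",
        state_variables = if (k_vars) sprintf("v%d", seq_len(k_vars))
                          else character(),
        binding_sites = sprintf("b%d", seq_len(k_sites)))))
      n_cx <- if (k_vars == 0L) 1L else sample.int(min(3L, 3L^k_vars), 1L)
      # distinct state maps: sample value tuples without replacement
      tuples <- sample.int(3L^k_vars, n_cx)
      cxs <- lapply(seq_len(n_cx), function(j) {
        vals <- tri_states()[1L + ((tuples[j] - 1L) %/% 3L^(seq_len(k_vars) - 1L)) %% 3L]
        states <- if (k_vars)
          stats::setNames(vals, state_key("m1", "core",
                                          sprintf("v%d", seq_len(k_vars))))
        else character()
        species_complex(sprintf("%s_c%d", sname, j), states)
      })
      species[[i]] <- complex_species(sname, c(m1 = mname), complexes = cxs)
      n_sites[i] <- k_sites
      complex_names[[i]] <- vapply(cxs, `[[`, "", "name")
    }
    names(n_sites) <- sprintf("S%02d", seq_len(spec$n_species))
    names(complex_names) <- names(n_sites)

    pick <- function() {
      s <- sample(names(n_sites), 1L)
      c(species = s, complex = sample(complex_names[[s]], 1L))
    }
    rules <- lapply(seq_len(spec$n_rules), function(j) {
      category <- sample(rule_categories(), 1L, prob = spec$category_weights)
      n_r <- if (category == "association") 2L else 1L
      n_p <- if (category == "dissociation") 2L else 1L
      re <- do.call(rbind, lapply(seq_len(n_r), function(...)
        as.data.frame(as.list(pick()), stringsAsFactors = FALSE)))
      pr <- do.call(rbind, lapply(seq_len(n_p), function(...)
        as.data.frame(as.list(pick()), stringsAsFactors = FALSE)))
      bs <- NULL
      if (category == "association") {
        bs <- list(binding_site_ref(re$species[1],
                                    sample.int(n_sites[[re$species[1]]], 1L)),
                   binding_site_ref(re$species[2],
                                    sample.int(n_sites[[re$species[2]]], 1L)))
      } else if (category == "dissociation" && n_sites[[re$species[1]]] >= 2L) {
        idx <- sort(sample.int(n_sites[[re$species[1]]], 2L))
        bs <- list(binding_site_ref(re$species[1], idx[1]),
                   binding_site_ref(re$species[1], idx[2]))
      }
      reaction_rule(sprintf("R%03d", j), category, re, pr, bond_sites = bs,
                    rate_constant = stats::runif(1))
    })
    reaction_model(molecules, species, rules,
                   metadata = list(fixture = "random", seed = spec$seed))
  })
}
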