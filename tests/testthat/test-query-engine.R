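test_that("name filtering matches complexes and flags child matches", {
  m <- gprotein_model()
  f <- filter_by_name(m, "gdp")
  get <- function(sp, cx = NA) {
    if (is.na(cx)) f$highlight[f$entity == "species" & f$species == sp]
    else f$highlight[f$entity == "complex" & f$species == sp &
                       f$complex == cx]
  }
  expect_identical(get("LigRec_Gabg", "LigRec_Gab_GDP"), "match")
  expect_identical(get("LigRec_Gabg"), "child_match")
  expect_identical(get("Ligand"), "none")
  # case-insensitive in both directions
  expect_identical(filter_by_name(m, "GDP"), f)
  expect_identical(filter_by_name(m, "Gdp"), f)
  # term matching nothing
  expect_true(all(filter_by_name(m, "zzz")$highlight == "none"))
  expect_error(filter_by_name(m, ""), "non-empty")
})

test_that("name filtering equals a brute-force substring scan", {
  for (m in random_models_for_tests(10, base_seed = 500L)) {
    for (term in c("s0", "C1", "_c2", "q")) {
      f <- filter_by_name(m, term)
      oracle <- oracle_name_filter(m, term)
      for (sp in names(oracle)) {
        expect_identical(
          f$highlight[f$entity == "species" & f$species == sp],
          oracle[[sp]]$species)
        for (cx in names(oracle[[sp]]$complexes))
          expect_identical(
            f$highlight[f$entity == "complex" & f$species == sp &
                          f$complex == cx],
            unname(oracle[[sp]]$complexes[[cx]]))
      }
    }
  }
})

test_that("molecule filtering is hereditary and never yields child_match", {
  m <- gprotein_model()
  f <- filter_by_molecule(m, "Ligand")
  hits <- unique(f$species[f$highlight == "match"])
  expect_setequal(hits, c("Ligand", "Ligated Receptor", "LigRec_Gabg"))
  expect_false(any(f$highlight == "child_match"))
  # species and child complexes always agree
  for (sp in unique(f$species)) {
    states <- unique(f$highlight[f$species == sp])
    expect_length(states, 1)
  }
  expect_true(all(filter_by_molecule(m, "NotHere")$highlight == "none"))
})

test_that("tri-state matching agrees with the exhaustive truth table", {
  vals <- tri_states()
  for (a in vals) for (b in vals)
    expect_identical(tri_match(a, b), oracle_tri_match(a, b))
  m <- gprotein_model()
  # all-dont-care pattern matches every complex of the species
  p <- state_pattern("Receptor")
  for (cx in m$species[["Receptor"]]$complexes)
    expect_true(match_state_pattern(p, cx, m))
  p_off <- state_pattern("Receptor", c("rec/intracellular/active" = "off"))
  expect_true(match_state_pattern(
    p_off, model_complex(m, "Receptor", "Rec inactive"), m))
  # pattern constraining a variable the species does not declare
  bad <- state_pattern("Receptor", c("rec/intracellular/ghost" = "on"))
  expect_error(match_state_pattern(
    bad, model_complex(m, "Receptor", "Rec inactive"), m), "unknown")
  # randomized agreement with per-variable oracle conjunction
  for (rm in random_models_for_tests(10, base_seed = 520L)) {
    for (sp in rm$species) {
      decl <- species_state_table(rm, sp$name)
      if (nrow(decl) == 0L) next
      keys <- state_key(decl$instance_id, decl$component,
                        decl$state_variable)
      for (i in seq_len(3)) {
        pv <- tri_states()[((i + seq_along(keys)) %% 3) + 1]
        p <- state_pattern(sp$name, stats::setNames(pv, keys))
        for (cx in sp$complexes) {
          sv <- stats::setNames(cx$states$value,
                                state_key(cx$states$instance_id,
                                          cx$states$component,
                                          cx$states$state_variable))
          want <- all(oracle_tri_match(pv, unname(sv[keys])))
          expect_identical(match_state_pattern(p, cx, rm), want)
        }
      }
    }
  }
})

test_that("relaxing a pattern can only grow the match set", {
  for (rm in random_models_for_tests(8, base_seed = 540L)) {
    g <- build_network_graph(rm)
    for (sp in rm$species) {
      decl <- species_state_table(rm, sp$name)
      if (nrow(decl) == 0L) next
      keys <- state_key(decl$instance_id, decl$component,
                        decl$state_variable)
      tight <- state_pattern(sp$name,
                             stats::setNames(rep("on", length(keys)), keys))
      relaxed <- state_pattern(sp$name, stats::setNames(
        c("dont_care", rep("on", length(keys) - 1)), keys))
      m_tight <- search_species(rm, g, tight)$matching_complexes
      m_rel <- search_species(rm, g, relaxed)$matching_complexes
      expect_true(all(m_tight %in% m_rel))
    }
  }
})

test_that("state search highlights the matching complexes' reactions", {
  m <- gprotein_model()
  g <- build_network_graph(m)
  sel <- search_species(m, g, state_pattern(
    "Receptor", c("rec/intracellular/active" = "off")))
  expect_setequal(sel$matching_complexes,
                  c("Rec inactive", "Receptor_2", "Rec inactive unbound"))
  expect_setequal(sel$highlighted_rules,
                  c("receptor ligation", "ligand dissociation",
                    "receptor desensitization"))
  expect_identical(sel$searched_species, "Receptor")
  # every highlighted edge belongs to a highlighted rule
  e <- g$edges[g$edges$id %in% sel$highlighted_edges, ]
  expect_setequal(unique(e$rule), sel$highlighted_rules)
  expect_error(search_species(m, g, state_pattern("Ghost")), "unknown")
})

test_that("an occupied PLC site excludes all PLCgamma1 associations", {
  m <- egfr_model()
  g <- build_network_graph(m)
  sel <- search_species(m, g, state_pattern(
    "EGFR", c("egfr/cytoplasmic/bndPLCg992" = "on")))
  plc_rules <- names(Filter(function(r)
    any(r$reactants$species == "PLCg1"), m$rules))
  expect_length(intersect(sel$highlighted_rules, plc_rules), 0)
  expect_gt(length(sel$highlighted_rules), 0)
  # likewise a bound Shc at pY1148 blocks PLCgamma1 at pY1173
  sel2 <- search_species(m, g, state_pattern(
    "EGFR", c("egfr/cytoplasmic/bndSHC1148" = "on")))
  expect_false("PLCg1 binds EGFR pY1173" %in% sel2$highlighted_rules)
})

test_that("selecting a reaction overlays the involved complexes", {
  m <- gprotein_model()
  g <- build_network_graph(m)
  sel <- select_reaction(m, g, "receptor ligation")
  expect_setequal(names(sel$overlays),
                  c("s:Ligand", "s:Receptor", "s:Ligated Receptor"))
  expect_identical(sel$overlays[["s:Receptor"]]$complex, "Rec inactive")
  expect_identical(sel$overlays[["s:Ligated Receptor"]]$role, "product")
  expect_setequal(sel$highlighted_edges,
                  g$edges$id[g$edges$rule == "receptor ligation"])
  # transformation: detached before/after pair
  tr <- select_reaction(m, g, "Receptor mediated Galpha GDP GTP exchange")
  ov <- tr$overlays[["s:LigRec_Gabg"]]
  expect_identical(ov$before, "LigRec_Gab_GDP")
  expect_identical(ov$after, "LigRec_Gabg_GTP")
  expect_error(select_reaction(m, g, "ghost rule"), "unknown rule")
})

test_that("selecting a complex highlights exactly its reactions", {
  m <- gprotein_model()
  g <- build_network_graph(m)
  sel <- select_complex(m, g, c("Receptor", "Rec inactive"))
  expect_length(sel$highlighted_rules, 2)
  expect_length(sel$overlays, 0)
  for (rm in random_models_for_tests(8, base_seed = 560L)) {
    rg <- build_network_graph(rm)
    for (sp in rm$species) for (cx in sp$complexes) {
      got <- select_complex(rm, rg, c(sp$name, cx$name))$highlighted_rules
      expect_setequal(got, oracle_rules_of_complex(rm, sp$name, cx$name))
    }
  }
})

test_that("reactions_by_category partitions the rule set in model order", {
  m <- egfr_model()
  by_cat <- reactions_by_category(m)
  expect_length(by_cat$association, 6)
  expect_length(by_cat$dissociation, 0)
  expect_length(by_cat$transformation, 0)
  empty <- reactions_by_category(reaction_model())
  expect_identical(lengths(empty),
                   c(association = 0L, dissociation = 0L,
                     transformation = 0L))
  mg <- gprotein_model()
  groups <- reactions_by_category(mg)
  expect_setequal(unlist(groups, use.names = FALSE), names(mg$rules))
  expect_identical(sum(lengths(groups)), length(mg$rules))
  # stable model order within groups
  expect_identical(groups$transformation,
                   names(mg$rules)[vapply(mg$rules, `[[`, "",
                                          "category") == "transformation"])
})
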