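test_that("serialization round-trips models field-for-field", {
  for (model in list(reaction_model(), tiny_association_model(),
                     egfr_model(), gprotein_model())) {
    txt <- serialize_model(model)
    expect_true(model_equal(parse_model(txt), model))
  }
})

test_that("an empty document parses to an empty model and back", {
  m <- parse_model('{"format_version":"1.0","molecules":[],"species":[],"rules":[]}')
  expect_length(m$molecules, 0)
  expect_length(m$species, 0)
  expect_length(m$rules, 0)
  reparsed <- parse_model(serialize_model(m))
  expect_true(model_equal(m, reparsed))
})

test_that("construction order does not affect the serialized bytes", {
  build <- function(perm_sp, perm_rules) {
    base <- gprotein_model()
    reaction_model(unname(base$molecules)[c(3, 1, 2, 6, 5, 4)],
                   unname(base$species)[perm_sp],
                   unname(base$rules)[perm_rules],
                   metadata = base$metadata)
  }
  a <- build(seq_len(8), seq_len(11))
  b <- build(rev(seq_len(8)), c(5, 1, 11, 3, 2, 4, 10, 9, 8, 7, 6))
  expect_identical(serialize_model(a), serialize_model(b))
})

test_that("YAML is accepted as a reading dialect producing identical models", {
  m <- tiny_association_model()
  ym <- yaml::as.yaml(jsonlite::fromJSON(serialize_model(m),
                                         simplifyVector = FALSE))
  expect_true(model_equal(parse_model(ym, format = "yaml"), m))
})

test_that("unknown keys are ignored with a warning", {
  txt <- '{"format_version":"1.0","molecules":[],"species":[],"rules":[],
           "simulator_settings":{"dt":0.1}}'
  expect_warning(m <- parse_model(txt), "unknown key")
  expect_s3_class(m, "reaction_model")
})

test_that("malformed and dangling documents raise informative errors", {
  expect_error(parse_model('{"format_version": '), regexp = ".")
  dangling <- '{"format_version":"1.0","molecules":[],"species":[],
    "rules":[{"name":"r","category":"transformation",
              "reactants":[{"species":"ghost","complex":"c"}],
              "products":[{"species":"ghost","complex":"c"}]}]}'
  expect_error(parse_model(dangling), "UNKNOWN_SPECIES")
  expect_error(parse_model('{"molecules":[]}'), "format_version")
})

test_that("single injected violations are reported once with matching codes", {
  base <- gprotein_model()
  inject <- function(mutate) {
    m <- base
    m <- mutate(m)
    validate_model(m)
  }
  # association with one reactant
  v <- inject(function(m) {
    m$rules[["receptor ligation"]]$reactants <-
      m$rules[["receptor ligation"]]$reactants[1, , drop = FALSE]
    m$rules[["receptor ligation"]]$bond_sites <- NULL
    m
  })
  expect_identical(v$code, "ARITY")
  # transformation carrying bond sites
  v <- inject(function(m) {
    m$rules[["Galpha GTP hydrolysis"]]$bond_sites <-
      list(binding_site_ref("Galpha", 1L))
    m
  })
  expect_identical(v$code, "BOND_ON_TRANSFORM")
  # state map omitting one declared variable
  v <- inject(function(m) {
    cx <- m$species[["Receptor"]]$complexes[[1]]
    cx$states <- cx$states[-1, , drop = FALSE]
    m$species[["Receptor"]]$complexes[[1]] <- cx
    m
  })
  expect_identical(v$code, "STATE_COVERAGE")
  expect_identical(nrow(v), 1L)
  # negative rate
  v <- inject(function(m) {
    m$rules[["effector deactivation"]]$rate_constant <- -1
    m
  })
  expect_identical(v$code, "RATE_NEGATIVE")
  # dangling complex reference
  v <- inject(function(m) {
    m$rules[["effector deactivation"]]$products$complex <- "ghost"
    m
  })
  expect_identical(v$code, "UNKNOWN_COMPLEX")
  # bond index beyond the species' sites
  v <- inject(function(m) {
    m$species[["Gbg"]]$structural_bonds <- list(c(2L, 9L))
    m
  })
  expect_identical(v$code, "BOND_SITE_RANGE")
})

test_that("duplicate complex state maps warn rather than error", {
  m <- gprotein_model()
  cx <- m$species[["Receptor"]]$complexes[[1]]
  cx$name <- "Rec duplicate"
  m$species[["Receptor"]]$complexes <-
    c(m$species[["Receptor"]]$complexes, list(cx))
  v <- validate_model(m)
  expect_identical(v$code, "DUP_COMPLEX_STATES")
  expect_identical(v$severity, "warning")
  expect_silent(assert_valid_model(m))
})

test_that("serialize_model refuses invalid models with an aggregated report", {
  m <- gprotein_model()
  m$rules[["receptor ligation"]]$reactants$complex[1] <- "ghost"
  m$rules[["effector deactivation"]]$rate_constant <- -2
  err <- tryCatch(serialize_model(m), error = identity)
  expect_match(conditionMessage(err), "UNKNOWN_COMPLEX")
  expect_match(conditionMessage(err), "RATE_NEGATIVE")
})

test_that("site indexing follows declaration order across instances", {
  m <- gprotein_model()
  tab <- species_site_table(m, "LigRec_Gabg")
  expect_identical(tab$site_index, 1:8)
  expect_identical(tab$instance_id,
                   c("lig", "rec", "rec", "ga", "ga", "gb", "gb", "gg"))
  expect_identical(tab$site_name[1:3], c("rec", "lig", "gprot"))
  expect_true(all(tab$bonded))
  expect_false(any(species_site_table(m, "Receptor")$bonded))
})

test_that("molecule containment is hereditary and matches a linear scan", {
  m <- gprotein_model()
  with_lig <- names(Filter(function(sp)
    species_contains_molecule(sp, "Ligand"), m$species))
  expect_setequal(with_lig, c("Ligand", "Ligated Receptor", "LigRec_Gabg"))
  expect_false(species_contains_molecule(m$species[["Ligand"]],
                                         "NotAMolecule"))
  for (rm in random_models_for_tests(10)) {
    for (sp in rm$species) for (mol in names(rm$molecules)) {
      expect_identical(species_contains_molecule(sp, mol),
                       mol %in% sp$molecule_instances$molecule)
    }
  }
})
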