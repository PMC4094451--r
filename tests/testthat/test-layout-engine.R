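test_that("reaction distances halve the bipartite BFS distances", {
  g <- build_network_graph(gprotein_model())
  la <- reaction_distance(g, "Ligand")
  expect_identical(la$levels[["s:Ligand"]], 0)
  expect_identical(la$levels[["s:Ligated Receptor"]], 1)
  expect_setequal(la$unreachable,
                  c("s:Effector", "r:effector deactivation"))
  for (m in random_models_for_tests(8, base_seed = 400L)) {
    rg <- build_network_graph(m)
    if (nrow(rg$nodes) == 0L) next
    ref <- rg$nodes$id[rg$nodes$kind == "species"][1]
    la <- reaction_distance(rg, ref)
    oracle <- oracle_bfs_levels(rg, ref)
    for (id in names(la$levels))
      expect_identical(la$levels[[id]], oracle[[id]] / 2)
    for (id in names(la$reaction_levels))
      expect_identical(la$reaction_levels[[id]], oracle[[id]] / 2)
    expect_setequal(la$unreachable, names(oracle)[is.infinite(oracle)])
  }
  expect_error(reaction_distance(g, "NotASpecies"), "not a species")
  # reaction nodes cannot serve as reference
  expect_error(reaction_distance(g, "r:receptor ligation"), "not a species")
})

test_that("the force layout is seeded, centered and overlap-free", {
  g1 <- build_network_graph(tiny_association_model())
  single <- build_network_graph(reaction_model(
    list(molecule("X", list(mol_component("c")))),
    list(complex_species("X", c(x = "X"),
                         complexes = list(species_complex("X")))), list()))
  lay <- layout_force(single, seed = 1)
  expect_equal(unname(lay$positions["s:X", ]), c(0, 0))

  for (seed in c(1, 2, 77)) {
    a <- layout_force(g1, seed = seed)
    b <- layout_force(g1, seed = seed)
    expect_identical(a$positions, b$positions)
    expect_identical(count_overlaps(a), 0L)
  }
  eg <- build_network_graph(egfr_model())
  for (seed in c(1, 9)) {
    expect_identical(count_overlaps(layout_force(eg, seed = seed)), 0L)
  }
})

test_that("level layout puts the reference on top with y monotone in level", {
  g <- build_network_graph(gprotein_model())
  lay <- layout_level(g, "Ligand")
  ys <- lay$positions[, 2]
  expect_identical(unname(min(ys)), unname(ys[["s:Ligand"]]))
  oracle <- oracle_bfs_levels(g, "s:Ligand")
  sp_ids <- g$nodes$id[g$nodes$kind == "species"]
  reach <- sp_ids[is.finite(oracle[sp_ids])]
  for (i in seq_along(reach)) for (j in seq_along(reach)) {
    if (oracle[[reach[i]]] < oracle[[reach[j]]])
      expect_lt(ys[[reach[i]]], ys[[reach[j]]])
  }
  # unreachable nodes sit strictly below every reachable one
  expect_gt(min(ys[c("s:Effector", "r:effector deactivation")]),
            max(ys[setdiff(names(ys), c("s:Effector",
                                        "r:effector deactivation"))]))
  expect_identical(count_overlaps(lay), 0L)
})

test_that("two disconnected species land in the unreachable band at distinct x", {
  m <- reaction_model(
    list(molecule("X", list(mol_component("c"))),
         molecule("Y", list(mol_component("c")))),
    list(complex_species("X", c(x = "X"),
                         complexes = list(species_complex("X"))),
         complex_species("Y", c(y = "Y"),
                         complexes = list(species_complex("Y")))), list())
  g <- build_network_graph(m)
  lay <- layout_level(g, "X")
  expect_lt(lay$positions["s:X", 2], lay$positions["s:Y", 2])
  expect_identical(count_overlaps(lay), 0L)
})

test_that("circular layout centers the reference with radius monotone in level", {
  g <- build_network_graph(gprotein_model())
  lay <- layout_circular(g, "Ligand")
  expect_equal(unname(lay$positions["s:Ligand", ]), c(0, 0))
  oracle <- oracle_bfs_levels(g, "s:Ligand")
  r <- sqrt(rowSums(lay$positions^2))
  ids <- names(oracle)
  lev <- ifelse(is.finite(oracle), oracle, max(oracle[is.finite(oracle)]) + 4)
  for (i in ids) for (j in ids) {
    if (lev[[i]] < lev[[j]]) expect_lt(r[[i]], r[[j]] + 1e-9)
    if (lev[[i]] == lev[[j]]) expect_equal(r[[i]], r[[j]], tolerance = 1e-9)
  }
  expect_identical(count_overlaps(lay), 0L)
})

test_that("circular angles preserve the level layout's within-ring order", {
  g <- build_network_graph(egfr_model())
  base <- layout_level(g, "EGFR")
  circ <- layout_circular(g, "EGFR")
  oracle <- oracle_bfs_levels(g, "s:EGFR")
  for (lv in setdiff(unique(oracle[is.finite(oracle)]), 0)) {
    ring <- names(oracle)[oracle == lv]
    if (length(ring) < 2L) next
    ang <- atan2(circ$positions[ring, 2], circ$positions[ring, 1])
    ang <- ang %% (2 * pi)
    expect_identical(order(base$positions[ring, 1]), order(ang))
  }
})

test_that("layout persistence round-trips bit-exactly with overrides", {
  g <- build_network_graph(gprotein_model())
  lay <- layout_force(g, seed = 4)
  lay$positions["s:Ligand", 1] <- 123.456789012345  # manual adjustment
  lay$visual_overrides <- list(`receptor ligation#reactant#Ligand#1` =
                                 list(width = 5))
  txt <- save_layout(lay, g)
  back <- load_layout(txt, g)
  expect_identical(back$positions, lay$positions)
  expect_identical(back$sizes, lay$sizes)
  expect_equal(back$visual_overrides[[1]]$width, 5)
  expect_identical(back$mode, lay$mode)
})

test_that("loading against a changed graph reports a reconciliation diff", {
  m <- gprotein_model()
  g <- build_network_graph(m)
  lay <- layout_force(g, seed = 2)
  txt <- save_layout(lay, g)
  m2 <- reaction_model(
    c(unname(m$molecules), list(molecule("Z", list(mol_component("c"))))),
    c(unname(m$species),
      list(complex_species("Zed", c(z = "Z"),
                           complexes = list(species_complex("Zed"))))),
    unname(m$rules), metadata = m$metadata)
  g2 <- build_network_graph(m2)
  expect_warning(back <- load_layout(txt, g2), "differ")
  rec <- attr(back, "reconciliation")
  expect_identical(rec$missing, "s:Zed")
  expect_length(rec$extra, 0)
  keep <- setdiff(g$nodes$id, "s:Zed")
  expect_identical(back$positions[keep, ], lay$positions[keep, ])
  expect_error(load_layout("{not json", g), regexp = ".")
  expect_error(load_layout('{"mode":"force"}', g), "malformed")
})
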