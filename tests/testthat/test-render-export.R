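test_that("edge colors hit the saturation bounds with a fixed hue", {
  style <- style_palette()
  for (cat in rule_categories()) {
    lo <- grDevices::rgb2hsv(grDevices::col2rgb(edge_color(cat, 0, style)))
    hi <- grDevices::rgb2hsv(grDevices::col2rgb(edge_color(cat, 1, style)))
    expect_equal(unname(lo["s", 1]), style$saturation_range[1],
                 tolerance = 0.01)
    expect_equal(unname(hi["s", 1]), style$saturation_range[2],
                 tolerance = 0.01)
    expect_equal(unname(lo["h", 1]), unname(hi["h", 1]), tolerance = 0.01)
    expect_equal(unname(lo["v", 1]), unname(hi["v", 1]), tolerance = 0.01)
  }
  expect_error(edge_color("association", 1.2), "0, 1")
  expect_error(edge_color("association", -0.1), "0, 1")
})

test_that("SVG output is well-formed, deterministic and styled by category", {
  m <- gprotein_model()
  g <- build_network_graph(m)
  lay <- layout_force(g, seed = 1)
  svg1 <- render_svg(m, g, lay)
  svg2 <- render_svg(m, g, lay)
  expect_identical(svg1, svg2)
  doc <- xml2::read_xml(svg1)
  expect_identical(xml2::xml_name(doc), "svg")
  # per-category hues appear via their saturation ramp endpoints
  expect_match(svg1, "edge-receptor ligation", fixed = TRUE)
  style <- style_palette()
  # last gradient stop of each category's ramp (segment midpoint 15/16)
  for (cat in c("association", "dissociation", "transformation"))
    expect_match(svg1, edge_color(cat, 15 / 16, style), fixed = TRUE)
  # rate-constant tool tips are embedded
  expect_match(svg1, "<title>receptor ligation (rate 1)</title>",
               fixed = TRUE)
})

test_that("each species glyph draws its declared sites and state squares", {
  m <- egfr_model()
  g <- build_network_graph(m)
  lay <- layout_level(g, "EGFR")
  svg <- render_svg(m, g, lay)
  doc <- xml2::read_xml(svg)
  ns <- c(s = "http://www.w3.org/2000/svg")
  for (sp in names(m$species)) {
    grp <- xml2::xml_find_first(doc, sprintf(
      "//s:g[@id='node-%s']", species_node_id(sp)), ns)
    expect_false(inherits(grp, "xml_missing"))
    n_sites <- nrow(species_site_table(m, sp))
    n_states <- nrow(species_state_table(m, sp))
    expect_length(xml2::xml_find_all(grp, "./s:circle", ns), n_sites)
    expect_length(xml2::xml_find_all(grp, "./s:rect", ns), n_states)
  }
})

test_that("transformation edges run between node centers", {
  m <- gprotein_model()
  g <- build_network_graph(m)
  lay <- layout_force(g, seed = 2)
  svg <- render_svg(m, g, lay)
  e <- g$edges[g$edges$rule == "Galpha GTP hydrolysis" &
                 g$edges$role == "reactant", ]
  doc <- xml2::read_xml(svg)
  ns <- c(s = "http://www.w3.org/2000/svg")
  grp <- xml2::xml_find_first(doc, sprintf("//s:g[@id='edge-%s']", e$id), ns)
  d <- xml2::xml_attr(xml2::xml_find_first(grp, "./s:path", ns), "d")
  start <- as.numeric(strsplit(d, " ")[[1]][2:3])
  expect_equal(start, unname(lay$positions["s:Galpha", ]),
               tolerance = 0.01)
})

test_that("rendering is selection-local", {
  m <- gprotein_model()
  g <- build_network_graph(m)
  lay <- layout_force(g, seed = 1)
  plain <- render_svg(m, g, lay)
  sel <- select_reaction(m, g, "receptor ligation")
  with_sel <- render_svg(m, g, lay, selection = sel)
  expect_false(identical(plain, with_sel))
  # node groups untouched by the selection are byte-identical
  grab <- function(svg) {
    doc <- xml2::read_xml(svg)
    ns <- c(s = "http://www.w3.org/2000/svg")
    groups <- xml2::xml_find_all(doc, "//s:g[@id]", ns)
    stats::setNames(vapply(groups, function(x) paste(as.character(x),
                                                     collapse = ""), ""),
                    xml2::xml_attr(groups, "id"))
  }
  a <- grab(plain)
  b <- grab(with_sel)
  touched <- c(paste0("node-", names(sel$overlays)),
               paste0("edge-", sel$highlighted_edges),
               "edges", "nodes")
  for (id in setdiff(names(a), touched))
    expect_identical(a[[id]], b[[id]])
  for (id in paste0("edge-", sel$highlighted_edges))
    expect_false(identical(a[[id]], b[[id]]))
  # searched species gets the red border
  search <- search_species(m, g, state_pattern(
    "Receptor", c("rec/intracellular/active" = "off")))
  svg_search <- render_svg(m, g, lay, selection = search)
  expect_match(svg_search, "#CC0000", fixed = TRUE)
  expect_no_match(plain, "#CC0000", fixed = TRUE)
})

test_that("render refuses a layout that misses nodes", {
  m <- tiny_association_model()
  g <- build_network_graph(m)
  lay <- layout_force(g, seed = 1)
  lay$positions <- lay$positions[-1, , drop = FALSE]
  expect_error(render_svg(m, g, lay), "missing nodes")
})

test_that("DOT and GraphML exports round-trip to isomorphic graphs", {
  empty <- build_network_graph(reaction_model())
  expect_match(export_dot(empty), "digraph")
  expect_no_error(xml2::read_xml(export_graphml(empty)))

  eg <- build_network_graph(egfr_model())
  gml <- read_graphml_export(export_graphml(eg))
  expect_identical(nrow(gml$nodes), 17L)
  expect_identical(nrow(gml$edges), 18L)

  for (m in random_models_for_tests(8, base_seed = 600L)) {
    g <- build_network_graph(m)
    want <- reaction_graph_signature(g)
    got_gml <- read_graphml_export(export_graphml(g))
    got_dot <- read_dot_export(export_dot(g))
    expect_identical(graph_signature(got_gml$nodes, got_gml$edges), want)
    expect_identical(graph_signature(got_dot$nodes, got_dot$edges), want)
  }
})
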