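# Deterministic SVG rendering with the contact-map iconography: species
# glyphs built from component ellipses, indexed binding-site circles
# (filled when bound, joined by blue bond lines) and tri-state squares
# (filled = on, open = off, half-filled = don't care); reactions drawn as
# small arrowheads; edges as category-colored Bezier curves whose
# saturation increases along the reaction direction.

#' Default style palette
#'
#' @param category_hue named colors per rule category (defaults: green
#'   associations, orange dissociations, purple transformations).
#' @param saturation_range low/high saturation fractions used to encode
#'   edge direction (less saturated at the source, more at the target).
#' @param edge_width,edge_opacity base stroke width / opacity.
#' @param highlight_width,highlight_opacity multipliers applied to
#'   highlighted edges.
#' @param site_radius,square_side,font_size glyph metrics in canvas units.
#' @return an object of class `style_palette`.
#' @export
style_palette <- function(category_hue = c(association = "#2CA02C",
                                           dissociation = "#FF7F0E",
                                           transformation = "#9467BD"),
                          saturation_range = c(0.25, 1),
                          edge_width = 2, edge_opacity = 0.55,
                          highlight_width = 2.2, highlight_opacity = 1.7,
                          site_radius = 7, square_side = 9, font_size = 11) {
  stopifnot(all(rule_categories() %in% names(category_hue)),
            length(saturation_range) == 2L,
            saturation_range[1] < saturation_range[2])
  grDevices::col2rgb(category_hue)  # errors on invalid colors
  structure(list(category_hue = category_hue,
                 saturation_range = saturation_range,
                 edge_width = edge_width, edge_opacity = edge_opacity,
                 highlight_width = highlight_width,
                 highlight_opacity = highlight_opacity,
                 site_radius = site_radius, square_side = square_side,
                 font_size = font_size),
            class = "style_palette")
}

#' Read a style palette from a JSON file
#'
#' Omitted fields take the [style_palette()] defaults.
#' @param path JSON file mirroring the `style_palette` fields.
#' @return a `style_palette`.
#' @export
read_style <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(doc$category_hue)) args$category_hue <- unlist(doc$category_hue)
  for (k in c("saturation_range", "edge_width", "edge_opacity",
              "highlight_width", "highlight_opacity", "site_radius",
              "square_side", "font_size"))
    if (!is.null(doc[[k]])) args[[k]] <- as.numeric(doc[[k]])
  do.call(style_palette, args)
}

#' Directional edge color
#'
#' Hue is fixed by the rule category; saturation interpolates linearly (in
#' HSV) from the low to the high bound along the curve parameter `t`
#' (0 = source, 1 = target), with the value channel held constant.
#'
#' @param category rule category.
#' @param t position along the curve, in `[0, 1]`.
#' @param style a [style_palette()].
#' @return a hex color string.
#' @export
#' @examples
#' edge_color("association", 0)
#' edge_color("association", 1)
edge_color <- function(category, t, style = style_palette()) {
  stopifnot(category %in% rule_categories())
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("t must be a number in [0, 1]", call. = FALSE)
  base <- grDevices::rgb2hsv(grDevices::col2rgb(
    style$category_hue[[category]]))
  s <- style$saturation_range[1] +
    t * (style$saturation_range[2] - style$saturation_range[1])
  grDevices::hsv(base["h", 1], s, base["v", 1])
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

num <- function(x) {
  out <- sprintf("%.3f", x)
  out <- sub("\\.?0+$", "", out)
  ifelse(out == "-0", "0", out)
}

# ---- glyph geometry -------------------------------------------------------

# Per-species drawing plan inside a (w x h) node box centered at (cx, cy):
# one ellipse per molecule component (stacked vertically), site circles
# along the ellipse's lower arc, state squares along its upper arc.
glyph_plan <- function(model, species_name, cx, cy, w, h, style) {
  sp <- model_species(model, species_name)
  comps <- list()
  for (i in seq_len(nrow(sp$molecule_instances))) {
    inst <- sp$molecule_instances$instance_id[i]
    mol <- model$molecules[[sp$molecule_instances$molecule[i]]]
    for (comp in mol$components)
      comps[[length(comps) + 1L]] <- list(instance = inst, comp = comp)
  }
  n <- max(1L, length(comps))
  row_h <- (h - style$font_size - 4) / n
  sites <- list()
  squares <- list()
  ellipses <- list()
  site_idx <- 0L
  for (k in seq_along(comps)) {
    ec <- cy - h / 2 + (k - 0.5) * row_h
    rx <- w / 2 - 4
    ry <- row_h / 2 - 2
    ellipses[[k]] <- list(cx = cx, cy = ec, rx = rx, ry = ry,
                          label = comps[[k]]$comp$name)
    bs <- comps[[k]]$comp$binding_sites
    for (j in seq_along(bs)) {
      site_idx <- site_idx + 1L
      x <- cx - rx + j * 2 * rx / (length(bs) + 1)
      sites[[site_idx]] <- list(index = site_idx, x = x, y = ec + ry * 0.55,
                                name = bs[j])
    }
    sv <- comps[[k]]$comp$state_variables
    for (j in seq_along(sv)) {
      x <- cx - rx + j * 2 * rx / (length(sv) + 1)
      squares[[length(squares) + 1L]] <- list(
        key = state_key(comps[[k]]$instance, comps[[k]]$comp$name, sv[j]),
        x = x, y = ec - ry * 0.55, name = sv[j])
    }
  }
  list(species = sp, ellipses = ellipses, sites = sites, squares = squares)
}

glyph_site_xy <- function(plan, site_index) {
  for (s in plan$sites) if (s$index == site_index) return(c(s$x, s$y))
  NULL
}

svg_square <- function(x, y, side, value, stroke = "#333333") {
  half <- side / 2
  fill <- switch(value, on = "#333333", off = "none", "none")
  out <- sprintf(
    '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="1"/>',
    num(x - half), num(y - half), num(side), num(side), fill, stroke)
  if (identical(value, "dont_care")) {
    # half-filled square marks don't care
    out <- paste0(out, sprintf(
      '<path d="M %s %s L %s %s L %s %s Z" fill="%s"/>',
      num(x - half), num(y + half), num(x - half), num(y - half),
      num(x + half), num(y - half), stroke))
  }
  out
}

glyph_svg <- function(plan, style, states = NULL, bonded_extra = integer(),
                      sublabel = NULL, red_border = FALSE, cx, cy, w, h,
                      node_id) {
  sp <- plan$species
  bonded <- unlist(sp$structural_bonds)
  out <- c(sprintf('<g id="node-%s">', xml_escape(node_id)))
  if (red_border)
    out <- c(out, sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#CC0000" stroke-width="2"/>',
      num(cx - w / 2 - 3), num(cy - h / 2 - 3), num(w + 6), num(h + 6)))
  for (e in plan$ellipses)
    out <- c(out, sprintf(
      '<ellipse cx="%s" cy="%s" rx="%s" ry="%s" fill="#F2F2F2" stroke="#555555" stroke-width="1"/>',
      num(e$cx), num(e$cy), num(e$rx), num(e$ry)))
  # bond lines beneath site circles
  for (b in sp$structural_bonds) {
    p1 <- glyph_site_xy(plan, b[1])
    p2 <- glyph_site_xy(plan, b[2])
    if (!is.null(p1) && !is.null(p2))
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#1F77DB" stroke-width="1.5"/>',
        num(p1[1]), num(p1[2]), num(p2[1]), num(p2[2])))
  }
  for (s in plan$sites) {
    filled <- s$index %in% bonded || s$index %in% bonded_extra
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="#333333" stroke-width="1"/>',
      num(s$x), num(s$y), num(style$site_radius),
      if (filled) "#333333" else "#FFFFFF"))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="%s" text-anchor="middle" fill="%s">%d</text>',
      num(s$x), num(s$y + style$site_radius * 0.45),
      num(style$site_radius * 1.2),
      if (filled) "#FFFFFF" else "#333333", s$index))
  }
  for (q in plan$squares) {
    value <- if (!is.null(states) && !is.null(states[[q$key]]))
      states[[q$key]] else NA_character_
    out <- c(out, svg_square(q$x, q$y, style$square_side,
                             if (is.na(value)) "unset" else value,
                             stroke = if (is.na(value)) "#999999"
                                      else "#333333"))
  }
  out <- c(out, sprintf(
    '<text x="%s" y="%s" font-size="%s" text-anchor="middle" fill="#000000">%s</text>',
    num(cx), num(cy + h / 2 + style$font_size), num(style$font_size),
    xml_escape(sp$name)))
  if (!is.null(sublabel))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="%s" text-anchor="middle" fill="#1F3FBF">%s</text>',
      num(cx), num(cy + h / 2 + 2.1 * style$font_size),
      num(style$font_size * 0.9), xml_escape(sublabel)))
  c(out, "</g>")
}

# ---- Bezier edges ---------------------------------------------------------

bezier_point <- function(p0, p1, p2, p3, t) {
  u <- 1 - t
  u^3 * p0 + 3 * u^2 * t * p1 + 3 * u * t^2 * p2 + t^3 * p3
}

edge_path_svg <- function(p0, p3, occurrence, category, style, width,
                          opacity, title = NULL, edge_id, n_seg = 8L) {
  chord <- sqrt(sum((p3 - p0)^2))
  d <- p3 - p0
  perp <- if (chord > 0) c(-d[2], d[1]) / chord else c(0, 1)
  side <- if (occurrence %% 2L == 1L) 1 else -1
  off <- side * 0.15 * max(chord, 1)
  p1 <- p0 + d / 3 + perp * off
  p2 <- p0 + 2 * d / 3 + perp * off
  ts <- seq(0, 1, length.out = n_seg + 1L)
  out <- sprintf('<g id="edge-%s">', xml_escape(edge_id))
  if (!is.null(title))
    out <- c(out, sprintf("<title>%s</title>", xml_escape(title)))
  for (k in seq_len(n_seg)) {
    # polyline subdivision of the cubic; per-segment color realizes the
    # saturation gradient along the path
    a <- bezier_point(p0, p1, p2, p3, ts[k])
    m <- bezier_point(p0, p1, p2, p3, (ts[k] + ts[k + 1L]) / 2)
    b <- bezier_point(p0, p1, p2, p3, ts[k + 1L])
    col <- edge_color(category, (ts[k] + ts[k + 1L]) / 2, style)
    out <- c(out, sprintf(
      '<path d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="%s" stroke-linecap="round"/>',
      num(a[1]), num(a[2]), num(2 * m[1] - (a[1] + b[1]) / 2),
      num(2 * m[2] - (a[2] + b[2]) / 2), num(b[1]), num(b[2]),
      col, num(width), num(min(opacity, 1))))
  }
  c(out, "</g>")
}

# ---- main renderer --------------------------------------------------------

#' Render a network graph as SVG
#'
#' Species glyphs are drawn at their layout positions; reaction nodes as
#' small arrowheads oriented from the centroid of their reactant
#' endpoints toward the centroid of their product endpoints; edges as
#' cubic Bezier curves anchored at the involved binding-site circle (or
#' the node center), hue by category and saturation increasing along the
#' reaction direction, with the rule's rate constant as an SVG
#' `<title>` tool-tip. A selection thickens and opacifies the highlighted
#' edges, overlays the involved species with their rule-side complex
#' states and blue complex-name sublabels, renders a transformation's
#' before/after pair in a detached side panel, and draws a red border
#' around a searched species. Output is deterministic: identical inputs
#' give byte-identical SVG.
#'
#' @param model the [reaction_model()] the graph was built from.
#' @param graph a `reaction_graph`.
#' @param layout a `network_layout` covering the graph's nodes.
#' @param style a [style_palette()].
#' @param selection optional `selection_result`.
#' @return a single SVG string.
#' @export
render_svg <- function(model, graph, layout, style = style_palette(),
                       selection = NULL) {
  stopifnot(inherits(graph, "reaction_graph"),
            inherits(layout, "network_layout"))
  missing <- setdiff(graph$nodes$id, rownames(layout$positions))
  if (length(missing))
    stop(sprintf("layout is missing nodes: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  pos <- layout$positions
  sz <- layout$sizes
  pad <- 90
  xr <- range(pos[, 1])
  yr <- range(pos[, 2])
  vb <- c(xr[1] - pad, yr[1] - pad, diff(xr) + 2 * pad + 160,
          diff(yr) + 2 * pad)

  sp_nodes <- graph$nodes[graph$nodes$kind == "species", , drop = FALSE]
  plans <- list()
  for (i in seq_len(nrow(sp_nodes))) {
    id <- sp_nodes$id[i]
    plans[[id]] <- glyph_plan(model, sp_nodes$name[i],
                              pos[id, 1], pos[id, 2], sz[id, 1], sz[id, 2],
                              style)
  }
  anchor_xy <- function(edge) {
    sid <- species_node_id(edge$species)
    if (!is.na(edge$anchor_site)) {
      xy <- glyph_site_xy(plans[[sid]], edge$anchor_site)
      if (!is.null(xy)) return(xy)
    }
    c(pos[sid, 1], pos[sid, 2])
  }

  highlighted <- if (is.null(selection)) character()
                 else selection$highlighted_edges
  overlays <- if (is.null(selection)) list() else selection$overlays
  searched <- if (is.null(selection)) NULL else selection$searched_species

  edge_svgs <- character()
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    sp_xy <- anchor_xy(e)
    rn <- reaction_node_id(e$rule)
    rx_xy <- c(pos[rn, 1], pos[rn, 2])
    hi <- e$id %in% highlighted
    width <- style$edge_width * if (hi) style$highlight_width else 1
    opacity <- style$edge_opacity * if (hi) style$highlight_opacity else 1
    p0 <- if (e$role == "reactant") sp_xy else rx_xy
    p3 <- if (e$role == "reactant") rx_xy else sp_xy
    edge_svgs <- c(edge_svgs, edge_path_svg(
      p0, p3, e$occurrence_index, e$category, style, width, opacity,
      title = sprintf("%s (rate %s)", e$rule, format(e$rate_constant)),
      edge_id = e$id))
  }
  ov <- layout$visual_overrides
  # arrowhead orientation: reactant-anchor centroid -> product-anchor centroid
  rx_nodes <- graph$nodes[graph$nodes$kind == "reaction", , drop = FALSE]
  node_svgs <- character()
  for (i in seq_len(nrow(rx_nodes))) {
    id <- rx_nodes$id[i]
    re <- graph$edges[graph$edges$rule == rx_nodes$name[i], , drop = FALSE]
    cen <- function(role) {
      sub <- re[re$role == role, , drop = FALSE]
      if (nrow(sub) == 0L) return(c(pos[id, 1], pos[id, 2]))
      xy <- rowMeans(vapply(seq_len(nrow(sub)),
                            function(j) anchor_xy(sub[j, ]), numeric(2)))
      xy
    }
    dvec <- cen("product") - cen("reactant")
    len <- sqrt(sum(dvec^2))
    ang <- if (len > 0) atan2(dvec[2], dvec[1]) else 0
    r <- sz[id, 1] / 2
    tip <- c(pos[id, 1] + r * cos(ang), pos[id, 2] + r * sin(ang))
    baseang <- ang + pi
    wing <- 0.45
    b1 <- c(pos[id, 1] + r * cos(baseang + wing),
            pos[id, 2] + r * sin(baseang + wing))
    b2 <- c(pos[id, 1] + r * cos(baseang - wing),
            pos[id, 2] + r * sin(baseang - wing))
    col <- style$category_hue[[rx_nodes$category[i]]]
    node_svgs <- c(node_svgs, sprintf(
      '<g id="node-%s"><polygon points="%s,%s %s,%s %s,%s" fill="%s" stroke="#333333" stroke-width="0.8"><title>%s</title></polygon></g>',
      xml_escape(id), num(tip[1]), num(tip[2]), num(b1[1]), num(b1[2]),
      num(b2[1]), num(b2[2]), col, xml_escape(rx_nodes$name[i])))
  }
  side_panels <- character()
  for (i in seq_len(nrow(sp_nodes))) {
    id <- sp_nodes$id[i]
    states <- NULL
    sublabel <- NULL
    bonded_extra <- integer()
    o <- overlays[[id]]
    if (!is.null(o) && is.null(o$before)) {
      cx_obj <- model_complex(model, o$species, o$complex)
      states <- as.list(complex_state_vector(cx_obj))
      sublabel <- o$complex
      # bond status at the rule's bond sites: a reactant-side association
      # site is shown unbound-to-be-bound; product side carries its
      # structural bonds already, reactant dissociation sites are bound.
      if (!is.null(o$rule_sites)) bonded_extra <- o$rule_sites
    } else if (!is.null(o) && !is.null(o$before)) {
      # transformation: detached before/after panel at the right margin
      px <- xr[2] + pad + 40
      py <- yr[1] + 40 + 120 * length(side_panels)
      bf <- model_complex(model, o$species, o$before)
      af <- model_complex(model, o$species, o$after)
      panel <- c(sprintf('<g id="panel-%s">', xml_escape(id)),
                 sprintf('<rect x="%s" y="%s" width="150" height="100" fill="#FFFFF2" stroke="#888888"/>',
                         num(px - 10), num(py - 20)))
      yy <- py
      for (cx_obj in list(bf, af)) {
        panel <- c(panel, sprintf(
          '<text x="%s" y="%s" font-size="%s" fill="#1F3FBF">%s</text>',
          num(px), num(yy), num(style$font_size * 0.9),
          xml_escape(cx_obj$name)))
        sv <- complex_state_vector(cx_obj)
        for (j in seq_along(sv))
          panel <- c(panel, svg_square(px + (j - 1) * 14 + 6, yy + 12,
                                       style$square_side, sv[[j]]))
        yy <- yy + 44
      }
      side_panels <- c(side_panels, panel, "</g>")
    }
    node_svgs <- c(node_svgs, glyph_svg(
      plans[[id]], style, states = states, bonded_extra = bonded_extra,
      sublabel = sublabel,
      red_border = !is.null(searched) && sp_nodes$name[i] == searched,
      cx = pos[id, 1], cy = pos[id, 2], w = sz[id, 1], h = sz[id, 2],
      node_id = id))
  }

  paste(c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="%s %s %s %s">',
    num(vb[1]), num(vb[2]), num(vb[3]), num(vb[4])),
    '<g id="edges">', edge_svgs, "</g>",
    '<g id="nodes">', node_svgs, "</g>",
    if (length(side_panels)) c('<g id="panels">', side_panels, "</g>"),
    "</svg>"), collapse = "\n")
}
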