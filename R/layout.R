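# Three layout modes over the bipartite graph: force-directed (overview),
# level-based (reaction-distance bands below a reference species) and
# circular (the level layout folded onto concentric rings). Canvas
# convention: y grows downward for FORCE/LEVEL; CIRCULAR is centered at
# the origin with the mathematical (counterclockwise) angle convention.

LAYOUT_FORMAT_VERSION <- "1.0"

default_layout_params <- function() {
  list(level_spacing = 120, node_spacing = 110, ring_spacing = 160,
       ring_gap_pad = 20, gutter = 1, scale = 70,
       species_size = c(90, 60), reaction_size = c(16, 16),
       overlap_tol = 1e-6, overlap_max_iter = 500L)
}

merge_params <- function(params) {
  p <- default_layout_params()
  for (k in names(params)) p[[k]] <- params[[k]]
  p
}

node_size_matrix <- function(graph, p) {
  n <- nrow(graph$nodes)
  sizes <- matrix(0, n, 2, dimnames = list(graph$nodes$id, c("w", "h")))
  is_sp <- graph$nodes$kind == "species"
  sizes[is_sp, 1] <- p$species_size[1]
  sizes[is_sp, 2] <- p$species_size[2]
  sizes[!is_sp, 1] <- p$reaction_size[1]
  sizes[!is_sp, 2] <- p$reaction_size[2]
  sizes
}

new_layout <- function(mode, positions, sizes, reference = NULL,
                       visual_overrides = list()) {
  structure(list(mode = mode, positions = positions, sizes = sizes,
                 reference = reference, visual_overrides = visual_overrides),
            class = "network_layout")
}

#' @export
print.network_layout <- function(x, ...) {
  cat(sprintf("<network_layout mode=%s, %d nodes%s>\n", x$mode,
              nrow(x$positions),
              if (is.null(x$reference)) ""
              else sprintf(", reference '%s'", x$reference)))
  invisible(x)
}

resolve_reference <- function(graph, reference) {
  id <- if (reference %in% graph$nodes$id) reference
        else species_node_id(reference)
  row <- graph$nodes[graph$nodes$id == id, , drop = FALSE]
  if (nrow(row) != 1L || row$kind != "species")
    stop(sprintf("reference '%s' is not a species node of the graph",
                 reference), call. = FALSE)
  id
}

#' Reaction distances from a reference species
#'
#' The reaction distance of a species is the minimal number of reactions
#' on a path connecting it to the reference species, i.e. half the
#' shortest-path length in the bipartite graph with edges treated as
#' undirected (species-species paths always have even length). Reaction
#' nodes sit between levels: a reachable reaction node is assigned the
#' minimum of its adjacent species levels plus one half.
#'
#' @param graph a `reaction_graph`.
#' @param reference species name (or species node id).
#' @return an object of class `level_assignment`: `reference` (node id),
#'   `levels` (named numeric over species node ids, non-negative
#'   integers), `reaction_levels` (named numeric over reaction node ids,
#'   half-integers) and `unreachable` (node ids in no common component
#'   with the reference).
#' @export
#' @examples
#' g <- build_network_graph(gprotein_model())
#' reaction_distance(g, "Ligand")$levels[["s:Ligated Receptor"]]
reaction_distance <- function(graph, reference) {
  ref_id <- resolve_reference(graph, reference)
  ig <- as_igraph(graph)
  d <- igraph::distances(ig, v = ref_id, mode = "all")[1, ]
  ids <- graph$nodes$id
  d <- d[ids]
  is_sp <- graph$nodes$kind == "species"
  unreachable <- ids[!is.finite(d)]
  levels <- d[is_sp & is.finite(d)] / 2
  reaction_levels <- d[!is_sp & is.finite(d)] / 2
  structure(list(reference = ref_id, levels = levels,
                 reaction_levels = reaction_levels,
                 unreachable = unreachable),
            class = "level_assignment")
}

# ---- overlap removal ------------------------------------------------------

boxes_overlap <- function(p1, s1, p2, s2, tol = 1e-6) {
  ox <- (s1[1] + s2[1]) / 2 - abs(p1[1] - p2[1])
  oy <- (s1[2] + s2[2]) / 2 - abs(p1[2] - p2[2])
  if (ox > tol && oy > tol) c(ox, oy) else NULL
}

#' Count overlapping node-box pairs of a layout
#'
#' Nodes are axis-aligned boxes (`position` +/- `size/2`); used as the
#' overlap-freedom post-condition of every layout mode.
#'
#' @param layout a `network_layout`.
#' @param tol boxes intersecting by no more than `tol` canvas units count
#'   as separated.
#' @return number of intersecting pairs.
#' @export
count_overlaps <- function(layout, tol = 1e-6) {
  pos <- layout$positions
  sz <- layout$sizes
  n <- nrow(pos)
  bad <- 0L
  if (n < 2L) return(0L)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!is.null(boxes_overlap(pos[i, ], sz[i, ], pos[j, ], sz[j, ], tol)))
      bad <- bad + 1L
  }
  bad
}

# Iterative pairwise box separation along the connecting vector. For
# axis = "x" only horizontal pushes are applied (used by the level layout
# so level monotonicity in y cannot be disturbed).
remove_box_overlaps <- function(pos, sizes, axis = c("both", "x"),
                                max_iter = 500L, tol = 1e-6) {
  axis <- match.arg(axis)
  n <- nrow(pos)
  if (n < 2L) return(pos)
  for (iter in seq_len(max_iter)) {
    moved <- FALSE
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      ov <- boxes_overlap(pos[i, ], sizes[i, ], pos[j, ], sizes[j, ], tol)
      if (is.null(ov)) next
      moved <- TRUE
      dx <- pos[j, 1] - pos[i, 1]
      dy <- pos[j, 2] - pos[i, 2]
      if (axis == "x") {
        dir <- if (dx != 0) sign(dx) else 1
        push <- (ov[1] / 2 + tol) * dir
        pos[i, 1] <- pos[i, 1] - push
        pos[j, 1] <- pos[j, 1] + push
      } else if (ov[1] <= ov[2]) {  # cheaper to separate horizontally
        dir <- if (dx != 0) sign(dx) else if (i < j) 1 else -1
        push <- (ov[1] / 2 + tol) * dir
        pos[i, 1] <- pos[i, 1] - push
        pos[j, 1] <- pos[j, 1] + push
      } else {
        dir <- if (dy != 0) sign(dy) else if (i < j) 1 else -1
        push <- (ov[2] / 2 + tol) * dir
        pos[i, 2] <- pos[i, 2] - push
        pos[j, 2] <- pos[j, 2] + push
      }
    }
    if (!moved) break
  }
  pos
}

# ---- force layout ---------------------------------------------------------

#' Force-directed layout
#'
#' Spring-embedder (Fruchterman-Reingold) positions with iterative box
#' overlap removal; deterministic for a fixed seed; centered so the node
#' centroid is at the origin (a single node lands exactly at the origin).
#'
#' @param graph a `reaction_graph`.
#' @param seed integer seed for the embedder's random initialization.
#' @param params named list overriding [default_layout_params()] entries
#'   (`scale`, node sizes, `overlap_tol`, `overlap_max_iter`, ...).
#' @return a `network_layout` with `mode = "force"`.
#' @export
layout_force <- function(graph, seed = 1L, params = list()) {
  stopifnot(inherits(graph, "reaction_graph"))
  p <- merge_params(params)
  ids <- graph$nodes$id
  sizes <- node_size_matrix(graph, p)
  n <- length(ids)
  pos <- matrix(0, n, 2, dimnames = list(ids, c("x", "y")))
  if (n > 0L) {
    xy <- with_preserved_rng(seed, {
      ig <- as_igraph(graph)
      igraph::layout_with_fr(ig, niter = 500)
    })
    xy <- xy * p$scale
    pos[, 1] <- xy[, 1]
    pos[, 2] <- xy[, 2]
    pos <- remove_box_overlaps(pos, sizes, axis = "both",
                               max_iter = p$overlap_max_iter,
                               tol = p$overlap_tol)
    pos[, 1] <- pos[, 1] - mean(pos[, 1])
    pos[, 2] <- pos[, 2] - mean(pos[, 2])
  }
  new_layout("force", pos, sizes)
}

# ---- level layout ---------------------------------------------------------

level_values <- function(graph, reference) {
  la <- reaction_distance(graph, reference)
  lev <- c(la$levels, la$reaction_levels)
  if (length(la$unreachable)) {
    band <- if (length(lev)) max(lev) + 2 else 0
    lev[la$unreachable] <- band
  }
  lev[graph$nodes$id]
}

adjacency_list <- function(graph) {
  adj <- stats::setNames(vector("list", nrow(graph$nodes)), graph$nodes$id)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$from[i]
    b <- graph$edges$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Level-based layout
#'
#' Arranges nodes in horizontal bands by reaction distance to the
#' reference species: the reference sits alone at the top (minimal y) and
#' y grows with level (`y = level * level_spacing`, y-down canvas).
#' Reaction nodes occupy half-levels between their adjacent species
#' bands. Within a band, nodes are ordered by the barycenter of their
#' already-placed upper-level neighbors, ties (and nodes with no upper
#' neighbor) broken by node name; unreachable nodes are placed in a
#' trailing band. Residual overlap within a band is removed by horizontal
#' pushes only, so y remains a strict function of level.
#'
#' @inheritParams layout_force
#' @param reference species name (or species node id).
#' @return a `network_layout` with `mode = "level"`.
#' @export
layout_level <- function(graph, reference, params = list()) {
  stopifnot(inherits(graph, "reaction_graph"))
  p <- merge_params(params)
  ref_id <- resolve_reference(graph, reference)
  lev <- level_values(graph, ref_id)
  sizes <- node_size_matrix(graph, p)
  ids <- graph$nodes$id
  pos <- matrix(0, length(ids), 2, dimnames = list(ids, c("x", "y")))
  adj <- adjacency_list(graph)
  placed_x <- numeric()
  for (lv in sort(unique(lev))) {
    members <- ids[lev == lv]
    bary <- vapply(members, function(id) {
      up <- intersect(adj[[id]], names(placed_x))
      up <- up[lev[up] < lv]
      if (length(up)) mean(placed_x[up]) else Inf
    }, 0)
    members <- members[order(bary, node_label(members), method = "radix")]
    k <- length(members)
    x <- (seq_len(k) - (k + 1) / 2) * p$node_spacing
    pos[members, 1] <- x
    pos[members, 2] <- lv * p$level_spacing
    placed_x[members] <- x
  }
  pos <- remove_box_overlaps(pos, sizes, axis = "x",
                             max_iter = p$overlap_max_iter,
                             tol = p$overlap_tol)
  new_layout("level", pos, sizes, reference = ref_id)
}

# ---- circular layout ------------------------------------------------------

#' Circular layout
#'
#' Folds the level-based layout onto concentric rings: the reference
#' species is fixed at the center, and a node at level L lands on ring
#' `r = L * ring_spacing` at angle
#' `theta = 2*pi * (x - x_min) / (x_max - x_min + gutter)` where `x` is
#' its level-layout abscissa (so angular order on each ring equals the
#' level layout's left-to-right order). Ring radii are inflated beyond
#' the nominal `L * ring_spacing` when a ring could not otherwise hold
#' its nodes without box overlap, and are forced strictly increasing, so
#' distance from the center remains monotone in level. Angles follow the
#' mathematical counterclockwise convention.
#'
#' @inheritParams layout_level
#' @return a `network_layout` with `mode = "circular"`.
#' @export
layout_circular <- function(graph, reference, params = list()) {
  stopifnot(inherits(graph, "reaction_graph"))
  p <- merge_params(params)
  ref_id <- resolve_reference(graph, reference)
  base <- layout_level(graph, ref_id, params)
  lev <- level_values(graph, ref_id)
  sizes <- base$sizes
  ids <- rownames(base$positions)
  x <- base$positions[, 1]
  gutter <- p$gutter * p$node_spacing
  span <- max(x) - min(x) + gutter
  theta <- 2 * pi * (x - min(x)) / span

  pos <- matrix(0, length(ids), 2, dimnames = list(ids, c("x", "y")))
  prev_r <- 0
  prev_maxdim <- max(sizes[ref_id, ])
  for (lv in sort(unique(lev))) {
    members <- ids[lev == lv]
    if (lv == 0) { prev_r <- 0; next }  # reference ring: center point
    maxdim <- max(sizes[members, , drop = FALSE])
    r <- max(lv * p$ring_spacing,
             prev_r + (prev_maxdim + maxdim) / 2 + p$ring_gap_pad)
    if (length(members) > 1L) {
      th <- sort(theta[members])
      gaps <- c(diff(th), 2 * pi - (th[length(th)] - th[1]))
      need <- maxdim + p$ring_gap_pad
      for (g in gaps) {
        if (g <= 0) next
        r_need <- if (g >= pi) need / 2 else need / (2 * sin(g / 2))
        r <- max(r, r_need)
      }
    }
    pos[members, 1] <- r * cos(theta[members])
    pos[members, 2] <- r * sin(theta[members])
    prev_r <- r
    prev_maxdim <- maxdim
  }
  new_layout("circular", pos, sizes, reference = ref_id)
}

# ---- persistence ----------------------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

#' Save a layout to the auxiliary-file format
#'
#' The auxiliary layout file persists node positions (bit-exact, as
#' decimal strings), node sizes, and visual attribute overrides (e.g. an
#' edge width), so that a visualization can be regenerated identically
#' when the file accompanies the model.
#'
#' @param layout a `network_layout` covering the graph's nodes.
#' @param graph the `reaction_graph` the layout belongs to.
#' @return a JSON string.
#' @export
save_layout <- function(layout, graph) {
  stopifnot(inherits(layout, "network_layout"),
            inherits(graph, "reaction_graph"))
  missing <- setdiff(graph$nodes$id, rownames(layout$positions))
  if (length(missing))
    stop(sprintf("layout does not cover graph nodes: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ids <- rownames(layout$positions)
  positions <- lapply(stats::setNames(ids, ids), function(id)
    c(fmt_num(layout$positions[id, 1]), fmt_num(layout$positions[id, 2])))
  sizes <- lapply(stats::setNames(ids, ids), function(id)
    c(layout$sizes[id, 1], layout$sizes[id, 2]))
  overrides <- layout$visual_overrides
  if (length(overrides) == 0L) overrides <- stats::setNames(list(),
                                                            character())
  doc <- list(format_version = jsonlite::unbox(LAYOUT_FORMAT_VERSION),
              mode = jsonlite::unbox(layout$mode),
              reference = if (is.null(layout$reference)) NULL
                          else jsonlite::unbox(layout$reference),
              positions = positions, sizes = sizes,
              visual_overrides = overrides)
  paste0(as.character(jsonlite::toJSON(doc, pretty = 2, digits = NA,
                                       null = "null", auto_unbox = TRUE)),
         "\n")
}

#' Load a layout from the auxiliary-file format
#'
#' Positions are restored bit-exactly. If the graph's node set differs
#' from the file's, a reconciliation diff is attached (attribute
#' `"reconciliation"`, components `missing` and `extra`) with a warning:
#' nodes absent from the file are positioned by a fallback force pass,
#' extra file entries are dropped, and all other positions are left
#' untouched.
#'
#' @param text JSON text produced by [save_layout()].
#' @param graph the `reaction_graph` to reconcile against.
#' @param fallback_seed seed for the fallback force pass.
#' @return a `network_layout`.
#' @export
load_layout <- function(text, graph, fallback_seed = 1L) {
  stopifnot(inherits(graph, "reaction_graph"))
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  for (k in c("format_version", "mode", "positions", "sizes"))
    if (is.null(doc[[k]]))
      stop(sprintf("malformed layout file: key '%s' missing", k),
           call. = FALSE)
  ids <- graph$nodes$id
  file_ids <- names(doc$positions)
  missing <- setdiff(ids, file_ids)
  extra <- setdiff(file_ids, ids)
  p <- merge_params(list())
  pos <- matrix(0, length(ids), 2, dimnames = list(ids, c("x", "y")))
  sizes <- node_size_matrix(graph, p)
  for (id in intersect(ids, file_ids)) {
    pos[id, ] <- as.numeric(unlist(doc$positions[[id]]))
    if (!is.null(doc$sizes[[id]]))
      sizes[id, ] <- as.numeric(unlist(doc$sizes[[id]]))
  }
  if (length(missing)) {
    fb <- layout_force(graph, seed = fallback_seed)
    off <- if (length(intersect(ids, file_ids)))
      max(pos[intersect(ids, file_ids), 1]) + p$node_spacing else 0
    pos[missing, 1] <- fb$positions[missing, 1] + off
    pos[missing, 2] <- fb$positions[missing, 2]
  }
  overrides <- doc$visual_overrides
  if (is.null(overrides)) overrides <- list()
  out <- new_layout(doc$mode, pos, sizes,
                    reference = if (is.null(doc$reference)) NULL
                                else doc$reference,
                    visual_overrides = overrides)
  if (length(missing) || length(extra)) {
    warning(sprintf(
      "layout/graph node sets differ (%d missing from file, %d extra)",
      length(missing), length(extra)), call. = FALSE)
    attr(out, "reconciliation") <- list(missing = missing, extra = extra)
  }
  out
}
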