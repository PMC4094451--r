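---
title: "Visualizing rule-based reaction networks as bipartite species–reaction graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visualizing rule-based reaction networks as bipartite species–reaction graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulenet)
```

## The model class

`rulenet` operates on rule-based models of multi-component, multi-state
molecular complexes. The data model has three layers:

* **Molecules** have named components (sub-domains). Each component
  declares ordered *binding sites* (drawn as indexed circles, filled when
  bound and joined to their partner by a blue line) and ordered *state
  variables* (drawn as squares) taking the tri-state values `"on"`,
  `"off"` or `"dont_care"`. State variables stand for binary biochemical
  properties — a phosphorylation, a conformation, a bound-ligand flag.
* A **complex species** is a structural prototype: an ordered set of
  molecule instances plus a set of structural bonds between site indices.
  Its **complexes** are state-specific instances; all complexes of one
  species share the structure and differ only in their (total) assignment
  of tri-state values. Site indices are 1-based per species, assigned in
  declaration order across molecule instances and components; the
  numbering is a package convention — the graphical tradition displays
  indices but leaves the scheme open.
* **Reaction rules** rewrite complexes in one of three categories:
  association (2 reactants → 1 product, forming a bond between two named
  sites), dissociation (1 → 2, dissolving a bond) and transformation
  (1 → 1, changing states only, never touching binding sites). Rules
  reference explicitly declared complexes; because rule-side complexes
  are patterns, they may legitimately carry `"dont_care"` states. Rate
  constants are stored as single non-negative numbers for reporting
  (edge tool-tips) and are never integrated — kinetics are out of scope.

Complexes are curated, not enumerated: the package never expands the
combinatorial state space of a species. Two complexes of one species
with identical state maps are flagged by the validator as a warning
rather than an error, since nothing in the formalism forbids aliases.

Models round-trip through a versioned JSON dialect (schema in
`inst/extdata/model-schema.json`; YAML is accepted on input). The
constructor normalizes entity order (C-locale name order), which makes
serialization canonical: equal content gives byte-identical documents.
Validation is complete rather than fail-fast — every violation is
reported with a machine-readable code and a JSON-pointer-style path.
Cross-references are case-sensitive; only the name *filter* is
case-insensitive, because filtering mimics a user typing a fragment
while linking must be deterministic.

## The bipartite graph

The network overview is a directed bipartite multigraph: one node per
complex species, one intermediate node per rule. Each reactant
occurrence contributes a species→reaction edge, each product occurrence
a reaction→species edge, so

* `n_nodes = n_species + n_rules`, and
* `n_edges = 3(A + D) + 2T` by category arity.

We keep one edge per *occurrence*, not per distinct species: a
homotypic rule (the same species twice on the left) yields two parallel
edges distinguished by `occurrence_index`. Collapsing them would break
the edge-count identity above, and occurrence multiplicity is what a
reader needs to see for dimerization-style rules.

Association and dissociation edges are anchored at the binding site the
rule's `bond_sites` name in that species. Product-side edges have no
site reference of their own, so the anchor is resolved by *molecular
identity*: the product species' lowest-indexed site with the same
(molecule, component, site name) as a bonded reactant site. The same
identity notion drives `edges_at_site()`, so querying a reactant-side
site returns both halves of a bond's edge pair. Transformation edges
anchor at node centers — they involve no sites by definition.

## Layouts

Three modes, all pure functions of `(graph, mode, reference, seed,
params)`:

* **Force** (`layout_force`): Fruchterman–Reingold via igraph under a
  fixed seed, scaled to canvas units, then iterative pairwise box
  separation (at most 500 iterations, tolerance 10⁻⁶ canvas units) until
  no two node rectangles intersect. Positions are centered on the node
  centroid, so a single-node graph sits exactly at the origin.
* **Level** (`layout_level`): bands by *reaction distance* — the minimal
  number of reactions between a species and the chosen reference
  species, i.e. half the undirected bipartite shortest-path length.
  The reference is alone at the top (y-down canvas, `y = level ×
  level_spacing`); reaction nodes sit at half-levels between their
  adjacent species bands (`min(adjacent species level) + 0.5` — the
  formalism shows arrows between bands but prescribes no rule, so the
  midpoint is our choice). Within a band, nodes are ordered by the
  barycenter of their upper-level neighbors with name tie-breaks; this
  is a deliberate, reproducible stand-in for whatever ordering an
  external layered layout engine would pick, and it is why the package
  does not promise to reproduce any particular published drawing's
  geometry. Disconnected nodes go to a trailing band. Overlap removal
  here only pushes horizontally, so y remains a strict function of
  level.
* **Circular** (`layout_circular`): the level layout folded onto
  concentric rings — radius `level × ring_spacing`, angle `2π(x −
  x_min)/(x_max − x_min + gutter)` from the level layout's abscissa, so
  angular order on every ring equals the band's left-to-right order.
  Two numerical guards keep the overlap-freedom invariant without
  breaking monotonicity: radii are forced strictly increasing across
  rings (by at least half the adjacent rings' node extents plus a pad),
  and a ring is inflated when the chord between its closest two nodes
  could not hold them. Rings therefore stay exactly circular (equal
  radius within a ring) and radius stays monotone in level.

Default spacings (110 canvas units between nodes in a band, 120 between
bands, 160 between rings, species boxes 90×60, reaction arrows 16×16)
are chosen so the spacing alone separates default-sized nodes and the
overlap pass is normally a no-op.

Layouts persist to an auxiliary JSON file: positions are written as
17-significant-digit decimal strings so a round-trip is bit-exact, and
visual attribute overrides (e.g. a per-edge width) travel with them.
Manual adjustment is an API edit of the layout object followed by
`save_layout()`. Loading against a graph whose node set changed is not
fatal: the diff is reported, new nodes are placed by a fallback force
pass, and all surviving positions are untouched.

## Queries and selection semantics

Tri-state matching is symmetric overlap: two values match when either is
`"dont_care"` or they are equal. The query side of this rule is standard
(an unconstrained search square matches both stored values); we apply
the same rule to the stored side because rule-pattern complexes may
carry `"dont_care"` and must remain searchable. This symmetric choice is
the package's own and is the one place the matching relation goes beyond
the obviously forced definition.

`search_species()` restricts matches to the pattern's species, marks it
for red-border rendering, and highlights every rule with a matching
reactant or product complex plus all edges of those rules — an edge is
only ever highlighted through its rule. `filter_by_name()` is
case-insensitive substring matching with a `child_match` state for a
species whose own name misses but whose child complex hits;
`filter_by_molecule()` is hereditary by construction (a complex contains
a molecule iff its species does), so species and complexes always agree
and `child_match` cannot occur there. Relaxing any pattern constraint to
`"dont_care"` can only grow the match set — monotonicity is covered by a
property test.

## Rendering

SVG output is deterministic (stable element order and ids; identical
inputs give identical bytes). Species glyphs stack one ellipse per
component, site circles with their indices (filled when structurally
bonded, or when a selected rule bonds them), and state squares — filled
for `"on"`, open for `"off"`, half-filled for `"dont_care"`, gray-open
when no complex is overlaid. Reaction nodes are arrowheads pointing from
the centroid of their reactant anchors to the centroid of their product
anchors. Edges are cubic Béziers (control points at 1/3 and 2/3 of the
chord, perpendicular offset alternating sign with `occurrence_index` so
parallel edges separate); since SVG has no along-path gradients, the
direction-encoding saturation ramp (low at the source, high at the
target, hue fixed per category: green associations, orange
dissociations, purple transformations) is realized as eight quadratic
sub-segments, each stroked with the midpoint color of its parameter
interval. Selections thicken and opacify edges, overlay complexes and
blue name sublabels, and render a transformation's before/after pair in
a detached side panel — the static equivalent of a hovering detail
frame. DOT and GraphML exports carry the full node/edge attribute set
and round-trip to isomorphic graphs (verified in tests with independent
readers).

## Synthetic models and what the tests show

`random_model()` generates single-molecule species with 1–3 sites, up to
two state variables and 1–3 distinct-state complexes, then samples rules
by category weights over the declared (species, complex) pairs,
respecting arity and drawing bond sites from the reactant species where
available. It emulates the *referential* structure of real models — and
therefore exercises validation, graph construction, queries, layouts and
exports — but not their chemistry: product species are not the
structural merge of their reactants, and bond topology across species is
not conserved. Passing property suites consequently demonstrates
structural correctness of the graph/query/layout machinery, not
biological plausibility of arbitrary inputs. Generation is a pure
function of its spec (seed included), which the determinism tests rely
on.

Property suites run on seeded batches (200 models of 3 species / 4 rules
for the query-oracle equivalences, 8–20 larger models elsewhere) — sizes
chosen so the full suite stays interactive while still covering every
category combination many times over.

## Reference models

The G-protein fixture encodes the canonical ligand → receptor →
heterotrimeric G-protein story: receptor ligation (intracellular
activity off → on), ligand dissociation (the reverse), receptor-mediated
GDP/GTP exchange on Gα (a transformation), receptor/G-protein coupling
and release, trimer dissociation into Gα-GTP and Gβγ, trimer
reformation, GTP hydrolysis, receptor desensitization and effector
deactivation — 8 species, 11 rules, hence 19 nodes and 29 edges. Only
the first three rules are fixed by the underlying narrative; the
completion is tagged `"fixture-completion"` in `metadata$rule_provenance`
so tests can separate core content from scaffolding. The receptor
desensitization rule deliberately links the complexes `Rec inactive
unbound → Receptor_2` so that `Rec inactive` itself participates in
exactly two reactions while the intracellular-off search touches three.

The EGFR fixture implements simultaneous-adaptor-binding constraints on
the phosphorylated EGFR cytoplasmic domain: Stat5 → pY992 and Grb2 →
pY1068 unconditioned; PLCγ1 → pY992 requires `bndPLCg992` and
`bndPLCg1173` off; PLCγ1 → pY1173 additionally requires `bndSHC1148`
off; Shc → pY1148 requires `bndSHC1148` and `bndPLCg1173` off. The
fifth EGFR site is an unused membrane anchor; no conditions are imposed
on Shc → pY1173 because none are specified; receptor dimerization is
deliberately out of scope. Bound-product species are named
`EGFR_<Adaptor>_<site>`.

## Known limitations

* No structural pattern matching (bond-topology queries) beyond declared
  complexes, no rule expansion into concrete reaction instances, no
  reachability or stoichiometry analysis, and no kinetic simulation.
* The validator checks referential and arity invariants, not chemical
  consistency of products with reactants.
* Layout quality: no edge-crossing minimization; overlap removal
  guarantees separation, not aesthetics; exact published drawings of
  comparable tools are not reproduced (within-band ordering is
  heuristic, see above).
* SVG rendering targets correctness and determinism; label de-overlap
  beyond node separation is not attempted.
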