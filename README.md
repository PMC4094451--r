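# rulenet

Bipartite species–reaction graphs for rule-based models of
multi-component, multi-state molecular complexes.

## The problem

Cell-signaling models written in rule-based frameworks describe molecules
with binding sites and tri-state state variables ("on", "off", "don't
care"), *complex species* (structural prototypes: a fixed set of molecules
and bonds) whose *complexes* differ only in component states, and
categorized reaction rules:

* **association** — two reactant complexes form a bond: 2 → 1;
* **dissociation** — a bond is dissolved: 1 → 2;
* **transformation** — only component states change: 1 → 1 (no binding
  sites involved).

Drawing one node per biochemically distinct complex makes such networks
unreadable. `rulenet` instead builds the compact **directed bipartite
species–reaction graph**: one node per complex species, one intermediate
node per reaction rule, and an edge per reactant occurrence (species →
reaction) and product occurrence (reaction → species). The node count is
therefore exactly

```
n_nodes = n_species + n_rules
n_edges = 3·(A + D) + 2·T
```

for A associations, D dissociations and T transformations. Association
and dissociation edges are anchored at the binding site the rule bonds or
dissolves; transformation edges point at node centers.

On top of the graph the package provides the query layer a modeler needs
to read such a model — name and molecule filters, tri-state pattern search
with don't-care semantics, reaction/complex selection with rule-condition
overlays — plus three deterministic layouts (force-directed, level-based
by reaction distance to a reference species, and circular), layout
persistence in an auxiliary JSON file, and deterministic SVG / DOT /
GraphML export with contact-map-style glyphs.

It ships two programmatically constructed reference models: a
ligand/receptor/heterotrimeric G-protein cycle (8 species, 11 rules) and
an EGFR adaptor-binding model (11 species, 6 association rules) in which
three EGFR state variables encode which adaptors (Grb2, PLCγ1, Stat5,
Shc) may bind the phosphotyrosines pY992/pY1068/pY1148/pY1173
simultaneously.

## Worked example

```r
library(rulenet)

m <- gprotein_model()
g <- build_network_graph(m)
graph_stats(g)
#> nodes: 19 (8 species + 11 reactions)
#> edges: 29
#> rules: 3 association, 4 dissociation, 4 transformation
```

19 nodes are the 8 complex species plus the 11 reactions; 29 edges are
3·(3+4) + 2·4. Which reactions involve the inactive receptor complex?

```r
reactions_of_complex(m, g, c("Receptor", "Rec inactive"))
#> [1] "ligand dissociation" "receptor ligation"
```

Search the Receptor species for complexes whose intracellular component
is "off" (a don't-care query square matches both stored values):

```r
sel <- search_species(m, g, state_pattern(
  "Receptor", c("rec/intracellular/active" = "off")))
sel$matching_complexes
#> [1] "Rec inactive"         "Rec inactive unbound" "Receptor_2"
sel$highlighted_rules
#> [1] "ligand dissociation"      "receptor desensitization"
#> [3] "receptor ligation"
```

Lay the network out in concentric rings around the ligand and render it:

```r
lay <- layout_circular(g, "Ligand")
svg <- render_svg(m, g, lay, selection = sel)
writeLines(svg, "gprotein.svg")
```

In the EGFR model, searching with `bndPLCg992 = "on"` (a PLCγ1 already
bound) highlights four association rules, none of which binds PLCγ1 —
the mutual-exclusion constraint is visible directly in the network:

```r
me <- egfr_model(); ge <- build_network_graph(me)
search_species(me, ge, state_pattern(
  "EGFR", c("egfr/cytoplasmic/bndPLCg992" = "on")))$highlighted_rules
#> [1] "Grb2 binds EGFR pY1068" "Shc binds EGFR pY1148"
#> [3] "Shc binds EGFR pY1173"  "Stat5 binds EGFR pY992"
```

The same operations are available from a shell via the thin wrapper
`inst/cli/netview` (subcommands `fixtures`, `stats`, `layout`, `query`,
`search`, `render`).

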