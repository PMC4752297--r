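---
title: "Topology analysis of process-description disease maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology analysis of process-description disease maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdnet)
```

## The problem

Curated disease maps — large CellDesigner drawings of everything known
about a disease's molecular biology — are written in the SBGN
process-description (PD) notation. PD is a hypergraph: each reaction node
connects a set of reactants, a set of products and a set of modifiers, so
standard graph-theoretic machinery does not apply directly. To ask
questions like *which molecules sit on the most signalling routes?* the
map must first be flattened into an ordinary graph.

pdnet implements that flattening and the downstream topology analysis:

1. **Binarisation.** Every reaction is decomposed into binary relations:
   one reactant→product pair per (reactant, product) combination and one
   modifier→product pair per (modifier, product) combination; reversible
   reactions additionally contribute the product→reactant pairs. The
   relation universe is then restricted to six molecule classes —
   proteins, complexes, genes, RNAs, simple molecules and phenotypes —
   because ions and degraded products are ubiquitous small participants
   that would create shortcuts with no pathway meaning. Self-loops
   (e.g. a transport recorded under one species id) are removed and
   parallel relations between the same node pair collapse into a single
   edge that retains the identity of every supporting reaction.
2. **Betweenness centrality.** For a node $v$,
   $$C_B(v) = \sum_{s \ne v \ne t} \frac{\sigma_{st}(v)}{\sigma_{st}},$$
   where $\sigma_{st}$ counts shortest $s$–$t$ paths and
   $\sigma_{st}(v)$ those passing through $v$; the edge version sums
   $\sigma_{st}(e)/\sigma_{st}$ over all pairs. High-betweenness nodes
   are the molecules that bridge otherwise distant parts of the map;
   high-betweenness edges form its backbone, the "primary pathway".
3. **Derived networks.** The top-$k$ edges by edge betweenness (default
   $k = 50$) form the primary pathway; the $k$-hop neighbourhood around
   named seed molecules (default two hops around "Ceramide" and
   "Inflammation") isolates the part of the map connecting them, and edge
   betweenness is **recomputed** inside that subnetwork before its own
   top-$k$ edges are reported.

## Conventions that change numbers

Every one of the following is recorded in the run manifest, because each
can change a reported score.

* **Directedness.** Relations are intrinsically directed
  (source→product), and the graph stores that direction, but the default
  analysis treats edges as undirected: undirected shortest paths are the
  common convention for pathway-topology betweenness, and they keep
  "two hops from A and B" symmetric. A `directed = TRUE` switch is
  provided throughout.
* **Normalisation.** Node scores are reported normalised by the number
  of eligible pairs — $(n-1)(n-2)/2$ undirected, $(n-1)(n-2)$ directed —
  with $n$ the node count of the *whole* graph, also on disconnected
  graphs (unreachable pairs simply contribute 0). Edge scores are
  reported raw, since only their ranking is used. Both are togglable.
* **Endpoint exclusion.** Path endpoints are never counted as
  intermediates: $\sigma_{st}(v)$ requires $v \notin \{s, t\}$.
* **Merge-by-name.** CellDesigner maps often carry the same biological
  entity as several species (one per compartment); transport reactions
  connect them. By default, species sharing a whitespace-normalised
  display name *and* molecule class merge into one node — the refinement
  over name-only merging prevents a gene and its protein, which usually
  share a label, from collapsing into one node. `merge_by_name = FALSE`
  keys nodes by species id instead.
* **Tie-breaking.** Edge rankings break score ties lexicographically on
  the sorted (source label, target label) pair, so rankings are
  deterministic and reproducible byte for byte.
* **Hop distance** is always measured on the undirected skeleton, even
  when the centrality analysis is directed.

## The algorithm and its validation

Node and edge betweenness are computed in one pass of Brandes'
single-source accumulation algorithm (the unweighted, breadth-first
variant; exact, $O(nm)$), implemented in C++. Dependencies are
accumulated in double precision; scores are rounded only at presentation
time.

Correctness is established by a dual oracle in the test suite:
`brute_force_betweenness()` recomputes both score sets by literally
enumerating every shortest path of every pair (breadth-first search plus
backtracking through the predecessor DAG) and crediting each path
fractionally — an implementation that shares no code with the Brandes
pass and refuses graphs above 15 nodes — and `igraph`'s independent
implementations serve as a second, external cross-check. The suite
verifies agreement to $10^{-9}$ on hundreds of random graphs, together
with structural invariants: degree-1 nodes score zero, scores are
invariant under node relabelling, and the total edge-betweenness mass of
a graph equals the sum of shortest-path distances over all connected
pairs (every unit of distance is carried by exactly one edge of some
shortest path, fractionally across ties).

## The synthetic-map generator

Real curated maps are distributed under their own terms, so the package
ships a generator that emulates their *composition* and provides ground
truth for recovery tests. `make_alzpathway_like_config()` reproduces the
published census of a large Alzheimer's disease map — 721 proteins, 246
complexes, 300 simple molecules, 33 genes, 37 RNAs, 24 ions, 23 degraded
products and 138 phenotypes, with 1,124 reactions across nine types led
by 472 state transitions — 1,522 species in all. (The source publication
prints totals of "1,538 species" and "1,127 reactions" that disagree
with its own breakdowns, which sum to 1,522 and 1,124; the generator
follows the breakdowns, the only figures that are mutually consistent,
and the census functions always report raw counts.)

Wiring is the generator's own model, chosen because no topology
statistics of the real map are published:

* Participants are sampled with probability proportional to
  $1 + \mathrm{degree}$, a preferential-attachment rule that yields the
  heavy-tailed degree structure typical of curated maps.
* Arities default to 1–3 reactants, 1–2 products and 0–2 modifiers,
  skewed toward small reactions; structurally fixed types override this
  (heterodimer association 2→1, dissociation 1→2, transport and the
  genetic-information reactions 1→1). Transcription prefers gene
  reactants and RNA products, translation RNA reactants and protein
  products, when those classes exist.
* Phenotypes appear only in product roles: they are outcome states, not
  reactants. Configurable.
* Reactions are reversible with probability 0.1 — a minority, as in
  curated signalling maps; under the undirected default this only
  affects provenance, not scores.
* **Planted hubs** are nodes the generator keeps wiring into reactions
  until they reach a target degree; they provide known-truth
  high-centrality nodes. The map-scale preset plants an "amyloid-β"-like
  protein (degree 60), a "Ceramide"-like simple molecule (degree 40) and
  an "Inflammation" phenotype (degree 12), so the default seed
  subnetwork has its anchors and the two molecule hubs dominate the
  centrality ranking the way the corresponding real molecules do.

For the hub-recovery property the test conditions follow the real map's
shape: 100 species, 75 reactions (the real reaction:species ratio is
about 0.74), one planted degree-20 hub; the hub must reach the top 3 by
node betweenness in at least 18 of 20 generator seeds.

What passing these tests shows — and does not show. The generator
reproduces class composition, reaction-type composition, arity ranges
and a heavy-tailed background; it does not reproduce the real map's
modular structure, pathway annotations, compartment layout or
degree-degree correlations. Recovery results therefore validate the
pipeline's mechanics (parsing, binarisation, centrality, extraction),
not any biological claim about a particular disease map.

## Worked example

```{r example, eval = FALSE}
library(pdnet)

out <- tempfile("run")
res <- run_pipeline(run_config(preset = "alzpathway-like",
                               out_dir = out, seed = 1))

# census of the synthesised map
census_species(res$map)$counts

# top of the node-betweenness ranking
head(res$centrality$nodes[order(-res$centrality$nodes$normalized), ])

# the primary pathway and the seed subnetwork
res$primary[1:5, ]
res$subnetwork
```

On the map-scale preset this runs in a few seconds on one CPU: the
binary graph has roughly 900 nodes and 2,400 edges, the planted
amyloid-β and Ceramide hubs rank first and second by normalised node
betweenness, and the two-hop subnetwork around Ceramide and Inflammation
covers the well-connected core of the graph. Exact values for a given
seed are written to `node_betweenness.tsv` and `manifest.json` in the
output directory.

## Degenerate inputs and numerical choices

* An empty graph is an error; normalised scores on fewer than three
  nodes are defined as zero (with a warning) since no pair has an
  intermediate.
* Graphs must be simple before centrality; `build_binary_graph()`
  guarantees this, and the centrality functions verify it.
* Reactions with empty product lists decompose to nothing, with a
  warning; parse-time warnings (unknown CellDesigner classes, dangling
  references) are collected on the returned map object rather than
  silently dropped. Unrecognised classes can be remapped through an
  explicit `class_map`; the default is exclusion, because admitting an
  unknown class silently would change the node universe.
* Seed labels resolve case-insensitively after whitespace
  normalisation; unresolvable seeds error with near-miss suggestions,
  ambiguous ones with the full match list.

## Known limitations

* Modifier semantics are uniform: catalysis, inhibition and unknown
  modification all map to one modifier→product rule; signs are carried
  as edge metadata only, and no signed or weighted analysis is offered.
* Complexes are single nodes; their internal composition is ignored.
* SBML Level 3 and SBGN-ML inputs are out of scope; the parser requires
  the CellDesigner annotation namespace and rejects plain SBML
  explicitly.
* Betweenness is the only centrality provided, exactly, with no
  sampling; maps beyond roughly $10^5$ edges would need approximate
  methods this package deliberately omits.
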