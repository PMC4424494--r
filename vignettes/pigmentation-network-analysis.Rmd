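---
title: "Modelling UV-mediated skin pigmentation as a directed signalling network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling UV-mediated skin pigmentation as a directed signalling network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigmentnet)
```

## The model

Ultraviolet radiation triggers signalling cascades in epidermal
keratinocytes that, through secreted paracrine factors, drive melanocytes
to synthesise melanin, grow dendrites, and hand melanosomes back to
keratinocytes for phagocytosis. `pigmentnet` represents this biology as a
**directed typed graph**: nodes are proteins, small molecules, complexes,
biological end processes and environmental triggers; edges are curated
directed interactions carrying a type from a small controlled vocabulary
(`activates`, `inhibits`, `induces`, `increases level`,
`increases expression`, `decreases level`, `decreases expression`,
`third molecule regulation`). Compartment membership is encoded in the
node id itself — a terminal `_kerat` or `_melan` suffix — so paracrine
signalling appears as edges whose endpoints carry different suffixes.
Complexes are written with members separated by colons
(`RAC1:PARD6A:CDC42_melan`).

Three analyses sit on top of the graph:

1. **Topology**: in/out degree distributions, hub identification,
   node and edge betweenness, a reachable-set closeness, and radiality.
2. **Route enumeration**: shortest directed paths from designated
   *sources* (UV triggers and membrane receptors, in-degree ~0) to
   *targets* (phenotypic end processes such as eumelanin synthesis or
   melanosome phagocytosis, out-degree 0), and the S2T sub-network these
   routes induce.
3. **Virtual knockouts**: remove one candidate node at a time, recompute
   every source→target route, and classify each pair as *abrogated*
   (signal can no longer arrive), *rerouted* (arrives via an alternate
   route) or *unchanged*. A node's **essentiality count** is the number of
   baseline-connected pairs its removal abrogates.

### Assumptions

* **Unit edge weights.** Every interaction counts equally; a shortest
  path is a minimum-hop route. No kinetic or confidence weighting.
* **Sign-blind traversal.** Inhibitory edges are walked exactly like
  activating ones: an inhibition transmits information no less than an
  activation does, and the curated analyses treat sign as annotation.
  Consequently "signal arrives" means *some causal chain exists*, not
  that the net effect is positive.
* **Static structure.** No dynamics, no dose, no time. A knockout is a
  purely structural deletion of a node and its incident edges.
* **Merged parallel edges.** Duplicate curated rows for the same ordered
  node pair merge into one edge holding the union of their types, so the
  edge count is the number of distinct ordered pairs.

## Numerical and procedural choices

**Canonical tie-breaking.** Unit weights make ties common. Among routes
of minimal length the package deterministically reports the
lexicographically smallest node sequence; `all_shortest_paths()` exposes
the full tied set. Every published route table can then be reproduced
byte-for-byte by anyone running the same inputs.

**Closeness and radiality on a graph that is not strongly connected.**
Unreachable pairs must contribute something or nothing; we adopt the
reachable-set convention. With `r` the number of nodes reachable from
`v`, `n` the node count and `d(v,w)` directed distances,

* closeness: `(r / (n-1)) * (r / sum of d(v,w) over reachable w)`, and 0
  when `v` reaches nothing;
* radiality: `sum over reachable w of (D + 1 - d(v,w)) / (n-1)`, where
  `D` is the finite directed diameter.

Both reduce to the textbook definitions on strongly connected graphs.
Betweenness splits each ordered pair's contribution equally among its
tied shortest paths (the standard Brandes convention), which is what the
exhaustive-enumeration oracle in the test-suite computes independently.

**Knockout classification against the tied set.** A pair is *rerouted*
when the removed node lay on at least one baseline shortest route and the
pair stays connected, *unchanged* when it lay on none (every baseline
shortest route survives verbatim), *abrogated* when the pair disconnects,
and *not applicable* when the pair was disconnected at baseline or the
removed node is itself the source or target. Classifying against the
full tied set rather than only the canonical route matters: removing one
of two equally short parallel receptors (e.g. PTGER3 beside PTGER1) is a
genuine rerouting of the curated control route even when the canonical
(alphabetically first) route happens to survive. For an affected pair
the reported baseline route is the lexicographically smallest baseline
shortest route *through the removed node* — the route the perturbation
actually severed, which is how the published control/alternate tables
present it. Essentiality counts abrogations only; rerouting is reported
but never counted, and a source or target is never scored on its own
pairs.

**Self-loops and degenerate inputs.** Self-loops are kept (flagged) and
contribute one to both in- and out-degree, but never appear in shortest
routes — the zero-length path always wins. Empty networks yield empty
profiles; an empty candidate set, empty designation sets, unknown ids and
malformed tables raise classed errors (`pigmentnet_schema_error`,
`pigmentnet_lookup_error`, `pigmentnet_value_error`,
`pigmentnet_consistency_error`) so drivers can map failure modes to
distinct exit paths.

**Name normalisation.** Node names are trimmed and internal whitespace
runs become single underscores; case is preserved because ids are
case-significant. Interaction types are case-folded (the curated sample
table itself mixes `Increases level` and `increases level`). The
compartment suffix is recognised only terminally.

## Packaged fixtures

Three desk-scale inputs ship with the package, stored as plain TSV and
pinned by checksum in the tests:

* `table1_fixture()` — the published 20-row sample of the curated
  interaction table (21 nodes).
* `table2_designations()` — the 20 curated sources and 9 end-process
  targets.
* `printed_paths_fixture()` — the union of every published predicted,
  control and alternate route string (60 nodes, 65 edges). Routes are
  parsed from the arrow dialect `A- > B- > C`. Two editorial quirks of
  the printed tables are kept deliberately: composite route terminals
  ("eumelanin / pheomelanin") are split into one route per terminal, and
  the distinct spellings of the melanogenesis end process
  (`melanogenesis`, `Melanogensis`) remain distinct nodes — merging them
  would invent curation the source tables do not state. Likewise `UV`,
  `UVA` and `UVB` stay three distinct triggers exactly as printed, and
  all three are designated sources. Path strings carry no interaction
  types, so fixture edges are typed `activates` uniformly.

The full 265-node/429-edge curated model lives in supplementary data
files that are not part of the package; analyses that depend on it (the
33,779 all-vs-all connected pairs, the 157 source→target routes, the
127-node/150-edge S2T sub-network, the full essentiality ranking) are
therefore demonstrated here at fixture scale, while the machinery —
`all_pairs_connectivity()`, `source_target_paths()`,
`extract_s2t_subnetwork()`, `essentiality_scan()` — accepts the full
table unchanged via `parse_interaction_table()` whenever a user supplies
it.

## The synthetic generator

`generate_network(synthetic_spec(...))` produces seeded two-compartment
layered networks with the structural properties the analyses assume:
layer 1 holds zero-in-degree trigger/receptor sources, the last layer
zero-out-degree biological end processes, and every non-source node draws
one incoming edge from the previous layer (which guarantees every end
process is reachable from at least one source) plus a Poisson number of
further incoming edges from earlier layers.

Parameters, with defaults chosen to mirror the curated model's scale:

| parameter | default | meaning |
|---|---|---|
| `n_keratinocyte`, `n_melanocyte` | 142, 113 | compartment node counts (the curated model's compartmentalised nodes) |
| `n_sources`, `n_targets` | 20, 9 | designated triggers/receptors and end processes |
| `n_layers` | 8 | cascade depth (receptor → second messenger → kinase → transcription factor → effector scale) |
| `cross_talk_prob` | 0.2 | probability an edge's upstream partner is drawn from the other compartment (paracrine edges) |
| `redundancy` | 1.6 | mean incoming branches per non-source node; the curated model averages ~1.6 edges per node |
| `inhibition_frac` | 0.15 | fraction of edges typed `inhibits`, a typical minority share in curated signalling maps |
| `feedback_prob` | 0 | optional backward edges; the default keeps the instance acyclic so exhaustive oracles stay cheap, but no analysis code assumes acyclicity |

The generator owns one seeded RNG per call and restores the caller's RNG
state; the same spec and seed reproduce a byte-identical edge table.

What the generator does *not* emulate: the heavy-tailed degree
distribution of the real curated network, uncompartmentalised nodes
(environmental triggers and shared end processes), feedback loops under
the default, or biologically meaningful node identities. Passing tests
on synthetic instances therefore demonstrates algorithmic correctness on
networks with the assumed *structure*, not fidelity to any particular
curated biology.

## What the tests establish

Correctness rests on independent brute-force oracles rather than on
comparing one library to another: exhaustive simple-path enumeration
arbitrates shortest-path sets, betweenness (node and edge), and the
cut-node criterion for knockout abrogation — a removal abrogates a pair
exactly when the removed node lies on *every* simple route between them.
The suite runs these comparisons over 200 seeded random digraphs of up
to 10 nodes, alongside closed-form radiality checks on chains and stars,
distance-monotonicity under knockout, degree conservation, exact
parser/writer round-trips, and generator determinism. Fixture-level
tests reproduce the published sample-network counts, the two tied
PGE2→eumelanin routes, every printed route string, and the five
published knockout outcomes. Problem sizes were chosen so the whole
suite enumerates millions of paths in well under a minute; the same
properties hold at larger sizes at super-linear cost.

## Known limitations

* Edge sign is ignored in traversal; a route mixing activations and
  inhibitions is reported like any other. Boolean or ODE semantics are
  out of scope.
* Only single-node knockouts are implemented; the biology sometimes
  requires two or more simultaneous losses to silence a pathway.
* Node categories beyond the packaged heuristics (UV triggers,
  complexes, end processes) default to `unknown` unless an annotation
  table is supplied, because the full per-node category assignment lives
  in the out-of-package supplementary data.
* The published 33-node knockout shortlist cannot be reconstructed —
  its degree and path-frequency thresholds were never stated — so
  `shortlist_candidates()` exposes the construction rule with explicit
  `top_by_degree` / `top_by_path_frequency` parameters instead of
  hard-coding a membership.
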