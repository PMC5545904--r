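---
title: "Comparing cause-and-effect disease models across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cause-and-effect disease models across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbel)
```

## The problem

Mouse models are the workhorse of preclinical neuroscience, yet drugs that
modulate neuroinflammation in transgenic mice have repeatedly failed in
human Alzheimer's disease trials. One way to make the translation gap
explicit is to curate, for each species separately, a computable
cause-and-effect model — a directed graph whose edges encode "A increases
B" / "A decreases B" claims with literature evidence — and then ask, edge
by edge, whether what has been demonstrated in humans is reflected in the
mouse literature, contradicted by it, or simply never tested.

`crossbel` implements that comparison as a pipeline: model I/O in a BEL
(Biological Expression Language) subset, human–mouse orthology mapping,
edge-level concordance classification, gene-level expression concordance
from differential-expression call tables, over-representation analysis,
and signed-path mode-of-action propagation for drug perturbations.

## Model representation

A model is species-scoped. Nodes (entities) carry a function class —
protein, gene, chemical, bioprocess, cell population, or complex — a
namespace (HGNC for human genes, MGI for mouse, CHEBI/GOBP/MESH for
species-neutral chemicals, processes and cell types) and an identifier.
The supported BEL term functions are `p()`, `g()`, `a()`, `bp()`,
`complex()`, with `act()` and `pmod()` as decorations. Two representation
choices deserve a note:

* **Cell populations.** The BEL subset has no dedicated term function for
  cell types, so they are encoded as abundances in the MESH namespace:
  `a(MESH:microglia)` is a `cell_population` node, while `a(CHEBI:...)`
  is a `chemical`. This keeps microglia, astrocytes and macrophage
  subsets first-class nodes of the graph.
* **Decorations are not nodes.** `act(p(HGNC:AKT1))` and
  `p(HGNC:AKT1, pmod(P))` both refer to the AKT1 node; the
  activity/modification tag is entity metadata. Matching and propagation
  ignore it by default because the curated literature freely mixes
  "phosphorylated Akt1" with "Akt1"; `strict = TRUE` restores exact
  decoration matching where that distinction matters.

Edge identity is the canonical (subject, relation, object) triple;
`association` edges are symmetric and canonicalised to lexicographic
endpoint order. Duplicate statements raise the statement count but not
the edge count, which is why a model can have more statements than edges.
Relation polarity is total: `increases`/`directlyIncreases` are +1,
`decreases`/`directlyDecreases` are −1, `association`/`causesNoChange`
are 0.

## Orthology

The comparison needs human↔mouse gene correspondence. The default policy
`table_then_casefold` uses a curated symbol table first and falls back on
the standard case conventions (HGNC all-caps, MGI capitalised), because
for the genes in these models the conventions are essentially exact;
`table_only` disables the fallback for conservative analyses. One-to-many
orthology is allowed: every counterpart is a candidate match, so a human
edge is "found in mouse" if any counterpart pair supports it — a
deliberately generous reading that avoids overcounting species-unique
edges.

## Edge concordance classification

For each human edge, the mouse candidates are the mouse edges whose
orthology-translated endpoints match **in the same direction**
(association edges match either orientation). The category rules, in
order:

1. any candidate with the same nonzero polarity → **consistent**
   (flagged `mixed_evidence` if an opposite-polarity candidate coexists —
   the tie resolves conservatively toward consistency and is surfaced for
   review rather than silently labelled contradictory);
2. otherwise any candidate with the opposite nonzero polarity →
   **contradictory** — "contradictory" means opposite effect sign, not
   reversed orientation; a mouse edge pointing the other way is simply
   not a match;
3. otherwise only correlative (zero-polarity) candidates →
   **consistent** with `nonpolar_match = TRUE` (demotable to
   unique via `nonpolar_as_consistent = FALSE`; the underlying curation
   contains correlative edges but never specifies this case, so both
   readings are available and the default is reported separately);
4. otherwise → **unique to human**. An endpoint with no orthologue under
   `table_only` also lands here, annotated `"no-orthology"`.

Mouse edges with no human counterpart are reported separately as
unique-to-mouse. Edges are stratified into a **molecular** level (both
endpoints protein/gene/chemical/complex) and a **cellular** level (either
endpoint a bioprocess or cell population), and percentages are integers
rounded half away from zero within each level's denominator — the
convention that reproduces a 9/5/19 split over 33 molecular interactions
as 27/15/58. Note that not every printed integer-percentage triple is
reachable from an integer count vector under a single rounding rule; when
reconstructing published splits we therefore work at the level where the
counts and percentages are mutually consistent (the molecular one).

## Expression concordance

Differential-expression evidence enters as pre-computed GEO2R-style call
tables (symbol, logFC, p-value, optional adjusted p) — the package never
re-analyses raw expression matrices. Multiple probes per gene collapse to
the smallest p-value per gene per dataset. A call is significant at
`alpha` (default 0.05 on the unadjusted p-value, with `use_adjusted`
available) and directional by the sign of its log fold change; a
significant call with exactly zero fold change is treated as
non-significant with a warning.

Genes are classified in a fixed precedence order: within-species
up-and-down conflict first, then all-non-significant, then
single-species significance, then agreement/contradiction between
species. This yields the six categories `same_pattern`, `human_only`,
`mouse_only`, `inconsistent_within_species`,
`contradictory_between_species`, `non_significant`; genes with no calls
at all are "uncovered" and excluded from the denominator. Tissue labels
travel as metadata only — the human and mouse datasets in this design
come from different tissues, so no tissue weighting is defensible.

One subtlety: tightening `alpha` shrinks the set of significant calls,
so a gene in a no-conflict category can never *become*
between-species-contradictory at a smaller `alpha`; but a gene that was
inconsistent *within* a species can, when one of its two conflicting
calls loses significance while the other species stays significant in
the opposing direction. The property tests assert exactly this weaker,
correct monotonicity law.

## Over-representation analysis

Gene-list enrichment against GMT collections uses the plain
hypergeometric upper tail, `P(X ≥ k)` for an overlap of `k` between a
query of size `n` and a set of size `K` in a universe of size `N`, with
Benjamini–Hochberg adjustment across sets. The modified Fisher (EASE)
score of popular web tools is deliberately not reproduced: its outputs
depend on the tool's database version, which makes them irreproducible
from a fixed gene-set file. Pathway counts therefore depend on the
user-supplied collection and threshold and are reported, not asserted.

## Mode-of-action propagation

A drug action is a set of (target, sign) pairs — celecoxib inhibits both
PTGS2 and PDPK1, so both targets carry −1. From each target the engine
enumerates **simple** directed paths (no repeated node) of length at most
`max_len` through polar edges only; association edges have no sign to
compose and are excluded. A path's sign is the action sign times the
product of edge polarities, so inhibiting an inhibitor activates:
(−)·(−) = +. Per node, all path signs are aggregated: a pure +1 or −1,
`conflict` when both signs arrive, `unreached` otherwise. Conflicts are
surfaced, never resolved numerically — the curation reasons
qualitatively, and pretending to weigh paths would manufacture
precision.

The default `max_len = 6` covers the longest curated celecoxib chain
(PDPK1 → AKT1 → TSC2 → RHEB → MTOR → BACE1 → amyloid-β, six edges);
the simple-path rule terminates cleanly on cycles such as the
Nfkb1 → Ptgs2 → amyloid-β → Nfkb1 self-regulatory loop. Cross-species
comparison pairs nodes through orthology and buckets them into
agree / disagree / one-species-only, with "both conflicted" reported as
its own agreement flavour.

On the bundled case study the contrast is sharp: the mouse model
predicts celecoxib suppresses Il4, Ins and (via Ptgs2) amyloid-β, while
the human model predicts increased insulin resistance, an MTOR rise
through the AKT1/TSC2 chain, and a conflicted amyloid-β node —
suppressed via PTGS2 but raised via the MTOR/BACE1 route — which is
exactly the kind of off-target human-unique mechanism that a
mouse-derived expectation misses.

## The synthetic generator

Every pipeline stage is testable without downloads because the generator
constructs fixtures whose truth is known *exactly*:

* `generate_model_pair()` draws a human model over synthetic gene
  symbols plus bioprocess/cell nodes, then builds the mouse model by
  orthology translation, sign flip, or omission according to per-edge
  labels. Category counts come from largest-remainder apportionment of
  the requested proportions, so they are exact integers, never sampled —
  closure tests can demand label recovery edge-for-edge with zero error.
  Randomness affects only symbol assignment, topology and relation
  signs. Subject/object pairs are unique (self-edges disallowed,
  duplicates resampled) so that a flipped mouse edge can never collide
  with a kept one.
* `generate_expression_tables()` builds per-gene calls that force each
  gene's six-way category at the target `alpha`: significant p-values
  are drawn strictly below it, non-significant ones strictly above,
  within-species-inconsistent genes get one up and one down call in two
  datasets of one species.

The defaults mirror the observed study conditions: 73 interactions with
a 33/40 molecular/cellular split and a 27/15/58 molecular concordance
mix for model pairs; 100 genes with the 31/14/19/17/7/12 six-way mix
across three datasets per species for expression. What the generator
does **not** emulate: literature redundancy and citation structure,
realistic degree distributions, probe-level noise, or tissue effects.
Passing closure tests therefore demonstrate that the classifiers
implement their definitions exactly — not that real curated models are
this clean.

## Problem sizes and numerical choices

The test-suite and acceptance runs use a 33-edge molecular pathway
reconstruction, 100-gene expression cohorts, a 200-edge closure pair,
brute-force oracle comparisons on models of up to 20 edges and graphs of
12 nodes, and exhaustive hypergeometric enumeration at N = 20 — sizes at
which independent oracles (explicit enumeration, igraph's simple-path
search, combinatorial counting) are exact and fast. Percentages round
half away from zero; BH q-values come from `p.adjust`; seeds make every
generated fixture reproducible byte-for-byte.

## Limitations

* Orthology is symbol-level; paralog resolution and sequence-based
  inference are out of scope, and the casefold fallback, while accurate
  for these gene families, is a convention, not biology.
* Matching is identifier-level: no ontology reasoning over GO term
  hierarchies, so `bp(GOBP:autophagy)` and a hypothetical
  `bp(GOBP:"macroautophagy")` are different nodes.
* Propagation is qualitative sign algebra over curated edges — no
  kinetics, dose, or probability. A `conflict` is a statement about the
  curated graph, not a prediction of net biology.
* The published full-scale neuroinflammation models (hundreds of nodes)
  are not redistributable here; the bundled celecoxib models are the
  hand-curated case-study subgraphs, and full-model statistics are
  whatever `model_stats()` reports on the models a user supplies.
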