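# crossbel

Cross-species comparison of cause-and-effect disease models.

Preclinical findings in mouse models of neuroinflammation translate
poorly to human Alzheimer's disease. `crossbel` makes the gap
measurable: it represents each species' curated knowledge as a causal
graph of BEL-style statements (`subject relation object`, with relation
polarity +1/−1/0), matches human and mouse edges through gene-symbol
orthology, and classifies every human interaction as **consistent**
(same effect sign in mouse), **contradictory** (opposite sign), or
**unique to human** (never shown in mouse), stratified into a molecular
level (protein/gene/chemical endpoints) and a cellular level
(bioprocess or cell-population endpoints). Around that core it provides:

* **Expression concordance** — a six-way per-gene classification
  (same pattern / human-only / mouse-only / inconsistent within a
  species / contradictory between species / non-significant) from
  GEO2R-style differential-expression call tables at a significance
  threshold α (default 0.05, unadjusted p).
* **Over-representation analysis** — hypergeometric upper tail
  `P(X ≥ k)` against GMT gene sets with Benjamini–Hochberg correction.
* **Mode-of-action propagation** — a drug's target signs composed
  multiplicatively along simple directed paths (sign of a path =
  action sign × ∏ edge polarities), with per-node aggregation to
  +1 / −1 / conflict and a cross-species agreement table. The bundled
  case study is celecoxib, which inhibits PTGS2 and PDPK1.
* **A synthetic-data generator** whose category counts are exact by
  construction (largest-remainder apportionment), so every classifier is
  testable with zero-error closure checks.

## Worked example: why celecoxib disappoints in humans

```r
library(crossbel)
mods <- celecoxib_models()          # curated human + mouse subgraphs
act  <- celecoxib_action()          # PTGS2 -1, PDPK1 -1
res_h <- propagate(mods$human, act, max_len = 6)
res_m <- propagate(mods$mouse, act, max_len = 6)
compare_perturbation(res_h, res_m, neuroinflammation_orthology())
```

The mouse model predicts a clean benefit, the human model does not
(output from `analysis/05_celecoxib_moa.R`):

```
mouse model predicts: Il4 -1 | Ins -1 | amyloid-beta -1
human model predicts: MTOR +1 | insulin resistance +1 | amyloid-beta conflict
species disagree on: amyloid-beta, amyloid-beta clearance, inflammatory response
```

Reading: in mouse, inhibiting Ptgs2 lowers amyloid-β (−1). In human,
the same inhibition is undercut by an off-target chain — PDPK1 ⊣
celecoxib reduces AKT1, which raises phospho-TSC2, RHEB and MTOR (+1),
driving BACE1-mediated amyloid-β production — so the amyloid-β node is
`conflict`, insulin resistance rises (+1), and the two species land in
the `disagree` bucket on three nodes.

Edge-level concordance on a simulated 73-interaction pathway
(`analysis/02_compare_models.R`) prints per-level integer percentages
(half-away rounding), e.g.:

```
      level        category count denominator percent
1 molecular      consistent     9          33      27
2 molecular   contradictory     6          33      18
3 molecular unique_to_human    18          33      55
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study on generated
inputs and write their tables under `results/`:

1. `01_simulate.R` — labelled model pair + expression cohort
2. `02_compare_models.R` — edge concordance and label recovery
3. `03_expression.R` — six-way expression concordance
4. `04_enrichment.R` — ORA of the case-study models
5. `05_celecoxib_moa.R` — the perturbation contrast above

`run_pipeline()` offers the same orchestration as a single function over
a YAML/list configuration, emitting a JSON report.

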