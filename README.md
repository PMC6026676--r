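# fluxscope

Constraint-based analysis of gut-bacterial genome-scale metabolic models
(GEMs) in R: flux balance analysis, synthetic lethality of reactions and
nutrient exchanges, pathway sensitivity to reaction blocking,
minimal-sufficient-nutrient search, and growth-coupled secretion
profiling — with a deterministic toy-model generator so the whole
pipeline is testable offline, without downloading any reconstruction.

## Who this is for

Researchers studying how gut microbes (e.g. *Escherichia* sp.,
*Akkermansia muciniphila*, *Subdoligranulum variabile*,
*Intestinibacter bartlettii*) grow, compete and cross-feed in the
intestinal nutrient pool, and anyone who needs a small, fully tested R
implementation of reaction-level essentiality analysis on
AGORA-convention models (compartments `c`/`e`, `EX_*` boundary
exchanges with uptake as negative flux, one biomass objective,
per-reaction subsystem annotations).

## The model at the core

All analyses reduce to linear programs over the stoichiometric matrix
`S` (metabolites × reactions):

```
max  v_biomass
s.t. S v = 0                (steady-state mass balance)
     lb_i <= v_i <= ub_i    (flux bounds, mmol/gDW/h)
```

On top of this FBA core the package provides:

* **Parsimonious tie-breaking** — among biomass-optimal flux vectors,
  the one minimizing `sum(|v_i|)` (two-stage LP), so flux comparisons
  across perturbations are well defined.
* **FVA** — per-reaction flux range `[min v_i, max v_i]` subject to the
  objective retaining a fraction (default 0.90) of its optimum.
* **Synthetic lethality** — single lethal reactions (blocking drops
  growth below `1e-5`) and double-lethal pairs (jointly but not
  individually lethal), found with a support-pruned search in the
  spirit of Fast-SL and contractually identical to exhaustive knockout
  enumeration (`enumerate_lethals()`), which ships as the oracle.
* **Pathway sensitivity** — per-subsystem fraction of reactions whose
  flux (FBA mode, threshold 0.01 mmol/gDW/h absolute or 1 % relative)
  or flux range (FVA mode) changes when lethal or exchange reactions
  are blocked.
* **Minimal nutrient search** — close uptake of all non-essential
  exchanges, then reopen combinations (1-by-1, 2-by-2, 3-by-3) and
  record which restore growth, under aerobic and anaerobic regimes.
* **Secretion profiling** — with biomass pinned at its maximum on a
  minimal medium, maximize/minimize each exchange flux to get
  growth-coupled production/consumption envelopes, overlaid across
  organisms into a commensalism/competition matrix.

Two interchangeable LP backends are provided: a native bounded-variable
two-phase simplex (default, pure R) and `scipy.optimize.linprog`
(HiGHS) through a `python` subprocess; the test suite enforces
agreement to 1e-6.

## Worked example

`TOY-O2` encodes the iron/oxygen coupling motif of facultative
anaerobes: biomass requires both ferrous (Fe2+) and ferric (Fe3+) iron,
and Fe3+ can come either from its own exchange or from oxidation of
Fe2+ by oxygen (mirroring 4Fe2+ + 4H+ + O2 -> 4Fe3+ + 2H2O).

```r
library(fluxscope)
model <- make_fixture("TOY-O2")$model
res <- lethality_analysis(model)
res
#> <lethality_result 'TOY-O2': 5 singles (2 exchange), 6 pairs (4 with >=1 exchange, 1 with 2)>
res$exchange_single_lethals
#> [1] "EX_A"   "EX_Fe2"
sapply(res$pairs_two_exchanges, paste, collapse = " + ")
#> [1] "EX_Fe3 + EX_O2"
```

Ferrous iron uptake is essential on its own, while oxygen and ferric
iron form a synthetic-lethal exchange pair: either alone is dispensable
(the other route covers Fe3+ supply), blocking both abolishes growth.
Deleting the oxygen exchange (`anaerobic_variant()`) makes ferric iron
uptake essential too:

```r
an <- anaerobic_variant(model)
intersect(single_lethals(an), detect_exchanges(an))
#> [1] "EX_A"   "EX_Fe2" "EX_Fe3"
```

The full pipeline over all fixtures writes deterministic TSV/JSON
reports (lethality tables, sensitivity heatmaps, nutrient combinations,
exchange profiles, cross-organism comparison):

```r
run_pipeline(c("TOY-A", "TOY-B", "TOY-C", "TOY-D", "TOY-O2"),
             out_dir = "reports")
```

A command-line entry point with the same functionality is installed at
`system.file("cli", "fluxscope", package = "fluxscope")` (subcommands
`simulate`, `lethality`, `all`).

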