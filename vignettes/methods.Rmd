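---
title: "Methods: constraint-based lethality, nutrient and secretion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based lethality, nutrient and secretion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscope)
```

## The model and its assumptions

`fluxscope` analyzes genome-scale metabolic models (GEMs) in the
constraint-based framework.  A model is a stoichiometric matrix $S$
(metabolites $\times$ reactions) with per-reaction flux bounds
$l \le v \le u$ (mmol/gDW/h) and one biomass objective reaction.  Flux
balance analysis (FBA) assumes a quasi-steady state, $Sv = 0$: internal
metabolite pools neither accumulate nor deplete on the timescale of
growth.  Exchange reactions — boundary pseudo-reactions touching exactly
one extracellular metabolite — connect the cell to the environment, with
the COBRA/AGORA sign convention that negative exchange flux is uptake
and positive flux is secretion.  Biomass, DNA, RNA and protein
pseudo-reactions are treated as intracellular and never classified as
exchanges, even when they formally touch a single species.

FBA optima are generally degenerate: many flux vectors achieve the same
maximal growth.  Any analysis that *compares flux values* across
perturbations is ill-defined without a selection rule, so all flux
comparisons in this package use parsimonious FBA: among biomass-optimal
vectors, the one minimizing $\sum_i |v_i|$, computed by a second LP with
each flux split into non-negative forward/backward parts.  Pure
feasibility queries (does the model grow above threshold?) use a single
plain LP, since only the objective value matters there and it is unique.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `growth_threshold` | 1e-5 | 1/h (biomass flux) | below this the model counts as "no growth"; applied uniformly to lethality and the nutrient search for consistency |
| `flux_change_threshold` | 0.01 | mmol/gDW/h | absolute flux change above which a reaction counts as altered in pathway sensitivity |
| `relative_change_threshold` | 0.01 | fraction | the ">1 % of reference flux" variant, used for nutrient-search pathway reports |
| `fva_fraction` | 0.90 | fraction of optimum | flux-variability ranges are computed subject to biomass $\ge$ 0.90 $\times$ optimum |
| `k_max` | 2 | – | maximal nutrient-combination size (1–3) |
| lethality cutoff mode | absolute | – | `relative = TRUE` switches to a fraction-of-wild-type cutoff, the convention of some essentiality tools; both are exposed because published analyses differ |

Biomass flux is conventionally 1/h while all other fluxes are
mmol/gDW/h; the package reports the raw LP value per reaction and
leaves unit labeling to the reaction type.

## Design choices where the design was genuinely open

**Alternate optima.** Parsimonious tie-breaking everywhere a flux
*vector* is consumed downstream (pathway sensitivity, Fast-SL support
pruning); raw FBA where only the optimum matters (lethality
verification, nutrient search, growth envelopes).

**Lethal scenarios in pathway sensitivity.** Blocking an essential
reaction leaves no biomass-optimal flux state to compare against.  Such
scenarios are still tabulated: the comparison state is the
feasibility-relaxed, parsimoniously minimal flux state (the objective
constraint is dropped and $\sum|v|$ minimized — on most models the zero
vector), and the rows carry a `lethal = TRUE` flag so they can be
filtered.  This is an interpretive choice, documented rather than
hidden.

**"Altered" under FVA.** A reaction counts as altered when its range
midpoint shifts by more than the threshold *or* its width
(max $-$ min) changes by more than the threshold.  The rule reduces
exactly to the FBA rule when ranges collapse to points, and on the test
fixtures the FVA-altered set always contains the FBA-altered set —
consistent with variability analysis being the more sensitive
instrument.

**Flux-change thresholds.** Both an absolute (0.01 mmol/gDW/h) and a
relative (1 %) mode exist because the two conventions answer different
questions; the absolute mode is the default for sensitivity reports and
the relative mode for nutrient-search pathway reports.

**Nutrient search semantics.** The search *unblocks* combinations of
previously closed non-essential uptakes (rather than blocking
combinations of open ones): single-essential exchanges stay open the
whole time so that lack of growth is attributable to the candidate
nutrients alone.  "Unblocking" restores the exchange's original
declared lower bound — not an arbitrary $-1000$ — preserving
per-nutrient uptake limits encoded in the model.  A combination is
flagged minimal when no proper subset grows; non-minimal growing
combinations are retained for growth-rate tables.

**Media never widen bounds.** `apply_medium()` sets an exchange's lower
bound to $\max(\mathrm{declared}, -\mathrm{rate})$: a medium can
restrict but not extend what the model declares possible.  Under
`anaerobic = TRUE` the oxygen exchange uptake is forced shut regardless
of the medium entry.

**Growth pinning for envelopes.** Growth-coupled
production/consumption fixes biomass at its computed maximum backed off
by a $10^{-9}$ relative epsilon, avoiding infeasibility at the LP
vertex without measurably relaxing the constraint.

## Numerical choices

The native LP backend is a bounded-variable two-phase primal simplex
(dense full tableau): pivot and optimality tolerances $10^{-9}$,
feasibility assertion $10^{-7}$, Dantzig pricing with a deterministic
switch to Bland's rule against cycling, lowest-index tie-breaks
throughout.  Determinism is a feature: two runs of the pipeline produce
byte-identical reports.  A second backend calls
`scipy.optimize.linprog` (HiGHS) in a `python` subprocess; the
acceptance suite runs the full fixture pipeline under both backends and
requires agreement of every numeric output to $10^{-6}$.  The dense
tableau is adequate for the toy-scale models this package targets
(tens of reactions); genome-scale models (thousands of reactions) would
need a sparse factorized solver, which is out of scope.

Degenerate inputs: infeasible models yield `status = "infeasible"` and
downstream errors name the stage; models with a wild-type growth below
the threshold are rejected by the lethality entry points ("model does
not grow"); empty blocking sets, empty media and single-organism
pipelines are all defined no-ops rather than errors.

## What the synthetic generator emulates — and what it does not

`make_fixture()` and `make_random()` produce AGORA-shaped toy models:
`c`/`e` compartments, `EX_*` exchanges with uptake negative, a biomass
objective, subsystem labels, SBML Level 3 + fbc serialization.  Each
fixture encodes one motif that drives the analyses: parallel paths
(double lethals), iron/oxygen coupling (the Fe2+/O2 oxidation motif
where the O2 and Fe3+ exchanges are pair-lethal while Fe2+ exchange is
single-lethal), jointly required substrates (minimal nutrient pairs),
and a growth-coupled byproduct (secretion envelopes).  Random models
are layered substrate $\to$ precursor $\to$ biomass networks, at most
40 reactions, with ground truth computed at generation time by
exhaustive knockout enumeration; generation is pure in the seed.

A green test on these models establishes *algorithmic correctness* —
search equals oracle, envelopes match hand-computed LP values,
determinism holds.  It does **not** establish anything about real
organisms: toy models have none of the scale (AGORA reconstructions
have $\sim$1000–1800 reactions), redundancy structure, cofactor
coupling, compartment complexity or curation artifacts of genome-scale
reconstructions.  Organism-level claims require running the same code
on downloaded AGORA SBML files with their published minimal media,
which the offline test environment deliberately does not do.

## Known limitations

* Dense LP algebra: fine to a few hundred reactions, not genome scale.
* Reaction-level analysis only: no gene–protein–reaction rules, so no
  gene essentiality.
* No community (joint multi-organism) FBA: the interaction matrix
  overlays per-organism envelopes, it does not simulate co-growth.
* Triple lethals are out of scope (the search stops at pairs; the
  nutrient search, in contrast, does go to triplets).
* SBML support targets Level 3 + fbc v2 (with a Level-2 kinetic-law
  fallback); exotic dialects may need pre-conversion.
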