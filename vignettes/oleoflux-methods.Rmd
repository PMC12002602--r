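---
title: "Constraint-based screening and FSEOF target discovery with oleoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based screening and FSEOF target discovery with oleoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleoflux)
```

## The model

oleoflux analyses genome-scale metabolic models (GEMs) of oleaginous
fungi by flux balance analysis (FBA). A GEM is a stoichiometric matrix
$S \in \mathbb{R}^{m \times n}$ over $m$ metabolites and $n$ reactions
together with flux bounds and an objective, and FBA solves

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\; lb \le v \le ub,$$

where $v$ are reaction fluxes in mmol·gDW⁻¹·h⁻¹ and the objective is
usually the biomass reaction, so the optimum is the growth rate $\mu$
(h⁻¹). The package targets the three-compartment layout common in
filamentous-fungal reconstructions (extracellular space, cytosol,
mitochondrion) but the compartment registry is extensible.

Key modelling conventions, all community standard:

* **Exchange sign.** Boundary reactions are written `met_e →`, so uptake
  is negative flux. "Leaving an exchange unconstrained" means a lower
  bound of −1000 mmol·gDW⁻¹·h⁻¹.
* **Default bounds.** Reversible reactions default to (−1000, 1000),
  irreversible ones to (0, 1000).
* **GPR rules.** Gene–protein–reaction associations are boolean
  expressions where `and` joins subunits of a complex and `or` joins
  isozymes; `and` binds tighter than `or`, identifiers are
  `[A-Za-z0-9_.-]+`.

## The linear-programming core

No LP interface is assumed: the package carries its own revised simplex
for bounded variables (`lp_solve()`), with phase-1 artificials, bound
flips in the ratio test, Dantzig pricing, and a Bland fallback against
cycling. The pivot tolerance is 1e-9 and phase-1 feasibility is accepted
below 1e-7. Problems in this package are dense and small (tens to a few
hundred reactions), which is the regime where a dense basis-inverse
update is both simple and fast. The engine's optima are cross-checked in
the test suite against closed forms, exhaustive vertex enumeration on
tiny instances, and an independent reference LP implementation.

**Degenerate optima and pFBA.** FBA optima are usually degenerate: many
flux vectors attain the same objective, and which one a solver returns is
arbitrary. Any analysis that interprets *which* reactions carry flux
(activity pooling, FSEOF) therefore runs on parsimonious FBA
(`solve_pfba()`): the objective is fixed at its optimum and total
absolute flux $\sum_j |v_j|$ is minimised, which yields a deterministic,
minimal-support distribution. Only reactions whose bounds allow both
signs are split into positive/negative parts, keeping the second LP close
to the first in size. Raw-FBA activity is available behind a flag.

## Biomass equation

`compose_biomass()` converts a two-level macromolecular composition
(dry-weight fraction per macromolecule class, within-class mass fraction
per component) into molar drain coefficients:

$$\text{coef}(i) = \frac{1000 \cdot f_{\text{macro}} \cdot f_i}{MW_i}
\quad \text{mmol·gDW}^{-1},$$

with $MW_i$ in g/mol (equal to mg/mmol), so the drains jointly account
for exactly 1000 mg of biomass per gram dry weight — the invariant
$\sum_i |\text{coef}(i)| \cdot MW_i = 1000$ is asserted to 1e-6.
Growth-associated maintenance (GAM) adds
`ATP + H2O → ADP + Pi + H⁺` at the configured rate; the curated value for
the oleaginous *Umbelopsis*-type composition shipped with the package
(`umbelopsis_biomass_composition()`) is 153 mmol ATP/gDW, and the
default composition is DNA 2.5%, RNA 5%, protein 35%, lipids 40%,
carbohydrates 17.5%.

Numerical choices worth knowing:

* Published composition tables carry rounding residuals (here the protein
  breakdown sums to 100.09%, the lipids to 100.2%, the RNA to 99.9%).
  `validate_composition()` reports these exactly; `compose_biomass()`
  renormalises them by default with a warning, because silently composing
  an unnormalised table would break mass closure. Strict mode refuses.
* Molecular weights are *polymer-residue* masses (monomer minus water)
  for nucleotides, amino acids and sugars, and representative-species
  masses for lipid classes. The shipped table
  (`reference_component_weights()`) is data, not truth — callers
  modelling a specific strain should substitute weights reflecting its
  acyl-chain and sugar composition. Mass closure holds for any positive
  weight table, by construction.
* GAM is placed inside the biomass reaction (the common convention);
  because the RNA precursor ATP and the GAM ATP are the same species,
  their drains merge when the equation is realised as a model reaction
  via `biomass_to_reaction()`.

## Minimal-medium phenotype screening

`screen_carbon_sources()` reproduces a Biolog-style carbon-source screen
in silico. The minimal medium leaves a fixed set of exchanges
unconstrained — phosphate, sulphite, sulphate, ammonium, plus CO₂, O₂,
water and protons — and opens exactly one carbon exchange per source,
uptake-bounded at 10 mmol·gDW⁻¹·h⁻¹ by default. Only qualitative
growth/no-growth is claimed at that default, so its exact value is not
critical; it is configurable in `medium_spec()`. All other exchanges are
closed for uptake but never for secretion.

The in vitro call per source uses the standard majority rule: positive
only when at least two of three replicates grew. The in silico call is
positive when the optimal objective exceeds `growth_threshold`
(default 1e-6 h⁻¹ — any truly positive optimum passes, solver noise does
not). Sources with no exchange reaction in the model are recorded as
structural no-growth with reason `no_exchange` rather than an error: a
missing transporter is a *finding* of this kind of screen, and the
concordance table keeps such sources in the false-no-growth cell.

The result is a 2×2 confusion summary (concordant growth, concordant
no-growth, false no-growth, false growth) and
`agreement = 100·(TP+TN)/total`.

## Reaction-activity classes

`classify_reaction_activity()` pools the per-source pFBA solutions and
computes, for each reaction, the fraction of solutions in which it
carries flux (|v| > `activity_epsilon`, default 1e-6). The partition is:
always active, active at least once (the *auxiliary* set), never active.
The auxiliary set is subdivided at 10%/90% activity:

* **near-core** — inactive in at most 10% of solutions;
* **type-associated** — active in between 10% and 90% (typically tied to
  a substrate class such as carbohydrates or amino acids);
* **source-specific** — active in at most 10% of solutions.

The two quoted boundary phrases overlap at exactly 10%; the classifier
evaluates near-core first, then source-specific, and the remainder is
type-associated, which guarantees a true partition. The boundaries are
arguments, not constants.

## FSEOF

Flux Scanning based on Enforced Objective Flux (`run_fseof()`) looks for
amplification targets for a secreted product (here a linoleate-like
demand): reactions whose flux rises as product formation is forced while
biomass remains the optimisation objective.

Protocol: compute the maximal product flux $v^{max}_{prod}$; place
`n_steps = 10` enforcement levels evenly from the baseline product flux
to `max_fraction = 0.9` of $v^{max}_{prod}$ (stopping short of the often
degenerate extreme vertex); at each level fix the product's lower bound
and re-optimise biomass with pFBA; record all fluxes. The biomass optimum
is checked to be non-increasing along the grid.

**Slope.** The per-reaction slope is the least-squares regression of
$|v_j|$ on the enforced product flux. Field tools print a single slope
per reaction without defining it; regression over all steps is robust to
single-step degeneracy, and the endpoint difference quotient is available
via `slope_method = "endpoint"`. A reaction is reported when its slope is
positive (beyond `activity_epsilon`), its flux profile is non-decreasing,
and it does not change direction across the grid — "flux increases" is
ill-defined across a sign change, so direction-changers are listed
separately instead.

**Aggregation.** `aggregate_fseof()` pools scans across carbon sources
and retains reactions reported with slope above 2 in at least 5 sources
(both filters configurable; these defaults follow the retention rule the
screening literature uses). `map_targets_to_genes()` unions the GPR gene
sets of the retained reactions and flags reactions lacking gene
annotation as `orphan_gpr` — transport steps typically land there.

## Synthetic data: what it does and does not emulate

All inputs are generated in code, so the entire pipeline is testable
offline:

* `make_toy_core_model()` — a feasible oleaginous-core caricature: carbon
  exchanges funnel into a central pool, two routes of different yield
  produce a biomass precursor (so the FBA optimum is
  `uptake × best yield` in closed form), and biomass additionally drains
  ammonium and phosphate so the minimal-medium configuration is
  load-bearing. The optional product branch plants a carboxylation-like
  reaction consuming `coupling` units per unit product, making its FSEOF
  slope exactly `coupling` and the maximal product flux
  `uptake/(coupling+1)`.
* `make_random_feasible_model()` — a guaranteed-feasible backbone pathway
  threaded through every metabolite plus random shortcut reactions.
  Rejection-sampling random stoichiometries almost never grows, so
  feasibility is built in; with unit stoichiometry throughout, the
  optimum equals the uptake bound exactly.
* `make_phenotype_panel()` — a plate with planted confusion counts. The
  default emulates a 95-source panel with the substrate-class mix
  7 amines/amides, 13 amino acids, 15 carboxylic acids, 46 carbohydrates,
  5 polymers, 9 other. False-no-growth sources are realised as
  plate-positive compounds with *no* exchange in the model (the
  missing-transporter mechanism), false-growth as model-feasible
  compounds with negative plates. Replicate noise only ever flips a
  replicate that cannot change the majority call, so planted counts are
  recovered exactly; this is a deliberate property of the generator, not
  of real plates.

What the toys do **not** emulate: genome-scale network statistics
(thousands of reactions, long redundant pathways), realistic biomass
precursor reachability, kinetic or regulatory effects, Biolog dye
chemistry, or degenerate optimum structure at scale. Passing tests
demonstrate that the algorithms implement their definitions exactly; they
do not certify predictions on any real reconstruction.

## Problem sizes and determinism

The shipped analyses use a 51-carbon-source core model (~160 reactions)
for the 95-source screen, six media for the FSEOF aggregation, and a
59-solution pool for activity classification; each stage completes in
seconds on one core. Every stage is deterministic given its inputs: the
LP core has no randomised choices, generators take explicit seeds, and
`run_pipeline()` reruns byte-identically for a fixed configuration, with
every threshold recorded in its manifest.

## Using a real reconstruction

The package reads SBML Level 3 Version 1 with FBC v2 — the format
genome-scale fungal reconstructions are distributed in (standard-GEM
repository layout) — as well as a JSON dialect mirroring the package's
domain types one-to-one and a TSV reaction table. A deposited model can
be converted with `read_model("model.xml")` followed by
`write_model(m, "model.json")`; no network access is ever attempted.
Counts published for a specific reconstruction (reaction/metabolite/gene
totals, activity partitions of real solution pools, retained target sets)
additionally depend on that model's exact medium and uptake settings,
which is why this package validates its algorithms on planted synthetic
ground truth instead of asserting those numbers.

## Known limitations

* The LP core is dense; it is sized for curated and toy models (up to a
  few hundred reactions), not for whole genome-scale LPs at interactive
  speed.
* `slim_model()` defines an orphan metabolite as one participating in
  exactly one reaction and iterates removal to a fixed point by default
  (single-pass behaviour is a flag); other dead-end definitions
  (producer-only/consumer-only in the directed sense) are not
  implemented.
* SBML support covers core + FBC v2 (species, bounds, objectives, gene
  products); groups, layout and annotation RDF are out of scope.
* pFBA minimises the 1-norm; it does not break ties among alternative
  minimal-norm supports, which can differ across solvers at exact
  degeneracy.
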