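---
title: "Methods: multiobjective evolutionary knockout design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiobjective evolutionary knockout design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moeko)
```

## The model

`moeko` works on the standard constraint-based representation of
metabolism. A network with m metabolites and n reactions (m < n in any
realistic reconstruction) is a sparse stoichiometric matrix S; steady
state imposes the mass-balance constraints S·v = 0 on the flux vector v,
and environmental conditions enter as per-reaction bounds lb ≤ v ≤ ub in
mmol·gDW⁻¹·h⁻¹. Exchange reactions follow the community sign convention:
uptake is negative, secretion positive, so a glucose exchange flux of
−10 means 10 units of glucose enter the cell. Growth is the flux through
an artificial biomass reaction selected by the objective vector c.

Three linear programs are built on this polytope:

* **FBA** maximizes cᵀv. The optimum is unique; the optimizing vertex
  generally is not.
* **FVA** computes, for each reaction, the min and max flux attainable
  while cᵀv stays at or above a fraction of the FBA optimum (2n LP
  solves). A production range that collapses to a single value identifies
  a *robust* strain: its output is guaranteed at the growth optimum, not
  merely attainable.
* **pFBA** pins cᵀv at the FBA optimum and minimizes Σ|vᵢ| through the
  split reformulation v = p − q, p, q ≥ 0. This removes flux through
  futile cycles and other biologically meaningless degeneracies, and all
  point metrics (product flux, carbon uptake, cofactor flux-sums) are
  taken from the pFBA solution for that reason.

Genes act through GPR (gene–protein–reaction) Boolean rules: AND joins
subunits of one enzyme complex, OR joins isoenzymes. A deletion set turns
its genes false; every reaction whose rule evaluates false is clamped to
lb = ub = 0, which is exactly how a knockout is simulated in
constraint-based modelling. Reactions without a rule (exchanges,
spontaneous reactions) are never knockable — the search deletes genes,
never bare reactions. Knock-in pathways are value-level modifications: a
`pathway_definition` adds columns (reactions), rows (new metabolites) and
genes to a copy of the model, so the same run can compare designs with
and without the heterologous route; the shipped case-study configuration
pins the knock-in on, matching how a production pathway would be fixed in
a real campaign.

## The search

The optimizer is an elitist non-dominated-sorting evolutionary algorithm
in the NSGA-II mould: binary tournament selection on (front rank,
crowding distance), uniform crossover, per-gene bit-flip mutation, and
environmental selection over parents plus children. The published method
this design follows describes its evolutionary algorithm only at the
level of "mutation, crossover, selection, Pareto front"; we chose the
NSGA-II skeleton because it is the community-standard elitist
dominance-based EA, is deterministic under a fixed seed, and is testable
against an exhaustive oracle. The individual is a logical vector over the
*knockable* genes — genes that occur in at least one GPR rule and are not
declared essential — so mutation can never switch off a protected gene by
construction.

Feasibility is constraint-domination: candidates violating any constraint
are kept in the population with worst-sentinel objectives (they lose
every dominance comparison but preserve search gradient), and are never
archived. The constraints are:

* **growth floor** — growth ≥ `growth_floor_fraction` × wild-type growth,
  default 0.90, i.e. a 10% bound on growth reduction;
* **cofactor flux-sum bounds** — the production flux-sum
  Σⱼ max(0, S[met, j]·vⱼ) of each configured cofactor (ATP, GTP, NADH,
  NADPH, FADH2 by default) must stay within
  `cofactor_bound_fraction` of its wild-type value. The bound defaults to
  *disabled* because it entered the original workflow only as a
  refinement for the second case study; when enabled without a value it
  uses 0.10 by analogy with the growth bound, which is how the source
  describes it ("a similar bound"). Metabolite identifiers are
  configurable per model because compartment-suffixed ids differ between
  reconstructions, and paired redox couples are counted on one species
  only (NADH, not NAD⁺) to avoid double counting;
* **essential genes** and **synthetic-lethal pairs** — a listed pair may
  lose either member but not both; this reading ("allowing deletions of
  genes involved in synthetic double deletions") permits useful single
  knockouts while excluding strains that flux balance notoriously
  mispredicts.

The archive accumulates every feasible strain ever evaluated and prunes
to mutual non-domination after each generation; equal objective tuples
from different designs are all kept, since they are distinct engineering
options. Evaluations are memoized by deletion set, and all randomness
flows from `rng_seed`, so a run is exactly reproducible.

### Objectives

Six objectives can be combined: growth rate, product yield, min/max
productivity (both maximized — the FVA-derived extremes of
yield × growth), knockout count (minimized) and chromosome co-location
score (maximized). The default pair {growth, yield} mirrors the
carotenoid case study; {min productivity, max productivity} mirrors the
succinate one. The co-location score is the fraction of deletions on the
modal chromosome, with unknown loci counted in the denominator only; the
zero-deletion design scores 1 by convention. The source lists "number of
used chromosomes" as an objective without a formula, so the score is
implemented as a soft (third) objective rather than a hard constraint —
the published strain tables themselves span chromosomes, which rules out
a hard reading. A config switch can demote it to a tie-breaker.

On the yield/productivity vocabulary: the source's strain tables label a
quantity "max productivity" that numerically equals product flux over
glucose uptake (a yield), while elsewhere "productivity" is yield ×
growth. The implementation therefore exposes both quantities explicitly
(`yield`, `productivity`, `productivity_range`) and the report generator
documents which formula produced each column; carbon uptake in both is
the evaluated strain's own exchange magnitude, not the wild type's.

## Numerical choices

* The LP solver is a dense two-phase bounded-variable primal simplex
  written for this package, because no LP library is available in the
  target environment. Feasibility/optimality tolerances are 1e−9;
  Bland's rule engages after 50 degenerate pivots to guarantee
  termination. Problem sizes here (tens of variables) make a dense
  factorization per iteration acceptable. Correctness is not taken on
  faith: the test suite checks the solver against an independent
  vertex-enumeration oracle on random LPs and on the fixtures, and every
  optimal flux state is asserted to satisfy ‖S·v‖∞ ≤ 1e−6.
* pFBA fixes the objective at exactly the FBA optimum (a configurable
  relative slack defaults to 0); FVA defaults to fraction 1.0 of the
  optimum for productivity ranges.
* Degenerate inputs fail loudly: empty models, all-zero objectives and
  bound inversions are validation errors, not silent zeros. Infeasible
  LPs surface as `status = "infeasible"` and map to infeasible strains.
* Yield is mole/mole by default (`molar_mass_ratio = 1`); mass
  normalization is an option because the molar masses used for the
  published normalization are not stated.
* Selection tie-breaks are crowding distance, then a lexicographic design
  key, so equal-fitness truncation is deterministic.

## What the synthetic models emulate — and what they do not

`make_core_model()` is a ten-reaction network designed so that every
mechanism the package exercises has a closed-form answer: an uptake step
gated by an AND of two essential subunit genes; two capacity-limited
efficient conversion routes (one OR-gated by isozymes); a lossy route
whose byproduct has no sink until a three-gene knock-in pathway is
grafted on (so wild-type product flux is exactly 0, and the wild-type
growth optimum is exactly 10 = 6 + 4 from the two capacities); a futile
two-reaction cycle for pFBA; and an ATP-like cofactor produced in
proportion to uptake. Deleting conversion routes forces carbon through
the lossy coupled route, producing a genuine growth/yield trade-off with
a stepped four-point front — qualitatively the cluster-and-step structure
seen in real knockout fronts. The random toy generator
(`make_random_toy`) varies the same grammar — backbone length, isozyme
and subunit decorations, essential fraction, product branch point — under
a seed, keeping knockable genes ≤ 12 so `brute_force_front()` remains an
exact oracle.

These fixtures reproduce the *structure* of the strain-design problem,
not the *statistics* of genome-scale reconstructions: no compartments, no
thousands-of-reactions redundancy, no realistic cofactor stoichiometry,
no transcriptional context. A green test therefore establishes that the
algorithms are implemented correctly (LP optima, GPR semantics, dominance
logic, constraint enforcement, archive exactness against enumeration) —
it does not establish that any particular genome-scale prediction is
biologically right, and reproducing the published genome-scale strain
tables would additionally require the external models and unstated medium
and knock-in stoichiometries those runs used.

## Known limitations

* No MOMA/ROOM quadratic knockout predictors, no bilevel MILP
  (OptKnock-style) formulation, no expression/thermodynamic (ETFL-type)
  constraints — only the FBA-family LPs the source method uses.
* Gene over/under-expression is out of scope; designs are full knockouts
  plus pathway knock-ins.
* The SBML reader covers the Level 3 + FBC subset used by current model
  distributions (flux-bound parameters, gene-product associations,
  active objective); exotic constructs (initial assignments, kinetic
  laws) are ignored.
* Run configurations are JSON rather than YAML: the target environment
  ships no R YAML parser, and the structure is identical.
* Population size, generation count and operator rates for the published
  runs were never stated; defaults (100, 500, 1/g, 0.9) are exposed in
  `moea_config()` and scaled down in tests for runtime, not asserted as
  the original values.
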