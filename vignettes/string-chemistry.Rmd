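---
title: "String chemistries, flux balance analysis, and minimal metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{String chemistries, flux balance analysis, and minimal metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stringchem)
```

## The model

A string chemistry is an abstract chemistry in which every molecule is a
linear string over an alphabet of `A` monomer characters, and the only
allowed transformations are pairwise condensation (`ab + aa <-> abaa`) and
its reverse, splitting a string at any internal position. Monomers are the
conserved atomic units: no reaction creates, destroys, or interconverts
characters. A *chemical universe* is the complete network for a choice of
`A` and maximum string length `L`:

* metabolites: all strings of length 1..`L`, of which there are
  $\sum_{i=1}^{L} A^i$ (equal to $A(A^L-1)/(A-1)$ when $A \neq 1$, and to
  $L$ when $A = 1$);
* reactions: one per (product string, internal split position), i.e.
  $\sum_{i=1}^{L} (i-1) A^i$, which collapses to $A\frac{(L-1)A^{L+1} -
  LA^L + A}{(A-1)^2}$ when $A \neq 1$ and to $L(L-1)/2$ when $A = 1$.

Both counts are accumulated by exact integer recurrence in double precision
with a hard guard at $2^{53}$, beyond which doubles stop being exact; the
package's size guard (refusing universes above $10^6$ reactions in the
file-export path) keeps every buildable universe far below that limit, so
the counts returned are always exact.

Two deliberate combinatorial choices:

* **Split positions are not deduplicated.** Positions 1 and 3 of `aaaa`
  yield the same unordered reactant pair `{a, aaa}` but are distinct
  reactions, because the per-position sum above counts them separately (the
  single-monomer branch $L(L-1)/2$ only works under this convention). An
  optional `dedupe` flag collapses them for users who want stoichiometrically
  unique columns.
* **Deterministic enumeration order**: length-major, then lexicographic in
  alphabet order, then ascending split position. Nothing in the chemistry
  prefers one order; fixing it makes reaction ids, stoichiometric matrices
  and inclusion vectors stable across runs and machines.

The stoichiometric matrix `S` has one row per metabolite and one column per
reaction; a condensation column carries -1 per distinct reactant (-2 for a
self-condensation such as `a + a -> aa`) and +1 for the product. Every
column conserves each monomer character, a property the test suite checks
exhaustively for the `A = 2, L = 5` universe.

## Flux balance analysis

`build_model()` turns a universe (or a reaction subset) into a
constraint-based model: import exchanges for the chosen nutrients, export
exchanges for all metabolites or none, and a single irreversible biomass
reaction consuming the precursor set in fixed proportions (coefficients 1
unless specified). `solve_fba()` maximizes biomass flux `Z = c'v` subject
to steady state `S v = 0` and box bounds on `v`.

Default bounds — internal reactions `[-1000, 1000]`, imports `[0, 100]`,
exports and biomass `[0, 1000]` — are conventional finite boxes. Absolute
optimal fluxes scale with the import bound (the analytic toy case below
makes this visible); all quantities this package reports as science
(pruned-network composition, sizes, ratios, similarities) are invariant to
these magnitudes.

The linear programs are solved by the package's own bounded-variable primal
simplex (`src/simplex.cpp`). Because the right-hand side is zero and every
variable's box contains zero, the zero flux vector is always feasible, so no
phase-1 is needed: the initial basis is artificial, fixed at zero, and leaves
through degenerate pivots. The basis inverse is maintained by product-form
updates with refactorization every 64 pivots; Dantzig pricing switches to
Bland's rule after a prolonged degenerate stall, which rules out cycling.
Numerical conventions used throughout:

* optimality tolerance `1e-9` on reduced costs;
* a flux with `|v| < 1e-9` counts as "no flux" (pruning relies on this);
* basic values are recomputed from the final factorized basis, which keeps
  the steady-state residual `max |S v|` near machine precision — the package
  contract is `<= 1e-6`, and tests assert it on every optimum they touch.

The solver returns one optimal vertex. Degenerate optima are real in these
models, so all downstream logic is written against objective values and
zero/nonzero flux patterns of the returned solution, never against a unique
`v`. The test suite cross-checks the kernel against an independent external
LP solver on random box LPs, and checks the whole FBA pipeline end to end by
exporting a model to SBML and re-optimizing it with an independent
constraint-based toolbox.

An analytically solvable case anchors everything: the `A = 1, L = 2`
universe with nutrient `a`, biomass `{aa}`, and import bound `U` has optimum
`U/2`, because each biomass unit consumes one `aa` built from two imported
`a`.

## Pruning to minimal networks

Real metabolic networks are small subsets of what chemistry allows. The
package models this with two greedy reduction rules, both operating only on
internal reactions (exchanges and the biomass sink are never candidates) and
both requiring the input model to support positive biomass flux:

**Minimum-flux rule** (`prune_min_flux()`). Repeat: solve FBA; remove every
internal reaction with no flux; remove the internal reaction with the
smallest nonzero `|flux|` (earliest in enumeration order on ties). When that
removal drives the biomass objective to zero, put the reaction back and
stop. Removing zero-flux reactions can never hurt the objective — the
current optimum remains feasible — so only the smallest-flux removal is ever
restored, and at termination it is provably irremovable.

**Biomass-impact rule** (`prune_biomass_impact()`). Repeat: remove the
internal reaction whose single deletion leaves the highest residual biomass
flux (smallest impact); stop when every possible single deletion kills
biomass (maximum residual below `1e-9`). Deleting a reaction that carries no
flux at the current optimum leaves the optimum exactly unchanged (old
solution still feasible; deletions never improve), so zero-flux candidates
are always among the argmax set. The package removes the earliest zero-flux
candidate when one exists — no re-solving needed, and the stored optimum
remains valid — and only when every remaining reaction carries flux does it
re-solve one deletion per candidate, removing the earliest reaction within
`1e-6` relative tolerance of the maximum residual. This tie-break among
provably equal-impact choices is a design choice made for determinism and
tractability; the step rule itself ("remove the reaction with the smallest
impact") is followed exactly.

Both rules are greedy heuristics: the result is locally minimal (the
biomass-impact output additionally has the property that *every* single
deletion kills biomass), but no global minimality is claimed or tested.
Trajectories — the retained-reaction count after each iteration — are
strictly decreasing by construction and are recorded on every pruned
network.

## Ensembles and what the generator does (and does not) emulate

`sample_design()` draws random precursor sets and nutrient sets uniformly
without replacement from the universe's metabolites; `run_ensemble()` prunes
every nutrient x biomass combination of the design. The defaults mirror the
headline experiment: the `A = 2, L = 5` universe (62 metabolites, 196
reactions), 100 sets of 5 biomass precursors, 100 pairs of nutrients, unit
biomass coefficients; a variant draws each coefficient as an independent
uniform integer in 1..10. The test suite and examples run a 10 x 10 crossed
design plus ensembles of 50-100 independent input combinations — sizes
chosen so the entire suite completes on a laptop in minutes while leaving
the qualitative contrasts far from their decision boundaries.

Uniform sampling means a metabolite can serve as both nutrient and precursor
in one combination (a flag forbids it), and it means some combinations are
chemically doomed — e.g. an all-`a` nutrient pair cannot supply any
`b`-containing precursor, and without export exchanges every byproduct must
be recycled, which is sometimes impossible. Such combinations are recorded
with `feasible = FALSE` rather than dropped, and functions that require
feasible inputs (the pruning rules) refuse infeasible models loudly.
Ensembles are reproducible byte for byte: a master seed derives one child
seed per combination, so records do not depend on evaluation order.

This generator produces random *uniform* environments and biomass
compositions over an abstract chemistry. It does not emulate real
metabolism's irreversibility, energy currencies, cofactors, branched or
cyclic molecules, or empirically weighted biomass compositions; conclusions
the tests establish (e.g. that biomass composition shapes pruned-network
composition more than nutrient choice, measured as mean within-group Jaccard
similarity of reaction-inclusion vectors) are statements about this model
class, not about any organism.

Composition similarity uses the Jaccard index of retained-reaction sets,
encoded as 0/1 inclusion vectors over the universe's reaction enumeration;
two all-zero vectors have similarity 1 by convention (they are identical).
Two-dimensional embeddings of inclusion vectors are intentionally out of the
tested surface — they are visualization, parameter-dependent and stochastic;
the package exports the inclusion matrix as CSV for any external embedding
tool.

## Network statistics

`degree_distribution()` treats a network as an undirected bipartite
metabolite-reaction graph with one edge per participation (a
self-condensation contributes a single edge between `a` and its reaction,
the simple-graph convention of standard graph libraries) and histograms
metabolite-node degrees only. Exchange and biomass columns are excluded by
default — they are modeling artifacts whose inclusion would add a constant
degree to every metabolite — with a flag to include them.
`flux_distribution()` normalizes `|v|` by the largest absolute flux and bins
into 10 equal bins on `[0, 1]`, the last bin right-closed so a normalized
flux of exactly 1 lands in it. `aggregate_distributions()` aligns histograms
on the union of observed degrees (absent degree = frequency 0) and reports
per-degree mean and standard deviation. Flux histograms are computed at the
single returned optimum; with degenerate optima they are solver-dependent,
which is why tests pin the solver's deterministic pivoting rules.

## Degenerate and edge inputs

* `A = 1, L = 1`: one metabolite, zero reactions; models on it solve (the
  biomass can only be fed by direct import).
* Empty nutrient set: the model is valid and its optimum is exactly 0 — mass
  cannot be created at steady state.
* A pruned network can retain zero internal reactions when every precursor
  is itself a nutrient; `network_size()` then reports participating
  metabolites of an empty reaction set, i.e. `(0, 0)`.
* Fixed (deleted) reactions are encoded as bounds `[0, 0]`, never by
  mutating the matrix, so deletion studies leave the model untouched.

## Known limitations

* The simplex kernel is dense and factorizes bases of size equal to the
  metabolite count; it is comfortable for the desk-scale universes this
  package targets (hundreds of reactions) and is not intended for
  genome-scale matrices.
* Greedy pruning outcomes depend on the solver's choice among degenerate
  optimal vertices; with the fixed pivot rules used here they are fully
  reproducible, but a different LP solver could legitimately return
  different (equally valid) minimal networks.
* The SBML writer emits Level 3 Version 1 with the flux-bound (`fbc`)
  extension — enough for standard constraint-based toolchains — and does not
  read SBML; external models are out of this package's scope.
* No power-law fitting is attempted: the heavy-tail check on pruned-network
  degree distributions is deliberately a conservative structural assertion
  (low modal degree, long tail), not a formal scale-free hypothesis test.
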