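---
title: "Multi-objective reserve prioritization: models, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective reserve prioritization: models, generator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reservemax)
```

`reservemax` builds and solves the integer programs behind a two-scenario
protected-area prioritization for the boreal caribou distribution: a
network-*expansion* scenario driven by an area budget, and a
*habitat-protection* scenario driven by per-sub-population critical-habitat
targets. This vignette explains the models and their assumptions, the
synthetic landscape the package tests itself on, and the choices made where
the design was genuinely open.

## Planning units and conservation values

The decision space is a set of planning units — hexagonal grid cells of
nominal area 5000 km² (a reasonable minimum size for a protected area),
clipped where the grid crosses the distribution boundary, so a landscape
mixes full and partial units. Each unit carries its total area, the area
already protected, and two precomputed "undisturbed" areas: the unprotected
area more than 500 m from human disturbance, and that area additionally
unburned for over 40 years. The GIS work that produces these columns
(buffering, fire-history overlay, zonal statistics) is upstream of this
package; units, adjacency and per-unit sums arrive as plain CSV tables.

Six conservation values are computed per unit (`assemble_objective_matrix()`):

* **caribou habitat** — the scenario-specific undisturbed area (human-only
  definition for the expansion scenario, full definition for the habitat
  scenario, where it enters through constraints instead of the objective);
* **species richness** — the number of at-risk species whose extent of
  occurrence overlaps the unprotected portion of the unit;
* **taxonomic representation** — a modified inverse Berger–Parker index,
  species count divided by the count in the dominant taxonomic group;
* **unique species** — the count of present species covering ≤ 20% of the
  distribution with > 50% of their Canadian extent inside it;
* **climate refugia** — the summed 0–1 refugia-potential score over the
  unprotected portion;
* **soil carbon** — tonnes of organic carbon in the top metre of soil.

Two readings of the Berger–Parker denominator are defensible: the dominant
group *among the unit's own species* (so the index is 0 for an empty unit
and otherwise at least 1, rewarding within-unit taxonomic spread), or the
most speciose group *in the whole species pool* (a fixed rescaling of the
unit's dominant-group count that can fall below 1). The per-unit reading is
the default because it is the dominance form of the index and keeps the
invariant `value ∈ {0} ∪ [1, n_groups]`; `taxonomic_denominator = "global"`
switches to the pool reading. An empty unit scores 0 by convention — this
keeps the objective finite and monotone in presence. Filter boundaries are
applied exactly as printed: coverage ≤ 0.20 inclusive, inside-fraction
> 0.50 strict.

## The four integer programs

All problems select binary units `x_i` with cost `c_i` equal to the unit's
unprotected area — the area actually added to the network.

**Single-objective selection** is a budgeted knapsack: maximize
`Σ v_ik x_i` with `Σ c_i x_i ≤ B`. Its optimum `V*_k` serves as the
normalizer ("best possible outcome") for the multi-objective problems, and
`V*_k / Σ_i v_ik` is reported as the coverage of the maximum possible
value.

**Expansion maximin**: maximize `t − p Σ s_i` subject to
`Σ_i v_ik x_i ≥ t · V*_k` for every objective and the budget. Because of
the normalization, `t` is directly the minimum "fraction of best" across
objectives. The default budget fraction is 0.195 — the gap between a
landscape 10.5% protected and a 30% protection commitment.

**Minimum-area coverage**: minimize `Σ c_i x_i` subject to
`Σ_i h_{i,s} x_i + P_s ≥ target_s` for each sub-population `s`, where
`h_{i,s}` is the unit's unprotected undisturbed habitat inside the range
and `P_s` the already-protected undisturbed habitat, which is credited
toward the target. Targets are `scaling × pct × range_area` with
`pct = 0.40` for one designated sub-population and `0.65` for the rest,
capped at the habitat actually available — capping makes the problem
feasible by construction and the capped flag is reported.

**Habitat-target maximin**: maximize
`t − p Σ s_i − q (Σ c_i x_i) / C_total` subject to the habitat-target
constraints and maximin constraints over the five non-caribou objectives.
There is no budget; the dimensionless penalty `q` (normalized by the total
unprotected area `C_total`, so the 0–1000 design grid is comparable across
landscapes) governs how much extra land the optimizer will add beyond what
the targets force. Normalizers for this problem are the per-objective
optima at a budget equal to the minimum area for the same targets,
recomputed per scaling.

### Elastic minimum-area constraints

Partial units below 5000 km² should only be selected if, together with
their surroundings, they can anchor a viably sized protected area. The
constraint for unit `i` is

```
A_i + Σ_{j∈N(i)} (prot_j + c_j x_j) + M s_i ≥ M x_i,  s_i ∈ [0, 1]
```

with `M` the nominal unit area. Three choices here were open and are worth
recording:

* "its area" is the unit's **total** area `A_i` (its land counts regardless
  of protection status);
* neighbors contribute both their existing protected area and their
  **co-selected** unprotected area, so clusters of mutually adjacent small
  units can jointly qualify — the contiguity reading of the constraint;
* the violation is a **continuous** shortfall fraction `s_i` penalized
  linearly at rate `p`, which keeps the LP relaxation tight; a binary
  violation indicator would be a coarser alternative.

When `p = 0` the solver leaves slack values arbitrary, so reported
per-unit shortfalls are always recomputed analytically from the returned
selection — they are deterministic diagnostics, not solver output. The
minimum-area problem omits these constraints by default
(`include_minarea = TRUE` adds them as hard constraints).

## Solving

`solve_milp()` passes the assembled mixed-integer program to the HiGHS
branch-and-cut solver through scipy in a Python subprocess (JSON in, JSON
out). Defaults mirror standard planning practice: a 0.5% relative gap
tolerance and a 300 s time limit, after which the best feasible incumbent
is returned and flagged `feasible_timeout`. The desk-scale problem sizes
here (≤ a few hundred units) solve in well under a second each, so the
time limit is a guard, not a constraint. `brute_force_solve()` enumerates
all subsets of up to 20 units, computing optimal slack and maximin levels
analytically per subset and breaking objective ties toward the
lexicographically smallest id-set; it is the exact oracle against which the
solver path is tested on hundreds of random instances per problem class.

Statuses are `optimal_within_gap`, `feasible_timeout`, or `infeasible`;
reported bounds are clamped so the incumbent never appears to beat its own
bound through floating-point roundoff.

## The synthetic landscape generator

Real inputs for the 665-unit study system live in an external deposition;
the generator produces landscapes with the same *statistical* structure so
every stage of the pipeline is exercised without a download. The default
profile is a 10 × 20 hex grid (200 units), 80% of boundary units clipped to
partial areas, 10.5% of area protected in clustered blocks, a clustered
human-disturbance footprint affecting 35% of unprotected area plus 15%
fire-only disturbance, 10 overlapping sub-population ranges (one with the
0.40 target), and 80 species in up to nine taxonomic groups with
heavy-tailed range sizes.

Choices worth knowing:

* **Determinism.** Every stage draws from its own substream derived from
  the root seed, so adding or rerunning a stage never perturbs the others;
  all outputs are pure functions of (config, seed).
* **Value layers.** One latent Gaussian field per objective is smoothed by
  neighbor averaging (`smoothing_passes`, default 2) for spatial
  autocorrelation, whitened against its empirical covariance, mixed by the
  symmetric square root of the configured correlation matrix — so latent
  (log-scale) cross-layer correlations match the configuration *exactly in
  sample* — and exponentiated (`exp(0.75 · field)`) into nonnegative values
  with localized hotspots. Exponentiation attenuates value-scale Pearson
  correlations by roughly 0.05 at the strongest configured pair; the
  default correlation matrix is weak (|r| ≤ 0.2) except a 0.8
  richness–taxonomic pair, mirroring the strong overlap those two
  objectives show in the real system.
* **Protection and disturbance.** Protection grows breadth-first from a few
  seed units with the final unit only partially protected, so the realized
  protected fraction lands on the 10.5% target rather than near it.
  Disturbance fractions come from smoothed lognormal fields rescaled to
  their aggregate targets; the ordering
  `undist_full ≤ undist_human ≤ unprotected` holds by construction.
* **Sub-populations and species.** Ranges grow by randomized multi-source
  region growing and absorb adjacent foreign units with probability 0.3 to
  create overlap; each unit's habitat and protected-undisturbed area are
  split equally among covering ranges, which guarantees the habitat-sum
  invariants. Species metadata are *recomputed from* the generated ranges
  (coverage fraction = range area / landscape area); the inside-Canada
  fraction is drawn from a mixture with a 0.09 high-component probability,
  calibrated so a handful of the 80 species pass the uniqueness filter, as
  in the real species pool.
* **What is not emulated.** No real geography, no polygon geometry (partial
  units are area reductions, not clipped shapes), and only
  order-of-magnitude value scales. Passing tests on these landscapes show
  the *optimization and reporting machinery* is correct under realistic
  structure; they do not validate conclusions about any real region.

## Scenario orchestration and reporting

`run_expand_protection()` and `run_protect_habitat()` run the full
procedure: single-objective suite, normalizer assembly, multi-objective
solve, and audits (budget satisfied, every effective target met, slack
totals). Reports include the per-objective fractions of best, the
trade-off matrix (each single-objective plan evaluated on every other
objective), and the count of *exceptions* — objective pairs where some
single-objective plan beats the multi-objective plan on a third objective.
On default synthetic landscapes the multi-objective plan wins the large
majority of pairs; the exceptions that do occur are concentrated in the
strongly correlated richness–taxonomic pair, the same place the real
analysis found them. This pattern is reported by the test suite, not
asserted, since it is a property of the landscape draw.

`sensitivity_grid()` sweeps the penalty designs (the standard grid is
0, 0.001, 0.01, 0.1, 1, 10, 100, 1000 for both penalties; crossed with the
four target scalings the habitat design has 256 cells) and reports per-cell
summaries plus the pairwise Jaccard matrix of selections; cells can be
checkpointed to files and resumed. The reported default configurations are
a zero minimum-area penalty for the expansion scenario and
`(p, q) = (0, 10)` for the habitat scenario.

## Overlap statistics

`jaccard_coefficient()` compares selections as unit id-sets (no area
weighting — the analysis is unit-level throughout).
`expected_jaccard()` gives the reference expectation under independent
uniform subsets of the observed sizes; the exact method collapses the
enumeration over all subset pairs through the hypergeometric distribution
of the intersection size. `jaccard_permutation_test()` draws seeded null
subset pairs with fixed marginal sizes and applies the add-one p-value
`(1 + #{at least as extreme}) / (1 + n_permutations)`, so p is never
exactly 0; the two-sided alternative doubles the smaller tail. A
permutation test with fixed set sizes was chosen as a transparent,
assumption-light stand-in for packaged Jaccard significance tests whose
internal method varies; exact p-value matching against any particular
package is a non-goal. Because J is discrete, the test is conservative to
a degree that depends on where the α threshold falls between hypergeometric
atoms; the calibration check in the test suite uses 120- and 125-unit
selections from a 250-unit universe, for which the exact operating
characteristic at α = 0.05 is ≈ 0.049 rejections under the null.

## Numerical conventions and degenerate inputs

* Area identities are checked to 1e-6 km²; read/write round-trips preserve
  numeric fields to 1e-9.
* A zero normalizer (an objective unattainable at the budget) is an error
  at problem build time; the habitat scenario substitutes a unit normalizer
  only in the fully degenerate case of all-zero targets, where the optimum
  is the empty selection regardless.
* Zero-target sub-population constraints are dropped as vacuous; a target
  exceeding available habitat cannot arise through `compute_effective_targets()`
  (capping) but is reported `infeasible` if constructed by hand.
* Brute-force ties are broken toward the lexicographically smallest
  selected id-set; the branch-and-cut backend makes no such promise, so
  cross-route tests compare objective values, not selected sets.
* Empty selections evaluate to zero on every objective; the Jaccard of two
  empty sets is 0 by convention.

## Problem sizes used in the tests

The test suite runs entirely on generated data: oracle-equivalence sweeps
use 200 random instances of 4–12 units across the four problem classes;
monotonicity checks use 10-unit instances under exhaustive enumeration;
generator-fidelity checks use 20 seeds of an 80-unit grid; and the
end-to-end scenario checks use the default 200-unit profile with 10
sub-populations — the package's desk-scale stand-in for the 665-unit
system, chosen so the full suite and the acceptance script each complete in
a few minutes on a single CPU.

## Known limitations

* No spatial-configuration or connectivity objectives: units with equal
  undisturbed area are equal in value regardless of its arrangement, and
  the minimum-area constraint is the only spatial coupling.
* Area stands in for cost; no land-price or stewardship-cost surface.
* No heuristic solvers; everything goes through exact branch-and-cut (or
  enumeration), which is the right tool at these problem sizes.
* The generator's species and disturbance processes are statistical
  stand-ins — results on synthetic landscapes characterize the method, not
  any real planning region.
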