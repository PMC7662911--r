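---
title: "Methods: multi-objective RCF configuration and the modified immune algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-objective RCF configuration and the modified immune algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcfopt)
```

## The problem and the model

A district holds `I` population centers with care demand `w_i` (the share of
the elderly needing residential care, 2.5% under the planning norm) and `J`
pre-screened candidate facility sites with a bed-capacity class (300 beds for
downtown districts). A configuration opens `p` sites, sizes beds, and
allocates each center to its nearest open facility. Four constraint families
define feasibility: the open count equals `p`; every center is allocated
exactly once; allocation only to open sites; open sites hold between 1 and
`max_beds` beds.

Access is measured by gravity-based accessibility: a facility's beds are
discounted by travel distance to the power `-beta` and shared among the
demand competing for them,

$$A_i = \sum_j \frac{v_j d_{ij}^{-\beta}}{\sum_{i'} w_{i'} d_{i'j}^{-\beta}}\, Y_j.$$

Its demand-weighted mean collapses algebraically to total beds over total
demand, `a = V/W`, independent of geometry; the test suite asserts this
identity to machine precision on 1000 random instance/configuration pairs,
which pins the implementation of both numerator and denominator.

Four stakeholder objectives are scalarized: equity (squared dispersion of
`A_i` around `a`, minimized), configuration efficiency (mean relative change
of `A_i` versus a pre-optimization baseline, maximized; skipped with its
weight renormalized when no baseline exists, as in greenfield scenarios),
per-capita travel cost (minimized), and mean facility profit (maximized,
with the surveyed bed charge 2050 and running cost 1250 currency units per
bed-month). Each objective is min–max standardized over the current solution
population so that smaller is better on `[0, 1]`, combined with weights
(equal by default; an optional adaptive mode weighs objectives inversely to
their current range), and multiplied by an adaptive penalty
`r = 1 + mean_g (db_g/db_{g,max})^eta >= 1` over the four constraint
families. The optimizer maximizes affinity `1/F`, `F = f r`, with `f`
floored at `1e-6` so affinity stays finite.

Two conventions deserve a note. First, the profit objective divides by the
number of *open* facilities, which is what makes the reported per-facility
unit come out right (a mean over all candidate sites would shrink as the
candidate pool grows, which is not a property of any investor's profit).
Second, the penalty is built to *increase* `F` with violation; a penalty
that rewarded violations would invert the search.

## The modified immune algorithm

Antibodies are sorted `p`-subsets of site indices; completing one to a full
configuration (nearest allocation, demand-sized beds) is deterministic, so
raw objective vectors are memoized per encoding. Each generation:

1. **Scoring.** Population and memory bank are standardized and penalized in
   one shared context; affinity is `1/F`.
2. **Memory.** The bank (capacity `N/2`) keeps the best distinct encodings;
   population antibodies Jaccard-similar (threshold 0.8) to a strictly
   better memory cell have their selection score damped (factor 0.5) so
   crowded lineages lose ground.
3. **Clonal selection.** Scores are normalized affinity times
   `(1 - concentration)`, where concentration is the fraction of the
   population similar to the antibody. Antibodies above the
   `sigma(t)`-quantile are cloned, with a fixed total clone budget
   apportioned by largest remainder. The threshold `sigma(t)` stays at
   `a_sel = 0.3` until `t_ave = t_max/2`, then rises to 1 along a quarter
   sine wave: broad cloning early, sharply elitist late.
4. **Mutation.** With probability `P_m(t) = eps |cos(2 pi t / T)| + gamma`
   (defaults `eps = 0.1`, `gamma = 0.05`, `T = t_max/5`) a clone is replaced
   by an elite recombination offspring: weights drawn uniformly on
   `[-0.5, 1.5]` and renormalized to sum to one combine the top `10%` of
   the population as real index vectors, then rounding and
   nearest-unused-index repair restore a valid subset. Clones that skip the
   draw undergo a plain index swap with probability 0.05, keeping a light
   local search.
5. **Perturbation.** Every `theta` iterations the *working* comparison value
   of the global best is inflated by `exp(-t/theta) u^2`; the archived
   incumbent is never touched, so convergence reporting stays monotone while
   stale incumbents are easier to displace early.
6. Parents and mutated clones are re-scored together and truncated to `N`.

**Reporting contexts.** Because standardization bounds are
population-relative, `F` values from different generations are not directly
comparable. The per-iteration `best_F` trace is therefore the running
minimum of generation-context values (non-increasing by construction), and
the returned solution is chosen by re-scoring every *search-visited*
encoding in one final context whose bounds are pinned by a deterministic
reference population — the full enumeration when `choose(J, p) <= 1000`,
otherwise 600 uniformly sampled subsets. The reference only pins the scale;
it is never eligible to be returned, so the search is not silently replaced
by random sampling. Without the pinning, a cache biased toward good
solutions underestimates the worst-case ranges and can flip the ranking of
near-ties; with it, the optimizer's final choice agrees with an exhaustive
enumeration scored over the whole subset space.

Several symbols in the source description of the algorithm are ambiguous or
corrupted; the package resolves them as follows and exposes each as a
parameter: the ramp of the selection threshold is a sine from `a_sel` to 1
over `(t_ave, t_max]` with `t_ave = t_max/2`; antibody concentration
(undefined in the original description) is the population share with
Jaccard similarity of site sets at or above 0.8; the elite pool is 10% of
the population (at least 2); the perturbation decays as `exp(-t/theta)`
because a constant exponent would contradict the stated weakening. The text
also claims the mutation probability must stay positive at `t = kT/2`,
where the cosine magnitude is in fact 1; the formula is implemented as
printed and `gamma > 0` guarantees positivity at the actual zeros,
`t = (2k+1)T/4`.

## Baselines

GA (tournament of 2, one-point crossover on the index sequence with
duplicate repair, swap mutation, one elite), global-best PSO on the relaxed
real vector with the same rounding repair as the recombination offspring,
and a standard IA (fixed threshold, constant mutation probability, swap
mutation only) consume the identical evaluation engine, so any scoring
change affects all algorithms equally. `compare_algorithms()` re-scores the
per-algorithm winners against each other in one shared context and reports
relative gaps as `(other - reference)/other`, and iterations to convergence
as the first iteration within `1e-6` of the final best.

## Planning workflow

`plan_configuration()` runs the applied three-step pipeline:

1. **Relocate.** A same-count optimization provides model-optimal sites; an
   existing facility is flagged when it is farther than a tolerance
   (default 500 m) from every optimal site *and* redundant — closing it
   moves none of its centers more than the tolerance farther from service.
   Retained facilities are resized to their nearest-allocation demand capped
   at capacity; the overflow at a capped facility is peeled from its
   farthest-assigned centers. The boundary center can be left partially
   unmet, so the final combined configuration uses a fractional allocation
   matrix whose rows still sum to one; an all-or-nothing rule would
   overstate unmet demand relative to the capacity arithmetic (an overflow
   of 50 at a 300-bed cap is 50 unmet persons, not a whole center).
2. **Extend.** The residual problem (unmet centers, unoccupied sites) is
   swept from the minimum feasible count `ceiling(unmet/cap)` upward; the
   per-count winners are re-scored in one shared context and the count with
   the lowest comprehensive value wins.
3. **Size.** New facilities take their catchment demand as beds, which by
   construction sums to the unmet demand.

The evaluation report deliberately re-determines the decay exponent per
configuration: existing configurations are assessed at `beta = 1.8` (the
value consistent with observed travel behavior), optimized ones at
`beta = 1` (the dispersion-minimal value a grid scan selects after
optimization, see below). Travel is evaluated under the model's own
supposition that each center is served by its nearest open facility. Two
published improvement rates in the source case study (equity 64.23%, travel
cost 18.53%) are inconsistent with their printed before/after values; the
package reports plain relative differences (69.29% and 28.53% on those
numbers) and makes no attempt to reproduce the unexplained rates.

The quantity assessment converts gravity accessibility (beds per
demand-person) into beds per 100 elderly with each center's demand rate
before comparing against the 2.5/100 planning target; the two scales differ
by the demand rate and comparing them directly would make the target
unreachable by two orders of magnitude.

## Distance-decay sensitivity

`beta_sensitivity()` recomputes the field over a grid (default 0.8–2.4 in
steps of 0.2, nine scenarios) and summarizes each with max, min and the
unweighted population standard deviation; dispersion grows with `beta`, and
`select_beta()` picks the dispersion-minimal exponent (ties to the smaller
value). The package exposes only this grid scan; calibrating `beta` against
interview-based travel times is outside its scope.

## The synthetic district generator

`generate_scenario()` emulates a dense downtown district: clustered centers
(5 clusters, 500 m spread on a 6 km square), lognormal elderly counts
(meanlog 7, sdlog 0.5, so per-center demand at the 2.5% rate is ~30,
matching the demand density of a real central district), 120 candidate
sites placed mostly near population, and 12 existing facilities with three
planted defects the workflow is meant to expose: a fraction (default 0.15,
i.e. 2 of 12) sited in low-demand corners; per-facility bed imbalance
(half around 2.5x their catchment demand, half around 0.15x); and an
overall supply ratio of 0.7 of demand, mirroring the typical central-city
bed deficit. With these settings the generated "current" configurations
show roughly 75–85% of centers below the 2.5/100 target and an
accessibility Gini near 0.45–0.55 at the assessment exponent — the same
order as reported for real dense districts — so the planning pipeline is
exercised under realistic starting inequality. Distances are Euclidean with
a 1 m floor (the decay weight diverges at zero distance), or shortest paths
over a random connected road graph (4-nearest-neighbour links plus
connecting edges, 20% length wiggle, per-edge dwell times up to 60 s
converted to distance at 3–8 m/s speeds).

What the generator does *not* emulate: real street geometry, correlated
land-use constraints on candidate sites, demographic change over time, and
demand elasticity to accessibility. Passing tests on synthetic districts
shows the pipeline is internally coherent and improves planted
inefficiencies; it does not validate the behavioral calibration of `beta`
or the cost parameters on any real district.

## Problem sizes, tolerances, degenerate inputs

The test and acceptance workloads use desk-scale sizes chosen to keep full
runs in minutes: oracle instances with `choose(10, 3) = 120` subsets
(exhaustive enumeration is the ground truth; the optimizer at `N = 30`,
`t_max = 300` is expected to recover it in at least 95% of 20 seeded runs
per instance), and 10 synthetic districts at the default 60 x 120 scale
with `N = 40`, `t_max = 100` for the workflow stages. Numerical choices:
nearest-allocation ties break to the lowest site index; degenerate
standardization ranges map to 0.5; the scalarized `f` is floored at `1e-6`;
recombination weight draws are rejected when their sum is within 0.1 of
zero; distance matrices must be strictly positive (clamp co-located pairs
with `clamp_distances()`). Configurations whose retained facilities lose
their whole catchment during adjustment close those facilities rather than
carrying a zero-bed open site, which the capacity constraint would reject.

## Known limitations

* The scalarization is a weighted sum; no Pareto front is computed, and
  solutions optimal under other weightings are invisible.
* Comprehensive values are only comparable within one standardization
  context; cross-run comparisons must re-score in a shared context (the
  package does this in its sweep and comparison functions).
* The two-stage plan allocation holds retained catchments fixed when siting
  new facilities; a joint re-optimization could do better at the cost of
  abandoning the published three-step structure.
* Profit uses a single district-wide margin; site-specific land or staffing
  costs are not modeled.
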