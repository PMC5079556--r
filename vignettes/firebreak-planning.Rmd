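---
title: "Centrality-guided fuel-break placement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality-guided fuel-break placement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firebreaks)
```

## The problem

Fuel breaks -- land patches cleared of flammable vegetation -- are the
main preventive instrument against large wildland fires, but deciding
*where* to cut is hard: treating the densest stands first (the
conventional forestry practice) ignores how fire actually travels
through a landscape.  This package implements a two-level approach:

1. fire spread is modelled as a stochastic cellular automaton (CA) on a
   square lattice of land patches, and
2. the CA's cell-to-cell ignition probabilities are read as the edge
   weights of a directed network, so that *network centrality* measures
   identify the patches through which fire flows most readily; removing
   the top-ranked patches (subject to a non-clustering constraint)
   yields the fuel-break plan.

The package provides both spread models, the network construction, four
centrality measures, three placement strategies, and the Monte-Carlo
machinery to compare them: hazard-intensity curves, per-density Welch
tests, burning-frequency maps, and a phase-transition detector.

## The spread models

Each cell carries a fire state: susceptible (0), burning (1), burned
(-1).  Dynamics are synchronous; a burning cell always burns down in
exactly one step.  A susceptible cell with burning Moore neighbours
(the 8 surrounding cells) receives **one independent Bernoulli trial
per burning neighbour** in that step and ignites if any succeeds, so
with per-neighbour probabilities $p_l$ the combined ignition
probability is $1 - \prod_l (1 - p_l)$.  The pairwise probability is
defined per receiving cell; its combination across simultaneous burning
neighbours is a modelling choice, and independent trials is the
standard one for lattice contact processes.  Internally the kernel
draws one uniform per cell per step against the combined probability,
which is distributionally identical and keeps runs with common seeds
aligned across nested break plans (common random numbers).

**Simple model** (`artificial_forest()`): a flat, single-type landscape
where each cell has an *emptiness* $s_2 \in [0,1]$ (1 = bare or burned,
0 = very dense).  Fire enters a cell with probability $p_b = 1 - s_2$.
The synthetic forest draws $s_2 \sim U(0,1)$ i.i.d. on an $n \times n$
torus; this is the ensemble all desk-scale experiments use.

**Full model** (`synthetic_landscape()`, `read_landscape_rasters()`):
heterogeneous terrain where the probability of a crossing from cell $l$
into cell $k$ is

$$p_{l \to k} \;=\; p_0\,(1 + s_{2k})\,(1 + s_{3k})\,e^{a\,\theta_s},$$

with $s_{2k}$ the vegetation-type effect, $s_{3k}$ the density effect
(both looked up from category tables), and $\theta_s$ the slope angle
of the crossing: $\tan^{-1}((E_l - E_k)/\ell)$ for orthogonal
neighbours and $\tan^{-1}((E_l - E_k)/(\ell\sqrt2))$ for diagonal ones,
$\ell$ the cell side.  The product may exceed 1 (steep slopes, dense
pine) and is clamped to $[0,1]$.  A multiplicative wind hook
(`wind_gain`) is exposed but defaults to 1; no wind formula ships.

Defaults (`ca_params()`): $p_0 = 0.58$ and $a = 0.078$, values
calibrated against observed Mediterranean island wildfires, with
density effects $\{-0.4, 0, 0.3\}$ (sparse/moderate/dense) and type
effects $\{-0.3, 0, 0.4\}$ (agricultural/other/pine) and a 10 m cell
side.  Note the sign convention of $\theta_s$ follows the formula as
calibrated: the gain exceeds 1 when the burning cell sits above the
receiving one.

## The fire-spread network

`build_network()` emits one directed edge per ordered Moore-neighbour
pair with positive crossing probability; entry $(l, k)$ of the sparse
adjacency is the weight of $l \to k$, fire flowing *into* $k$.
Non-flammable cells are isolated.  Shortest-path measures need
distances that shrink as probabilities grow; the default transform is
the literal reciprocal $1/p$ (`edge_distance()`), with $-\log p$
available -- both are monotone, so rankings on uniform-structure
lattices agree.

Four measures (`centrality()`):

* **betweenness** -- weighted-geodesic betweenness with exact path
  multiplicity (Brandes' algorithm via igraph), paths taken in the flow
  direction;
* **closeness** -- inverse summed out-distances; with unreachable
  targets the sum runs over reached nodes $r$ and is penalised as
  $(r/(N-1)) / \sum d$, so isolation lowers the score (closeness is not
  used by the acceptance experiments);
* **eigencentrality** -- the principal eigenvector of $A^\top$ (a
  node's weight aggregates its in-edges), by sparse Arnoldi (ARPACK)
  iteration, unit-sum normalised;
* **Bonacich** -- $x = (I - (\beta/\lambda_{max})A^\top)^{-1}e$ by a
  sparse direct solve.  The attenuation is read as
  $\beta/\lambda_{max}$: the literal product $\beta\lambda_{max}$ would
  make the series diverge for any $\beta \ge 1/\lambda_{max}^2$,
  whereas the Katz-style scaling reproduces the stated limits -- the
  weighted in-degree ordering as $\beta \to 0$ (at $\beta = 0$ the
  solved vector is exactly constant; the first-order term carries the
  degree ranking) and eigencentrality as $\beta \to 1$.

Numerical choices: eigenvector solves use relative tolerance $10^{-8}$
with an iteration cap of $\max(3000, 10N)$; score ties are broken by
ascending node index (`rank_nodes()`), making every ranking
deterministic.

## Placement strategies and the adjacency constraint

`place_by_centrality()` (and the generic `place_breaks()`) sweep a
ranking computed **once on the intact landscape**, best first, skipping
any node adjacent to an already-selected break, until
$\lfloor d_f n_v + 1/2 \rfloor$ breaks are placed ($n_v$ = flammable
cells; rounding half away from zero).  Re-ranking after each removal is
a documented extension, deliberately off: the method's appeal is one
cheap global computation.  If the constraint exhausts candidates the
plan reports the shortfall in `d_f_achieved` rather than failing --
near the packing limit that is the honest answer.

"Adjacent" means the **4 orthogonal neighbours** (`exclusion =
"rook"`), the same sense in which the slope formulas distinguish
adjacent from diagonal neighbours.  The distinction matters
quantitatively: under an 8-neighbour (Moore) exclusion the densest
feasible break pattern covers only 1/4 of the lattice and a greedy
random sweep jams near 0.19, well below the break densities the sweep
experiments must reach, whereas the orthogonal rule admits checkerboard
patterns up to density 1/2.  The Moore variant remains available as an
option.

The **random benchmark** (`place_random()`) is an unconstrained uniform
scatter by default: the non-clustering rule exists to stop *top-ranked*
cells -- which are spatially correlated -- from coalescing into one
clearing, a failure mode a uniform scatter does not have.  Empirically
the constraint flatters the random strategy (rook-constrained random
spaces its breaks better and its hazard curve plateaus instead of
completing its transition), so benchmarking against constrained random
would understate the gap the ranked strategies must beat.  Both
constrained variants remain available.

The **conventional benchmark** (`conventional_ranking()`) orders cells
dense-pine, dense-other, moderate-pine, moderate-other, sparse-pine,
sparse-other, with agricultural cells (any density) last -- the sort
omits them, and placing them last keeps the ranking total.  Ignition
cells known in advance are excluded from removal (`forbidden`); in
multi-ignition campaigns ignitions are drawn after planning and no
exclusion applies.

## Hazard campaigns

`hazard_campaign()` evaluates strategies over a grid of break densities
$d_f$, recording each run's burned fraction $n_b/n_v$.  The hazard
intensity $R(d_f)$ is the mean burned fraction; 90th percentiles
accompany it.  Two modes:

* **ensemble** -- independent landscape realisations, one fire each
  from a fixed (default central) ignition: the artificial-forest
  protocol, 100 realisations of a $50\times50$ torus by default;
* **multi-ignition** -- one landscape, many fires from uniformly random
  flammable ignitions (drawn from the untreated landscape; a fire whose
  ignition falls on a break burns nothing).

Break sets along the $d_f$ sweep are nested prefixes of one greedy
sweep per (landscape, strategy), and simulation seeds are shared across
strategies and densities, so comparisons are paired.  All seeds derive
from `base_seed` (landscape seeds `base_seed + run`; placement and
simulation streams at fixed offsets), making campaigns bit-reproducible.
The default sweep, 0 to 0.5 in steps of 0.02, brackets both plateaus of
every strategy while keeping the transition localisable to about
$\pm 0.01$.

`compare_strategies()` applies the unequal-variance (Welch) two-sample
t-test to the per-run burned fractions at each $d_f$; Welch is the
safer default near the transition, where variances differ sharply
between strategies, and the pooled test is a switch away.

`detect_transition()` formalises "where the curve drops": the high
plateau is the mean of the first two grid points, the low plateau the
mean of the last two, and the transition $d_f^*$ is the first crossing
of their midpoint, linearly interpolated between the bracketing grid
points.  A pure step between grid points is therefore located at the
segment's interpolated crossing, not at a grid point; a curve that
never crosses raises a `no_transition` condition rather than returning
a number.

`burning_frequency_map()` repeats one fire many times from the same
ignition, bins the nonzero per-cell burn frequencies into 16
equal-width bins over $(0, \max]$, and assigns the bins -- descending
-- the gray levels $256, 240, \ldots, 16$, so the most frequently
burned cells are darkest.  Zero-frequency cells would otherwise swamp
the first bin, so they sit outside the scale (white on export).  The
nominal level 256 exceeds the 8-bit range and is clamped to 255 in
image output only; the numeric map keeps exact levels.

## What the synthetic data does and does not emulate

The artificial forest reproduces the published study conditions
exactly: i.i.d. $U(0,1)$ emptiness, periodic boundaries, central
ignition.  It has no spatial autocorrelation in fuel, no terrain, no
wind, and wraps at the edges -- so conclusions drawn from it concern
the *method* (does centrality targeting beat random or conventional
placement under identical dynamics?), not any real landscape.  The
heterogeneous generator (`synthetic_landscape()`) adds categorical
fuel mixes (20 % agricultural, 40 % other, 40 % pine; equal density
thirds), a smooth sinusoidal relief of 60 m over 10 m cells (slopes up
to roughly 30 degrees) and 5 % bare cells, with absorbing boundaries --
plausible Mediterranean-island statistics, but still free of the
spatial structure (roads, ridgelines, stand contiguity) of real GIS
data, which is why the package also reads real rasters.

Test problem sizes are chosen to make the checks sharp but quick: the
ensemble experiment runs the full 100 forests at $50\times50$; oracle
comparisons use digraphs of up to 30 nodes where brute-force path
enumeration is exact; kernel Monte-Carlo checks use $10^5$ trials
(standard errors ~0.14 %); the heterogeneous comparison uses one
$40\times40$ landscape with 150 paired ignitions.

## Known limitations

* Exact betweenness on production-scale lattices (~$10^6$ nodes) is
  computationally out of reach; the spectral measures (Bonacich,
  eigencentrality) are the scalable choices, and approximate
  betweenness is deliberately not offered.
* Eigencentrality itself tends to localise on dense clusters and
  under-performs even random placement at high break densities -- it is
  included as a measure precisely to exhibit this.
* One-step burn-down admits no fuel-load or moisture dynamics, no
  spotting, and no wind (the hook accepts a per-direction multiplier
  if the user supplies one).
* The greedy, rank-once planner makes no optimality claim; it is the
  method under study, not a general optimiser.
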