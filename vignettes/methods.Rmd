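---
title: "Equity-aware facility siting with the Kolm-Pollak EDE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equity-aware facility siting with the Kolm-Pollak EDE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equisite)
```

## The access model

`equisite` measures a population's access to an amenity as the walking
distance from each demand block to its *nearest* open facility. This is
deliberately minimal: it ignores capacity, demand, store quality and
trip chaining, but proximity is a necessary condition for walkable
access and is the quantity a siting intervention directly moves.
Distances are consumed as data (a complete block-by-site matrix in
metres, typically from a road-network router); the package never
derives an access distance from coordinates, which exist only for
boundary geometry and mapping.

## The inequality-penalized average

A plain population-weighted mean hides the tail: it improves just as
much by trimming metres off many short walks as by fixing one
neighbourhood's very long walk. The Kolm-Pollak
equally-distributed-equivalent (EDE) distance,

$$K(\mathbf z) = -\frac{1}{\kappa}\,
  \ln\!\Big[\frac{1}{T}\sum_r p_r\, e^{-\kappa z_r}\Big],
  \qquad \kappa = \alpha\,\varepsilon,$$

is the uniform distance the community would accept in exchange for its
actual distribution. For a burden like distance the aversion parameter
is negative ($\varepsilon = -1$ by default), making $\kappa < 0$ and
placing the EDE at or above the weighted mean — with equality exactly
when everyone is equally served. Larger $|\varepsilon|$ penalizes the
tail harder. The scaling

$$\alpha = \frac{\sum_r p_r z_r}{\sum_r p_r z_r^2}$$

(units 1/m) adapts $\varepsilon$ to the data and makes the metric
scale-equivariant: rescaling all distances by $c$ rescales $\alpha$ by
$1/c$ and the EDE by $c$, so the choice of metres is a convention, not
a modelling assumption.

Two numerical regimes matter. For large $|\kappa z|$ the exponentials
overflow naive evaluation, so `kp_ede()` uses a shifted log-sum-exp.
For $|\kappa z| \to 0$ the EDE converges to the weighted mean, but the
shifted form divides a cancelling logarithm by a vanishing $\kappa$;
below $|\kappa z_{max}| < 50$ the implementation therefore switches to
an `expm1`/`log1p` formulation, which reproduces the mean to full
precision in the limit. $\kappa = 0$ itself is rejected with an
explicit error pointing callers to the mean — silently switching
formulas at a threshold masks bugs.

Zero-population blocks are accepted everywhere and contribute to no
sum; they are common in census extracts and dropping them at input
would complicate round-trip I/O.

## Walk-time convention

Distance targets are interconverted with walk times at a fixed
80 m/min: the constant consistent with the planning equivalences
1200 m = 15 min, 800 m = 10 min and 400 m = 5 min. Prose rules of
thumb in the planning literature imply anywhere from 75 to 85 m/min;
we standardize on the exact 80 m/min correspondence and expose the
speed as an overridable argument (`WALK_M_PER_MIN`).

## The two siting questions

With sites $S$ (existing stores $C \subseteq S$ plus candidate
locations), binary open variables $x_s$ and assignment variables
$y_{rs}$, the EDE of an assignment is a nonlinear function of the
decisions — but for *fixed* $\kappa$ it is a strictly monotone
transform of the **linear proxy**

$$\bar K(\mathbf y) = \sum_r \sum_s p_r\, y_{rs}\, e^{-\kappa d_{rs}},$$

so minimizing the proxy minimizes the EDE, and the optimum converts
back via $K = -\tfrac{1}{\kappa}\ln(\bar K / T)$.

* **Question 1** (`solve_k_stores()`): minimize the proxy subject to
  exactly $k$ new sites opened, all existing sites open, and each block
  assigned to one open site.
* **Question 2** (`solve_min_stores()`): minimize the number of new
  sites subject to the proxy not exceeding $L = T e^{-\kappa \ell}$,
  the bound equivalent to an EDE target of $\ell$ metres.

$\kappa$ itself depends on the distance distribution, so it is treated
as a constant, calibrated once on the baseline (existing-store) access
via `baseline_equity_params()` and held through optimization. The
calibration is exposed as an argument for sensitivity checks; no
iterative re-calibration is performed.

## Exact solution by branch-and-bound

The model has the classic uncapacitated facility-location structure:
once the open set is fixed, the optimal assignment puts every block at
the open site with the smallest coefficient — for both objectives, its
nearest open site. The search is therefore over candidate subsets
only. `equisite` solves it exactly with depth-first branch-and-bound:

* **Bounds.** Two complementary lower bounds are evaluated at each
  node, pruning on the tighter. (1) Opening *every* remaining candidate
  is a relaxation, since adding sites can only lower a min-based
  objective. (2) The objective reduction from opening a set of sites is
  subadditive in its members, so the current objective minus the sum of
  the `need` largest singleton gains is also a valid bound. The first
  bites when few sites remain to open, the second when many do.
* **Incumbent and order.** The search starts from the greedy solution
  (repeatedly add the best marginal site) and branches best-singleton
  first, so pruning engages immediately; optimality is still certified
  by exhausting the tree (reported `gap` is 0).
* **Ties.** Among equal-objective optima (within relative $10^{-12}$)
  the lexicographically smallest candidate-id set encountered is kept,
  so repeated runs return byte-identical plans; exactly duplicated
  candidate sites resolve to the lowest id.
* **Time limit.** `solver_opts$time_limit` (seconds) returns the
  incumbent with status `"time_limit"` rather than an uncertified
  answer presented as optimal.

Integrality of the assignment never needs relaxing or enforcing: it is
computed in closed form from the open set, and the reported assignment
maps each block to its nearest opened site with lowest-id
tie-breaking.

Question 2 is solved by bisection on $k$ over Question 1 solves, valid
because the optimal proxy is non-increasing in $k$. Infeasibility —
a target below what even the full candidate set achieves — is detected
first and reported as a status, since a too-coarse candidate grid is a
finding, not a failure.

`brute_force_k()` enumerates all candidate subsets (capped, default
20 000) and evaluates the EDE directly from the distance distribution,
never through the proxy. It is the independent oracle for two claims
tested in the suite: the branch-and-bound optimum is the true optimum,
and the proxy ranking of subsets coincides with the EDE ranking.

## Preprocessing rules

* **Density filter** (`filter_blocks_by_density()`): demand blocks at
  or below 200 housing units/km² (moderate suburban density) are
  dropped — walkable interventions are not meaningful where nothing is
  walkable, and stores there would be economically doubtful. The filter
  applies to demand blocks only, not candidate sites: it is a statement
  about where *residents* can plausibly walk, and candidate placement
  is already constrained to the in-city centroid grid.
* **Boundary buffer** (`buffer_filter_sites()`): existing stores within
  5 km beyond the city boundary are retained, since edge residents
  shop across the line; candidate sites outside the boundary are
  dropped regardless — a city cannot site stores outside its
  jurisdiction, and candidates are in-city centroids by construction.
  Polygon containment and edge distance are computed with planar
  ray-casting and point-to-segment geometry; lon/lat inputs are
  locally projected first and are never used for access distances.
* Missing block-site distance pairs are a hard error naming the first
  offenders, never an implicit infinity: a silent infinity would
  corrupt the $\alpha$ calibration invisibly.

## The synthetic-city generator

`generate_city()` produces instances with the statistical structure
the method assumes, so the whole pipeline is testable without any
download: blocks on a regular grid with a clustered (mixture-of-
Gaussians) population surface; existing stores sampled proportional to
population (real stores track demand, which is also what leaves
low-density tails underserved); candidate sites at coarse super-cell
centroids, mirroring the granularity of administrative centroid grids
and enabling genuine infeasibility at ambitious targets; and distances
from a true metric — closed-form Manhattan, or shortest paths on a
lattice with seeded random street closures (connectivity preserved),
computed with igraph. Everything is deterministic under the config
seed, and generation restores the caller's RNG state.

Defaults describe a compact mid-size town: a 12 x 12 grid at 250 m
spacing (3 km side), mean block population 40, three existing stores,
16 candidates. `perturb_access_inequality()` then manufactures the
motivating scenario — a population tail with multiplied distances —
to widen the EDE-mean gap on demand.

What the generator does *not* emulate: road-network detours of real
street grids beyond random closures, correlated store siting against
income, irregular block geometry, and multi-kilometre commercial
deserts. Tests passing on these instances certify the mathematics and
the solver contracts, not conclusions about any real city.

## Reporting conventions

Population-weighted box-plot statistics use the inverse empirical CDF
with lower interpolation (the smallest observed value whose cumulative
weight reaches the probability); duplicating weights leaves quantiles
unchanged. Whiskers extend to the most extreme observations within
1.5 x IQR of the quartiles. City rankings sort by baseline EDE, each
city with its own $\alpha$, and share dense ranks on exact ties in
first-occurrence order.

## Problem sizes and test design

The suite certifies solver exactness against full enumeration on
batches of seeded instances (25-block cities, up to 12 candidates,
$k \le 3$, 50 seeds), proxy/EDE rank equivalence across every
enumerated subset of those batches, the mean bound and small-$\kappa$
limit on 1 000 random distributions, scale equivariance across four
orders of magnitude, Question-1/Question-2 consistency (the returned
minimum count $n$ satisfies EDE$(n) \le \ell <$ EDE$(n-1)$) on 20
instances, infeasibility semantics, and the equity-versus-mean
trade-off on tail-inflated instances — where the two objectives
genuinely separate once the candidate grid is fine enough (a 16-point
grid on an 8 x 8 city); on coarser grids the same site is often
optimal for both, which is itself informative. These sizes keep the
full suite under half a minute on one core while the enumeration
oracles remain exhaustive.

## Limitations

Nearest-distance access ignores capacity and demand; $\kappa$ held at
its baseline calibration is an approximation (adequate in our checks,
and overridable); candidate grids inherited from administrative
centroids can make ambitious targets infeasible by construction; and
the branch-and-bound, while exact, is designed for desk-scale
instances (hundreds of blocks, tens of candidates) — metropolitan
instances with thousands of candidates call for a commercial MILP
solver behind the same interfaces.
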