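---
title: "Methods: spatial network morphometrics of radially symmetric particle systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial network morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`morphnet` studies how the spatial morphology of a two-dimensional
system of identical unit-diameter particles shapes the function of the
network induced by proximity. This vignette is the package's account
of its models, estimators and numerical conventions: what is computed,
under which assumptions, which knobs matter, and where the edges of
validity lie.

## The model class

Every system is a set of non-overlapping unit disks centered on the
origin; equivalently a planar point distribution with minimum pairwise
distance 1 (enforced to an absolute contact tolerance of 1e-9
diameters). The network over a point set at connectivity parameter
`r ≥ 1` is the *geometric graph*: an undirected, unweighted link for
every pair with euclidean distance `d_ij ≤ r`, evaluated with a
relative tolerance of 1e-9 so that contacts constructed at exactly one
diameter are never lost to floating-point rounding. `r = 1` is the
physical contact network; larger `r` models interactions that reach
beyond touch. Distances in the graph are always hop counts — the
minimum number of links — never euclidean path lengths.

Six generators cover the morphology spectrum at matched particle
number, each with a particle at the origin (row 1 of the point set):

* **Diffusion-limited aggregation (DLA).** Unit particles are released
  one at a time from a uniformly random point of the launch circle of
  radius `L = r_max + delta` (default `delta = 100` diameters, large
  enough that the launch circle is effectively at infinity relative to
  the cluster's screening length) and perform an isotropic random walk
  with mean free path 1 until contact, with a killing radius at `2 L`
  (default `kill_factor = 2`). Far from the cluster the walk takes an
  isotropic jump of length `d_near − 1`: a Brownian path exits an empty
  disk uniformly, so jumps to just outside contact range preserve the
  arrival distribution while removing the cost of wandering in empty
  space and between branches.
* **Ballistic aggregation (BA).** As DLA but with straight-line
  trajectories from the launch circle (`delta = 1000`), aimed at a
  uniformly random point of the disk of radius `r_max + 1` so that
  every chord that can intersect the occupied region occurs; misses
  are relaunched. The aiming rule is one of several defensible
  launch-direction laws (an alternative is a uniform inward
  half-plane direction); it covers all contact-capable chords and
  keeps the miss rate low.
* **Vicsek and Hexaflake fractals.** Iterated function systems with 5
  (respectively 7) maps of ratio 1/3 — the identity plus translations
  along the 4 axis (respectively 6 hexagonal) unit directions. The
  package evaluates the equivalent recursion "iterate n+1 = union of
  translated copies of iterate n at offsets `3^(n-1) u_k`", which
  keeps coordinates exact integer combinations instead of compounding
  1/3-scalings, and snaps the cosine/sine of axis directions to exact
  zeros. Iterate n has `5^(n-1)` / `7^(n-1)` points at unit spacing.
* **Hexagonal and Kagome lattices.** All sites of the triangular
  packing (coordination 6) or trihexagonal tiling (coordination 4,
  realized as the Bravais lattice (2,0), (1,√3) with basis (0,0),
  (1,0), (1/2,√3/2)) inside a disk guaranteed to contain the target
  count. The coefficient ranges of the site enumeration use the exact
  covering bound `|a| ≤ ρ|a2|/det(a1,a2)` — a clipped enumeration
  biases the boundary shells and measurably shifts path metrics.

### Contact placement

On each candidate step the walker's segment is tested against every
particle within reach and the step is cut at the smallest root of
`|p + t·u − c|² = 1`, i.e. exact continuous collision detection; the
arriving particle therefore sits at distance exactly 1 (to rounding)
from the first particle it touches. The alternative convention —
detect overlap only at step endpoints and pull back — retains sub-unit
overlaps whenever a second particle was crossed earlier in the step,
which violates the hard-disk invariant and, as a side effect,
manufactures occasional triangles in the contact graph. Under exact
contact placement a double contact is a measure-zero event, so DLA and
BA contact graphs are exact trees: `L = N − 1`, zero clustering, mean
degree `2(N−1)/N`. Analyses that report small nonzero clustering
(~1e-4..1e-2) for aggregates are measuring the overlap artifact of the
endpoint convention, not a property of hard-disk aggregation.

### Truncation by radial burning

Lattices and IFS iterates are cut to an exact particle count by
*radial burning*: starting from the center particle, repeatedly admit
the not-yet-selected particle with the smallest radius among those in
contact with the selected set, breaking ties by polar angle and then
by index. The selection is connected at `r = 1` by construction,
fills radially symmetric shells in order (for a lattice it coincides
with "keep the N closest sites"), and truncating a tree yields a
subtree (`L = N − 1` survives truncation). Row order of the output is
the input order restricted to the selection, so truncation to the full
size is the identity. The admission rule at the boundary shell — which
members of a partially admitted symmetry orbit are kept — is the one
genuinely arbitrary convention here; it moves edge counts by a handful
of edges and path means in the fourth decimal.

## Estimators

**Fractal dimension.** Growing aggregates record the radius of
gyration about the origin at every particle up to N = 1000 and every
10th particle beyond (the log-log fit gains nothing from denser
sampling at large N). The dimension is `D = 1/β` with `β` the
unweighted OLS slope of `log R_g` on `log N` restricted to
`N > 1000`, where the clusters are inside the self-similar regime; the
standard error is propagated as `se(β)/β²`. No binning is applied.
For the deterministic fractals the same regression runs across IFS
iterates, restricted to the top three (the analog of the `N > 1000`
cut: early iterates are pre-asymptotic and bias the slope downwards);
with ≥ 5 iterations this lands within 0.005 of the analytic
`log 5 / log 3` and `log 7 / log 3`. Reported lattice dimensions are
the embedding dimension 2.

**Bond-orientational order.** `⟨Ψ₆⟩` averages `exp(6 i θ)` over each
particle's contact neighbors (always `r = 1`, whatever the analysis
radius), normalizes per particle by its degree, averages over all N
particles, and takes the modulus. Since
`exp(6i(θ+π)) = exp(6iθ)`, each edge contributes the same term to
both endpoints. Isolated particles contribute zero but stay in the
denominator. The statistic is exactly 1 whenever every bond angle is
a multiple of 60° (hexagonal, kagome, hexaflake — including their
boundaries) and exactly 0 for the fourfold-symmetric Vicsek cross
(terms at 90° spacing cancel in conjugate pairs); for aggregates it
decays toward 0 with system size.

**Path metrics.** Exact mode runs one BFS per node (igraph's
unweighted distances, processed in source blocks of 512 to bound the
distance-matrix slice in memory) and accumulates `⟨l⟩` over connected
ordered pairs and `⟨E⟩` with disconnected pairs contributing zero
efficiency, per the convention `E_ij = 1/l_ij, E_ij = 0` when no path
exists. `⟨l⟩` over a disconnected graph is reported over connected
pairs with the disconnected-pair count surfaced — the reference
systems are always connected, so this only affects user-supplied
data. Sampled mode draws a seeded uniform subset of BFS sources and
reports standard errors of the per-source means; on a 3000-particle
lattice, 300 sources put the estimate within three standard errors of
the exact value in ≈ 99% of seeds. Exact mode is the default and is
practical to N = 15000 and a little beyond (minutes on one CPU).

**Center-perimeter ratio.** `η_max = l0_max / R` compares the hop
count from the center to the perimeter against the euclidean radius.
The perimeter of a hard-disk system is a shell one particle thick,
not a mathematical point: the target is therefore the particle within
half a diameter of `R` with the smallest polar angle (then smallest
index). For ordered systems this shell almost always contains a
particle on a straight lattice line through the origin, and `η_max`
sits within 1% of 1 — the defining signature of straight-line
center-perimeter communication — while branched aggregates give
1.3–1.5 regardless of convention. The strict euclidean maximizer is
reported alongside (`eta_max_strict`, plus the shell-wide maximum as
a diagnostic); note that for lattices the strict variant does *not*
converge to 1: the hop metric of the triangular lattice is
anisotropic by up to `2/√3 ≈ 1.155` depending on the direction of the
farthest particle, so a single extreme particle in a generic
direction reads η ≈ 1.06–1.14 even for a perfect crystal. Treating
the perimeter as a shell is what makes "straight-line communication"
a well-posed, reproducible quantity.

**Connectivity sweep.** The metric panel is recomputed on a grid of
`r` (default 1 to 6 in steps of 0.25), ratios are formed against a
baseline — conventionally the `r = 1` hexagonal lattice at the same N
— and the cut-off `r_c` is the first grid point with
`⟨E⟩/⟨E⟩_HEX ≥ 1`; a linear interpolation between the bracketing grid
points is reported as a diagnostic. Efficiency and edge count are
non-decreasing in `r` (adding links never lengthens a shortest path),
so the crossing is well defined whenever it is reached.

## Study conditions and problem sizes

The reference conditions are N = 15000 particles per system (15001
for the Vicsek tree, so a complete shell of arms surrounds the
center), ensembles of 10 clusters for the stochastic aggregates with
replicate seeds `base_seed + i − 1`, `delta = 100` (DLA) and `1000`
(BA), killing radius `2L`, mean free path 1. Because the ± spread of
an ensemble can be read as either SD or SEM, the ensemble harness
(`morphometry_table()`) reports both.

At those conditions the package reproduces the reference panel where
the construction is deterministic: hexagonal `L = 44553`,
`⟨l⟩ = 64.2009`, kagome `L = 29744`, `⟨l⟩ = 74.1370`, hexaflake
`L = 29854`, Vicsek `L = 15000`, center-perimeter hop counts
64/74/106/334, and `⟨E⟩ = 0.02379 / 0.02057` for hexagonal/kagome
(4-decimal truncations 0.0237 / 0.0205).

The test suite scales stochastic ensembles down to keep the default
run at desk scale: dimension-recovery ensembles use 10 clusters of
5000 (DLA) and 15000 (BA) particles — at these sizes the fitted
ensemble means sit at ≈ 1.72 ± 0.03 and ≈ 1.94 ± 0.01, against the
asymptotic ≈ 1.71 and 2 — and sweep monotonicity runs at N ≤ 625 per
system. The acceptance script uses 10 × 7500 DLA clusters and full
N = 15000 for everything deterministic and for the r = 4 DLA edge
budget (three clusters). BA's fitted dimension converges slowly from
below (1.94 at N = 15000); estimates closer to 2 require either
larger clusters or fit windows starting well above N = 1000.

## What the generators do and do not emulate

The generators produce the idealized geometry of contact-bonded
monodisperse systems: exact unit spacing, perfect radial centering,
no positional noise, no polydispersity, no rearrangement after
sticking. Passing tests therefore certify the analysis pipeline and
the growth models, not agreement with imaged biological structures:
real branching systems have variable unit sizes, curved and thickened
branches, anastomosis (which breaks tree-ness), and imaging noise.
External point sets in diameter units can be analyzed through the same
pipeline (`point_set()`/`read_point_set()` with model `"EXTERNAL"`),
and every graph-side metric applies unchanged; the hard-disk
invariant is then the user's responsibility (`validate_point_set()`).

## Degenerate inputs and numerical conventions

Single-particle systems have `R = R_g = 0`, an empty graph and
`⟨Ψ₆⟩ = 0`; `path_stats()` returns `NaN` path length and zero
efficiency below two nodes. Graphs with no degree ≥ 2 node have mean
clustering 0 by convention. The dimension fit refuses histories with
fewer than 10 usable samples or a non-positive slope. `r < 1` is
refused at graph construction (sub-contact radii disconnect every
hard-disk system by construction). Aggregation guards against
non-termination with a per-walker step budget (relaunch) and a global
budget (error). Edge lists are stored with `i < j`
lexicographically; files are 0-based with the center particle as row
0, in-memory indices 1-based with the center as node 1. All
tolerances are 1e-9 (absolute for contacts, relative for edges);
point-set CSV, edge TSV and JSON summaries round-trip to 15
significant digits.

## Known limitations

* Exact contact placement makes aggregate contact graphs exact trees;
  conventions that keep endpoint-overlap artifacts report slightly
  more edges and nonzero clustering at `r = 1`.
* The boundary-shell admission convention of radial burning moves
  path-metric means in the fourth decimal; quantities quoted to more
  digits than that are convention-dependent.
* Finite-size fractal dimensions are fit-window-dependent; the
  package fixes its windows (`N > 1000`; top three IFS iterates) and
  reports them with the fit.
* `r_c` is defined on the sweep grid at the reference N; its
  N-dependence is not characterized, and small-N crossings (as in the
  README example) shift with system size.
* The pipeline is strictly two-dimensional and has no periodic
  boundaries, weighted edges, or k-nearest-neighbor graph variants.
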