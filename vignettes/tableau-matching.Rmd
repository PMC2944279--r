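---
title: "Matching protein structures by simulated annealing over tableaux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching protein structures by simulated annealing over tableaux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tableauMatch)
```

## The representation: tableaux and distance matrices

A protein structure is reduced to its secondary structure elements
(SSEs): helices (alpha, pi, 3-10) and beta-strands. Each SSE gets a
fitted axis, and every pair of SSEs an *interaxial angle*: the signed
angle between the two axis vectors, measured in the plane normal to their
mutual perpendicular. The structure is then encoded as a **tableau**, an
N x N symmetric matrix whose off-diagonal entries are discrete
two-character codes for those angles and whose diagonal records the SSE
types (`e`, `xa`, `xi`, `xg`). Alongside the tableau sits a matrix of
distances (in Å) between the C-alpha centroids of the SSEs.

The two-character code comes from a *double-quadrant encoding*: the angle
is classified into four 90°-wide sectors twice, with the second
classification rotated by 45°. The first character is `P`, `O`, `L` or
`R` (parallel, anti-parallel, crossing-left, crossing-right), the second
`E`, `D`, `S` or `T`. Because the two grids are offset by half a sector,
a perturbation smaller than 45° changes at most one character — the
encoding degrades gracefully with noise in the geometry.

```{r encoding}
encodeAngle(c(143, 170, -170, 10, -10))
```

The exact interval endpoints are a convention the code alphabet does not
itself fix; this package uses half-open intervals oriented toward
increasing angle: first character `P` on [-45, 45), `R` on [45, 135),
`O` on [135, 180] and (-180, -135), `L` on [-135, -45); second character
`E` on [0, 90), `T` on [90, 180], `D` on [-90, 0), `S` on (-180, -90).
These choices make 143° encode as `OT` and anti-parallel angles as `OS`
or `OT`, the two fixed points of the encoding. The assignment of `E/D/S/T`
to the rotated quadrants beyond those fixed points is conventional; it is
applied uniformly on both sides of every comparison, so no score can
depend on it.

Two codes are compared with a three-valued score:

```{r zeta}
zetaScore(c("OT", "OT", "PE"), c("OT", "OS", "OT"))
```

2 for identical codes, 1 when exactly one quadrant character agrees
(adjacent sectors), and -2 otherwise. The reward structure makes a large
common subtableau worth finding and a spurious one costly.

### Chirality and the sign of the angle

Crossing-left versus crossing-right requires a signed angle, and a sign
requires an orientation convention. The convention here: the mutual
perpendicular `u x w` is flipped, when needed, so that it points from the
centroid of the lower-indexed SSE toward the centroid of the
higher-indexed one. Reflection of the coordinates then swaps `L` and `R`
codes, as it should — a mirror image is a different fold. The matrix is
filled from the `i < j` triangle and mirrored, and the angle itself is
invariant under swapping the two SSEs together with their centroids, so
either triangle yields the same tableau.

### Axis fitting

The axis of an SSE is fitted by total least squares: the axis point is
the centroid of the C-alpha coordinates and the direction is the first
principal direction of the centered coordinates, with the sign chosen so
that the axis points from the first toward the last residue (N to C).
This fit is rotation-invariant and needs no helix-specific machinery; on
ideal 12-residue helices it recovers the generating axis to well under
5°. For two-residue segments the direction is simply the normalized
difference. Axis fitting on very short runs is ill-conditioned, which is
one reason runs below the minimum SSE lengths (3 residues for helices, 2
for strands, both configurable) are discarded during DSSP segmentation.

## The matching problem and its objective

A correspondence between query SSEs and database-entry SSEs is a vector
`v` with `v[i] = j` (query SSE i matched to entry SSE j) or `v[i] = 0`
(unmatched). Nonzero values must be distinct, must respect the
helix/strand type classes, and — in sequential mode — must be strictly
increasing, which forbids non-sequential matchings. The objective is

    g(v) = sum over ordered pairs (i, k), i != k, v[i] = j, v[k] = l != 0
           of  zeta(T_A[i,k], T_B[j,l])   if |d_A[i,k] - d_B[j,l]| <= tau
               0                          otherwise

The distance-difference constraint with threshold `tau` (default 4 Å)
suppresses false positives from SSE pairs that agree in orientation but
sit at very different separations; it is applied in the soft,
zero-contribution form above rather than as a hard feasibility cut. The
sum runs over ordered pairs with the diagonal excluded (the diagonal
stores types, not codes), so each unordered pair counts twice and a full
self-match of an N-SSE structure scores exactly 2N(N-1). The size
normalization

    norm2 = 2 * g / (N_A + N_B)

makes scores comparable across structure sizes; a sequential self-match
has norm2 = 2(N-1).

Changing one entry of `v` touches only the pair terms involving that SSE,
so the score change of a move is computed in O(N) exactly, in integer
arithmetic — accumulated deltas never drift from a full recomputation,
and the test suite asserts bit-exact agreement over thousands of random
move sequences.

## The annealing schedule

Finding the optimal correspondence is a quadratic assignment-type
combinatorial problem; the package approximates it with simulated
annealing:

* **Initialization.** Each query SSE is matched, with probability
  `pm = 0.5`, to the first unused same-class entry SSE beyond the last
  assignment — a cheap, always-sequential-valid seed.
* **Move.** Pick a query SSE uniformly; re-assign it uniformly among the
  feasible entry SSEs (same class, unused, ordering-feasible in
  sequential mode, current assignment excluded). If no feasible target
  exists the SSE is unmapped. Excluding the current assignment forces an
  actual state change; deliberate unmapping therefore happens exactly
  when the candidate set is empty.
* **Acceptance.** A move is accepted when its objective exceeds the best
  value found so far, or when `exp(delta/T) > p` for a uniform `p` in
  [0, 1). Since `exp(delta/T) >= 1` for non-negative `delta`, improving
  and sideways moves are always accepted; worsening moves are accepted
  with the Metropolis probability. (A plausible alternative reading —
  comparing against the *current* rather than the *best* value — is
  subsumed by the Metropolis clause and would behave identically.)
* **Cooling.** The temperature starts at `T0 = 10` and is multiplied by
  `alpha = 0.95` after every proposed move, for `iterations = 100` moves
  per run. The maximum-objective state visited (including the initial
  state) is returned.
* **Restarts.** The whole schedule runs `restarts = 128` times (512 in
  the small-instance validation tests) and the best state over all runs
  wins.

`T0`, `alpha`, `iterations` and `pm` are exposed on `SearchParams` but
default to the tuned values above; `tau = 4` Å. Non-sequential matching
is the default (`sequential = FALSE`) since finding non-sequential and
substructure matches is the method's point; sequential mode is the
stricter, cheaper variant.

### Determinism

Each (query, entry, restart) triple gets its own counter-based RNG
stream: a 64-bit FNV-1a hash of the seed and the two ids, advanced per
restart with a splitmix64 finalizer. Search output is therefore
bit-identical for any number of workers and for any database ordering —
presorting the database by size (`sortBySize`) is purely a scheduling
aid. The inner loop is compiled (Rcpp); the R-level `objectiveFull` /
`objectiveDelta` / `randomInit` / `proposeMove` expose the same rules for
testing, and the suite asserts that the state returned by the compiled
search achieves its reported score under the R objective.

## What the synthetic generator emulates

`genRandomEntry` places SSEs as random points in a 40 Å box with random
axis directions and a 40% strand fraction, then derives codes and
distances through the same geometric path as real structures. This
guarantees the statistical structure the matcher relies on — metric
distance matrices, geometrically consistent codes, symmetric tableaux —
without simulating actual protein folds. What it does *not* reproduce:
the strong regularities of real architectures (parallel sheets, helix
packing angles near +-50°, contact-order statistics) or realistic SSE
counts per fold class. Passing tests on these fixtures therefore
demonstrate the correctness of encoding, objective and optimizer — not
retrieval accuracy on real fold benchmarks, which requires curated
structure classifications that are deliberately out of scope here.

`plantMotif` embeds an exact sub-entry (codes and distances copied) at
known positions, giving a ground-truth correspondence whose score is
2m(m-1) for an m-SSE motif; `bruteForceOptimum` enumerates all feasible
partial mappings (refusing instances whose enumeration bound (N_B+1)^N_A
exceeds 2^21) and serves as the independent oracle for the annealer.
`genIdealCoords` builds textbook ideal geometry — 1.5 Å rise and 100°
twist per residue at 2.3 Å radius for helices, 3.5 Å steps with a small
zigzag for strands — so axis fits and interaxial angles can be checked
against the generating axes.

## Numerical choices and degenerate inputs

* Near-parallel axes (`|u x w| < 1e-9`) get angle 0 or 180 by the sign of
  the dot product; ties in the sign reference keep the unflipped
  perpendicular.
* Angles are normalized into (-180, 180] before encoding; -180 and 180
  encode identically.
* Database distances are serialized with 3 decimals, which makes
  write-read-write byte-identical; 0.0005 Å of rounding is far below
  anything that matters at a 4 Å threshold.
* A single-SSE entry has an empty lower triangle, a [[0]] distance
  matrix, and scores 0 against everything (no pairs exist).
* The objective is *not* monotone in `tau` for a fixed state: enlarging
  `tau` admits more pairs, and an admitted pair can contribute -2. What
  does hold, and is tested, is that the admitted-pair set is nested in
  `tau` and that at `tau = Inf` the objective equals the unconstrained
  tableau score.
* Zero-SSE structures (DSSP finds no SSEs) are skipped when building a
  database, with a warning naming the entry.

## Evaluation

For benchmarking, per-query scores are pooled across queries after norm2
normalization, self-comparisons are removed, and gold-standard pairs
missing a score are filled with (minimum provided score - 1) so that
unreported comparisons rank last. The AUC is the rank statistic
P(pos > neg) + P(tie)/2 — identical to the trapezoidal area under the
ROC curve — with ties given half credit, and its standard error uses the
Hanley-McNeil closed form (Q1 = A/(2-A), Q2 = 2A²/(1+A)); the 95%
interval is A ± 1.96·SE clipped to [0, 1]. `qScore` implements the
SSM-style alignment quality N²/((1+(RMSD/3)²)·N1·N2) for turning
(aligned-residue, RMSD) pairs from residue-level aligners into a single
ranking score.

```{r eval}
rocAuc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
```

## Problem sizes in the shipped tests

The validation suite runs at deliberately small scale, chosen so the
exhaustive oracle stays exact: 100 random pairs with 2-5 SSEs at 512
restarts for optimality checks, 5-SSE motifs in 15-SSE hosts at the
default 128 restarts for recovery checks, and 1000-move sequences for
delta exactness. These sizes exercise every code path; genuine fold
retrieval runs on databases of thousands of entries with tens of SSEs
each, where only the stochastic guarantees (not per-instance optimality)
apply.

## Known limitations

* Secondary structure assignments are consumed from DSSP files, not
  computed; structures DSSP leaves without SSEs cannot be represented.
* The matcher scores SSE-level geometry only; it produces no
  residue-level superposition or RMSD.
* Scores of near-degenerate entries (many identical codes, e.g. an
  all-parallel helix bundle) admit many co-optimal matchings; the
  annealer returns one of them, deterministically for a fixed seed but
  with no canonical choice.
* The stochastic guarantees (optimum attainment, motif recovery) are
  calibrated on the synthetic generator's geometry; heavily distorted
  real structures may need more restarts.
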