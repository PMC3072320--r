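---
title: "Local fragment chaining: models, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local fragment chaining: models, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragchain)
```

## The problem

Sensitive seed-based homology searches — BLAST with small word sizes and
permissive E-values, short-read mappers in permissive modes — return
enormous numbers of short local match fragments, most of them random.  When
the homology being sought consists of short conserved blocks separated by
variable regions (structured non-coding RNAs are the canonical case), no
single fragment is significant, but a *chain* of colinear fragments is.

A fragment `f` is a scored match between an interval of a query sequence
(`y` axis) and an interval of a database sequence (`x` axis).  A chain is a
sequence of fragments that are pairwise non-overlapping and ordered the
same way on both axes; its score is the sum of the member fragment scores
minus a gap penalty for every consecutive pair.  `fragchain` finds, for
every possible chain start, the best-scoring *local* chain: a fragment is
appended to its optimal predecessor chain only when that chain's score
covers the gap cost, so a chain's score never drops below the score of its
last fragment.

## Gap cost models

Let `d_x` and `d_y` be the number of characters strictly between two
consecutive fragments on database and query.  Two models are provided
(`gapParams()`):

* **linear** — `g = λ·d_x + ε·d_y`.  Every skipped character on either
  sequence is penalised.  Appropriate when homologous regions are compact.
* **sum-of-pair** — `g = λ·|d_x − d_y| + ε·min(d_x, d_y)`.  This is the
  cost of optimally aligning the two anonymous gap regions against each
  other: `ε` pairs two anonymous characters, `λ` puts a character against
  a gap.  The closed form equals `min_a [ε·a + λ·(d_x + d_y − 2a)]`
  whenever `ε ≤ 2λ` (the package warns when a parameter choice breaks that
  reading, but still applies the formula).  With `ε = 0` only the
  *difference* of the distances is penalised, so two fragments separated
  by 5 kb on both sequences chain for free — exactly what scattered-block
  homologies need.

The model weights have no units of their own; they are per-character
penalties on the same scale as the fragment scores.  With fragment scores
equal to hit lengths (one point per matched position), `λ = 0.5, ε = 0`
reads as "punish distance differences at half the match score", which is
the setting used throughout this package's examples for the sum-of-pair
model; the linear default `λ = ε = 1` penalises every skipped character at
the match score.

## The sweep

Chaining is a sparse dynamic program over fragment start and end points
sorted by database position.  When a fragment's start point is reached,
every chain whose last fragment has already ended is *active*; the optimal
predecessor is found with range-maximum queries over the active set, the
candidate's true value `score − gap` is recomputed exactly from the
retrieved fragment, and the connection is made only if the value is
non-negative (ties connect, preferring longer chains).  When its end point
is reached, the fragment's own chain becomes active.  Finally, chains are
grouped by their first fragment and the best chain per group is reported —
a fragment interior to good chains heads no report of its own.

Two details make the RMQ ranges one- and two-dimensional rather than
three-dimensional:

* the database-axis constraint `pred.end_x ≤ succ.beg_x` is enforced by
  the event order itself.  End events are keyed at `end_x − 1` (the last
  covered base) and start events before end events at equal coordinate, so
  a fragment ending exactly where another begins (half-open abutment) *is*
  active for it, while fragments sharing a base are not.
* priorities.  Within a region where the gap formula is linear in the
  predecessor's end point, `score − gap` equals the stored priority plus a
  term that depends only on the successor, so the RMQ maximum is the
  optimal predecessor.  The linear model needs one region; the
  sum-of-pair model splits the predecessor half-plane at the successor's
  start diagonal `x − y` into two octants (`d_x ≥ d_y` and `d_x < d_y`),
  each with its own priority transform.  The boundary `d_x = d_y` is
  assigned to octant 1; both transforms agree there, so single counting is
  sufficient.

The structures (`Staircase`, `RangeTree2D`) are dominance staircases over
rank-condensed key universes fixed before the sweep: the linear model keys
active chains by `end_y`; octant 1 uses a range tree over
(end diagonal, `end_y`); octant 2 needs only a max-above staircase over
the diagonal, because within that octant the query-axis constraint follows
from activation order.  A staircase stores only entries not dominated by a
more permissive key with an equal-or-better priority, which reduces each
range-maximum query to one ordered-map lookup; pruning is eager at insert
time.  The ordered map satisfies the predecessor/successor/insert/delete
contract the algorithm needs; a stratified `O(log log n)` layout would be
a drop-in replacement but is a constant-factor optimisation only.  The
core runs in C++ (via Rcpp); an `O(n²)` reference chainer
(`bruteForceChain()`) written independently in R, with no priorities,
octants or sweep structures, serves as the oracle in the test suite.

## Clustering pre-pass

Databases are typically much longer than queries, so fragment sets often
decompose along the database axis.  `clusterFragments()` scans a group
once in `beg_x` order and opens a new cluster whenever the gap between the
current database frontier (largest `end_x` so far) and the next fragment
exceeds `clusterGapThreshold()`: the smallest database gap whose *minimum
possible* cost exceeds an upper bound on any achievable chain score.  With
score bound `S` and maximal query-axis distance `maxY`, the thresholds are
`⌊S/λ⌋ + 1` (linear; the query term only adds cost) and
`⌊S/λ⌋ + maxY + 1` (sum-of-pair, whose cost is at least
`λ·(d_x − maxY)`); with `λ = 0` no split is ever safe.  Because no
connection across such a gap can be afforded, chaining the clusters
separately provably reproduces the single-sweep output — the tests assert
score-exact agreement on hundreds of randomized instances, and clustering
is on by default.

Two bound realisations were open:

* **score bound** — the running sum of fragment scores already scanned.
  Any chain reachable at a split point consists of already-scanned
  fragments (they precede it in `beg_x` order), and a chain's score is at
  most the sum of its member scores, so the running sum is safe and needs
  no second pass.  An alternative bound, query length × maximal
  per-position score, requires knowing the query length, which the
  fragment formats do not carry.
* **query extent `maxY`** — taken as `max(end_y) − min(beg_y)` over the
  *whole group* (one extra linear pass) rather than a running estimate.  A
  running value would be unsafe: a later fragment can enlarge the query
  extent so that a pair straddling an earlier split becomes affordable
  under the sum-of-pair model with `ε = 0`.  The group-global extent is a
  stand-in for the query length and restores the guarantee.

## Synthetic data

Two generators make the package self-contained:

* `simulateUniformFragments()` — the benchmark geometry: `n` fragments of
  length 100 whose query starts are uniform over a 1 kb query and whose
  database starts are uniform over a 100 kb database, scores drawn from a
  normal distribution (mean 20, sd 5 — the distribution family is the
  prescribed part; the moments are this package's choice) truncated to
  positive by resampling.  Uniform placement means almost no true chain
  structure; it exercises throughput and the reporting path.
* `simulateScatteredHomology()` — plants one colinear chain of short
  blocks whose database and query inter-block distances (200–2000 bp)
  differ by at most `jitter`, plus uniform decoys (`decoyRate` per
  planted block).  With `jitter = 0` the planted chain is free under
  sum-of-pair `ε = 0` while paying thousands under linear costs — the
  scenario separating the two models.

What these simulations do *not* emulate: fragment scores correlated with
length or identity, overlapping co-linear hit stacks from repeat families,
multi-query/multi-chromosome mixtures (grouping is tested separately with
constructed cases), and any sequence-level signal.  Passing tests show the
chaining machinery is exact and scalable, not that any biological screen
will rank true homologs first.

## Numerical and convention choices

* Coordinates are 0-based half-open internally; all text formats are
  1-based inclusive.  Equality of a predecessor end and successor start
  means abutment and is chainable; the conversion is length-preserving in
  both directions.
* Minus-strand BLAST hits (`sstart > send`) are normalised by swapping the
  subject coordinates and labelled strand `-`; plus and minus fragments
  are chained in separate groups, as are different queries and subjects.
* Scores and costs are `double`s; the sweep compares recomputed values
  exactly, and tests use an absolute tolerance of 1e-9.  Priority
  comparisons inside the structures can misorder candidates only when the
  true values differ by floating-point noise, which the exact recompute
  then bounds at the same magnitude.
* Tie-breaking among equal-valued predecessors is arbitrary (whatever the
  RMQ returns); chain *scores* are deterministic, chain membership on
  exact ties is not guaranteed stable, and the tests compare scores.
* Degenerate inputs: empty files and empty groups yield empty results;
  zero-length fragments are rejected by the `FragmentSet` validity check;
  duplicate coordinates are kept as distinct fragments and never co-chain
  (they overlap).
* `λ = 0` under sum-of-pair makes the database axis cost-free; chaining
  still works but clustering is disabled (threshold `∞`).

## Problem sizes used in the checks

The bundled tests chain randomized instances of up to 60 fragments against
the quadratic oracle (200 instances per model), replay 1000-operation
randomized workloads against linear-scan RMQ oracles over five seeds, and
run one 100 000-fragment uniform instance per model end to end; the
acceptance script chains a 20 000-fragment uniform instance under both
models.  These sizes exercise every code path (including cluster splits and
both octants) while keeping a full run in the order of a minute or two on
one CPU.

## Known limitations

* Two-dimensional fragments only (one query, one database sequence per
  group); k-genome chaining is out of scope.
* Local chaining only; there is no global mode forcing chains to span the
  sequences.
* Fragment scores enter linearly; affine or nonlinear score weighting is
  not implemented.
* No SAM/PSL input in this version; BLAST tabular and the generic TSV
  cover the intended use.
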