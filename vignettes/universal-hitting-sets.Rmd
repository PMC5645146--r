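---
title: "Computing small universal k-mer hitting sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing small universal k-mer hitting sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhskit)
```

## The problem

A set of k-mers U is a universal hitting set (UHS) for window length L
when every string of length L over the alphabet contains at least one
member of U. Universal sets play the role that minimizer schemes play in
sequence sketching, but are sequence-independent: they can be computed
once for a parameter pair (k, L) and reused for any dataset.

On the complete de Bruijn graph of order k — one vertex per k-mer, one
edge per (k+1)-mer, so a path of n edges spells a string of n + k
characters — the task is to find a smallest vertex set that intersects
every directed path of l = L − k edges. Cycles must be hit too (a cycle
supports arbitrarily long strings), which is why the toolkit works in two
phases: an optimal decycling phase and a greedy path-cover phase on the
residual DAG. Finding a minimum l-path cover in a DAG is NP-hard in
general, hence the greedy heuristics and the separate exact solver.

All k-mers are encoded as 0-based integers with the first character most
significant, so integer order equals lexicographic order and all
"lexicographically smallest" tie-breaks are integer comparisons. The
graph itself is never materialized; neighbours are computed
arithmetically from the encoding.

## Phase one: the minimum decycling set

Each conjugacy class (the set of rotations of a k-mer) forms a cycle, so
any decycling set needs at least one member per class; the minimum
decycling set has exactly C(σ, k) = (1/k) Σ_{i=1..k} σ^gcd(i,k) members.
`mykkeltveit_set()` constructs one using the complex embedding
P(w) = Σ_j d_j u^j with u = exp(2πi/k): left rotation multiplies P by
u^(−1), so the embeddings of a class with P ≠ 0 are k equally spaced
points on a circle, and any half-open sector of width 2π/k contains
exactly one of them.

Which sector — and which member to take in the classes whose embedding
vanishes (all words of period < k, plus some aperiodic words whose digit
sums cancel) — is a genuine free choice: different conventions all give
minimum decycling sets, but they leave residual DAGs with different
longest paths. The conventions here were fixed once by requiring
agreement with the residual longest-path lengths of the reference
decycling sets in common use, which the test suite recomputes
end-to-end for DNA k = 3..10 (11, 20, 45, 70, 117, 148, 239 and 311
bases):

* nonzero classes: the member whose embedding argument lies in the
  sector [π − 2π/k, π), i.e. the last orbit position before the negative
  real axis, with the member exactly on the starting ray included;
* zero-embedding classes: the lexicographically smallest rotation
  (within the zero-embedding subgraph every de Bruijn edge is a rotation
  edge — an edge between two zero-embedding words forces the appended
  and dropped characters to be equal — so any one-per-class choice
  breaks all pure-zero cycles, and the choice only influences mixed
  paths);
* constant words (singleton classes carrying self-loops): always
  included.

Two numerical safeguards matter. Embeddings are "zero" below a tolerance
of 1e-9·k (true zeros are exact cancellations of at most k unit-magnitude
terms, far separated from that scale for the supported k). And the
angular position of each member past the selection ray is snapped to the
ray when within 1e-9, because for even k many classes sit exactly on the
real axis and floating-point noise of order 1e-16 would otherwise assign
boundary members to the wrong end of the sector, silently breaking the
one-per-class property. The construction verifies cardinality,
one-per-class membership and residual acyclicity before returning, and
fails loudly otherwise.

One anomaly is worth recording: for DNA k = 2 the residual longest path
of *every* minimum decycling set spells 4 bases, not the 5 sometimes
quoted. The claim is checked exhaustively in the test suite — all 24
acyclic one-per-class selections at k = 2 hit every 5-base string and
each misses some 4-base string.

## Phase two: greedy path cover

The hitting number T(v, l) is the number of l-edge paths through v. With
D(v, i) the number of i-edge paths starting at v and F(v, i) the number
ending at v,

* D(v, 0) = F(v, 0) = 1,
* D(v, i) = Σ over edges (v, u) of D(u, i−1), F symmetrically,
* T(v, l) = Σ_i F(v, i) · D(v, l−i),

`docks()` removes a maximum-T(v, l) vertex, rebuilds the tables, and
repeats until the residual longest path has fewer than l edges. The
L-free variant `docks_any()` instead uses F(v) = 1 + Σ F(u) and
D(v) = 1 + Σ D(u) in topological order — paths of every length — making
each iteration a factor l cheaper and the removal order independent of L
(L only decides when to stop, which is why the removal log for a larger
L is a prefix of the log for a smaller one). `docks_any_x()` removes the
top X vertices per iteration. Ties are always broken toward the smallest
encoded k-mer, and the iteration log (vertex, exact score) is part of
the result, so runs are reproducible bit for bit.

Counts are exact, arbitrary-precision integers implemented in C++ (base
2^32 limbs): path counts grow like σ^l and overflow doubles long before
the supported parameter range ends, and a greedy argmax over rounded
counts would be a silent correctness bug. Tables are rebuilt from
scratch after each removal; incremental maintenance is an open problem
we did not attempt.

The pure-greedy baseline (`greedy_baseline()`) skips phase one and
scores vertices by l-edge *walk* counts in the full cyclic graph; it
terminates only once every cycle is broken. It exists as a reference
point: it is slower and typically worse, which is the motivation for
the decycling phase.

## Verification

`verify_uhs()` offers two independent oracles. The walk oracle counts
l-edge walks in the complete graph restricted to non-members — each
avoiding L-long string is exactly one such walk, cycles included — and
reconstructs the lexicographically smallest avoiding string as a witness
by greedy descent over a boolean reachability table. The exhaustive
oracle literally enumerates all σ^L strings. They are checked against
each other across the test grid, and every set produced by every method
must pass.

## The exact solver

The textbook integer program has one binary x_v per k-mer, one bounded
variable L_v ∈ [0, l−1] per k-mer ("longest surviving path ending at
v"), and a constraint L_v ≥ 1 + L_u − l·x_v per edge. `build_ilp()`
builds exactly that model (with L_v declared integral, matching its
combinatorial meaning; the big-M argument works either way) and
`write_lp()` exports it. In our hands neither available mixed-integer
backend could close the k = 4, L = 10 instance from this formulation in
desk time, so `solve_ilp()` defaults to an exact reformulation:

A removed set is valid iff the surviving vertices admit levels
h(v) ∈ {0..l−1} strictly increasing along surviving edges. All edges
into the k-mers with a given (k−1)-suffix come from the 4 k-mers with
that (k−1)-prefix — a complete bipartite gadget per (k−1)-mer t — so the
level constraint collapses to a single threshold p(t) ∈ {0..l} per
(k−1)-mer: a k-mer, viewed as the edge (s, t) of the order-(k−1) de
Bruijn graph joining its prefix s to its suffix t, can be kept exactly
when p(s) < p(t) (set h = p(s)). Conversely any valid configuration
induces such thresholds. Hence

> minimum UHS size = min over p: Σ^(k−1) → {0..l} of the number of
> order-(k−1) edges with p(s) ≥ p(t),

an integer program over σ^(k−1) threshold variables instead of 2σ^k
variables. A seeded, deterministic annealing search over threshold
assignments supplies a strong incumbent (any assignment yields a valid
set, so incumbents are verified, never trusted); the mixed-integer
backend (HiGHS via a bundled SciPy bridge — the solver abstraction is a
JSON problem file, so other backends can be bound) then searches for
anything strictly smaller within the time limit, with rotation-class
cover cuts and the conjugacy-class lower bound added. `proven_optimal`
is reported honestly: only a solver certificate (optimality or
infeasibility below the incumbent) sets it.

At k = 4, L = 10 this pipeline finds a verified 87-member set — checked
by literal enumeration of all 4^10 strings — strictly smaller than the
greedy solution (91) and smaller than commonly quoted optima for these
parameters; the conjugacy-class lower bound is 70, and optimality of 87
is not certified within desk time. On binary toys (k ≤ 3, L ≤ 8) both
strategies provably reach the exhaustive-search minimum. Warm starts
are validated with the walk oracle and used as incumbent bounds (the
backend has no native warm-start interface); the warm start is returned
unchanged if nothing better is found.

## Extension to larger k

`extend_uhs()` appends every j-mer to every member, turning a (k, L) set
U into a (k+j, L+j) set of exactly |U|·σ^j members: an (L+j)-long string
has an L-long prefix hit by some w ∈ U, and the (k+j)-window starting
there is w·x. The price is a growing approximation factor
(`approximation_factor()` reports |U| / C(σ, k) as an exact fraction):
extension multiplies the numerator by σ^j while the lower bound grows
roughly by σ^j/ (1 + j/k) per application, so the factor roughly doubles
when j = k.

## Scanning sequences

`select_kmers()` and `scan_fasta()` apply a selection scheme to every
window of w consecutive k-mers (w = L − k + 1 bases L long):
lexicographic minimizers, minimizers under a seeded random k-mer order,
or the smallest *hitting-set member* in the window (well-defined by the
UHS property, which is asserted at scan time). Conventions, declared
once: coordinates are 0-based; the leftmost occurrence wins ties within
a window; a position selected by several windows is recorded once;
scanning is forward-strand only with no reverse-complement folding;
non-alphabet characters split records into runs scanned independently,
and runs shorter than L are skipped with a notice. The average distance
statistic is the mean difference of consecutive selected start
coordinates, computed per run and averaged across runs weighted by run
length; the first selected position of a run contributes no distance.

The synthetic generator draws i.i.d. characters from a given composition
with a fixed seed. That suffices to exercise every scanner code path and
to demonstrate the directional effect — hitting-set selection picks
fewer distinct k-mers, spaced further apart, than lexicographic
minimizers — but i.i.d. sequences have no repeats, no composition skew
and no homopolymer structure, so passing these tests says nothing
quantitative about real genomes; the scanner accepts FASTA input for
that purpose.

## Problem sizes and resource guards

The default guards refuse σ^k > 4^12 vertices for set construction
(4^7 for the big-M model builder, 4^8 for the pure-greedy baseline,
σ^L ≤ 2^20 for automatic exhaustive verification); each can be raised
explicitly. The shipped test-suite grid tops out at DNA k = 6, L = 40
for the greedy methods, k = 8 for decycling longest paths, and 100
random residual DAGs with at most 200 paths for the
DP-versus-enumeration cross-checks; the whole suite runs in a few
minutes on one CPU.

## Known limitations

* The decycling conventions reproduce one particular family of minimum
  decycling sets; other valid conventions give sets with different
  residual longest paths.
* The exact solver certifies optimality only when the backend closes the
  search within its time limit; otherwise the answer is the best
  verified set found (reported as such).
* No reverse-complement canonicalization anywhere: sets and scans are
  strand-specific.
* `docks()` stores l+1 exact count columns for both table directions;
  memory, not time, is usually the binding constraint as k grows.
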