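# uhskit

Design and evaluation of universal k-mer hitting sets in R.

A **universal hitting set (UHS)** U for parameters (k, L) is a set of
k-mers such that *every* possible string of length L over the alphabet
contains at least one member of U as a substring. Small universal sets are
drop-in replacements for minimizers in sequence-analysis pipelines —
read-overlap hashing, sparse suffix arrays, k-mer binning, Bloom filters —
with the advantage that they are sequence-independent and can be computed
once per (k, L).

On the complete de Bruijn graph D_k (one vertex per k-mer, one edge per
(k+1)-mer), the problem reads: find a smallest vertex set intersecting
every directed path with l = L − k edges. uhskit implements the two-phase
greedy approach:

1. **Decycling phase (optimal).** Remove a minimum-size set hitting every
   cycle — Mykkeltveit's minimum unavoidable set, with exactly one member
   per conjugacy (rotation) class, of cardinality
   C(σ, k) = (1/k) Σ_{i=1..k} σ^gcd(i,k),
   which also lower-bounds any UHS. Selection uses the complex embedding
   P(w) = Σ_j d_j e^(2πij/k).
2. **Path-cover phase (greedy).** In the residual DAG, repeatedly remove
   the vertex with the largest *hitting number* T(v, l) — the exact number
   of l-edge paths through v, computed by dynamic programming
   (D(v,i)/F(v,i) path-count tables in arbitrary-precision integer
   arithmetic) — until no l-edge path survives. The L-free variant scores
   by T(v) = F(v)·D(v) over paths of all lengths (removal order independent
   of L), optionally removing the top X vertices per iteration.

Also included: an exact integer-programming formulation with an exact
*threshold reformulation* that collapses the problem to σ^(k−1) integer
variables (see the methods vignette), verification oracles (walk-count DP
and literal enumeration), the U_{k+j,L+j} extension construction, set file
I/O, and a window-selection scanner for comparing hitting-set selection
against lexicographic and random-order minimizers on FASTA or synthetic
sequences.

## Worked example

```r
library(uhskit)

sp  <- kmer_space(4)           # DNA 4-mers
res <- docks(sp, L = 10)       # two-phase greedy
res
#> universal hitting set: k = 4, L = 10, method = docks
#>   size 91 = 70 decycling + 21 additional (lower bound 70, factor 1.300)

verify_uhs(res$set, 10)        # literal enumeration of all 4^10 strings
#> valid universal hitting set for L = 10 (exhaustive oracle)

sol <- solve_ilp(build_ilp(sp, 10), warm_start = res, time_limit = 120)
sol$size
#> [1] 87
```

The greedy solution uses 91 of the 256 4-mers: the 70-member minimum
decycling set (the theoretical lower bound) plus 21 additional 4-mers, an
approximation factor of 1.30. The exact solver then finds a verified
87-member set — the smallest known for these parameters.

Decycling alone suffices for long windows: the longest sequence avoiding
the k = 6 decycling set has 70 bases, so its 700 6-mers (out of 4096) hit
every sequence of 71 bases or more:

```r
sp6 <- kmer_space(6)
dec <- mykkeltveit_set(sp6)
longest_avoiding_sequence_length(sp6, dec)
#> [1] 70
```

On sequence data, hitting-set selection is sparser than minimizers:

```r
seq <- synth_sequence(50000, seed = 3)
u   <- docks_any(kmer_space(6), 20)
lex <- select_kmers(seq, selection_scheme("lexicographic", 15, space = kmer_space(6)))
uhs <- select_kmers(seq, selection_scheme("uhs", 15, set = u$set))
c(lex$distinct_selected, uhs$distinct_selected)   # fewer distinct k-mers
c(lex$avg_distance, uhs$avg_distance)             # larger gaps
```

A command-line wrapper lives in `exec/uhs`
(`compute`, `verify`, `extend`, `scan`, `lowerbound`).

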