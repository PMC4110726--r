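---
title: "Exact k-mer range queries and ensemble read mapping with apforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact k-mer range queries and ensemble read mapping with apforest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apforest)
```

## The problem

Heuristic short-read mappers are fast but give no guarantee that the
reported placement is the best one; as the sequencing error rate grows, the
fraction of reads they place wrongly or not at all grows with it. `apforest`
takes the complementary route: an *exact* metric-space index over the
reference's k-mers that answers range queries with zero false negatives, a
seed-and-extend mapper built on it, and a two-stage ensemble that lets a
fast heuristic aligner handle the easy reads while the exact index rescues
the uncertain ones.

## The metric and its role

All index structure rests on a metric $d$ over equal-length nucleotide
strings: non-negative, symmetric, obeying the triangle inequality, and zero
only for identical strings. The default is unweighted Hamming distance (the
mismatch count). A weighted Hamming variant can price transitions and
transversions differently via `weight_scheme()`; because every pruning step
in the index is an application of the triangle inequality, the cost table is
validated as a metric over `{a,c,g,t}` at construction time and rejected
otherwise. (Note that within the 4-letter alphabet a transversion can never
be shortcut by two transitions — the transition pairs are disjoint — so any
positive symmetric table with `transition <= 2 * transversion` and
`transversion <= transition + transversion` passes.) A banded
Needleman–Wunsch edit distance is provided for completeness
(`banded_nw()`), but the mapping path is Hamming-only: reads are placed
without gaps, which is what makes exhaustive verification cheap.

For a query radius $r$ on k-mers, the neighbourhood that a range query may
have to return grows as
$$B(k, r) = \sum_{i=1}^{r} \binom{k}{i} (n-1)^i,$$
with $n = 4$ nucleotides (`query_ball_size()`). This growth is why the
mapper splits reads into short seeds queried at small per-seed radii rather
than querying whole reads at the full budget.

## The adaptive projection forest

The index is a forest of multi-pivot excluded-middle vantage-point trees.
At each node:

1. A pivot $p$ is drawn and all point distances to it are computed; the
   (upper) median distance $d_m$ becomes the partition boundary. Points
   with $d < d_m$ go to the low child, $d \ge d_m$ to the high child.
2. An *exclusion band* $[d_m - \tau,\, d_m + \tau)$ is carved out around
   the boundary: points inside it are withheld from both children and
   pooled. The pool seeds the next tree of the forest, so excluded points
   are deferred, never lost.
3. If the excluded fraction exceeds the cap $m$, another pivot is added
   (chained from the previous one) up to $D$ pivots; with $d$ pivots the
   node has $2^d$ children, a point's child being the bit pattern of its
   $d$ comparisons against the per-pivot medians (`child_label()`).

A query at radius $r$ descends, per pivot, into the low side only if
$d(q,p) - r < d_m - \tau$ and the high side only if
$d(q,p) + r \ge d_m + \tau$; both tests are direct triangle-inequality
bounds under the half-open band convention, so skipped subtrees provably
contain no hits. Every tree is searched and results pooled, which is what
makes the forest exact at *any* radius, including $r > \tau$. When the
query interval falls entirely inside a pivot's band, no child of that node
can contain a hit — those points live in later trees — and the traversal
visits none, a small sharpening of the "at least one side" reading that
remains exact and is covered by the oracle-equivalence tests.

### Conventions chosen where the design was open

Several details admit more than one self-consistent reading; the package
fixes them as follows and the test suite enforces exactness under exactly
these conventions:

* **Band semantics.** A point is excluded if it falls in *some* pivot's
  band (union over pivots), and the band is half-open
  ($d_m - \tau \le d < d_m + \tau$), so at $\tau = 0$ the construction
  degenerates cleanly to the plain `<` / `>=` split. Union semantics is
  the only convention under which the traversal rule above is exact; an
  intersection reading would leave band points inside children that the
  pruning rule is entitled to skip.
* **Full exclusion defers, it does not collapse.** When a node's band
  swallows every remaining point, the points are pooled to the next tree
  and the node keeps only its pivots. This preserves the characteristic
  behaviour that wide bands on tightly concentrated distances multiply
  trees (nearly linearly in $\tau$), at the price of many small trees —
  the regime a sensible build avoids via the derived-$\tau$ rule below.
* **Median.** Upper median (element at index $\lfloor n/2 \rfloor$ of the
  sorted distances, 0-based): deterministic, and the median element itself
  lands on the $\ge$ branch.
* **Pivots are index points.** They are tested for membership when their
  node is visited (their query distances are computed for traversal
  anyway), and they count toward the conservation identity.
* **First pivot** is a uniform random draw under the build seed;
  subsequent pivots follow the configured strategy, with ties broken by
  the lowest `(chrom, start, strand)` triple so builds are reproducible.
* **Degenerate clouds** (all points equidistant from the first pivot
  candidate, e.g. all-identical k-mers) provide no separating information
  and become leaves directly; this guarantees termination.

### Parameters

* `tau` — exclusion half-width, in distance units. Fixed integer, or
  `"auto"`: each node derives the largest integer half-width whose
  excluded fraction stays within `m`. Genomic k-mer distances are tightly
  concentrated around their median (for random 16-mers the mass within
  $d_m \pm 2$ is over half), so fixed wide bands exile most of the data;
  `"auto"` is the default for reference indexing and typically yields
  $\tau = 0$–$1$ per node and a handful of trees.
* `m` — maximum excluded fraction per node (default 0.1). With fixed
  `tau` it is the pivot-addition cap instead.
* `D` — maximum pivots per node (default 4), i.e. up to $2^D$ children.
* `leaf_size` — recursion stop (default 32 points per leaf).
* `pivot_strategy` — `"optimal"` picks the next pivot at the median
  distance from the previous one (a cheap stand-in for variance-maximising
  selection), `"random"` draws uniformly, `"poor"` deliberately picks the
  closest point; the three exist to quantify how much pivot quality
  matters, and the regression property `optimal <= random <= poor` in mean
  distance calls is asserted on a fixed seeded 8-mer dataset.

## The mapper and the ensemble

`map_reads()` splits each read into $\lfloor L/k \rfloor$ non-overlapping
seeds (plus a trailing seed covering the last $k$ bases when $k \nmid L$)
and queries each at radius $r' = \lfloor r / \lfloor L/k \rfloor \rfloor$.
The pigeonhole argument makes this lossless: a placement with at most $r$
mismatches over the whole read leaves at most $r'$ mismatches on at least
one disjoint seed, so that placement is discovered by some seed query.
Every seed hit is projected to the full-read location it implies,
candidates are deduplicated, scored by full-read Hamming distance against
the reference, and the minimum wins. Co-optimal locations are resolved by
a seeded uniform pick with MAPQ 0 and `status = "tied_random"`; unique
winners get MAPQ $\min(42, 6 \cdot \text{gap})$ where gap is the distance
margin to the runner-up candidate — a deliberately simple monotone score,
since only its ordering relative to the rescue cutoff matters here.
A read whose best candidate exceeds the radius budget is reported
unmapped rather than guessed.

`rescue_pipeline()` implements the two-stage ensemble: records with MAPQ at
or above the cutoff (default 14) pass through untouched; unmapped or
low-MAPQ reads are re-mapped exactly and their records replaced, tagged
`PG:Z:apforest`. The bundled first stage, `heuristic_stub_align()`, is a
deliberately fallible exact-seed hash aligner (first 16 bases, first hit
wins) so the ensemble can be exercised end to end without external
binaries; any SAM producer can be substituted.

## The simulator and what it does (and does not) emulate

`simulate_genome()` draws a uniform ACGT background and can plant diverged
duplications — the minimal structure needed to create genuinely ambiguous
and unrecoverable reads. `simulate_reads()` draws positions and strands
uniformly and substitutes bases with a position-dependent probability:
a linear ramp from 0.001 at the first base to 0.01 at base 80 (an
Illumina-like degradation toward the 3' end), scaled by a 1x/2x/10x
multiplier and capped at 0.75. The defaults are the package's study
conditions: 80-bp reads, substitutions only (the mapper is ungapped), and
a truth table recording every read's origin and planted error count.

What passing tests on this generator show is the *algorithmic* guarantee:
exactness of the index, the pigeonhole soundness of seeding, and the
directionality of the ensemble (rescue helps most when errors are heavy).
What they cannot show is robustness to what the generator omits — indels,
quality-correlated errors, non-uniform genome composition, real repeat
families — so accuracy figures from these simulations are not forecasts
for real libraries.

`evaluate_mappings()` scores mappings against truth with a positional
tolerance of 0 by default (exact origin). It separates *incorrect* from
*unrecoverable* placements: a read is unrecoverable when an exhaustive
scan of the genome (both strands) finds a location strictly closer than
its true origin, in which case no exact method can rescue it — the
realized accuracy ceiling of any optimal mapper. The headline accuracy
counts unmapped reads as errors; `accuracy_mapped` is also reported for
the other denominator convention.

## Problem sizes used by the test batteries

The randomized exactness battery runs 45 builds (9 parameter combinations
$\times$ 5 replicates, 100–600 random 8-mers each) with 23 queries per
build — over 1000 build/query instances verified against a brute-force
scan written in plain vectorised R. The read-level battery builds a 1-Mb
single-chromosome index (about 2 million 16-mer points on both strands)
for the error-free 100%-accuracy check, verifies mapper distances against
an exhaustive sliding-window oracle on a 60-kb genome for 200 high-error
reads, and runs the three-multiplier ensemble comparison on a 50-kb genome
with two planted diverged repeats and 300 reads per multiplier. These
sizes were chosen as the smallest at which every mechanism (multi-tree
descent, repeat-induced ties, unrecoverable reads, rescue gains) is
actually exercised.

## Known limitations

* Hamming-only mapping: indels shift every downstream seed and will
  defeat the mapper; `banded_nw()` exists but is not wired into the
  mapping path.
* The radius budget is a hard reporting cutoff: reads farther than `r`
  from everywhere are honestly unmapped, so at extreme error rates the
  rescue stage's ceiling is set by `r`, not by the index.
* The index holds encoded points in memory (4 bytes per base plus
  structure); it targets desk-scale references, not whole mammalian
  genomes.
* MAPQ from the rescue mapper is an ordinal confidence score, not a
  calibrated error probability.
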