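# apforest

Exact metric-space indexing of genomic k-mers and ensemble short-read
mapping in R.

Heuristic read mappers trade accuracy for speed: as sequencing error rates
rise, a growing fraction of reads is placed wrongly or dropped. `apforest`
implements the complementary exact approach — a metric-space index, the
**adaptive projection forest**, over all k-mers of a reference genome —
plus a seed-and-extend mapper built on it and a two-stage ensemble in which
a fast heuristic aligner handles the confident reads and the exact index
rescues the rest, selected by SAM MAPQ.

## The method in brief

A range query asks for *every* indexed k-mer `t` with `d(q, t) <= r` under
a metric `d` (default: Hamming distance); the index answers it exactly —

```
for all t in T:  t in R  <=>  d(q, t) <= r
```

— with no false negatives at any radius. The forest consists of multi-pivot
excluded-middle vantage-point trees. Each node picks up to `D` pivots,
splits points at each pivot's median distance `dm`, and carves out an
exclusion band `dm ± tau`; band points are deferred to the next tree of the
forest. Queries descend only the children that the triangle inequality
cannot rule out: per pivot, the low side is needed iff `d(q,p) - r < dm -
tau` and the high side iff `d(q,p) + r >= dm + tau`. The expected
neighbourhood size `B(k, r) = sum_{i=1..r} C(k,i) * 3^i` motivates mapping
reads via short seeds at small per-seed radii: a read with at most `r`
mismatches somewhere must, by pigeonhole, have a seed with at most
`floor(r / n_seeds)` mismatches there, so the seed queries never miss the
optimal placement within the budget.

The package also ships a synthetic genome/read simulator with a scalable
position-dependent substitution-error profile (1x/2x/10x) and an accuracy
evaluator that distinguishes *incorrect* placements (the origin is still
globally optimal — an exact mapper recovers them) from *unrecoverable*
ones (planted errors made another locus strictly closer, so no exact
method can help).

## Worked example

```r
library(apforest)

genome <- simulate_genome(50000, seed = 7)
idx <- reference_index(genome, k = 16,
                       params = apf_params(tau = "auto", m = 0.1, D = 4, seed = 7))
idx
#> <ref_index> 1 reference sequence(s), 50,000 bp; k=16 stride=1 strands=+-
#> <apforest> 99970 points (k=16), 1 tree(s); tau=auto m=0.1 D=4 leaf_size=32

# exact range query: the window at position 100, radius 2
range_query(idx, substr(genome$sequences[[1]], 101, 116), 2)
#> <apf_query> 1 hit(s), 13926 distance call(s), 1664 node(s) visited
#>                seq  chrom start strand distance
#> 1 aatctcttagatgtgc synth1   100      +        0

# heavy-error reads: first-stage stub aligner, then exact rescue
sim    <- simulate_reads(genome, 500, profile = error_profile(10), seed = 8)
first  <- heuristic_stub_align(sim$reads, genome, k = 16)
merged <- rescue_pipeline(first, sim$reads, idx,
                          ensemble_params(mapq_cutoff = 14, r = 6, seed = 9))

evaluate_mappings(sam_to_mappings(first), sim$truth, genome)
#> <accuracy_report> 500 reads: 348 correct, 0 incorrect, 152 skipped (0 unrecoverable)
#>  accuracy 69.60% (all reads), 100.00% (mapped reads)
evaluate_mappings(sam_to_mappings(merged), sim$truth, genome)
#> <accuracy_report> 500 reads: 424 correct, 0 incorrect, 76 skipped (0 unrecoverable)
#>  accuracy 84.80% (all reads), 100.00% (mapped reads)
```

At a 10x error profile the stub aligner (exact 16-bp first seed, first hit
wins) drops 30% of the reads; the exact rescue stage re-maps every read
whose full-read distance fits the radius budget `r = 6`, halving the loss.
The reads still skipped carry more than 6 substitutions — raise `r` to
trade time for recall. `accuracy` counts unmapped reads as errors;
`accuracy_mapped` shows the mapped-only denominator.

A thin CLI wraps the same functions (`inst/cli/apforest`):

```sh
apforest simulate --length 100000 --reads 1000 --error-x 10 --seed 7 --out sim/
apforest build-index --ref sim/ref.fa --k 16 --tau auto --seed 7 --out idx.apf
apforest map --index idx.apf --reads sim/reads.fq --radius 6 --out out.sam
apforest rescue --index idx.apf --sam first.sam --reads sim/reads.fq \
         --mapq-cutoff 14 --out merged.sam
apforest evaluate --truth sim/truth.tsv --ref sim/ref.fa --sam merged.sam
apforest selftest
```

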