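# broadGuide

Most CRISPR guide-design tools answer the question "which single guide RNA
uniquely targets this one locus?". Applications built on catalytically dead
Cas9 — chromosome painting with dCas9–GFP, epigenome editing with
dCas9-fused methyltransferases or KRAB domains — need the opposite: a
*single* guide whose binding sites are **many** and **concentrated** inside
a chosen large genomic region (tens of kb to Mb), with as few binding sites
elsewhere as possible. broadGuide finds and ranks such multi-targeting
guides, and ranks all targetable windows of a genome, for Cas9-class
(3'-PAM) and Cas12a-class (5'-PAM) systems.

## Method

For a genome and a PAM pattern (default `NGG`, 3', 20-nt protospacer), the
pipeline:

1. **extract** — enumerates every PAM-anchored candidate protospacer on
   both strands, including overlapping occurrences, with an optional GC
   filter (sites overlapping `N` are discarded);
2. **map** — finds *all* genomic alignments of each candidate up to a
   mismatch budget (0–3 substitutions in the protospacer; the PAM must
   match exactly under IUPAC degeneracy), using a pigeonhole
   seed-and-verify search with a per-guide hit cap (default 10,000);
3. **window / score** — assigns hits to sliding windows of size *k* and
   scores each window as

   W = Σᵢ (mᵢ − nᵢ − gᵢ) / L

   over the contained hits, with mᵢ, nᵢ, gᵢ the matches, mismatches and
   gap bases of hit *i* and L the guide length. Windows with fewer than
   `minHits` (default 5) hits are dropped;
4. **select** — per guide, greedily picks up to `nBins` non-overlapping
   top-scoring windows as target bins; every hit outside the bins is an
   off-target. With *t* total hits, *h* on-target, *o* off-target, and the
   evenness E of hit positions within the bins, the aggregate guide score
   is

   S = w_E·E + (h/t)·(ΣW/h) − (o/t)·(ΣW′/o)

   (per-hit mean-normalized on- and off-target window scores). With the
   default evenness weight w_E = 0, S is bounded in [−1, +1]: +1 for an
   all-on-target perfect guide, −1 for an all-off-target one;
5. **pool** — merges target bins across guides into shared regions.

Guides are ranked by descending S (ties: higher *h*, then sequence).
A region-restricted mode designs guides only inside user-supplied BED
regions while still counting off-targets genome-wide, and external
end-to-end aligner output can be imported from SAM in place of the
internal mapper.

## Worked example

The package ships a synthetic-genome generator that plants repeat families
with known copy number and divergence — the same machinery the test suite
uses as ground truth:

```r
library(broadGuide)

fx <- generateFixture(
    c(chrA = 8000L, chrB = 4000L),
    plants = list(plantSpec("GATTACAGATTACAGATTAC", "TGG",
                            copiesOnTarget = 8L,
                            clusterChrom = "chrA",
                            clusterStart = 1500L, clusterEnd = 5500L)),
    seed = 3)

res <- runBroadGuide(fx$genome, windowSize = 5000, step = 500,
                     minHits = 5, maxMismatches = 1)
res
#> BroadGuideResult: 1 ranked guides, 1 target bins, 1 pooled regions
#>   top guides:
#>     1. GATTACAGATTACAGATTACTGG  S=1.0000  h=8 o=0
```

The ranked report (`reportTable(res)`, or the TSV written when
`outPrefix` is set) holds one row per guide:

```
rank  guide                    score   gc      onTargets offTargets totalHits ... bins
1     GATTACAGATTACAGATTACTGG  1.0000  0.3478  8         0          8             chrA:1-5000
```

The planted guide scores exactly 1: all 8 of its hits are perfect and fall
inside the selected 5-kb bin (`chrA:1-5000`), and it has no off-targets.
`guideBins(res)` and `pooledRegions(res)` expose the bins and the pooled
multi-guide regions as `GRanges`; hit coordinates are reported 1-based
inclusive as `chrom:start-end:strand`.

The same run is available from a shell:

```sh
Rscript inst/scripts/broadguide.R run --genome genome.fa \
    --window-size 5000 --step 500 --min-hits 5 --max-mm 1 --out myrun
```

which writes `myrun.report.tsv`, `myrun.bins.bed`, `myrun.pooled.bed`, a
JSON run log, and per-stage intermediates that let the expensive stages be
re-run individually (`broadguide.R select --out myrun ...` after changing
only selection parameters).

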