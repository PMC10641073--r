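---
title: "Designing multi-targeting guide RNAs with broadGuide"
author: "broadGuide authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-targeting guide RNAs with broadGuide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broadGuide)
```

## The problem

dCas9-based applications — fluorescent labeling of chromosome elements,
targeted DNA methylation, KRAB- or LSD1-mediated chromatin modification —
scale with the number of guide-RNA-directed binding events inside the
region of interest. Recruiting fifty-plus dCas9 molecules to a region with
a panel of individually designed single-target guides is expensive and
multiplies off-target risk. The alternative pursued here is a single
*multi-targeting* guide: one protospacer sequence that the genome itself
repeats many times inside a window (tandem duplications, dispersed repeat
families), with few occurrences elsewhere. broadGuide enumerates all such
guides, quantifies how concentrated and how clean their binding is, and
ranks them.

## Model and scoring

A candidate guide is a protospacer (default 20 nt) plus an adjacent PAM
matching an IUPAC pattern (default `NGG`, 3' of the protospacer; 5'-PAM
layouts for Cas12a-class systems are supported). Every genomic position on
either strand whose PAM slot matches the pattern yields one candidate;
overlapping candidates are all kept, and identical full sequences from
different loci collapse into one guide with several origins.

A *hit* of a guide is an end-to-end alignment of its protospacer at a
genomic locus with at most `maxMismatches` substitutions (0–3) whose PAM
matches the pattern exactly — the PAM tolerates IUPAC degeneracy but never
a mismatch, mirroring the biology of PAM recognition. Mismatches are
penalized equally at every protospacer position; no seed-region weighting
is applied, and consequently no CFD/MIT-style position-weighted off-target
score is computed. Each hit carries the score

$$ s_i = \frac{m_i - n_i - g_i}{L} $$

with $m_i$ matched bases over the full $L$-base footprint (the
exactly-matched PAM counts toward $m_i$), $n_i$ substitutions and $g_i$
gap bases. The internal mapper is ungapped ($g_i = 0$); gapped alignments
enter only through SAM import (below). A window of size $k$ scores
$W = \sum_i s_i$ over the hits whose start position lies inside it.

Per guide, up to `nBins` non-overlapping windows with highest $W$ are
selected greedily as target bins (ties: leftmost start, then chromosome
name — deterministic, and near-optimal for the disjoint cluster structure
that repeat families produce; no optimal set-cover is attempted). With $t$
total hits, $h$ inside the bins, $o = t - h$ outside, the aggregate score
is

$$ S = w_E\,E \;+\; \frac{h}{t}\cdot\frac{\sum_{on} W}{h}
       \;-\; \frac{o}{t}\cdot\frac{\sum_{off} W'}{o} $$

where a term with zero hits contributes zero. The on- and off-target sums
are normalized to per-hit means before weighting: the raw sums grow
without bound in the hit count, which would make scores of guides with
different $t$ incomparable and would break the intended $[-1, +1]$ range.
The mean-normalized form collapses algebraically to
$S = w_E E + (\sum_{on} W - \sum_{off} W')/t$, is bounded in $[-1, +1]$
at $w_E = 0$, reaches exactly $+1$ for an all-on-target all-perfect guide
(at any $h$ — scale invariance) and $-1$ for an all-off-target one. The
raw sums are still reported in the output table.

### Evenness and dispersion

A guide whose hits carpet a window uniformly is more useful for painting
or epigenome spreading than one whose hits pile onto one spot. Evenness is
measured as the positional standard deviation of the on-target hits
(offsets within their own bin, pooled across bins) divided by the standard
deviation of a uniform distribution over the window, $k/\sqrt{12}$, capped
at 1:

$$ E = \min\!\left(1,\ \mathrm{sd}(\text{positions}) \big/
       (k/\sqrt{12})\right) $$

This is a design choice: any measure that is 0 for a point mass, near 1
for uniform spread, and translation invariant would serve; the sd ratio is
the simplest such measure with an exact Monte-Carlo-checkable limit. By
default `evennessWeight = 0`, so $S$ stays within $[-1, +1]$ and evenness
is reported as a separate column; setting the weight to 1 adds $E$
literally, which widens the attainable range upward. Dispersion — the
population standard deviation of hit positions within the top bin, in
bases — is reported alongside (0, flagged degenerate, below two hits).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pam`, `pamSide` | `NGG`, 3' | IUPAC PAM pattern and side |
| `spacerLen` | 20 nt | protospacer length (≥ 10) |
| `gcMin`, `gcMax` | 0, 1 | GC bounds on the full guide sequence |
| `maxMismatches` | 3 | protospacer substitution budget (0–3) |
| `hitCap` | 10,000 | per-guide cap on enumerated hits |
| `windowSize` | 50,000 b | target window size *k* |
| `step` | *k*/10 | sliding-window advance |
| `minHits` | 5 | hits required to retain a window |
| `nBins` | 1 | target bins per guide |
| `evennessWeight` | 0 | weight of E in S |
| `mergeGap` | 0 b | pooling gap (0 = strict overlap) |

The window count depends on `step`, so the step is echoed in the JSON run
log of every run. Guides whose enumeration stops at `hitCap` carry a
`saturated` flag into the report rather than being silently truncated.

## Coordinates, degenerate inputs, numerical choices

Internally coordinates are 0-based half-open; `GRanges` objects follow the
1-based closed Bioconductor convention, and all user-facing reports print
1-based inclusive coordinates (`chrom:start-end:strand`). A hit belongs to
a window iff its leftmost base lies inside the half-open window interval —
membership by start is unambiguous for fixed-length footprints, and a hit
starting exactly at a window's end coordinate is excluded. Window tiling
emits full windows while they fit and one end-clipped window when the full
windows do not reach the chromosome end and the remainder is at least one
step long; a chromosome shorter than *k* becomes a single window.

Lowercase (soft-masked) genome sequence is uppercased and treated as
ordinary sequence. IUPAC ambiguity codes in the input are normalized to
`N`; any candidate or hit whose footprint overlaps an `N` is discarded —
unknown sequence should neither seed a guide nor count as a binding site —
while the exported `iupacMatch()` primitive lets a pattern `N` (and only a
pattern `N`) match a genomic `N`. Chromosomes shorter than the guide
length are skipped with a warning; a guide with zero hits is kept in the
hit-count table with t = 0 and excluded downstream; `aggregateScore()`
refuses t = 0.

Floating-point output is fixed at 4 decimals and every table is
canonically sorted (guide, chromosome order, start, strand) before
writing, so a rerun with the same configuration — at any `threads`
setting — is byte-identical. No pipeline stage consumes randomness; the
only seeded code is the fixture generator, which saves and restores the
global RNG state.

## Mapping: pigeonhole seeding, SAM import

The internal mapper splits the protospacer into `maxMismatches + 1`
disjoint pieces; any hit within the budget must contain at least one exact
piece, so candidate loci come from a k-mer index of the genome keyed on
the leading bases of each piece and are then verified by direct
comparison (early exit past the budget), with exact PAM verification
precomputed per position. Hits are deduplicated on (chromosome, start,
strand) and enumerated in canonical order so the hit cap cuts
deterministically.

Gapped alignment of 20-mers is aligner-idiosyncratic, so it is delegated:
`importSamHits()` accepts any end-to-end aligner's SAM, derives
$(m, n, g)$ from CIGAR and the NM tag ($g$ = inserted + deleted bases,
$n$ = NM − g, $m$ = aligned bases − n), re-verifies the PAM against the
genome before accepting a record, and drops records beyond the mismatch
budget. `exportSamHits()` writes the internal hits in the same format for
parity checks against external aligners.

## The synthetic-genome generator and what the tests show

`generateFixture()` plants repeat families of known copy number,
divergence (0–3 substitutions per copy, never in the PAM) and spatial
clustering into i.i.d. background sequence of chosen GC content, then
rejection-checks the background so no spurious exact copy of a planted
protospacer survives; the manifest of realized coordinates is exact ground
truth. The test suite uses these fixtures for oracle equivalence (the
production mapper against a brute-force position-by-position scan, 200
seeded genomes at every mismatch budget), exact parameter recovery
(reported t, h, o, per-hit mismatch counts and bin placement against the
manifest), the score contract, monotonicity trends (off-targets fall and
scores rise with more bins and larger windows), and byte-level
determinism. Test genomes are 2–20 kb and the acceptance script uses 50
fixtures of ~5 kb — sizes at which the brute-force oracle is exact and
fast and random 20-mer recurrence is vanishingly improbable.

The i.i.d. background is deliberately simpler than real genomes: no
Markov structure, no nested or diverged repeat hierarchies, no
chromatin context. Passing these tests therefore demonstrates algorithmic
correctness — the right hits, counts, scores and orderings for known
truth — not that a top-ranked guide will perform in a given cell type;
guide activity, chromatin accessibility and learned off-target models are
out of scope by design.

## Known limitations

- The internal mapper is ungapped; bulged protospacers are only visible
  via SAM import.
- Equal per-position mismatch penalties are a modeling commitment, not an
  approximation of cleavage biochemistry.
- With imperfect (mismatched) hits, adding a *low-scoring* off-target hit
  to a guide whose score is already deeply negative can raise $S$
  slightly (the mean off-target penalty is diluted); the monotonicity
  guarantee — one more perfect off-target hit never raises $S$, one more
  perfect on-target hit never lowers it — holds exactly and is what the
  test suite asserts.
- Greedy bin selection is optimal for disjoint hit clusters but not in
  general; it is kept for determinism and interpretability.
- Evenness compares against a uniform reference only; periodic hit
  spacings with the same sd are not distinguished.
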