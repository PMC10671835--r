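---
title: "Pan-mitogenome NUMT discovery: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-mitogenome NUMT discovery: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pannumt)
```

## The problem and the model

Nuclear mitochondrial DNA segments (NUMTs) are fragments of the
mitochondrial genome fixed in nuclear chromosomes. Because mtDNA is
polymorphic across human populations, a NUMT derived from one haplotype
can be substantially diverged from the single reference mitogenome
(rCRS), and reference-only alignment under-counts them. The remedy
implemented here is to query with a *pan-mitogenome*: a pool of many
full-length mitogenomes, control-region (D-loop) fragments, and the
reference, so that the query set itself carries the population's
mutational spectrum.

Discovery is classical thresholded local alignment. For a hit of raw
score $S$ between a query of length $m$ and a nuclear search space of
length $n$, the expected number of equal-or-better chance hits is the
Karlin–Altschul expectation

$$E = K\,m\,n\,e^{-\lambda S},$$

where $\lambda$ is the unique positive root of
$\sum_{ij} p_i p_j e^{\lambda s(i,j)} = 1$ for background base
frequencies $p$ and the scoring matrix $s$. A region is called a NUMT
when $E \le 10^{-4}$, percent identity (identical columns over all
alignment columns, gaps included) exceeds 63, and the nuclear interval is
at least 28 bp; overlapping calls from all pool records are merged.

## The tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `pad` | 100 | bp | circular extension; lets alignments cross the linearisation origin of the circular molecule |
| `min_full_len` | 16,530 | bp | full-length cutoff; excludes partial deposits while keeping naturally short variants of the ~16,569 bp molecule |
| reward / penalty | +2 / −3 | score units | megablast-style nucleotide scoring appropriate for ~90%+ identity homology |
| gap open / extend | 5 / 2 | score units | affine gaps: a gap of length $g$ costs $5 + 2g$ |
| `max_evalue` | 10⁻⁴ | — | stringent chance-hit ceiling; with a pool of ~10⁵ queries this keeps the pool-wide expected false-call count of order 10 |
| `min_identity` | 63 (strict >) | % | divergence ceiling ≈ the oldest recognisable insertions; a copy at 40% divergence falls below it |
| `min_length` | 28 (inclusive ≥) | bp | the knee of the mapped short-segment length distribution (below) |
| `word_size` | 11 | bp | exact-match seed length; standard nucleotide word size |
| `x_drop` | 20 | score units | extension abandons a front that falls 20 below the running optimum |
| `k` | 20 | bp | short-segment word length |

Two wordings of the length rule circulate ("greater than 28 bp" vs a
printed minimum of exactly 28); the inclusive interpretation
($\ge 28$) is used because reported compilations contain 28 bp entries.
The identity filter is strict ($> 63$).

## Alignment engine

Seeding enumerates *maximal* exact matches of length ≥ `word_size`
between each (circularly padded) query and the genome, on both strands,
each maximal run reported once. Extension is X-drop dynamic programming
(Gotoh three-state affine recurrences) leftwards and rightwards from the
seed, with the seed interior scored as matches. On sequences where the
optimal local alignment passes through a seed and never dips more than
`x_drop` below its running maximum, the extension score equals the full
Smith–Waterman–Gotoh optimum; the test suite verifies this equivalence
against an independently implemented full-matrix dynamic program on
hundreds of seeded random pairs.

Consequences of the default `x_drop = 20` worth knowing:

* an insertion/deletion of 8–10 bp costs 21–25 score units, so a single
  long indel inside an otherwise well-conserved insertion can split one
  planted NUMT into two adjacent calls separated by a few bases. Both
  pieces pass the filters and the region is still recovered, but a
  boundary-error statistic computed against the unsplit truth interval
  will show it. Raising `x_drop` trades this for longer chance
  extensions.
* ties among equally scoring extensions are broken toward the smaller
  nuclear start coordinate, then the plus strand, so results are
  deterministic.

Statistical parameters: for the default scheme the gapped
$(\lambda, K) = (0.625, 0.410)$ are shipped as constants (gapped
Karlin–Altschul parameters are empirical); any other scheme falls back to
computed *ungapped* values — $\lambda$ by bracketed root-finding to a
residual below $10^{-9}$ and $K$ by the classical lattice series
truncated at a relative change of $10^{-6}$ — with a warning. Search
lengths $m$ and $n$ are the raw query and total genome lengths; no
BLAST-style effective-length adjustment is applied, and the choice is
recorded in the result metadata. Since acceptance thresholds sit far from
the filter boundary, a constant factor on $E$ does not change calls.

## Interval conventions

Internal coordinates are 0-based half-open (BED); mitochondrial positions
are reported 1-based inclusive (the control region is 16,024–16,569 ∪
1–576), with conversion centralised in `bed_to_mt1()` / `mt1_to_bed()`.
Merging joins overlapping *and book-ended* intervals, matching the
default of the standard BED toolchain; `min_gap` is exposed for
sensitivity analysis. The summary statistics use the lower median for
even counts, stated here because downstream tables are compared against
published ones whose median convention is unstated. Because published
overlap percentages sometimes use the comparator's length and sometimes
the union as denominator, `overlap_stats()` emits both fractions.

## k-mer short-segment scan

The pool is decomposed into overlapping 20-mers; windows containing `N`
or IUPAC ambiguity codes are discarded. The k-mer table maps directly to
the genome by exact dictionary matching on both strands (an optional
mismatch tolerance up to 3 scans per k-mer); duplicate placements of the
same k-mer at the same position collapse. An intermediate pseudo-FASTQ
representation (fake quality strings fed to a short-read aligner) adds
nothing mathematically and is deliberately bypassed. Mapped positions
merge into maximal segments, and the segment-length histogram typically
shows an abrupt drop: random 20-mer matches chain into segments only
slightly longer than 20 bp, while genuine homology produces long ones.
The "turning point" is operationalised — no formula exists in the
literature, so this package defines one — as the length within
$[k+1, 3k]$ with the largest drop of log-counts between consecutive
occupied lengths, ties toward the smaller length, with a configured
default of 28 bp returned (with a warning) when the range is empty or
flat. This knee motivates the 28 bp minimum NUMT length.

## Circular breakpoint profiling

Filtered hits are projected back onto 1-based circular mitogenome
coordinates: padded positions past 16,569 wrap to the origin, coverage
increments once per hit per position, and each hit contributes its two
wrapped endpoints. Coverage is exactly conserved
($\sum$ coverage $= \sum$ wrapped hit lengths), and the projection is
rotation-equivariant; both are enforced by tests. "Breakpoint" has no
agreed statistic, so two operationalisations are reported: endpoint
density, and maximal circular runs of positions at or below the 5%
coverage quantile with a minimum run of 20 bp. On a constant positive
profile the quantile equals the maximum and no region is reported; an
all-zero profile returns the full circle with a warning. Hits from
simulated molecules longer than 16,569 bp (lineages with net insertions)
have no exact canonical coordinates and are excluded from projection by
`mt_projectable()`. Coverage counts filtered, pre-merge hits; whether to
count merged regions instead is a flag-level choice left to the caller,
since the two differ only by hit multiplicity. The feature annotation is
an input table, not a hardcoded gene map; the bundled
`mt_annotation_synthetic.tsv` is a synthetic rCRS-like layout for tests,
not an authoritative annotation.

## The simulator: what it emulates and what it does not

`simulate_population()` draws each distinct lineage i.i.d. from a single
random root (a star phylogeny) with per-site substitution and indel
rates, then appends exact byte-copies to reach the configured duplicate
fraction. This reproduces the two features of public mtDNA deposits the
method actually consumes — redundancy (exact duplicates) and diversity
(a cloud of near-identical haplotypes) — without modelling a genealogy;
the real pool is an observational database, not a coalescent sample.
Defaults mirror the scaled-down shape of that database: duplicate
fraction 0.25 (the public full-length set is roughly one quarter
duplicates), substitution rate 0.002/site (tens of differences per
lineage pair, the scale of human mtDNA haplogroup divergence), indel
rate 5×10⁻⁵/site. Control fragments are drawn from the control region
(16,024–16,569 ∪ 1–576) of random members with lengths uniform in
400–1,598 bp, wrapping the origin as needed.

`plant_numts()` builds an i.i.d. nuclear background at GC 0.41 (the
human genome-wide value) and inserts source segments copied from the
circular root, mutated to a per-insertion divergence applied as a 10:1
substitution:indel mix (indel lengths geometric(0.5), capped at 10 bp).
The truth BED records exact post-insertion coordinates. The standard
scene used throughout testing is seed 7: a 2 Mb background, 50
insertions with lengths log-uniform in 35–14,855 bp (the span reported
for real compilations) and divergences uniform in 0–20%.

What the simulator does **not** model — and hence what passing tests do
not show about real data: repetitive nuclear sequence (an i.i.d.
background has no Alu/satellite structure, so real-genome specificity is
easier here than in practice), post-insertion decay of old NUMTs beyond
simple divergence, nested or rearranged insertions, haplogroup tree
topology, and sequencing error. Recall/precision on the scene
characterise the algorithm under its stated assumptions, not performance
on a telomere-to-telomere assembly.

## Problem sizes and numerical choices

The discovery pool for the standard scene is 8 full-length records, 12
control fragments and the reference — a deliberately modest pool, since
scene insertions derive from a single root and additional near-identical
queries only multiply redundant hits; the pooling path itself (mixed
kinds, padding bookkeeping, id uniqueness) is exercised in full. Oracle
comparisons run at sizes where brute force is exact: full-matrix dynamic
programming on pairs ≤ 120 bp, boolean-mask interval algebra on
coordinate ranges ≤ 50 kb, naive sliding-window k-mer scans on ≤ 100 kb.
Root-finding uses bracketing plus Newton polish (residual well below the
$10^{-9}$ contract); the lattice-series truncation for $K$ stops at a
relative change of $10^{-6}$, which moves e-values by far less than the
distance of any call from the $10^{-4}$ boundary.

Degenerate inputs are defined behaviour, not errors, wherever a sensible
answer exists: empty FASTA yields an empty record set with a warning;
`pad = 0` and `min_len = 0` are identities; an empty interval set
summarises to zeros with a warning. Errors are reserved for contract
violations: non-IUPAC characters (named with record and position),
padding a record not longer than the pad, duplicate pool ids, invalid
BED lines (with line numbers), non-positive search lengths, a
non-negative expected pair score (no valid $\lambda$), and corrupt hit
coordinates.

## Known limitations

* Exact deduplication only: near-duplicate collapsing (as a self-search
  with permissive defaults would do) is not attempted, because the exact
  criterion is not reproducible; identical regions merge downstream
  anyway.
* The e-value uses raw search lengths; absolute e-values differ from
  BLAST's by a bounded factor near short-sequence edges.
* Exact k-mer mapping is stricter than a seed-tolerant short-read
  aligner; the mismatch mode (≤ 3) approximates it but scans per k-mer.
* The X-drop default can split calls at long indels (see above).
* No masking of low-complexity sequence; on real genomes a
  dust/seg-style prefilter would be advisable, and real-genome-scale
  throughput is out of scope.
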