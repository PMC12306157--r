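---
title: "Discovering palindromic elements in prokaryotic genomes with PEscan"
author: "PEscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering palindromic elements in prokaryotic genomes with PEscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PEscan)
```

# The problem

Bacterial and archaeal intergenic DNA is rich in short palindromic
elements (PEs): sequences whose two arms are reverse complements of each
other and can fold into a stem-loop. Two classes dominate.
*Rho-independent terminators* (RITs) are hairpins immediately followed
by a thymine/uridine-rich 3' tail; they terminate transcription.
*Repetitive extragenic palindromic elements* (REPs) are hairpins
without a tail signal that occur in many near-identical copies per
genome, cluster near gene ends, and have been implicated in mRNA
stabilization, translational control and nucleoid organization. PEscan
finds both classes in an annotated genome (FASTA + GFF3), labels each
candidate, and annotates it with respect to the flanking genes.

# The method

The scan is an exhaustive, deterministic structural search — there is
no statistical model and no multiple-testing machinery. For each
intergenic region, in both orientations:

1. **Seeding.** The region is decomposed into overlapping k-mers
   (default $k = 6$). Every ordered position pair $(i, j)$ whose k-mers
   are exact reverse complements, whose arms do not overlap, and whose
   outer span is at most 50 nt becomes a seed. K-mers containing `N`
   never seed.
2. **Extension.** Each seed is grown symmetrically inward and outward
   while the newly added base pair is Watson–Crick (A·T, G·C) or G·T
   wobble; extension stops at the first non-pairing position and at
   region edges. Arms never cross.
3. **Assembly.** Two extended pairs whose left arms and right arms are
   each separated by at most 2 nt are merged into one stem; the bulged
   positions are recorded as gaps. Merging repeats to a fixed point and
   contained pairs are discarded.
4. **Energy.** The implied stem-loop is scored additively: G-C pairs
   contribute $-2.3$, A-T $-0.9$, G·T wobble $+1.3$ kcal/mol; a
   mismatch costs $+3.5$, a bulged (gap) position $+6.0$; the loop adds
   $1 \times (n - 2)$ for a loop of $n$ nt. Hairpins must score at or
   below $-0.2$ kcal/mol.
5. **Structural filters.** Arm length 5–32 nt, loop at most 11 nt, at
   least one paired stem position, stem-to-loop ratio at least 0.2, and
   whole-element length at least 10 nt. All thresholds are inclusive:
   the cutoffs are quoted without strictness anywhere we know of, and
   inclusive comparisons are exactly reproducible.
6. **Tail score and classification.** The up-to-15-nt sequence
   immediately 3' of the hairpin is scored
   $-\sum_{i=1}^{L}\prod_{j=1}^{i} w(x_j)$ with $w(T) = 0.9$ and $w$
   of any other base $= 0.6$. An all-T window scores $\approx -7.15$,
   a T-free window at worst $-1.5$. Elements scoring at or below
   $-2.5$ are RITs; everything else is a REP. This is the
   terminator-tail scoring scheme popularized by TransTermHP-style
   predictors. Because the published description of the tail equation
   is a citation rather than a formula, the cumulative-product form
   above is our reconstruction; it uses only the two published weights,
   weighs thymines nearest the hairpin most, and reproduces the
   documented discrimination between all-T and all-A tails. It lives
   behind `tailScore()` so an alternative form can be swapped in
   without touching classification.
7. **Annotation.** Each candidate records the nearest gene ending at or
   before its start and starting at or after its end (forward axis),
   with gap distances in nt. A candidate further than
   `maxGeneDistance` (default 200 nt; 6,200 for a full-genome
   reproduction run, covering the longest intergenic stretches of
   *E. coli* K-12) from its upstream gene is dropped, as are
   record-edge candidates without an upstream gene unless
   `keepEdge = TRUE`. A REP whose same-strand upstream stop codon lies
   at most 15 nt away is flagged (`within_15nt_of_stop`) — the class
   of putative translational regulators ("group 1"); REPs with an
   upstream same-strand gene at 16 nt or more form "group 2".

## Orientation handling

A hairpin is orientation-symmetric: the reverse complement of a
stem-loop is again a stem-loop at the same genomic position. The tail
is not. Both orientations of every region are therefore scanned, and a
detection is reported on the strand on which a qualifying T-rich tail
lies 3' of the hairpin. Opposite-strand detections of the same
physical hairpin (identical span, or reciprocal overlap of at least
0.9 — G·T wobble makes extension slightly orientation-asymmetric, so
spans can differ by a base or two) are collapsed: a RIT beats a REP,
two REPs are reported once on "+", two RITs keep the more negative
tail score. We deliberately do not double-report symmetric detections
on both strands.

## Deduplication

Overlapping same-type candidates (overlap above half the shorter span)
are resolved in favour of the lowest hairpin energy, with leftmost and
then longest as tie-breaks. Candidates of different types are never
deduplicated against each other. This policy is a declared design
choice of this package; other implementations of this kind of scanner
may resolve overlaps differently, which is the main reason exact
genome-wide totals are implementation-sensitive.

## Coordinates

All in-memory objects use the 1-based inclusive convention native to
`GRanges`/`Biostrings`. Conversion happens only at I/O boundaries: GFF3
and the TSV output are 1-based inclusive (identity), BED output is
0-based half-open. The TSV is the authoritative output; the BED score
column is `round(-10 * hairpin_energy)` clamped to [0, 1000].

# Tunable parameters

| parameter | default | meaning (units) |
|---|---|---|
| `k` | 6 | seed k-mer size (nt) |
| `maxSpan` | 50 | maximum seed outer span (nt) |
| `maxGap` | 2 | maximum assembly bulge (nt) |
| `minArm` / `maxArm` | 5 / 32 | stem arm length bounds (nt) |
| `maxLoop` | 11 | maximum loop (nt) |
| `minStem` | 1 | minimum paired stem positions |
| `minStemLoopRatio` | 0.2 | stem/loop ratio |
| `minElementLen` | 10 | minimum whole element (nt) |
| `maxGeneDistance` | 200 | maximum upstream-gene gap (nt) |
| `stopProximity` | 15 | group-1 stop-codon distance (nt) |
| `eGC`, `eAT`, `eGT` | −2.3, −0.9, +1.3 | pair energies (kcal/mol) |
| `mismatchPen`, `gapPen` | 3.5, 6.0 | penalties (kcal/mol) |
| `hairpinCutoff` | −0.2 | hairpin energy cutoff (kcal/mol) |
| `window`, `wT`, `wOther` | 15, 0.9, 0.6 | tail model |
| `tailCutoff` | −2.5 | RIT threshold |

The structural defaults are the values used for genome-wide scans of
annotated prokaryotic genomes; they were derived from the annotated
REP complement of *E. coli* and we do not re-derive them here.
`maxSpan` is measured as the outer span of the seed pair by default
(`spanMode = "outer"`); measuring between start positions is available
as `spanMode = "start"`. The "palindrome length" bounds apply to the
stem *arm*, not the whole element: only this reading is consistent
with whole elements up to ~70 nt under a 32-nt bound.

# The synthetic study fixture

Real assemblies are too large to ship and genome-wide truth does not
exist, so validation uses `makeGenome()` + `implantElements()`: an
i.i.d. background chromosome (100 kb, GC 0.5 by default) with anchor
genes laid out at bacterial-scale intergenic gaps (220 nt) and one
implanted element per gap at a controlled distance (20–150 nt, or an
exact `stopGap`) from its same-strand anchor gene. The standard
fixture implants 20 REPs (including one each at stop-codon gaps 15 and
16 nt, the group-1/group-2 boundary) and 10 RITs split across both
strands.

Implants are *clean* by construction, which is what makes recovery
insensitive to the choice of seed:

* perfect palindromic arms (`arm + loop + revcomp(arm)`), GC 0.8,
  with homopolymer runs capped at 4 nt and no internal
  reverse-complementary 4-mer pair (either feature would let the arm
  pair with chance background runs and seed a competing hairpin);
* an all-A loop and non-pairing single-base flanks, so extension stops
  exactly at the designed arms in both orientations;
* a 15-nt downstream context free of T for REPs (tail score at worst
  −1.5, always above the −2.5 RIT cutoff) and a 12-T tail for RITs
  (score ≈ −6.6, always below it);
* a 15-nt upstream context free of A, so the opposite-orientation scan
  cannot see a spurious T-rich tail either.

What the fixture does *not* emulate: real genomes have skewed
composition, repeat families, operon structure and overlapping signal;
random background still produces genuine chance palindromes, so
fixture runs have near-perfect recall but precision well below 1 —
exactly as an exhaustive structural scanner should behave. (Very
rarely a chance background palindrome overlapping an implant forms a
stronger hairpin and wins the deduplication; recall per kind stays at
or above 95% in every seed we have examined, and kind accuracy stays
at 100% by construction of the contexts.) Passing the fixture
therefore demonstrates correctness of the machinery (seeding,
extension, energies, classification, annotation arithmetic), not
genome-wide accuracy on real data.

The worked fixture run in the test suite (30 implants, seeds fixed)
recovers 100% of both kinds with 100% kind accuracy; the numbers for
any seed are reproduced by `scripts/acceptance.R`.

# Numerical choices and degenerate inputs

* All energy constants have one decimal digit; sums are computed in
  double precision and compared inclusively, which is bit-stable at
  these magnitudes.
* The loop penalty is applied literally even for loops of 0–2 nt
  (where it is zero or negative); admissibility is the job of the
  structural filters, not of the energy term.
* The stem-to-loop ratio uses `max(loopLen, 1)` so zero-loop hairpins
  are well-defined.
* Tails truncated by a region edge are scored as-is; an empty tail
  scores 0 (REP).
* Ambiguity codes other than N are normalized to N on input; N never
  seeds, never pairs (counts as mismatch if reached), and takes the
  non-T tail weight.
* Sequences shorter than the k-mer, regions shorter than the minimum
  element, empty gene sets and fully genic records all yield empty —
  not error — results; the three writers emit a header-only TSV and
  empty BED/FASTA in that case.
* Identical inputs give byte-identical outputs; candidate order is the
  total order (seq_id, start, end, strand).

# Design decisions taken where the method description is open

* **Seed span.** The 50-nt seed distance threshold is measured as the
  outer span of the seed pair, which bounds total element size
  consistently; the start-to-start alternative is exposed but not
  default.
* **Extension strictness.** Internal mismatches do not extend a stem;
  mismatch pricing enters only through assembly bulges. This is the
  literal reading of "extend until a mismatch".
* **Wobble.** G·T is accepted during extension because the energy
  model prices it; seeds remain exact reverse complements for speed
  and determinism.
* **Gene space.** Genes on both strands block intergenic space, and
  chromosomes are treated as linear (no origin wrap-around); window
  densities use the same linear partition. The feature class defining
  genic space is a parameter (default `gene`, falling back to `CDS`
  when a GFF has no gene rows).
* **Upstream distance.** The gene-distance bound applies to the gap
  between a candidate and its forward-axis upstream gene; one knob,
  200 nt by default, 6,200 nt for full-genome reproduction runs.
* **Motif similarity input.** The motif-group similarity module
  consumes a pairwise count table (`group_a, group_b, na, nb, nab`)
  produced by external motif discovery/comparison tools; motif
  discovery itself is out of scope here. Each motif is counted once
  per group (unique motifs), the diagonal is fixed at 0.5 by
  convention and excluded from per-group match totals.

# Problem sizes used in the test suite

Unit tests run on 20-kb fixtures with 6 implants; the end-to-end
recovery check uses the standard 100-kb, 30-implant fixture; the
seed-oracle property check compares against a brute-force double loop
on 200 random sequences up to 2 kb. These sizes keep the whole suite
in the low minutes on a single CPU while exercising every code path.
Genome-scale runs (megabase assemblies, `maxGeneDistance = 6200`) use
exactly the same code path via `regressionCheck()`, which the user
points at a locally downloaded assembly; published genome-wide totals
depend on unstated extension/assembly/deduplication details of other
implementations, so agreement there is expected to be approximate
(the deduplication policy above is the declared deviation).

# Known limitations

* The energy model is additive per pair, not nearest-neighbour
  thermodynamics; it ranks hairpins the way the classification needs,
  but the absolute kcal/mol values are heuristic.
* The tail equation is a reconstruction (see above).
* No partial/background terminator confidence model: classification is
  a single threshold.
* Circularity is ignored; elements spanning the origin are missed.
* `N`-rich assemblies lose seeding density; heavily fragmented drafts
  will under-report elements near contig edges unless
  `keepEdge = TRUE`.
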