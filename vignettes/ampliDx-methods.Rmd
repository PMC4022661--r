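---
title: "Methods: tiled-amplicon variant calling and exon-level aCGH in ampliDx"
author: "ampliDx maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiled-amplicon variant calling and exon-level aCGH in ampliDx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(ampliDx)
  library(GenomicRanges)
})
```

## The assay this package models

ampliDx implements the computational core of a targeted germline
diagnostic assay built from two arms:

* **Tiled-amplicon sequencing** of the coding exons (plus a small
  intronic flank) of a six-gene high-risk breast-cancer panel, for
  nucleotide substitutions and small insertions/deletions, including
  low-level mosaic variants.
* **Exon-resolution array CGH**, for gross deletions and duplications
  that short amplicons cannot see.

Both arms are implemented end to end on synthetic data: the package
ships generators for the mini-genome, the tiled panel, sequencing reads
with injected variants, and probe log2-ratio tracks with injected
copy-number events — each with recorded ground truth, so every claim the
test suite makes is checked against a known answer.

## Why primer trimming is the central computation

In PCR-based enrichment the primer is physically incorporated into every
product. Read bases over a primer footprint therefore report the
*primer* sequence — the reference allele — regardless of what the
sample carries under the primer. Two consequences drive the design:

1. **Dilution.** Where amplicons overlap, a variant inside amplicon B's
   insert can lie under amplicon A's primer. A's reads flood the pileup
   with reference bases at that position, diluting the observed allele
   fraction (in the motivating assay, from an expected ~50% down to
   ~11% for one causative insertion). The fix is to *soft-clip* every
   read base whose reference placement falls inside its own amplicon's
   primer footprints, reconstructing the alignment start, so the pileup
   at a footprint position only sees inserts of *other* amplicons. On a
   noise-free two-amplicon fixture the closed forms
   `v/(d_A + d_B)` (untrimmed) and `v/d_B` (trimmed) hold exactly, and
   the bundled worked example reproduces the 11% → 44% lift.
2. **Allele drop-out.** A polymorphism under a primer can abolish
   amplification of that haplotype. A single-amplicon design then
   silently loses any variant on the same haplotype. The simulator
   models this with an allele-specific yield factor (default 0,
   complete drop-out; the worst case depicted in the source assay's
   redundancy argument), and the tiling generator places two staggered
   passes of amplicons so that interior target bases lie in at least
   two inserts. The acceptance suite shows the same variant being
   missed on a single-amplicon design and called on the tiled one.

The simulator states explicitly what the assay description only
implies: primer-footprint bases in a read always carry the primer
(reference) sequence, never the sample allele. This is the mechanism
that makes both phenomena reproducible in silico.

## Read model and alignment

Reads are assigned to amplicons by their primer prefix (exact-match
dictionary with a Hamming-distance rescue, tolerance 2 by default, ties
broken by fewest mismatches then amplicon id). Assigned reads are
aligned to their amplicon's reference span with a banded
Needleman–Wunsch, anchored at the primer end the read starts from, with
affine gap costs (match +1, mismatch −1, gap open −3, extend −1). The
affine penalty is what keeps a single 4-bp insertion from being split
into equal-scoring scattered gaps under a linear penalty; indels are
afterwards normalized to their left-most equivalent placement, so a
duplication-style insertion is keyed reproducibly. The adapter tail is
appended to the alignment window so read-through into the adapter
aligns exactly and is then converted to terminal soft clips rather than
spurious insertions. The aligner is authored here (the original
pipeline's external mapper is out of scope); in the tests an
independent dynamic-programming aligner cross-checks its scores.

Coordinates are handled as 1-based closed `GRanges`/`IRanges`
throughout, the Bioconductor convention, which supplies the interval
algebra (merging, overlap, coverage) used by the panel model. On disk,
BED remains 0-based half-open and VCF 1-based.

## Variant calling and the clinical filter chain

The pileup counts only non-soft-clipped bases with Phred quality ≥ 20;
column depth is the sum of its allele counts (deletion spans count as a
deletion allele; insertions key to their left-flanking column; indel
events are keyed by their left-normalized span). The "quality ≥ 20"
rule is applied at the *base* level — the testable reading of a filter
that is coupled to an allele-count threshold — and variant-level
quality is reported as mean alt base quality but not thresholded.

Calls follow the assay's clinical thresholds, all exposed in
`filterConfig()`:

| parameter | default | meaning |
|---|---|---|
| `minBaseQual` | 20 | Phred floor for pileup counting |
| `minAltReads` | 50 | supporting reads needed to emit a call |
| `lowCovThreshold` | 50 | bases at ≤ this depth are flagged for orthogonal sequencing (inclusive) |
| `lowRatioCutoff` | 0.2 | allele ratios below this go to a review tier |
| `polymorphismFreqCutoff` | 0.01 | population frequency at which unprotected variants are filtered |

Two deliberate softenings mirror clinical practice: calls under the
0.2 ratio are *tiered for review*, not discarded — true mosaics (the
bundled 14.9% @ 7,439X case) and trimming-rescued calls live there —
and variants on the `protectedVariants` list (known causative
mutations) are emitted even when they fail thresholds, including
outside the reportable range. The population-frequency cutoff default
(0.01) is a package choice; the assay names its frequency sources but
no numeric value.

The reportable range is the union of coding exons extended by a 5-base
intronic flank (configurable). The 50-bp flank used when *designing*
amplicon tilings is a separate parameter of the fixtures — the two
flanks serve different purposes and are kept distinct.

## aCGH arm

Probe tracks are processed as: noise estimation → centralization →
optional GC regression → segmentation → fuzzy-zero pruning →
aberration filter.

* **Noise** is the derivative MAD: median absolute successive
  difference × 1/(√2·0.6745), robust to true events (each contributes
  only two jumps).
* **Centralization** shifts the kernel-density mode of the log2 values
  to zero; on a targeted track the copy-neutral state dominates, so the
  mode — unlike the mean — ignores sizeable aberrant fractions.
* **Segmentation** is a documented recursive scan: the interval
  maximizing `|mean(log2)|·√n / sd` is accepted when its score reaches
  the threshold (default 6.0) and the scan recurses into the flanks;
  adjacent same-sign segments merge. On tracks of ≤ 200 probes this is
  provably identical to exhaustively scoring all intervals and greedily
  accepting non-overlapping maxima, which is how the tests verify it.
  The threshold value 6.0 preserves the *interface* of the proprietary
  detection algorithm the assay used; no claim of equivalence to that
  implementation is made.
* **Fuzzy zero** removes long, faint segments: a segment is pruned when
  `|mean| < z·sd·(a + b/√n)` (defaults z = 3, a = 0.25, b = 1), a
  one-parameter-family model of long-range correlated noise that the
  per-probe sd underestimates. The constants are package choices — the
  original correction is unpublished — and are exposed in
  `acghConfig()`.
* **Aberration filter**: at least 4 probes, and mean log2 classified as
  high gain (> 0.6), gain (0.35–0.6), heterozygous deletion (−1 to
  −0.45) or homozygous loss (< −1).

The simulator's default het-deletion level is −0.7 rather than the
theoretical −1: observed single-copy losses sit well above −1 (the
assay's own filter places heterozygous deletions in the (−1, −0.45]
band), and −0.7 exercises the classification without straddling a
boundary. Probes are laid out at 13 per exon with intronic backbone
probes every 2.5 kb, matching the array's stated design; the two-channel
intensity stage is not modelled — log2 ratios are generated directly.

## Synthetic data: what it does and does not emulate

The generators are deterministic for a fixed seed (a single global seed
fans out to per-stage child seeds). They emulate: tiled redundant
amplicons with verbatim adapter tails, log-normal per-amplicon depth
(CV 0.3 by default; the real depth distribution is unpublished),
quality-dependent substitution errors (rate 10^(−Q/10), qualities drawn
from {12, 22, 32, 37} with weights {2, 8, 50, 40}%), het/hom/mosaic
zygosity with binomial allele sampling, under-primer polymorphisms with
configurable allele drop-out, read-through into adapter, and off-panel
decoy reads for the on-target metric.

They do **not** emulate PCR chimeras, polymerase slippage in long
homopolymers, strand bias, UMI/duplex structure, alignment ambiguity
from genome-wide repeats, or dye/wave artifacts on the array. Passing
tests therefore demonstrate the correctness of the *computations* —
trimming arithmetic, filter logic, segmentation — under the stated
error model, not robustness to every artifact class of real
instruments. Primer lengths (18 nt) and tiling overlap are package
choices; the source assay does not publish them.

## Problem sizes and numerical choices

The test and acceptance workloads are sized for a desk-scale run: the
trimming worked example uses 400 reads at one site, the mosaic case
7,439× at one site, the parameter-recovery sweep 200 simulated mosaics
at ~2,000× each, aCGH fixtures a few hundred probes, and oracle
equivalences cap at 200 probes where the exhaustive oracle is O(n²).
Cohort-scale figures (multi-sample mean depths, genome-scale FP counts)
are represented by their formulas computed from the published
tabulations, not re-simulated.

Degenerate inputs are defined behavior: empty exon lists, empty panels
and empty truth tables error or return typed empty results; a read
lying entirely within primer footprints is returned fully soft-clipped
and flagged unusable; deletions stranded against a clip are dropped;
insertions at a primer/insert boundary are retained with the insert
(conservative retention of sample-derived bases); amplicons outside the
110–199 bp design bounds warn rather than fail, since out-of-bounds
amplicons are a design smell, not a structural fault.

## Known limitations

* The variant caller is count-based; it has no genotype likelihood
  model and no multi-sample joint calling.
* Multi-nucleotide substitutions are emitted per-column; deletions are
  merged per left-normalized event, but adjacent distinct events are
  not phased.
* The segmentation stand-in shares only the score *interface* with the
  proprietary algorithm it replaces; boundary behavior on real arrays
  may differ.
* Pathogenicity is a lookup table; no classification logic is
  implemented.
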