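---
title: "Methods: circRNA discovery, quantification and classification on synthetic data"
author: "circlr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circRNA discovery, quantification and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model of the data

Circular RNAs (circRNAs) arise when the spliceosome joins a downstream
splice donor back to an upstream acceptor. The single sequence feature that
distinguishes a circRNA from its linear host is the backsplice junction
(BSJ): a non-colinear exon–exon junction whose read count proxies circRNA
abundance, while the two adjacent forward splice junctions (FSJs) proxy
linear host expression. `circlr` implements a desk-scale version of this
analysis — discovery of BSJs from RNase R-enriched reads, junction-contig
quantification, circular-to-linear ratios, negative-binomial differential
testing, and an SVM disease-state classifier — and pairs every stage with a
synthetic-data generator that knows the ground truth, so each claim the
pipeline makes can be checked against what was planted.

## The synthetic-data generator

`generate_genome()` lays non-overlapping multi-exon genes (default 3–6
exons of 150–350 nt, introns 200–600 nt) on random sequence with GC 0.5.
Introns carry canonical `GT..AG` dinucleotides in transcription
orientation, so splice-signal-aware detection behaves as on a real genome.
`plant_circrnas()` circularizes contiguous, *internal* exon windows:
backsplicing requires a downstream donor intron and an upstream acceptor
intron, so circles bounded by terminal exons are not generated by default
(`internal_only = FALSE` restores them for edge-case testing). Each circle
receives a circular-to-linear ratio drawn log-uniformly from
`clr_range = c(0.01, 0.2)` — circRNA steady-state levels are typically well
below 10% of host mRNA levels, and keeping the circular fraction of the
library small also keeps CPM compositional coupling (below) mild.

`simulate_library()` draws 150 nt paired-end fragments (mean insert
260 nt) from spliced linear transcripts and from circular sequences;
junction fragments wrap the backsplice, and circles shorter than the
fragment are read from a tandem concatenation. Two depth modes exist:
an integer `depth` draws exactly that many fragments (multinomially over
sources), while `depth = NULL` draws Poisson counts around each source's
expectation so that absolute calibrations hold — `fsj_coverage` fragments
over each linear junction window and `copies.<state>` BSJ-spanning
fragments per circle, with
`copies = CLR × (fsj_coverage + 1) × state_multiplier`. This makes the
measured CLR = #BSJ/(mean(#FSJ)+1) recover the planted value in
expectation, and a `state_multiplier` of 2.8 plants a global
circularization increase with unchanged linear output. RNase R treatment is
a uniform linear survival probability (default 0.02) with circular
fragments untouched; libraries are unstranded (each fragment's orientation
randomized); sequencing errors are substitutions only. The generator does
not model GC or positional bias, PCR duplicates, indels, length-dependent
RNase R escape, or rRNA carry-over — so green tests certify the logic of
the pipeline under its stated assumptions, not robustness to every artifact
of real libraries.

## Discovery

Both detectors share one anchor scan. A mate that places colinearly on the
genome (exact 20 nt anchor seed, extension with ≤ 2 substitutions over its
full length) is ignored. Otherwise its terminal 20 nt anchors are looked up
exactly; when the 3′ anchor lands upstream of the 5′ anchor on one
chromosome, the two alignments are extended toward each other and the
breakpoint with the fewest total mismatches is taken. Equal-mismatch ties
prefer breakpoints within ±2 nt of annotated exon boundaries, then those
flanked by `GT..AG` in transcription orientation, then the leftmost; a mate
whose different anchor placements support distinct breakpoints is dropped
as ambiguous and tallied. The anchor-mode detector requires the splice
signal; the annotation-guided detector instead snaps breakpoints to the
nearest exon start/end within ±2 nt and drops what cannot be snapped.
Candidates are filtered to junctions lying inside exactly one gene, with
genomic distance in [50 nt, 100 kb] and at least 2 supporting fragments,
and the per-detector catalogs are merged by coordinate union (support
summed, provenance concatenated). Internally all coordinates are 0-based
half-open; reports are 1-based inclusive `chr:start-end`.

Anchor length 20 nt is the classical default for this family of detectors
and is long enough to be effectively unique on the simulated genome sizes
(0.35–2 Mb). The minimum support of 2 mirrors the identification cutoff of
≥ 2 reads per BSJ.

## Quantification

For every catalog entry a junction contig is built from 100 nt of genomic
sequence on each side of the backsplice (for circles shorter than 200 nt,
halves of ⌊len/2⌋ so no base is duplicated); one contig per annotated
linear junction represents spliced linear alignment across that FSJ. Mates
are placed on genome + contigs by the same seeded extension, multimaps
retained, and placements hanging over a contig end are clipped. Each
placement is additionally trimmed to its maximal-scoring contiguous stretch
(match +1, mismatch −3), emulating an aligner's soft-clipping so that
chance-matching overhangs cannot manufacture junction coverage.

A fragment (read pair) counts once for a junction when either mate covers
at least 8 nt of the 10 nt window centred on it (5 nt each side — the
symmetric centring is the only one consistent with a single stated window).
The robust-expression filter keeps circRNAs with ≥ 2 fragments in ≥ 3
replicates of ≥ 1 time point. CLR = #BSJ/(mean(#FSJ)+1), where the mean
runs over the *available* adjacent FSJs: a circle bounded by a terminal
exon contributes one value, and zero junctions leave the denominator at 1 —
treating absent junctions as zero would bias CLR upward systematically.
CPM normalizes by total placed fragments per sample (configurable, since
the denominator convention is a choice); cumulative circularization is the
per-replicate sum of CPM-normalized BSJ counts, diversity the number of
distinct expressed species (raw count ≥ 1), and the normalized load their
ratio.

**Junction ambiguity.** On a compact genome, a linear junction whose donor
or acceptor flank shares a few terminal bases with the backsplice produces
forward-splice reads that align across the BSJ window within the mismatch
tolerance; any window-counting scheme then books linear reads as circular.
`flag_ambiguous_junctions()` detects this by constructing, for every
linear junction of the host gene, the junction-crossing read it would
produce, aligning it to the backsplice contig with the same local-trimming
rule the placement step uses, and flagging the circRNA when that mimic
read reaches 8 nt of window overlap within the mismatch budget — the
criterion is exactly the counting rule, so whatever would be miscounted
is flagged. Load and CLR statistics exclude flagged circRNAs. On real
genomes the same ambiguity exists but is diluted by exon diversity; at
desk scale a few loci in sixty are affected and would otherwise dominate
the cumulative statistics.

**Compositional note.** CPM is a proportion, so planting a 2.8-fold
circular increase with constant linear output yields a cumulative-CPM ratio
slightly below 2.8 (the library grows). With the default circular fraction
(≲ 5% of fragments) the deflection is a few percent and the planted ratio
is recovered within the stated 15% band; the FSJ-based ratio deflects by
the same factor below 1.

## Differential testing

Size factors are median-of-ratios over features positive in every sample
(total-count fallback with a warning). Dispersion is per-feature method of
moments on normalized counts, α = max((var − mean)/mean², 10⁻⁸) — a
deliberate simplification with no cross-feature shrinkage and no
independent filtering: the reproducible content is the thresholds and test
construction, not the refinements of a production DE engine. The Wald test
compares group means of normalized counts, with log2FC given a 0.5
pseudocount only when a group mean is zero, the standard error from the NB
variance μ + αμ² via the delta method, and a two-sided normal reference.
On 2,000 null NB features (α = 0.1, 5 vs 5) the empirical false-positive
rate at p < 0.05 sits in [0.03, 0.07]. BH adjustment is the step-up
procedure with NAs excluded from the family size.

The CLR contrast has no canonical test construction, so it is a label
permutation test on the difference of group means of log2(CLR + 0.01):
exact enumeration when the arrangement count is ≤ 10,000, otherwise
sampled permutations with the +1 correction; fewer than 20 arrangements
yields NA rather than a meaninglessly coarse p-value. Expression calls use
|log2FC| > 1 and adjusted P < 0.05; CLR calls use |log2FC| > 0.1 and
adjusted P < 0.2.

## Classification

Features passing the DE cuts are ranked twice: by information gain
(exhaustive single-threshold binarization of each feature, in bits —
deterministic and dependency-free, in place of MDL-style discretization)
and by mean-decrease-in-impurity importance from a seeded random forest
(500 trees, √p feature subsampling, bootstrap resampling). The two ranks
are combined by rank sum, ties broken by the information-gain rank and then
the feature id, giving a total order. The SVM is tuned over cost
{0.1, 1, 10, 100}, gamma {0.001, 0.01, 0.1, 1}, kernels
{linear, radial, polynomial} and degree {2, 3} by stratified inner-CV AUC,
refit with sigmoid probability calibration, and evaluated by pairwise-
concordance AUC (ties ½) with stratified, seeded 10-fold cross-validation
pooling out-of-fold probabilities. Standardization statistics and feature
selection are computed on training folds only; the test suite verifies with
a recording learner that no test row ever reaches training.

## Reference problem sizes

The property checks run at the sizes the package treats as its reference
conditions: discovery on a 2 Mb genome with 100 genes and 60 planted
circRNAs (error-free RNase R reads, ≥ 15 expected junction fragments per
circle); the global-increase analysis on 100 genes at linear junction
coverage 40 with 3 replicates per state; DE calibration on 2,000 features;
classification cohorts of 40–100 samples with 500 features. Counting, CLR,
BH and AUC are checked exactly against brute-force enumerations.

## Known limitations

Multi-split reads (a mate spanning two FSJs and the BSJ simultaneously)
are not realigned and simply remain unplaced; the discovery scan handles
substitutions but not indels; host-transcript abundance for the coherence
analysis is proxied by FSJ counts rather than assembled transcripts; the
NB test's plug-in dispersion is noisy below ~5 replicates per group and is
not shrunk; and the permutation CLR test's resolution is bounded by the
arrangement count at small n. The classifier's null behaviour (CV AUC near
0.5) is the relevant guarantee for small cohorts; with tuned
hyperparameters the pooled null AUC is mildly below 0.5 on average, a known
property of selection by noisy inner-CV scores.
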