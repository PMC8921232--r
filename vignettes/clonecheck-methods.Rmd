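---
title: "Methods: coverage karyotyping, integration-site mapping, indel quantification and growth kinetics in clonecheck"
author: "clonecheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage karyotyping, integration-site mapping, indel quantification and growth kinetics in clonecheck}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecheck)
```

clonecheck implements the computational checks a lab runs to establish what
an immortalized cell line actually is: whether its chromosomes are present
at the expected copy numbers, whether it descends from a single
transduction event, whether CRISPR edits at a target locus took, and how
fast it grows. Each check is an ordinary estimator with a classed result
object; this vignette describes the models behind them, the tunable
parameters, and the choices made where the design was genuinely open.

## Coverage karyotyping and the MCN level

In a mosaic population, subclones carry different integer chromosome copy
numbers, so sequencing depth on a chromosome reflects the
*population-average* copy number — generally a non-integer. Binned read
depth is piled up per chromosome (`coverage_from_intervals()`, 0-based
half-open intervals, default bin 1000 bp: wide enough to smooth
read-length granularity, narrow enough to leave hundreds of bins per
chromosome). The mean-copy-number (MCN) coverage level is estimated as the
global mode of the pooled per-bin depth density across chromosomes
(`estimate_mcn()`): most chromosomal mass sits at the population-typical
copy number, so the mode tracks that level even when individual
chromosomes deviate. Each chromosome's own density mode
(`chromosome_peak()`) is then expressed as a percentage of the MCN and
classified `below`/`at`/`above` with a ±10% "at" band
(`classify_copy_state()`); the 0.5× and 1.5× levels are reference
annotations, not thresholds.

Numerical choices:

* Densities are Gaussian KDEs with Silverman's rule-of-thumb bandwidth and
  a configurable override. `bw.nrd0` degenerates to `abs(x[1])` on
  zero-spread input, so constant tracks fall back to a narrow kernel
  (0.1% of the level) and peak at their own value. Densities are
  renormalized by trapezoid integration so they integrate to 1 exactly.
* Zero-depth bins are excluded from MCN pooling — they encode unsequenced
  or absent sequence (an absent W chromosome would otherwise drag the
  pooled density) — but are kept in per-chromosome histograms, where an
  all-zero chromosome legitimately peaks at 0.
* Chromosomes with fewer than 50 bins are flagged low-confidence: mode
  estimation on few bins is unstable (the microchromosome situation).
* `est_avg_copies = ratio/100 × baseline_ploidy` assumes the MCN level
  corresponds to `baseline_ploidy` copies. In a heavily aneuploid line
  the MCN need not represent a diploid pair, so the column is an
  assumption-dependent estimate, not a measurement.

A mode estimate on binned coverage has appreciable sampling noise:
neighboring bins are correlated over a read length, so a 1 Mb chromosome
at 1 kb bins contributes far fewer effectively independent depth values
than its bin count. At the scale the test-suite simulations use
(six 1 Mb chromosomes, 10× per copy, ~8 kb reads) the pooled-mode MCN is
reproducible to a few percent, and per-chromosome average-copy estimates
to roughly ±0.2–0.3 copies; precision grows with chromosome length and
depth. Sex inference (`infer_sex()`) needs only coarse ratios: ZZ requires
the W below 10% of MCN with the Z at the MCN, ZW requires both Z and W
near 50%; anything else is `ambiguous` rather than forced into a call.

## Integration-site mapping

A single-copy proviral insertion is detectable as reads that contain
vector sequence flanked by genomic sequence. `find_vector_reads()` calls a
read a hit when it shares at least `min_kmers = 5` distinct k-mers
(k = 21, either strand) with the vector; the match span is the minimal
seed cover with ungapped extension, and orientation is the majority seed
strand. Reverse-orientation hits are normalized before flank mapping, so
calls are invariant under reverse-complementing the input.

Flanks are anchored by unique-k-mer voting (`map_flank()`): every flank
k-mer that occurs exactly once in the reference implies a junction
coordinate, and the modal coordinate wins if it has at least
`min_votes = 5` votes and twice the runner-up. Only reference-unique
k-mers vote, so repetitive or heavily corrupted flanks go honestly
unplaced instead of mis-anchoring. The junction is defined as the
reference base immediately 3′ of the left flank; when both flanks anchor
but disagree by more than `cluster_window` (500 bp) the hit is counted
unplaced. Junctions cluster by running median (`call_insertions()`), and
the accounting identity `sum(support) + unplaced = hits` always holds.

k = 21 and the vote thresholds are sized for desk-scale genomes at
long-read error rates: with ~1–2% substitution error a 1 kb flank yields
hundreds of intact 21-mers, while random sequence essentially never
produces five agreeing unique hits. Ungapped extension can stop a few
bases early when an error sits near the vector/genome boundary, which
shifts a single read's implied junction by a few bp; the cluster median
across reads absorbs this.

## Amplicon indel quantification

The cut site is derived from the guide (`amplicon_ref()`): the
protospacer followed by its PAM (IUPAC-aware, default `NNGRRT` for
SaCas9) must occur exactly once in the amplicon on either strand, and the
blunt cut falls `cut_offset = -3` bp from the PAM-proximal protospacer
end, mirrored on the reverse strand.

Each read is aligned globally to the amplicon with an affine-gap
Needleman–Wunsch/Gotoh core (`align_global()`; a gap of length L scores
`gap_open + L·gap_extend`). The default scoring (+2/−4, −10/−1) strongly
prefers one long gap over scattered mismatches, which is what indel
typing needs. Tie-breaking is fully deterministic — deletion over
insertion over diagonal, gap extension over re-opening — and gap runs are
left-shifted to the conventional left-aligned placement. The
implementation is validated two ways: against exhaustive enumeration of
all alignments on tiny instances, and against an independent aligner on
longer constructed cases.

A read counts as modified when an indel run overlaps the window
`[cut − w, cut + w]` (`quantify_edits()`, default w = 1). An indel inside
a repeat has no unique position — every placement in its equivalence
range scores identically — so the overlap test uses the whole range, not
just the left-aligned placement; otherwise a cut-site deletion in a
homopolymer would slide out of a narrow window and be missed.
Substitutions never count by default (the assay quantifies indel
formation; sequencing substitutions would inflate it), with an opt-in
flag. Since most real indels fall within ~15 bp of the cut, w = 15 is the
suggested wide-window setting for dispersed-indel review. Reads identical
to the reference skip alignment entirely, which makes low-editing
datasets cheap.

Clone classification (`classify_clone()`) is a fixed three-way rule on
inferred allele percentages: no wildtype contribution → complete
knockout; otherwise 25–99% edited → incomplete knockout; under 25% →
unedited/ambiguous. The 25 and 99 boundaries are inclusive on the
incomplete side, and a clone with >99% edited but residual wildtype is
still incomplete — total knockout requires zero wildtype, not merely high
editing.

## Growth kinetics

The doubling time between two timed counts is
`g = (T₂ − T₁)·log 2 / (log N₂ − log N₁)` (`interval_doubling()`; the log
ratio is base-invariant). Log phase is operationalized as the three
consecutive intervals with the steepest summed slope of log mean count
versus time (`log_phase_window()`), ties broken earliest; the reported
estimate (`mean_doubling_time()`) is the arithmetic mean of the
per-interval doubling times over that window, computed on per-time
replicate mean counts. A declining series passes through as a
warning-flagged negative estimate rather than an error, and
`compare_doubling()` wraps a two-tailed t-test on per-interval g values
for passage-to-passage comparisons.

## What the synthetic-data module emulates

`make_genome()` draws i.i.d. bases at a target GC; `simulate_population_reads()`
samples reads per chromosome at a rate proportional to the
population-average copy number with lognormal read lengths (heavy-tailed,
long-read-like; default mean 8 kb, sdlog 0.5), uniform expected depth
across each chromosome, substitution-only errors, and an optional
proviral insertion spliced into carrier reads at the target coordinate
(truth placements keep pre-insertion reference coordinates).
`simulate_amplicon_reads()` plants exactly one indel per edited read at
the cut (deletions centered on it, insertions of random bases), and
`simulate_growth_counts()` produces exponential counts with mean-1
multiplicative lognormal noise of a stated CV. Every generator is
deterministic given its seed.

Deliberate simplifications, and hence what passing tests do *not* show
about real data: no indel sequencing errors (real long-read errors are
indel-rich, which degrades k-mer anchoring more than substitutions do),
no coverage bias with GC or mappability, no within-chromosome segmental
aneuploidy, no chimeric or quality-degraded reads, no PCR artifacts in
amplicons, and no confluence effects in growth. The generators establish
that the estimators are correct and well-calibrated under their stated
models — performance on real libraries still depends on upstream read
quality and mapping.

## Problem sizes and defaults used in the test suite

The packaged checks run simulations sized for quick, reproducible desk
verification: six 1 Mb chromosomes at 10× per copy for copy-state
recovery; 500 kb chromosomes for sex inference; a 115-read
insertion scenario with four deliberately unmappable flanks; amplicon
sets of 20,000 reads at edited fractions spanning 0.001–0.9; and
seven-point growth curves. These sizes were chosen so that each
stochastic check sits comfortably inside its statistical tolerance
(binomial standard errors for edited fractions, ±0.25 copies for
copy-state recovery at ≥500 bins) while remaining fast enough to re-run
habitually.
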