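---
title: "Models and methods behind osseqtools"
author: "osseqtools maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind osseqtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osseqtools)
```

# The assay this package models

In-solution OS-Seq (Oligonucleotide-Selective Sequencing) is a targeted
sequencing strategy built for clinical material of low quality and quantity,
notably FFPE-derived DNA. Input DNA sheared to roughly 550 bp is repaired by
*excision only* — damaged bases such as deaminated cytosines are removed
without a corrective fill-in — then fully denatured, and a sequencing
adapter is ligated to the single-stranded molecules. Target enrichment
happens in solution: pools of target-specific *primer-probes* anneal to the
adapter-ligated templates and are extended by polymerase toward the adapter,
completing the library. Read 1 therefore always starts with a probe at its
fixed genomic anchor, while Read 2 starts at the (random) adapter-ligated
fragment end.

osseqtools re-implements the computational layer of that assay as a
self-contained toolkit: panel design and scoring, an OS-Seq/FFPE read
simulator with truth provenance, probe-aware QC metrics, a minimal Bayesian
variant caller with benchmarking arithmetic, a read-depth copy-number caller
with iterative Thompson-Tau outlier detection, and ddPCR quantification
arithmetic. Everything runs on synthetic references; no external downloads
or aligners are required (simulator truth alignments substitute for an
aligner in all tests).

# Coordinate and insert conventions

All genomic intervals are 0-based, half-open (BED convention). A probe's
*anchor* is the 3'-most template position from which polymerase extension
proceeds: the rightmost footprint base for a plus-strand probe, the leftmost
for a minus-strand probe.

The *library insert* is the captured template between the probe's extension
start and the adapter-ligated fragment end, i.e.
`insert = |anchor − ligated end|`. Aligned Read 1 additionally contains the
synthetic probe bases, so on the QC side the insert of a tagged pair is the
R1-start..R2-end reference span minus the probe length; for an untagged pair
the raw span is used. This keeps the simulator truth and the QC metrics on
the same scale.

# Panel design

Probes tile **both strands** of every ROI at a target density of one probe
per 100 bp per strand (about one per 50 bp combined). Each tiling window is
filled greedily with the highest-scoring candidate; ties break to the
leftmost anchor and then the plus strand, so a design is bit-reproducible.
Windows with no candidate at or above `score_threshold` become explicit
coverage-gap records rather than silent holes.

The empirical candidate score is a weighted sum of eight components, each
normalized to [0, 1] before weighting (the scale is a package choice; a
perfect candidate scores `sum(weights)`):

* **tm** — nearest-neighbor melting temperature inside a window compatible
  with a common annealing temperature (default 58–66 °C). The model is the
  unified nearest-neighbor parameter set with terminal initiation terms, a
  `0.368·(N−1)·ln[Na+]` entropy salt correction and a `CT/4` oligo
  concentration term (defaults 50 mM Na+, 250 nM oligo).
* **gc** — GC fraction inside a window (default 0.30–0.70).
* **homopolymer** — runs longer than `max_homopolymer` (default 4 bp) are
  penalized linearly.
* **structure** — hairpin/self-dimer propensity, scored from the longest
  complementarity run terminating at the 3' end against the candidate
  itself.
* **snp** — a candidate overlapping a masked polymorphic position scores 0
  here (a SNP under a primer destabilizes annealing allele-specifically).
* **specificity** — the 3'-terminal k-mer (default k = 16) must be unique
  genome-wide (both strands); a k-mer seen `c` times scores `1/c`. Exact
  k-mer multiplicity, not alignment, keeps this desk-scale.
* **position** and **coverage** — the named-but-unspecified "relative target
  position" and "anticipated contribution to ROI coverage" notions are
  implemented as a distance-to-ROI-edge term and an
  uncovered-bases-gained term.

Pool-level cross-interactions are screened separately: any probe pair with a
3'-terminal complementarity run of `min_run` bases or more (default 6) is
flagged, symmetrically — the classic primer-dimer risk in a multiplexed
pool.

A note on the stated density: descriptions of the assay give both "one
primer per 70 bp on both strands" and "one per 100 bp on each strand", which
are mutually inconsistent (100 per strand implies 50 combined). The
per-strand figure (100) is used as the design target here; the discrepancy
is documented rather than resolved.

# The read simulator

The simulator follows the library architecture step by step, emitting a
truth record per read pair.

**Fragmentation.** Fragment lengths are `N(550, 50)` truncated at 100 bp.
Fragments are placed uniformly so they overlap a ROI; the sampling weight of
a gene's ROIs is multiplied by its copy ratio, which is how copy-number
events enter read space.

**Capture geometry.** Each single-stranded template is captured by a probe
of the matching orientation whose footprint lies inside the fragment.
Crucially, the site closest to the adapter is *not* always the site used:
the distance from the ligated end to the nearest eligible anchor is
uniform on (0, spacing) because anchors fall on a grid while fragment ends
are random, and the index of the site actually used beyond the nearest one
is Geometric(p) with p = 2/3, truncated to the sites the fragment contains.
With 100 bp spacing this gives a mean insert of
`E[U] + spacing·(1−p)/p ≈ 50 + 50 = 100 nt`, with observed inserts bounded
at 600 bp — matching the assay's observed insert distribution. The p = 2/3
default is the package's calibration of this published observation; the
assay description gives the observation, not the mechanism.

**FFPE damage.** Deamination converts template cytosines with a per-C,
per-strand probability. With `repair = "off"` the damaged base is read as
the C>T transition (G>A in plus coordinates when the minus strand was the
template). With `repair = "excision_on"` the uracil is removed by excision
only: synthesis terminates at the damaged site instead of emitting the
transition base, so the molecule shortens and no artifact base is ever
written — excision cannot restore sequence, and modeling it as a corrective
repair would be wrong. The probe part of each molecule is a pristine
synthetic oligo, so damage only affects the extension region. Published
work does not quantify per-sample deamination rates; the package defaults
are illustrative only. `single_strand_fraction` is carried as provenance of
the input state; it does not alter per-molecule damage sampling.

**Variants.** Each molecule overlapping a variant site carries the
alternate allele independently with probability equal to the VAF, so
observed allele fractions are exactly binomial at the fragment level. This
is why the bundled pileup counts *fragments* by default: mates of one pair
are not independent observations, and read-level counting would inflate the
binomial variance.

**Nuisance processes.** Sequencing errors are uniform per-base
substitutions (default 10^-3) with constant Q30 qualities; PCR duplicates
re-emit a pair sharing probe and fragment end; mispriming relocates a
capture to a random locus (the read still begins with the probe's synthetic
sequence). A misprimed molecule that happens to land back inside its
probe's ROI is labelled on-target in the truth — deliberately matching the
QC definition, since no observable distinguishes it from a correct capture.

# Read QC

Bases below the Phred floor (default 28, strict inequality) are masked to
`N` rather than trimmed, preserving pair coordinates. Read 1 prefixes are
matched against the probe metadata file to identify the generating probe;
ambiguous prefixes are excluded from on-target attribution. A pair is
on-target iff the probe is identified, the mate orientation is consistent
with the probe strand, the alignment falls within the probe's ROI enlarged
by its flank (default 50 bp), and the insert does not exceed 1.5 kb; the
first failed criterion is recorded. The on-target denominator is all
aligned pairs, ambiguous tags included (a documented choice).

Duplicates collapse on (probe id, fragment-end position, orientation) —
Read 1 starts are fixed by the probe in OS-Seq, so a conventional both-end
key would over-collapse; note that at high per-probe depth genuinely
independent molecules will collide on this key, so the marked duplicate
rate exceeds the generative PCR duplicate rate by design, exactly as with
standard duplicate-marking tools on amplicon-like libraries.

Coverage metrics are computed over ROI bases only, from on-target,
non-duplicate pairs. The **fold 80 base penalty** is the fold-change of
non-zero coverage needed to bring 80% of ROI bases to the observed mean:
`mean(non-zero coverage) / 20th percentile`, with the percentile taken as
the value at rank `ceiling(0.2·n)` of the ascending non-zero values (the
convention is documented because the metric's definition does not fix it).
Perfect uniformity gives exactly 1.

# Variant calling and benchmarking

The built-in caller is intentionally minimal — binomial read likelihoods
with a fixed error rate — and exists so the toolkit is testable end to end;
it is a non-equivalent stand-in for production germline/somatic callers.
Germline genotypes maximize the posterior over hom-ref/het/hom-alt with
Hardy-Weinberg priors. The somatic model is a two-node network: the tumor
inherits the normal genotype and may incur a de novo somatic mutation with
prior `somatic_prior` (default 10^-6); with no matched normal the germline
component is imputed from the germline allele-frequency prior alone, which
is how common SNPs at ~50% VAF in tumor-only data are labelled germline
rather than somatic. The exact factorization of the published network is
not specified beyond its structure; this implementation is a documented
interpretation. Reported somatic calls additionally require multiple read
support (default ≥ 2 alternate reads) above a 40X overall depth threshold.

Benchmarking restricts both callsets to the flanked ROI universe,
normalizes representations (trailing/leading trims with left-alignment
against the reference), and matches on position + alleles, ignoring
genotype (the squash-ploidy convention). Sensitivity and PPV are
percentages at one decimal. The true-negative universe is the number of
callable ROI bases minus truth positions; specificity defaults to the
as-printed formula TN/(TN+FN) — kept because it is stated verbatim in the
assay's description even though it is likely a typo for the conventional
TN/(TN+FP), which is available as an option; the choice is recorded in the
result.

The FFPE damage readout is the C>T/A>G ratio: the percentage of observed
SNVs that are C>T or G>A. Under identical seeds, repair-off simulations
must and do show a strictly higher ratio than repair-on.

# Copy-number calling

Depths per ROI are normalized by the sample's own median across all ROIs
(making overall yield cancel), log2 ratios are formed against the diploid
control per ROI and then aggregated per gene — the median of ROI ratios,
chosen for robustness to single-ROI artifacts where the original
description says only "at the ROI and then at the gene level". Gene ratios
are screened with the **iterative** Thompson-Tau test: at each step the
most deviant value among unflagged genes is flagged if
`|x − mean| / SD > tau`, with `tau = t·(n−1)/(√n·√(n−2+t²))` and `t` the
two-tailed α quantile (α = 0.01). Iteration is not optional: a 1.32×
event is invisible in a single pass when 4.9× and 2.25× events inflate the
SD, yet becomes unambiguous once the larger events are removed.
Amplifications and deletions are treated symmetrically by the two-tailed
test.

Degrees of freedom default to n−1 recomputed per iteration. A published
critical value of t = 2.629 at α = 0.01, df = 129 does not match the
standard two-tailed quantile (≈ 2.614); since the provenance of that
printed value is unknown, an explicit `t_critical` override is provided
rather than guessing intent. Gene-level testing is the default; ROI-level
testing is available behind the `level` flag because the source description
is ambiguous about which level is tested.

# Synthetic data: what it does and does not emulate

The generators reproduce the *designed* features of the study materials:
a 130-gene-panel-like ROI layout; somatic VAF ladders at 5/10/15/25/40%;
copy-ratio spikes at 4.90, 2.25 and 1.32 (log2 2.29, 1.17, 0.40) over
N(0, 0.05) gene-level noise; FFPE deamination with and without excision
repair; per-ROI negative-binomial depths with a shared log-normal
capture-efficiency bias (SD 0.3 on the log scale, a typical inter-ROI
spread for hybrid-capture panels).

They do **not** emulate GC-dependent coverage bias, indel sequencing
errors, optical/flow-cell artifacts, cfDNA fragment-size structure, or real
genome repeat structure (references are i.i.d. uniform sequence, which
makes k-mer specificity nearly always perfect). Passing tests therefore
demonstrate correctness of the algorithms under the stated models, not
performance on real libraries.

# Numerical choices and degenerate inputs

* All-zero coverage makes the fold 80 base penalty undefined: an error, not
  a sentinel.
* Median-zero depth vectors cannot be normalized: error.
* ROIs whose control depth is zero are masked (NA) from ratio analysis with
  a warning, not dropped silently.
* Thompson-Tau stops when SD collapses to 0 or fewer than 3 values remain.
* Zero-depth pileups produce no-calls rather than reference calls.
* Quality masking at the floor is a strict inequality: a base exactly at
  Phred 28 is retained.
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state, so library code never perturbs a session's
  randomness; derived stage seeds stay below 2^31.

# Problem sizes

The bundled tests run on references of 2–30 kb with 10^3–10^5 read pairs
and 60–130 simulated genes, sizes chosen so the full suite exercises every
code path, including the 100,000-pair insert-size experiment, in a few
minutes on a single core. All quantities scale linearly if larger
experiments are wanted.

```{r example, eval = FALSE}
# a complete miniature run
cfg <- run_config(seed = 4, n_genes = 8, n_pairs = 8000)
summary <- run_end_to_end(cfg, "osseq_demo")
str(summary$bench)
```
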