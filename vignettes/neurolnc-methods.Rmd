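---
title: "Methods: integrative lncRNA prioritization, CNV burden and ChIRP occupancy"
author: "neurolnc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative lncRNA prioritization, CNV burden and ChIRP occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurolnc)
```

# The analysis

`neurolnc` chains three independent lines of evidence to nominate long
non-coding RNAs (lncRNAs) with a plausible role in neuronal differentiation
and neurodevelopmental disease: dynamic behavior in a reprogramming
expression time course, physical association with chromatin, and
recurrent focal copy-number mutation in affected cohorts; ChIRP-seq
occupancy analysis then maps where a chosen lncRNA binds the genome and
which genes it may regulate. Each stage is an exported function with a
documented contract; `simulate_study()` generates a complete synthetic
study with planted ground truth so every stage can be exercised and
checked end to end.

All interval coordinates are 0-based half-open internally (BED
convention); GTF input/output is converted at the boundary. Overlap always
means at least one shared base pair.

# Candidate prioritization

## Dynamic-expression filter

`filter_dynamic_transcripts()` applies three filters to an FPKM matrix:

* **Abundance**: mean log2(FPKM + 0.1) across all samples ≥ 1. The 0.1
  pseudocount (FPKM units) keeps zero-expression transcripts finite; it is
  the same pseudocount used everywhere a ratio or log of FPKM is taken.
* **Fold change**: maximum pairwise ratio of pseudocounted timepoint means
  ≥ 2. Using timepoint means (not single samples) makes the statistic
  stable at 3 replicates.
* **Significance**: two-sided Welch t-test on log2(FPKM + 0.1) between the
  two timepoints attaining the maximal and minimal mean for that
  transcript, p < 0.05. We read "expression change during reprogramming"
  as the extreme-timepoint contrast; anchoring it at the per-transcript
  extremes keeps it well defined for non-monotone (transient) profiles and
  consistent with the fold statistic. In the noiseless limit the Welch
  standard error is zero and p is defined as 0 when the means differ and 1
  otherwise, so noiseless recovery is exact. With a single replicate per
  timepoint the test is disabled (flagged in the result) and only the
  abundance and fold filters apply.

## Chromatin association from H3 RIP

`chromatin_association()` declares a transcript chromatin associated when
its H3:IgG enrichment is **reproducible** — pseudocounted fold > 2 in
*every* replicate — and the pooled test is significant: a one-sided z-test
of the mean log2(H3/IgG) against zero at p < 0.05. Replicate counts in RIP
experiments (2–3) are too small for per-transcript variances, so the
replicate variance of the log-ratio is pooled across all transcripts; this
is the moderation idea used throughout small-sample genomics. Transcripts
with H3 = IgG = 0 have undefined enrichment: they are flagged and called
not associated. The output is binary, matching how such calls are
displayed in candidate heatmaps.

## Guilt-by-association co-expression

`correlate_and_binarize()` computes the Pearson correlation of every
(lncRNA, coding gene) pair across samples and binarizes at +0.5 / −0.5 to
calls in {+1, 0, −1}. The negative threshold is −0.5: symmetric thresholds
are the only coherent reading of the binarization. Zero-variance profiles
give undefined correlations; they are flagged and called 0.

`enrichment_matrix()` tests, for each lncRNA, its +1-correlated coding
genes against each gene set by the hypergeometric upper tail over the
coding universe, storing −log10 p clamped at 300 (so the matrix stays
finite). A lncRNA with no positive partners has an all-zero row.

`cluster_modules()` partitions lncRNAs into k = 3 modules by k-means on
enrichment rows scaled to unit L2 norm (so row magnitude does not dominate
profile shape), with a fixed seed and 50 restarts for determinism and
stability. Labels are reordered so module 1 is the module with the highest
mean enrichment over a designated term group (the neuronal terms);
clustering fails loudly when fewer than k distinct non-zero profiles
exist.

`nominate_candidates()` intersects the dynamic set with noncoding
biotypes and ranks lexicographically by (neuronal-module membership,
association call, fold change), all descending, with the transcript id as
a deterministic final tie-break.

# CNV burden

`burden_scan()` counts, per locus, *distinct subjects* (not events)
carrying ≥ 1 overlapping CNV in each cohort — burden cohorts are framed
per person, and one subject with two overlapping deletions is one
observation. Deletions and duplications are counted jointly (focal events
of both types are informative), with per-type sub-counts reported. Each
locus gets a two-sided Fisher exact p by the point-probability method
(the sum of the probabilities of all tables with fixed margins no more
probable than the observed one — R's convention, stated here because
two-sided exact conventions differ), a sample odds ratio with the
Haldane–Anscombe 0.5 correction when any cell is zero, and a
Benjamini–Hochberg q. Rank by ascending p is the primary output, mirroring
how morbidity-map hits are prioritized; q-values are reported for
multiple-testing hygiene. Cohort sizes default to the morbidity-map
cohorts (29,085 affected children, 19,584 controls) and are exposed as
arguments. `classify_focal()` labels a CNV focal when it overlaps the
locus and no coding-gene body.

# ChIRP occupancy

* `merge_even_odd()` — the concordance merge of the two probe-set tracks
  is the pointwise **minimum**, re-tiled into maximal constant steps:
  signal is only believed where both independent probe pools report it.
  The merge is commutative, idempotent and pointwise ≤ each input.
* `consensus_peaks()` — a peak from the designated reference replicate is
  kept iff it overlaps a peak in every other replicate; reference
  coordinates are kept (deterministic, no interval arithmetic surprises)
  and the −log10 p is the minimum across matched peaks (conservative).
* `high_confidence_filter()` — retains peaks with −log10 p **≥ 100**,
  even/odd Pearson correlation **> 0**, and mean merged coverage **>**
  the threshold (2 for mES-iN tracks, 1 for hNPC), with the inclusivities
  exactly as printed. The correlation is computed over the step-resolved
  grid of the two tracks restricted to the peak ("average coverage" is
  measured on the merged track); a peak resolving to fewer than two steps
  has undefined correlation and is dropped and flagged.
* `build_regulatory_domains()` — GREAT-style basal-plus-extension: basal =
  strand-aware [TSS − 5 kb, TSS + 1 kb); each side extends to the nearest
  neighboring basal boundary, at most 1000 kb, clipped to chromosome
  bounds. Extensions never invade a neighbor's basal region; basal regions
  themselves are assigned regardless of neighbors and may overlap. The
  implementation is closed-form and is checked in the test suite against a
  per-base brute-force oracle on random layouts.
* `assign_peaks_to_genes()` — any-overlap against domains (the quoted
  membership rule), so a peak straddling two domains maps to both genes.
* `annotate_peaks()` — exactly one of six categories per peak, testing the
  peak **midpoint** against strand-aware windows in priority order
  promoter (−2 kb..+1 kb of TSS) > enhancer (−10 kb..−2 kb) > exon >
  intron > gene tail (0..2 kb past the gene end) > intergenic. The
  midpoint rule is what makes the six-way partition exclusive; promoter
  wins the boundary base at −2 kb.
* `nearest_gene()` — closest TSS to the peak midpoint, ties broken by
  lexicographic gene id, distance signed strand-relatively.

# Permutation enrichment

`sample_random_peaks()` draws, per chromosome, the same number of peaks
with identical widths at uniform starts — matching the sampled peaks to
the observed ones in number and size, without claiming to preserve
spacing. An optional exclusion mask (e.g. assembly gaps) is available but
off by default, since the null is defined on the full chromosome unless
the user says otherwise. Each iteration's RNG substream is derived from
(seed, iteration), so results do not depend on execution order.

`permutation_overlap_enrichment()` compares the observed overlap of peaks
with each feature set against n_perm = 1000 such draws, at two levels:
peak level (number of peaks overlapping the feature set) and gene level
(number of distinct genes hit by both peaks and features, genes assigned
by nearest TSS for ChIP-style comparisons or by regulatory domains for
ChIRP-style gene sets). Empirical p uses the +1 convention
(1 + exceedances)/(1 + n_perm): it is never zero, and the calibration test
in the suite confirms near-uniformity under a null where features are
drawn by the same process as peaks. 2×2 overlaps can also be tested
directly with `chi_square_2x2()` (plain Pearson, no continuity correction
by default, as overlap chi-squares are conventionally reported),
`fisher_exact_2x2()` and `gene_set_overlap_test()`.

# The synthetic study

The generator's defaults are the study conditions the test suite runs
under, chosen once as a desk-scale emulation of the real design:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 10 Mb | smallest layout where 1000 kb extensions and Mb-scale CNVs behave non-trivially |
| genes | 150 coding + 120 lncRNA | ≥ 100 candidate loci for the burden scan; enough coding genes for modules and gene sets |
| time course | 5 timepoints × 3 replicates | typical reprogramming design |
| effect_fold | 4 | planted dynamic transcripts sit clearly above the 2-fold filter |
| noise_sd | 0.1 log2-FPKM units | low biological noise; log-normal on log2 FPKM matches the pipeline's log-scale filtering |
| CNV cohort | 500 cases / 500 controls, background rate 1/subject | scaled-down cohorts; lengths log-uniform in [10 kb, 2 Mb], spanning focal to large events |
| planted_case_hits | 30 | a recurrently mutated locus of realistic effect |
| ChIRP | 10 planted peaks + 30 decoys | one decoy class per filter criterion |

Three co-expression modules each tie 5 lncRNAs to 20 coding genes through
a shared latent log2 profile spanning exactly log2(effect_fold). The three
profiles are indicators of two-timepoint sets with pairwise intersection
one, which bounds the between-module correlation at (T−4)/(2T−4) < 0.5
for any T ≥ 3 — so binarization at |r| = 0.5 separates modules even in the
noiseless limit, and noiseless recovery of the planted candidate set is
exact rather than approximate. Module 1 is the neuronal module; its coding
members define the `NEURONAL_SYSTEM` gene set and the first ten of them
are the ChIRP target genes.

RIP assays give planted transcripts a log2 H3:IgG ratio of 2 plus a
folded-normal excursion, so the ratio is ≥ 4 in *every* replicate by
construction, while background ratios are centered at 1. The CNV simulator
plants focal events by sampling case CNVs inside the coding-gene-free
window around the focal locus, so planted events are focal by
construction and the generator fails loudly if the designated locus
overlaps a coding gene. ChIRP decoy peaks are built one violation at a
time: weak significance, anti-correlated even/odd profiles, sub-threshold
coverage, or high RNase signal. Because peaks are called against the RNase
control, an RNase-high region cannot attain −log10 p ≥ 100 in the calls;
the simulator therefore emits RNase-high decoys with weak significance
*and* genuinely elevated RNase track signal — that is how this violation
class manifests to a filter whose inputs are the peak calls and the
even/odd tracks.

Planted ChIRP peaks are placed inside the **basal** window of their target
gene. Since extensions never invade basal regions and the simulated gene
layout keeps basal windows disjoint (6 kb inter-gene margins), a peak in a
target's basal region maps to exactly that gene, which is what makes the
planted target-set recovery an exact (not approximate) check.

Everything is seeded: a configuration regenerates every file byte for
byte, which the suite asserts by md5. The truth sidecar
(`study.truth.json`) records every planted signal for programmatic
comparison.

**What the generator does not emulate**: read-level data (FASTQ,
alignment), fragment-level ChIRP chemistry, diploid genotypes,
GC/mappability biases, correlated noise between replicates, overdispersed
counts, and peak-calling internals (narrowPeak significance is assigned,
not computed from coverage). Passing tests therefore demonstrate the
correctness of the pipeline's logic and statistics under clean planted
signals — not robustness to the artifacts of real sequencing data.

# Numerical choices

* Pseudocount 0.1 FPKM before any ratio or log of expression values.
* −log10 p clamped at 300; empirical p never 0 by the +1 convention.
* Welch test degenerates gracefully at zero variance (p ∈ {0, 1}).
* Fisher two-sided p via point probability with R's relative tie
  tolerance; odds ratios use the 0.5 correction only when a cell is zero.
* k-means ties are controlled by a fixed seed and 50 restarts; candidate
  ranking breaks remaining ties by transcript id.
* Degenerate inputs fail loudly (zero margins, empty loci, k exceeding
  distinct profiles, genes off chromosome) or are flagged (zero-variance
  profiles, undefined RIP enrichment, single-step peaks).

# Problem sizes used by the checks

The suite verifies the exact tests against enumeration over all 2×2
tables with N ≤ 40; regulatory domains against a per-base oracle on 100
random layouts of up to 50 genes; the focal-locus rank across 50 seeded
cohort simulations; and permutation calibration over 200 trials × 200
permutations with 1000 peaks per trial — sizes chosen so each property is
exercised at meaningful scale while the whole suite stays quick on one
CPU.

# Limitations

The pipeline consumes peak calls and chromatin-state intervals; it does
not call peaks, fit chromatin-state models, score coding potential, or map
loci across species. The permutation null is uniform per chromosome —
no GC-, mappability- or gap-matched sampling (an exclusion mask hook is
provided). Gene-level enrichment inherits whichever assignment rule is
chosen; the two rules (nearest TSS vs regulatory domain) answer different
questions and are deliberately not mixed.
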