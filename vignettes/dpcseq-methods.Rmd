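---
title: "Models and methods behind dpcseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dpcseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcseq)
```

## The problem

DNA–protein crosslinks (DPCs) are bulky covalent adducts between chromosomal
DNA and cellular proteins, induced by formaldehyde and by crosslinking drugs.
Crosslink-enrichment sequencing ("DPC-seq") precipitates protein-linked DNA
fragments (200–500 bp after sonication) and sequences them under three
conditions: untreated control (**C**), immediately after a 2-h treatment
(**T**), and after a 5-h drug-free recovery (**R**). Comparing the three maps
answers two questions: *where do DPCs form*, and *where are they removed*.
The removal question is asked across repair genotypes — wild type, XPA
knockout (NER scaffold, both sub-pathways), XPC knockout (global-genome NER
sensor), CSB knockout (transcription-coupled NER initiator) — to dissect
which repair pathway acts where.

dpcseq implements the downstream computational analysis of such maps and a
seeded synthetic-data generator that emulates the biology, so every statistic
can be exercised and validated end to end without sequencing data.

## The analysis statistics

**Chromatin-state fold enrichment.** For a peak list and an 18-state
segmentation that partitions the genome,

$$\mathrm{FE}(s) = \frac{\text{overlap}(s, \text{peaks}) / \text{bases}(s)}
{\text{peak bases} / \text{genome bases}},$$

computed in base units on the merged peak set so double-covered bases count
once. FE = 1 means no enrichment; the state-base-weighted mean FE over a
covering segmentation is exactly 1 (tested). A state with zero bases is
reported as missing, never as zero. Conditions are compared per state with a
paired one-tailed t-test over replicates (formation: T > C; removal: R < T),
the direction always an explicit argument.

**Peak calling.** The established broad-peak callers build fragment models
and local background estimates; the contribution here is the enrichment
statistic, not the caller, so `call_broad_peaks()` is a deliberately simple
stand-in: flag bins at `min_fold` (default 2) times the background, merge
flagged runs closer than `merge_gap` (1 kb), drop runs shorter than
`min_width` (200 b). The background is a matched control track or, by
default in the pipeline, the track's own genome-wide mean — the synthetic
untreated track is far too sparse for a per-bin control (most bins are zero,
and dividing by it would flag every covered bin and compress enrichment to
~1; with the global-mean background the recovered T-condition enrichment
rank-correlates with the configured formation intensities at ρ ≈ 0.95).

**Coverage and metaprofiles.** Tracks are binned at 10 b and normalised to
counts per million mapped fragments (CPM); each fragment contributes over its
full insert. Genes are stratified by expression: Q0 = FPKM 0 (non-expressed),
Q1–Q4 = equal-size ascending rank groups of genes with FPKM ≥ 0.1. Genes
with 0 < FPKM < 0.1 fall below the threshold and are excluded, with an
explicit report; FPKM ties break by gene id for determinism. ("Quintile" is
the field's name for these five strata even though Q1–Q4 are quartiles of the
expressed genes.) TSS-centred matrices span ±20 kb by default, rows reversed
for minus-strand genes so columns run upstream → downstream; rows reaching a
chromosome edge are zero-padded and flagged. Genotypes are compared
position-wise by a paired one-tailed t-test on replicate-level stratum means
(direction: first genotype lower = more removal), reported as a −log10 p
curve.

**Repeat-locus RRE.** Repetitive loci (the rDNA arrays) cannot be quantified
through standard annotation, so reads are counted against a reconstructed
reference: one canonical repeat unit (13,357 b, the length of the 45S
pre-rRNA unit) plus 100 non-transcribed (Q0) and 100 highly transcribed (Q4)
control genes. Reads are hard-trimmed to their first 50 b (the least
error-prone part), and a trimmed read counts for a target only if it occurs
as an exact substring of the target or its reverse complement — equivalent
to zero-mismatch, gap-free alignment for uniform-length reads. Reads
matching targets in more than one group are discarded as ambiguous; matched +
ambiguous + unmatched always equals the total. The relative removal
efficiency is `RRE = count_T / count_R` per replicate, averaged; RRE ≈ 1
means no preferential removal. Raw counts are used (libraries are prepared
from equal DNA amounts); per-library depth scaling is available but off by
default. Reverse-complement matching is on by default because real libraries
are unstranded; it is switchable.

**qPCR percent removal.** A crosslink blocks amplification, so on
crosslink-enriched DNA, removal during recovery lowers the recovered-sample
signal: with ΔCt = Ct(recovered) − Ct(treated),

$$\text{percent removal} = \left[1 - 0.5^{\Delta Ct}\right] \times 100 .$$

Replicates with negative ΔCt are discarded per experiment and the discard
count always reported. Expression changes are quantified by the standard
2^−ΔΔCt fold change against a housekeeping gene. Summary statistics are mean
± SEM (n−1 denominator); the paired one-tailed t-statistic is computed from
the closed form with `stats::pt`, with a defined degenerate convention
(zero-variance differences: p = 1 if the mean difference is 0, else a
flagged p → 0 limit) that the stock implementation lacks.

## The synthetic-data generator

The generator's defaults *are* the study conditions; they are set once and
documented here.

* **Genome**: 4 chromosomes × 500 kb, segmented into 0.5–4 kb blocks
  labelled with the 18 chromatin states; 100 genes (20 per stratum) of 8 kb
  at regular spacing with alternating strand; stratum FPKMs drawn
  log-uniformly from non-overlapping decades (Q1 0.1–1 … Q4 100–1000), Q0
  exactly 0.
* **Formation**: C-condition fragments are uniform (Poisson, 0.5 per kb,
  state-independent — spontaneous DPCs are essentially uniformly
  distributed). T-condition fragments are Poisson per block at per-state
  intensities from 1 (quiescent) to 8 (bivalent TSS) per kb, highest for
  bivalent/Polycomb and strong-transcription states. The intensity scale is
  arbitrary — the assay reports relative enrichment, and no absolute DPC
  density per Mb is established — but the mean-state/baseline ratio (~8.9)
  is set above the >6-fold induction observed by gel quantitation, which the
  simulated T/C fragment-count ratio reproduces.
* **Removal**: the R condition is an *independent thinning of the paired T
  draw* (same derived seed, so R ⊆ T always). A fragment whose midpoint lies
  in a gene's body is deleted with probability
  `quintile_removal[genotype, stratum] × w(d)`, where `d` is the distance
  downstream of the TSS in transcription direction and `w` decays linearly
  from 1 at the TSS to 0 at 10 kb. The decay is the simplest monotone shape
  that makes the signal loss deepest at the TSS and tracking the direction
  of transcription; setting `tss_decay_bp = NULL` gives flat gene-body
  thinning (used by the binomial-oracle tests). Default fractions at the Q4
  stratum: WT 0.72, XPA-KO 0.40, XPC-KO 0.72, CSB-KO 0.10, calibrated to the
  locus-level qPCR phenotypes (72% vs 40% removal in WT vs XPA-KO; a
  substantially larger defect in CSB-KO; no defect in XPC-KO); baseline 0.10
  at Q0 for every genotype (non-transcribed removal is genotype-independent);
  Q1–Q3 interpolate linearly.
* **Repeat reads**: fixed-length reads (150 b) drawn from the canonical
  repeat and control panels with per-group abundances, either strand,
  uniform per-base substitution errors (default 0.001); the R library scales
  a group's abundance by 1 − removal. Since the mismatch filter hits T and R
  equally, the expected RRE under thinning is exactly 1/(1 − removal).
* **qPCR**: Ct(T) ~ Normal(25, σ); Ct(R) = Ct(T) − log2(1 − f) + Normal(0,
  σ) with σ = 0.15 cycles, so the forward transform returns 100·f exactly
  when σ = 0.
* **Seeding**: every (purpose, genotype, replicate, condition) tuple derives
  its own 31-bit stream seed from the master seed by a polynomial string
  hash, so any single output is reproducible in isolation and a full run is
  byte-identical under a fixed seed.

## What the generator does and does not emulate

It reproduces: state-dependent formation with uniform spontaneous background;
transcription-coupled, genotype-graded, TSS-anchored removal; repeat-locus
libraries with sequencing errors; Ct replicates with the discard-rule
pathology. It does **not** reproduce: sequence-composition biases, PCR
duplicates, diploidy, indels, mappability structure, or — importantly — the
correlation between gene positions and chromatin states. Genes are placed
independently of the segmentation, so removal (which is gene-anchored) is
visible in TSS metaprofiles and the RRE but *not* in per-state enrichment
differences between T and R; in real data, transcription states and
transcribed genes coincide, which is why the published state-level heatmaps
also show recovery-phase depletion in active states. Passing tests therefore
validate the statistics and their wiring, not read-level artefact handling.

## Numerical choices and edge cases

* Coordinates are 0-based half-open everywhere internally (BED-native);
  1-based external representations are converted at the boundary.
* Readers reject malformed input with the offending line number; they never
  silently repair. FASTA is read via `Biostrings::readBStringSet` and
  validated explicitly, because the DNA-specific reader silently drops
  invalid letter codes.
* Quintile boundaries: group sizes differ by at most one
  (`ceiling(rank · 4 / n)`); ties by gene id.
* Degenerate t-tests: see above. Empty strata and skipped rows produce
  messages, not silence. SEM is undefined (NA) at n = 1.
* Zero-variance signal vectors make a Spearman correlation undefined: the
  affected pairs are reported as missing, with a unit diagonal retained.
* RRE is undefined when any replicate has a zero R count: an error naming
  the replicate, not an Inf.
* The percent-removal discard rule truncates the noise distribution: at a
  true fraction of 0 with σ = 0.15 the retained-replicate mean is biased to
  ≈ +8 points. This is a property of the published rule, not of the
  implementation; recovery accuracy statements hold for fractions ≥ 0.5
  (mean within 5 points of truth in ≥ 95% of trials at n = 5) and the bias
  vanishes as the true ΔCt moves away from 0.

## Problem sizes

Simulation-backed checks run at the default 2 Mb genome (enrichment rank
recovery, stratum ordering over 10 seeds, genotype comparison) or on a
single 200-kb chromosome with 3-kb genes (round-trips, determinism); repeat
studies use ~1000 reads per group and 3 replicates, matching the replicate
structure of the sequencing experiments. These sizes keep every analysis in
seconds while leaving Monte-Carlo standard errors small enough for the
calibration checks (e.g. the null RRE test at 3 × 1000 reads has SE ≈ 0.03).

## Reproducing the analyses

The numbered drivers under `analysis/` run the whole study from one seed:
input generation (`01`), state enrichment with formation/removal tests
(`02`), TSS metaprofiles by stratum (`03`), WT vs XPA-KO comparison with
locus-level qPCR (`04`), and the repeat-locus RRE study (`05`). Each prints
what it found and writes its tables under `results/`.
`scripts/acceptance.R --seed N --out results/acceptance.json` recomputes the
headline quantities (null RRE, the transform limit, WT and XPA-KO percent
removal recovery) from scratch.
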