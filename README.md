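# dpcseq

Analysis of genome-wide DNA–protein crosslink (DPC) maps, with a seeded
synthetic-data generator for validation.

DPCs are bulky covalent adducts between chromosomal DNA and cellular
proteins, induced by reactive aldehydes (formaldehyde) and crosslinking
chemotherapeutics. Crosslink-enrichment sequencing ("DPC-seq") precipitates
protein-linked DNA fragments and sequences them under three conditions —
untreated control (C), immediately after treatment (T), after a drug-free
recovery (R) — across repair genotypes (WT, XPA-KO, XPC-KO, CSB-KO). dpcseq
implements the downstream statistics of such studies:

* **Chromatin-state fold enrichment** of peak lists:
  `FE(s) = (overlap(s, peaks)/bases(s)) / (peak bases/genome bases)`,
  with paired one-tailed t-tests per state for formation (T > C) and
  removal (R < T), plus a threshold/merge/min-width broad-peak stand-in
  caller and Spearman correlation of peak signals across tracks.
* **TSS metaprofiles by expression stratum**: CPM-normalised 10-bp coverage,
  strata Q0 (FPKM = 0) and Q1–Q4 (ascending rank groups of genes with
  FPKM ≥ 0.1), strand-oriented ±20 kb TSS matrices, per-stratum mean
  curves, and position-wise genotype comparison as a −log10 p curve.
* **Repeat-locus relative removal efficiency (RRE)**: reconstructed
  reference (canonical 13,357-b repeat unit + 100 Q0 + 100 Q4 control
  genes), 5′ hard-trim to 50 b, mismatch-free exact-substring counting on
  both strands, `RRE = count_T / count_R` averaged over replicates
  (RRE ≈ 1 ⇒ no preferential removal).
* **qPCR removal statistics**: percent DPC removal
  `[1 − 0.5^ΔCt] × 100` with the negative-ΔCt discard rule, 2^−ΔΔCt
  expression fold change, paired one-tailed t-tests, mean ± SEM.
* **Synthetic data**: a toy genome with an 18-state segmentation, Poisson
  state-dependent formation, transcription-coupled thinning removal graded
  by genotype and expression stratum, repeat-read libraries with
  substitution errors, and Ct replicates — all byte-reproducible from one
  seed.

## Worked example

Simulate a wild-type study and quantify transcription-coupled removal:

```r
library(dpcseq)

cfg    <- sim_config(seed = 1)             # 4 x 500 kb genome, 3 replicates
genome <- build_toy_genome(cfg)
strata <- assign_quintiles(genome$genes, seed = cfg$seed)

track_T <- merge_tracks(lapply(1:3, function(r)
  cpm_normalize(simulate_dpc_fragments(genome, cfg, "T", "WT", r))))
track_R <- merge_tracks(lapply(1:3, function(r)
  cpm_normalize(simulate_dpc_fragments(genome, cfg, "R", "WT", r))))

prof_T <- quintile_profiles(tss_matrix(track_T, genome$genes, 20000), strata)
prof_R <- quintile_profiles(tss_matrix(track_R, genome$genes, 20000), strata)
```

TSS-proximal (first kb) mean CPM by stratum, as printed by
`analysis/03_tss_metaprofiles.R` for this seed:

```
 stratum     cpm.R    cpm.T percent_loss
      Q0 193.23793 191.1596    -1.087197
      Q1 167.29357 190.1000    11.997084
      Q2 118.47180 158.4099    25.211854
      Q3 106.56960 196.8396    45.859671
      Q4  58.54481 177.3115    66.981943
```

Treated-condition signal is similar across strata (formation is
transcription-independent); after recovery the loss grades with expression,
deepest (~67%) at the most-expressed genes — the transcription-coupled
removal signature. The same seed's locus-level qPCR simulation
(`analysis/04_genotype_comparison.R`) recovers the genotype phenotypes:

```
 genotype true_percent mean_percent   sem n_retained n_discarded
       WT           72         71.3 1.751          5           0
   XPA_KO           40         35.2 2.816          5           0
   XPC_KO           72         72.6 0.591          5           0
   CSB_KO           10         13.2 3.521          5           0
```

and the repeat-locus study (`analysis/05_repeat_rre.R`) shows the repeat
behaving like the non-transcribed controls:

```
       group rre_mean rre_sem n
        rDNA    1.007 0.02387 3
 Q0_controls    0.969 0.00631 3
 Q4_controls    3.694 0.04498 3
```

The numbered scripts under `analysis/` run the full study
(`Rscript analysis/01_simulate_inputs.R`, … `05_repeat_rre.R`), each
printing its findings and writing tables under `results/`.

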