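#!/usr/bin/env Rscript
# Generate the study's synthetic inputs and write them in their native
# formats: chromatin-state segmentation (BED4), gene table (TSV), repeat
# reference (FASTA), one fragment set per condition/genotype/replicate
# (BED6), and example qPCR Ct tables (CSV).
#
# Everything downstream (02-05) regenerates what it needs from the same
# seeded configuration, so these files are a record of the inputs, not a
# dependency chain.

suppressPackageStartupMessages(library(dpcseq))

seed <- 1L
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
print(cfg)

genome <- build_toy_genome(cfg)
write_bed(setNames(genome$segmentation[, c("chrom", "start", "end", "state")],
                   c("chrom", "start", "end", "name")),
          file.path(out, "segmentation.bed"))
write_gene_table(genome$genes, file.path(out, "genes.tsv"))
write_fasta(genome$reference$sequences, file.path(out, "repeat_reference.fa"))

for (geno in c("WT", "XPA_KO")) {
  for (cond in c("C", "T", "R")) {
    for (r in seq_len(cfg$n_replicates)) {
      f <- simulate_dpc_fragments(genome, cfg, cond, geno, r)
      write_fragments_bed(f, file.path(
        out, sprintf("fragments_%s_%s_rep%d.bed", geno, cond, r)))
    }
  }
}

ct_wt <- simulate_qpcr_ct(default_quintile_removal()["WT", "Q4"],
                          n_replicates = 5, noise_sd = 0.15, seed = seed,
                          locus = "IL1B_like", genotype = "WT")
ct_xpa <- simulate_qpcr_ct(default_quintile_removal()["XPA_KO", "Q4"],
                           n_replicates = 5, noise_sd = 0.15, seed = seed,
                           locus = "IL1B_like", genotype = "XPA_KO")
write_ct_table(rbind(ct_wt, ct_xpa), file.path(out, "qpcr_ct.csv"))

cat(sprintf("inputs written to %s: %d files\n", out,
            length(list.files(out))))
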