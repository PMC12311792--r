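#!/usr/bin/env Rscript
# Chromatin-state fold enrichment of DPC peak lists across the C/T/R
# conditions, with paired one-tailed tests for formation (T > C) and removal
# (R < T) per state. The untreated condition should be near-uniform across
# states; the treated condition should be enriched in the states configured
# with high formation intensity; recovery should significantly deplete
# transcription-associated states.

suppressPackageStartupMessages(library(dpcseq))

seed <- 1L
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
res <- run_formation_removal_study(cfg, genotypes = c("WT", "XPA_KO"),
                                   out_dir = file.path(out, "study"))

cat(sprintf("T/C induction ratio: %.2f (reported induction is >6-fold)\n",
            res$summary$induction_ratio_t_over_c))

enrich_t <- rowMeans(res$enrichment[, grep("^T\\.", colnames(res$enrichment))])
enrich_c <- rowMeans(res$enrichment[, grep("^C\\.", colnames(res$enrichment))])
tab <- data.frame(state = names(enrich_t),
                  mean_enrichment_C = enrich_c,
                  mean_enrichment_T = enrich_t,
                  p_formation = res$enrichment_p$formation,
                  p_removal = res$enrichment_p$removal,
                  row.names = NULL)
write.table(tab, file.path(out, "state_enrichment_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("top treated-condition states:\n")
print(head(tab[order(-tab$mean_enrichment_T),
               c("state", "mean_enrichment_T", "p_formation")], 5),
      row.names = FALSE)
cat(sprintf("states with significant formation (T > C, p < 0.05): %d/18\n",
            sum(tab$p_formation < 0.05)))
cat(sprintf("states with significant removal (R < T, p < 0.05): %d/18\n",
            sum(tab$p_removal < 0.05)))
cat("note: the generator places genes independently of chromatin states, so\n")
cat("removal (which is gene-anchored) shows up in TSS metaprofiles (03), not\n")
cat("in per-state enrichment; see the methods vignette.\n")

rho <- cor(default_state_intensity()[tab$state], tab$mean_enrichment_T,
           method = "spearman")
cat(sprintf("rank agreement of T enrichment with configured intensity: %.2f\n",
            rho))
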