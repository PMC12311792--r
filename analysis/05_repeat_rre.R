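#!/usr/bin/env Rscript
# Relative removal efficiency (RRE) at the repeat locus via the
# reconstructed reference: simulate T and R read libraries, hard-trim to
# 50 b, count mismatch-free exact matches per group, and compare RREs. With
# transcription-coupled removal acting on the highly-transcribed controls
# only, the repeat RRE should sit at the non-transcribed control level
# (~1), significantly below the Q4 controls.

suppressPackageStartupMessages(library(dpcseq))

seed <- 1L
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed, n_replicates = 3)
res <- run_repeat_study(cfg,
                        removal = c(rDNA = 0, Q0_controls = 0,
                                    Q4_controls = 0.72),
                        depth = 1000, out_dir = out)

cat("RRE by target group (mean over 3 replicates, SEM):\n")
print(res$report$table, row.names = FALSE, digits = 3)
cat(sprintf("\npaired one-tailed p, Q4 controls > Q0 controls: %.4f\n",
            res$report$p_q4_vs_q0))
cat(sprintf("paired one-tailed p, repeat > Q0 controls: %.4f (expected n.s.)\n",
            res$report$p_rdna_vs_q0))
cat("interpretation: RRE ~ 1 at the repeat locus = no preferential removal;\n")
cat("the repeat behaves like the non-transcribed controls.\n")
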