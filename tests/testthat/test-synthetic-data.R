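test_that("toy genome generation is seeded-deterministic and well-formed", {
  cfg <- small_config(seed = 7)
  g1 <- build_toy_genome(cfg)
  g2 <- build_toy_genome(cfg)
  expect_identical(g1, g2)

  seg <- g1$segmentation
  expect_length(attr(seg, "state_set"), 18)
  expect_setequal(unique(seg$state), attr(seg, "state_set"))
  # exact partition per chromosome: sorted, contiguous, summing to length
  for (chrom in names(cfg$chrom_lengths)) {
    blocks <- seg[seg$chrom == chrom, ]
    expect_equal(blocks$start, c(0, head(blocks$end, -1)))
    expect_equal(sum(blocks$end - blocks$start), cfg$chrom_lengths[[chrom]])
  }

  genes <- g1$genes
  expect_equal(unname(table(genes$stratum)[paste0("Q", 0:4)]),
               rep(cfg$n_genes_per_stratum, 5), ignore_attr = TRUE)
  expect_true(all(genes$fpkm[genes$stratum == "Q0"] == 0))
  expect_true(all(genes$fpkm[genes$stratum != "Q0"] >= 0.1))
  expect_true(all(genes$tss >= 0 & genes$tss < cfg$chrom_lengths[genes$chrom]))

  ref <- g1$reference
  expect_length(ref$groups$rDNA, 1)
  expect_length(ref$groups$Q0_controls, 100)
  expect_false(anyDuplicated(names(ref$sequences)) > 0)
})

test_that("an over-stuffed genome raises a sizing error naming the constraint", {
  expect_error(
    build_toy_genome(sim_config(genome_length = 5e4, n_chromosomes = 1,
                                n_genes_per_stratum = 20, gene_length = 8000)),
    "too short")
})

test_that("fragment simulation is deterministic and conserves the paired T draw", {
  cfg <- small_config(seed = 11)
  g <- build_toy_genome(cfg)
  f1 <- simulate_dpc_fragments(g, cfg, "T", "WT", 1)
  f2 <- simulate_dpc_fragments(g, cfg, "T", "WT", 1)
  expect_identical(f1, f2)
  expect_gt(f1$total_count, 0)
  len <- f1$fragments$end - f1$fragments$start
  expect_true(all(len >= cfg$fragment_length_range[1] &
                    len <= cfg$fragment_length_range[2]))

  r1 <- simulate_dpc_fragments(g, cfg, "R", "WT", 1)
  expect_lte(r1$total_count, r1$paired_t_count)
  expect_equal(r1$paired_t_count, f1$total_count)
  # every R fragment is one of the paired T fragments
  key <- function(df) paste(df$chrom, df$start, df$end)
  expect_true(all(key(r1$fragments) %in% key(f1$fragments)))

  expect_error(simulate_dpc_fragments(g, cfg, "T", "NOT_A_GENOTYPE", 1),
               "unknown genotype")
})

test_that("zero removal fractions make R identical to its paired T draw", {
  qr <- default_quintile_removal(); qr[] <- 0
  cfg <- small_config(seed = 5, quintile_removal = qr)
  g <- build_toy_genome(cfg)
  ft <- simulate_dpc_fragments(g, cfg, "T", "WT", 1)
  fr <- simulate_dpc_fragments(g, cfg, "R", "WT", 1)
  expect_equal(fr$total_count, ft$total_count)
  expect_equal(fr$fragments, ft$fragments)
})

test_that("flat thinning removes the configured fraction of stratum-overlapping fragments", {
  # removal only at Q4, no TSS decay: survival of Q4-body-overlapping
  # fragments should be ~1 - 0.72 within binomial error
  qr <- default_quintile_removal(); qr[] <- 0; qr["WT", "Q4"] <- 0.72
  cfg <- sim_config(genome_length = 1e6, n_chromosomes = 2,
                    n_genes_per_stratum = 10, quintile_removal = qr,
                    tss_decay_bp = NULL, seed = 13)
  g <- build_toy_genome(cfg)
  ft <- simulate_dpc_fragments(g, cfg, "T", "WT", 1)
  fr <- simulate_dpc_fragments(g, cfg, "R", "WT", 1)
  q4 <- g$genes[g$genes$stratum == "Q4", ]
  in_q4_body <- function(frags) {
    mid <- floor((frags$start + frags$end) / 2)
    hit <- rep(FALSE, length(mid))
    for (i in seq_len(nrow(q4))) {
      lo <- if (q4$strand[i] == "+") q4$tss[i] else q4$tss[i] - q4$length[i]
      hi <- lo + q4$length[i]
      hit <- hit | (frags$chrom == q4$chrom[i] & mid >= lo & mid < hi)
    }
    hit
  }
  n_t <- sum(in_q4_body(ft$fragments))
  n_r <- sum(in_q4_body(fr$fragments))
  p_surv <- 1 - 0.72
  se <- sqrt(p_surv * (1 - p_surv) / n_t)
  expect_gt(n_t, 100)
  expect_lt(abs(n_r / n_t - p_surv), 3 * se)
})

test_that("stronger removal monotonically depresses R coverage over target gene bodies", {
  levels <- c(0.2, 0.5, 0.8)
  counts <- sapply(levels, function(f) {
    qr <- default_quintile_removal(); qr[] <- 0; qr["WT", "Q4"] <- f
    cfg <- small_config(seed = 21, quintile_removal = qr, tss_decay_bp = NULL)
    g <- build_toy_genome(cfg)
    vapply(1:10, function(r)
      simulate_dpc_fragments(g, cfg, "R", "WT", r)$total_count, 0)
  })
  # rank test: replicate counts at higher removal are stochastically smaller
  expect_lt(suppressWarnings(
    stats::wilcox.test(counts[, 1], counts[, 3],
                       alternative = "greater")$p.value), 0.05)
  expect_true(all(diff(colMeans(counts)) < 0))
})

test_that("repeat-read simulation honours truth labels, abundances and seeding", {
  cfg <- small_config(seed = 9, read_error_rate = 0)
  ref <- build_repeat_reference(cfg, canonical_length = 2000, n_controls = 3,
                                control_length = 500)
  ab <- c(rDNA = 2000, Q0_controls = 1000)
  reads <- simulate_repeat_reads(ref, cfg, ab, "T", 1)
  expect_identical(simulate_repeat_reads(ref, cfg, ab, "T", 1), reads)

  # error rate 0: every read is an exact substring of its source (or revcomp)
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    grp <- naive_match_groups(reads$seq[i], ref)
    reads$group[i] %in% grp
  }, TRUE)
  expect_true(all(ok))

  # 2:1 abundance recovered within multinomial error
  n <- table(reads$group)
  p_hat <- n[["rDNA"]] / sum(n)
  se <- sqrt(2 / 3 * 1 / 3 / sum(n))
  expect_lt(abs(p_hat - 2 / 3), 3 * se)

  expect_error(
    simulate_repeat_reads(ref, sim_config(read_length = 5000), ab, "T", 1),
    "read length")
})

test_that("qPCR Ct simulation inverts the percent-removal transform", {
  # noise-free: delta-Ct exactly -log2(1 - f)
  ct0 <- simulate_qpcr_ct(0, n_replicates = 4, noise_sd = 0, seed = 3)
  expect_equal(ct0$ct_R - ct0$ct_T, rep(0, 4))
  ct5 <- simulate_qpcr_ct(0.5, n_replicates = 4, noise_sd = 0, seed = 3)
  expect_equal(ct5$ct_R - ct5$ct_T, rep(1, 4))

  # Monte-Carlo: forward+inverse transform unbiased at f = 0.72
  ct <- simulate_qpcr_ct(0.72, n_replicates = 100, noise_sd = 0.1, seed = 17)
  res <- summarize_removal(ct)
  expect_equal(res$n_discarded, 0)
  expect_lt(abs(res$mean - 72), 3 * res$sem)

  expect_error(simulate_qpcr_ct(1, n_replicates = 3), "\\[0, 1\\)")
  expect_identical(simulate_qpcr_ct(0.4, seed = 8), simulate_qpcr_ct(0.4, seed = 8))
})
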