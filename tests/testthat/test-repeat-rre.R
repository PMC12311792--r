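test_that("hard-trimming keeps the 5' prefix and reports drops", {
  reads <- data.frame(
    read_id = c("r1", "r2", "r3"),
    seq = c(strrep("ACGT", 38),   # 152 b
            strrep("AC", 25),     # 50 b
            strrep("A", 49)),     # 49 b
    stringsAsFactors = FALSE)
  tr <- hardtrim_reads(reads, keep = 50)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$seq[1], substr(strrep("ACGT", 38), 1, 50))
  expect_equal(tr$seq[2], strrep("AC", 25))  # exactly 50 b: unchanged
  expect_equal(attr(tr, "n_dropped"), 1)
})

test_that("exact matching counts mismatch-free reads and only those", {
  set.seed(5)
  canon <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                 collapse = "")
  q0 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  ref <- manual_reference(
    c(canon = canon, ctrl = q0),
    list(rDNA = "canon", Q0_controls = "ctrl"))

  exact <- substr(canon, 101, 150)
  mutated <- exact
  substr(mutated, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                     substr(exact, 25, 25))[1]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(q0, 11, 60))))
  reads <- data.frame(read_id = c("a", "b", "c"),
                      seq = c(exact, mutated, rc), stringsAsFactors = FALSE)
  res <- exact_match_count(reads, ref)
  expect_equal(res$group_counts[["rDNA"]], 1)       # exact 50-mer
  expect_equal(res$group_counts[["Q0_controls"]], 1)  # reverse complement
  expect_equal(res$n_unmatched, 1)                   # single substitution
  expect_equal(res$n_ambiguous, 0)
  # strand switch off: the reverse-complement read no longer matches
  res_fwd <- exact_match_count(reads, ref, both_strands = FALSE)
  expect_equal(res_fwd$group_counts[["Q0_controls"]], 0)
})

test_that("reads matching several groups are discarded as ambiguous and the partition holds", {
  shared <- strrep("ACGTC", 12)  # 60-mer embedded in both groups
  ref <- manual_reference(
    c(a = paste0("TTTTT", shared, "GGGGG"),
      b = paste0("CCCCC", shared, "AAAAA")),
    list(rDNA = "a", Q4_controls = "b"))
  reads <- data.frame(read_id = "x", seq = substr(shared, 1, 50),
                      stringsAsFactors = FALSE)
  res <- exact_match_count(reads, ref)
  expect_equal(res$n_ambiguous, 1)
  expect_equal(sum(res$group_counts), 0)
  expect_equal(sum(res$group_counts) + res$n_ambiguous + res$n_unmatched,
               res$n_total)
})

test_that("the matcher agrees with a naive substring scan on simulated reads", {
  cfg <- small_config(seed = 31, read_error_rate = 0.01, read_length = 80)
  ref <- build_repeat_reference(cfg, canonical_length = 1500, n_controls = 4,
                                control_length = 400)
  reads <- simulate_repeat_reads(ref, cfg,
                                 c(rDNA = 120, Q0_controls = 60,
                                   Q4_controls = 60), "T", 1)
  trimmed <- hardtrim_reads(reads, 50)
  res <- exact_match_count(trimmed, ref)
  want_groups <- lapply(trimmed$seq, naive_match_groups, reference = ref)
  n_hit <- lengths(want_groups)
  expect_equal(res$n_unmatched, sum(n_hit == 0))
  expect_equal(res$n_ambiguous, sum(n_hit > 1))
  for (grp in names(ref$groups))
    expect_equal(res$group_counts[[grp]],
                 sum(n_hit == 1 & vapply(want_groups, function(g)
                   identical(g, grp), TRUE)))
  expect_equal(sum(res$group_counts) + res$n_ambiguous + res$n_unmatched,
               res$n_total)
})

test_that("the mismatch filter's throughput cost matches (1-e)^L", {
  e <- 0.01
  cfg <- small_config(seed = 41, read_error_rate = e, read_length = 50)
  ref <- build_repeat_reference(cfg, canonical_length = 3000, n_controls = 2,
                                control_length = 600)
  reads <- simulate_repeat_reads(ref, cfg, c(rDNA = 2000), "T", 1)
  res <- exact_match_count(reads, ref)
  p <- (1 - e)^50
  se <- sqrt(p * (1 - p) / res$n_total)
  expect_lt(abs(sum(res$group_counts) / res$n_total - p), 4 * se)
})

test_that("RRE arithmetic, identity and zero-count guard", {
  r <- compute_rre(c(400, 200), c(200, 100))
  expect_equal(r$rre_per_replicate, c(2, 2))
  expect_equal(r$rre_mean, 2)

  r1 <- compute_rre(c(300, 300, 300), c(300, 300, 300))
  expect_equal(r1$rre_mean, 1)

  expect_error(compute_rre(c(100, 100), c(0, 100)), "replicate 1")
  expect_error(compute_rre(c(1, 2, 3), c(1, 2)), "pairing")

  # optional depth scaling
  rs <- compute_rre(c(400, 200), c(200, 100),
                    depth_scale = list(T = c(2, 1), R = c(1, 1)))
  expect_equal(rs$rre_per_replicate, c(1, 2))
})

test_that("RRE converges to 1/f under pure thinning of the R library", {
  for (f in c(1, 0.5, 0.25)) {
    rres <- vapply(1:3, function(s) {
      cfg <- small_config(seed = 100 + s, read_error_rate = 0)
      ref <- build_repeat_reference(cfg, canonical_length = 2000,
                                    n_controls = 2, control_length = 500)
      n_t <- exact_match_count(
        hardtrim_reads(simulate_repeat_reads(ref, cfg, c(rDNA = 800), "T", 1), 50),
        ref)$group_counts[["rDNA"]]
      n_r <- exact_match_count(
        hardtrim_reads(simulate_repeat_reads(ref, cfg, c(rDNA = 800 * f), "R", 1), 50),
        ref)$group_counts[["rDNA"]]
      n_t / n_r
    }, 0)
    se <- sd(rres) / sqrt(3)
    expect_lt(abs(mean(rres) - 1 / f), max(3 * se, 0.15 / f))
  }
})

test_that("the RRE report table and tests require complete matched groups", {
  rre <- list(
    rDNA = compute_rre(c(300, 310, 290), c(295, 305, 300)),
    Q0_controls = compute_rre(c(300, 300, 300), c(290, 310, 300)),
    Q4_controls = compute_rre(c(300, 300, 300), c(100, 95, 105)))
  rep <- rre_report(rre)
  expect_equal(rep$table$group, c("rDNA", "Q0_controls", "Q4_controls"))
  expect_lt(rep$p_q4_vs_q0, 0.05)
  expect_gt(rep$p_rdna_vs_q0, 0.1)
  expect_error(rre_report(rre[1:2]), "missing group")
})
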