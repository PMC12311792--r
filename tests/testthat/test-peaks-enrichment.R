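# Independent oracle: exhaustive bin scan with explicit run merging.
brute_force_peaks <- function(values, bin_size, chrom, background, min_fold,
                              merge_gap, min_width) {
  flagged <- which(values >= min_fold * background & values > 0)
  if (!length(flagged)) return(data.frame(chrom = character(),
                                          start = integer(), end = integer()))
  starts <- (flagged - 1) * bin_size
  ends <- flagged * bin_size
  m_start <- starts[1]; m_end <- ends[1]
  out <- list()
  if (length(flagged) > 1) {
    for (i in 2:length(flagged)) {
      if (starts[i] - m_end < merge_gap) {
        m_end <- ends[i]
      } else {
        out <- c(out, list(c(m_start, m_end)))
        m_start <- starts[i]; m_end <- ends[i]
      }
    }
  }
  out <- c(out, list(c(m_start, m_end)))
  df <- do.call(rbind.data.frame, out)
  names(df) <- c("start", "end")
  df <- df[df$end - df$start >= min_width, , drop = FALSE]
  data.frame(chrom = chrom, start = as.integer(df$start),
             end = as.integer(df$end), stringsAsFactors = FALSE,
             row.names = NULL)
}

test_that("flat tracks yield no peaks and a plateau yields exactly one", {
  flat <- manual_track(list(chrT = rep(3, 200)))
  expect_equal(nrow(call_broad_peaks(flat)), 0)

  v <- rep(1, 500); v[101:150] <- 5  # 500-b plateau at 5x mean
  plateau <- manual_track(list(chrT = v))
  pk <- call_broad_peaks(plateau, min_fold = 2, merge_gap = 100,
                         min_width = 200)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 1000L)
  expect_equal(pk$end, 1500L)
})

test_that("threshold/merge/width behaviour matches the exhaustive bin-scan oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- rpois(400, 1) * runif(400, 0.5, 2)
    tr <- manual_track(list(chrT = v))
    bg <- mean(v)
    got <- call_broad_peaks(tr, min_fold = 2, merge_gap = 50, min_width = 30)
    want <- brute_force_peaks(v, 10, "chrT", bg, 2, 50, 30)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("mismatched bin grids are rejected", {
  a <- manual_track(list(chrT = rep(1, 100)), bin_size = 10)
  b <- manual_track(list(chrT = rep(1, 50)), bin_size = 20)
  expect_error(call_broad_peaks(a, b), "grid")
})

test_that("fold enrichment reproduces direct arithmetic and its identities", {
  # genome 1000 b, state A = 100 b, peaks = 50 b, overlap = 20 b -> 4.0
  seg <- manual_segmentation(
    chrom = "chrT", start = c(0, 100), end = c(100, 1000),
    state = c("A", "B"))
  peaks <- data.frame(chrom = "chrT", start = c(80L, 500L),
                      end = c(100L, 530L))
  fe <- fold_enrichment(peaks, seg)
  expect_equal(fe[["A"]], (20 / 100) / (50 / 1000))
  # complementary state: overlap 30 of 900
  expect_equal(fe[["B"]], (30 / 900) / (50 / 1000))

  # saturation: peaks tiling the genome -> 1.0 everywhere
  tile <- data.frame(chrom = "chrT", start = 0L, end = 1000L)
  expect_equal(unname(fold_enrichment(tile, seg)), c(1, 1))

  # disjoint peaks -> 0 for the untouched state
  off <- data.frame(chrom = "chrT", start = 200L, end = 300L)
  expect_equal(fold_enrichment(off, seg)[["A"]], 0)

  # double-covered bases count once (merged before overlap)
  dup <- data.frame(chrom = "chrT", start = c(0L, 0L), end = c(100L, 100L))
  expect_equal(fold_enrichment(dup, seg)[["A"]], (100 / 100) / (100 / 1000))
})

test_that("state-base-weighted mean enrichment is exactly 1 on a covering segmentation", {
  set.seed(42)
  ends <- sort(sample(10:990, 8)); ends <- unique(c(ends, 1000))
  starts <- c(0, head(ends, -1))
  seg <- manual_segmentation("chrT", starts, ends,
                             sample(LETTERS[1:4], length(ends), replace = TRUE),
                             state_set = LETTERS[1:4])
  peaks <- data.frame(chrom = "chrT", start = c(13L, 200L, 801L),
                      end = c(57L, 340L, 980L))
  fe <- fold_enrichment(peaks, seg)
  state_bases <- tapply(seg$end - seg$start, seg$state, sum)[names(fe)]
  state_bases[is.na(state_bases)] <- 0
  fe[is.na(fe)] <- 0
  expect_equal(sum(state_bases * fe) / 1000, 1)
})

test_that("fold enrichment agrees with naive per-base membership counting", {
  for (seed in 1:3) {
    cfg <- sim_config(genome_length = 8000, n_chromosomes = 1, n_states = 4,
                      state_intensity = c(A = 2, B = 5, C = 1, D = 8),
                      n_genes_per_stratum = 0, block_length_range = c(200, 800),
                      seed = seed)
    seg <- dpcseq:::simulate_segmentation(cfg)
    set.seed(seed + 100)
    s <- sort(sample(0:7900, 6)); peaks <- data.frame(
      chrom = "chr1", start = s, end = pmin(s + sample(50:400, 6), 8000))
    fe <- fold_enrichment(peaks, seg)
    # per-base oracle
    base_state <- rep(seg$state, seg$end - seg$start)
    in_peak <- rep(FALSE, 8000)
    for (i in seq_len(nrow(peaks)))
      in_peak[(peaks$start[i] + 1):peaks$end[i]] <- TRUE
    for (st in names(fe)) {
      sel <- base_state == st
      want <- (sum(in_peak & sel) / sum(sel)) / (sum(in_peak) / 8000)
      expect_equal(fe[[st]], want, info = paste("state", st, "seed", seed))
    }
  }
})

test_that("uniform random peaks show no state enrichment on average", {
  set.seed(99)
  seg <- manual_segmentation(
    "chrT", seq(0, 9000, by = 1000), seq(1000, 10000, by = 1000),
    rep(c("A", "B"), 5))
  means <- replicate(50, {
    s <- sample(0:9800, 20)
    fe <- fold_enrichment(data.frame(chrom = "chrT", start = s,
                                     end = s + 100L), seg)
    fe
  })
  for (st in c("A", "B")) {
    m <- mean(means[st, ]); se <- sd(means[st, ]) / sqrt(50)
    expect_lt(abs(m - 1), 3 * se)
  }
})

test_that("paired condition comparison follows the one-tailed t oracle", {
  m <- rbind(S1 = c(1.0, 1.1, 0.9, 2.0, 2.2, 1.8),
             S2 = c(1, 1, 1, 1, 1, 1))
  colnames(m) <- c("C.1", "C.2", "C.3", "T.1", "T.2", "T.3")
  p <- compare_state_enrichment(m, "C", "T", "greater")
  expect_lt(p[["S1"]], 0.05)
  expect_equal(p[["S2"]], 1)  # identical vectors: degenerate convention
  p_rev <- compare_state_enrichment(m, "C", "T", "less")
  expect_gt(p_rev[["S1"]], 0.5)
  expect_error(compare_state_enrichment(m[, -1], "C", "T"), "pairing")
})

test_that("peak-signal Spearman correlation handles monotone maps and ties", {
  v <- c(1, 4, 2, 8, 5, 7, 3, 6, 9, 10) * 1.0
  tr_a <- manual_track(list(chrT = v))
  tr_b <- manual_track(list(chrT = 2 * v))
  tr_c <- manual_track(list(chrT = -v + 20))
  peaks <- data.frame(chrom = "chrT", start = seq(0L, 90L, by = 10L),
                      end = seq(10L, 100L, by = 10L))
  rho <- peak_signal_correlation(peaks, list(a = tr_a, b = tr_b, c = tr_c),
                                 sample_size = nrow(peaks))
  expect_equal(rho["a", "b"], 1)
  expect_equal(rho["a", "c"], -1)
  expect_equal(diag(rho), c(a = 1, b = 1, c = 1))

  # ties: agree with explicit average-rank enumeration
  x <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 10)
  y <- c(2, 1, 4, 4, 6, 5, 9, 8, 8, 12)
  tr_x <- manual_track(list(chrT = x)); tr_y <- manual_track(list(chrT = y))
  rho2 <- peak_signal_correlation(peaks, list(x = tr_x, y = tr_y),
                                  sample_size = nrow(peaks))
  avg_rank <- function(v) {
    sorted <- sort(v)
    vapply(v, function(a) mean(which(sorted == a)), 0)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  want <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(rho2["x", "y"], want)

  # zero-variance track -> NA off-diagonal
  tr_z <- manual_track(list(chrT = rep(1, 10)))
  rho3 <- peak_signal_correlation(peaks, list(x = tr_x, z = tr_z),
                                  sample_size = nrow(peaks))
  expect_true(is.na(rho3["x", "z"]))
})
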