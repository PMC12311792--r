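#' CPM-normalised binned coverage track
#'
#' Bins the genome at `bin_size` and sets each bin's value to the number of
#' fragments overlapping it, scaled to counts per million mapped fragments:
#' `value = overlapping_fragments * 1e6 / total_fragments`. Fragments
#' contribute over their full insert length (the simulated fragments are
#' complete inserts, so no read extension is needed).
#'
#' @param fragments A `dpc_fragments` object (non-empty).
#' @param bin_size Bin width in bases (default 10).
#' @return Object of class `dpc_track`: list with `bin_size`, `values`
#'   (named list of per-chromosome numeric vectors), `total_fragments`,
#'   `chrom_lengths`.
#' @export
cpm_normalize <- function(fragments, bin_size = 10) {
  stopifnot(inherits(fragments, "dpc_fragments"))
  if (fragments$total_count == 0)
    stop("CPM normalization undefined for an empty fragment set")
  frag_gr <- GenomicRanges::GRanges(
    fragments$fragments$chrom,
    IRanges::IRanges(start = fragments$fragments$start + 1L,
                     end = fragments$fragments$end))
  values <- lapply(names(fragments$chrom_lengths), function(chrom) {
    len <- fragments$chrom_lengths[[chrom]]
    n_bins <- ceiling(len / bin_size)
    starts <- (seq_len(n_bins) - 1L) * bin_size
    bins <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(start = starts + 1L,
                              end = pmin(starts + bin_size, len)))
    counts <- GenomicRanges::countOverlaps(bins, frag_gr)
    counts * 1e6 / fragments$total_count
  })
  names(values) <- names(fragments$chrom_lengths)
  structure(list(bin_size = as.integer(bin_size), values = values,
                 total_fragments = fragments$total_count,
                 chrom_lengths = fragments$chrom_lengths),
            class = "dpc_track")
}

#' Mean of several tracks on the same grid (replicate merging)
#' @param tracks List of `dpc_track` objects sharing bin size and genome.
#' @return A `dpc_track` with bin-wise mean values; `total_fragments` is the
#'   replicate mean.
#' @export
merge_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  t0 <- tracks[[1]]
  for (t in tracks[-1])
    if (t$bin_size != t0$bin_size ||
        !identical(t$chrom_lengths, t0$chrom_lengths))
      stop("tracks must share bin size and genome")
  values <- lapply(names(t0$values), function(chrom) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[chrom]])) / length(tracks)
  })
  names(values) <- names(t0$values)
  structure(list(bin_size = t0$bin_size, values = values,
                 total_fragments = mean(vapply(tracks,
                                               function(t) t$total_fragments, 0)),
                 chrom_lengths = t0$chrom_lengths),
            class = "dpc_track")
}

#' Assign genes to expression strata Q0-Q4
#'
#' Genes with FPKM >= 0.1 are ranked ascending and split into four
#' equal-size groups Q1 (lowest) to Q4 (highest); group sizes differ by at
#' most one. Genes with FPKM = 0 form the Q0 pool, optionally down-sampled
#' (seeded) to `q0_sample_size`. Genes with 0 < FPKM < 0.1 fall below the
#' expression threshold and are excluded; the exclusion is reported, never
#' silent. FPKM ties are broken by gene id for determinism. "Quintile" is
#' kept as the field's name for these five strata even though Q1-Q4 are
#' quartiles of the expressed genes.
#'
#' @param genes Gene table (data.frame with `gene_id`, `fpkm`).
#' @param q0_sample_size Number of Q0 genes to sample (`NULL` = keep all).
#' @param seed Seed for the Q0 sampling.
#' @return Object of class `dpc_quintiles`: list with `assignment` (named
#'   character gene_id -> stratum), `strata` (list of gene-id vectors),
#'   `excluded` (gene ids with 0 < fpkm < 0.1).
#' @export
assign_quintiles <- function(genes, q0_sample_size = NULL, seed = 1L) {
  stopifnot(nrow(genes) > 0)
  expressed <- genes[genes$fpkm >= 0.1, , drop = FALSE]
  zero <- genes$gene_id[genes$fpkm == 0]
  excluded <- genes$gene_id[genes$fpkm > 0 & genes$fpkm < 0.1]
  if (!nrow(expressed))
    stop("stratification error: no genes with FPKM >= 0.1")
  ord <- order(expressed$fpkm, expressed$gene_id)
  n <- nrow(expressed)
  stratum_idx <- ceiling(seq_len(n) * 4 / n)  # sizes differ by <= 1
  strata <- split(expressed$gene_id[ord], paste0("Q", stratum_idx))
  q0 <- if (!is.null(q0_sample_size) && q0_sample_size < length(zero)) {
    with_stream(seed, "q0_sample", expr = sample(zero, q0_sample_size))
  } else zero
  strata <- c(list(Q0 = sort(q0)), strata)
  assignment <- setNames(rep(names(strata), lengths(strata)),
                         unlist(strata, use.names = FALSE))
  if (length(excluded))
    message(sprintf("%d gene(s) with 0 < FPKM < 0.1 excluded from strata",
                    length(excluded)))
  structure(list(assignment = assignment, strata = strata,
                 excluded = excluded),
            class = "dpc_quintiles")
}

#' TSS-centred metaprofile matrix
#'
#' One row per gene, columns spanning `[-window, +window)` around the TSS at
#' the track's bin size, reversed for minus-strand genes so columns always
#' run upstream -> downstream in transcription direction. Windows reaching
#' past a chromosome edge are zero-padded and the affected genes flagged in
#' the `truncated` attribute.
#'
#' @param track A `dpc_track`.
#' @param genes Gene table with `gene_id`, `chrom`, `strand`, `tss`.
#' @param window Half-window in bases; must be a multiple of the bin size.
#' @return Numeric matrix (genes x bins) with gene ids as rownames, bin
#'   start offsets as colnames, attributes `bin_size`, `window`, `truncated`.
#' @export
tss_matrix <- function(track, genes, window = 20000) {
  stopifnot(inherits(track, "dpc_track"))
  if (window %% track$bin_size != 0)
    stop("window must be a multiple of the track bin size")
  n_col <- 2L * window %/% track$bin_size
  mat <- matrix(0, nrow = nrow(genes), ncol = n_col,
                dimnames = list(genes$gene_id,
                                seq(-window, window - track$bin_size,
                                    by = track$bin_size)))
  truncated <- character()
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    v <- track$values[[chrom]]
    if (is.null(v)) stop(sprintf("unknown chromosome '%s'", chrom))
    center_bin <- genes$tss[i] %/% track$bin_size  # 0-based bin index
    idx <- (center_bin - window %/% track$bin_size) +
      seq_len(n_col) - 1L                           # 0-based bin indices
    inside <- idx >= 0 & idx < length(v)
    row <- numeric(n_col)
    row[inside] <- v[idx[inside] + 1L]
    if (!all(inside)) truncated <- c(truncated, genes$gene_id[i])
    if (genes$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  structure(mat, bin_size = track$bin_size, window = window,
            truncated = truncated, class = c("dpc_meta", "matrix", "array"))
}

#' Per-stratum mean-signal curves from a metaprofile matrix
#'
#' @param matrix A `dpc_meta` matrix from [tss_matrix()].
#' @param assignment A `dpc_quintiles` object.
#' @return List with `curves` (named list stratum -> column-wise mean
#'   vector) and `n_genes` (rows contributing per stratum). Empty strata are
#'   omitted with a message, as are matrix rows absent from the assignment.
#' @export
quintile_profiles <- function(matrix, assignment) {
  stopifnot(inherits(assignment, "dpc_quintiles"))
  unknown <- setdiff(rownames(matrix), names(assignment$assignment))
  if (length(unknown))
    message(sprintf("%d gene row(s) not in the stratum assignment, skipped",
                    length(unknown)))
  curves <- list(); n_genes <- integer()
  for (s in names(assignment$strata)) {
    ids <- intersect(assignment$strata[[s]], rownames(matrix))
    if (!length(ids)) {
      message(sprintf("stratum %s has no rows in the matrix; curve omitted", s))
      next
    }
    curves[[s]] <- colMeans(matrix[ids, , drop = FALSE])
    n_genes[[s]] <- length(ids)
  }
  list(curves = curves, n_genes = n_genes)
}

#' Position-wise comparison of two genotypes' metaprofiles
#'
#' For each column, the replicate-level stratum means of side a and side b
#' are compared by a paired one-tailed t-test (pairing by replicate index,
#' direction `a < b`, i.e. lower signal on side a = more removal on side a).
#' Returns the -log10 p curve.
#'
#' @param matrices_a,matrices_b Lists of replicate `dpc_meta` matrices
#'   (equal length >= 2).
#' @param stratum Stratum label to compare (e.g. `"Q4"`).
#' @param assignment A `dpc_quintiles` object.
#' @return Numeric vector of -log10 p per column.
#' @export
positionwise_compare <- function(matrices_a, matrices_b, stratum, assignment) {
  if (length(matrices_a) != length(matrices_b))
    stop("pairing error: replicate counts differ between sides")
  if (length(matrices_a) < 2)
    stop("pairing error: need >= 2 replicates per side")
  ids <- assignment$strata[[stratum]]
  if (is.null(ids)) stop(sprintf("unknown stratum '%s'", stratum))
  stratum_means <- function(mats) {
    t(vapply(mats, function(m) {
      keep <- intersect(ids, rownames(m))
      colMeans(m[keep, , drop = FALSE])
    }, numeric(ncol(matrices_a[[1]]))))
  }
  a <- stratum_means(matrices_a)   # replicates x columns
  b <- stratum_means(matrices_b)
  p <- vapply(seq_len(ncol(a)), function(j) {
    paired_one_tailed_t(a[, j], b[, j], direction = "greater")$p
  }, 0)
  -log10(p)
}
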