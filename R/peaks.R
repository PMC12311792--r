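#' Identify broad DPC-enriched regions on a binned coverage track
#'
#' A deliberately simple threshold/merge/filter caller (the contribution of
#' the pipeline is the downstream enrichment statistic, not peak calling):
#' bins where `treatment >= min_fold x background` are flagged, where the
#' background is the matched control track, or the genome-wide treatment
#' mean when no control is supplied; flagged runs separated by less than
#' `merge_gap` bases are merged; merged runs shorter than `min_width` are
#' dropped.
#'
#' @param treatment A `dpc_track`.
#' @param control Optional `dpc_track` on the same bin grid; `NULL` compares
#'   against the genome-wide treatment mean.
#' @param min_fold Enrichment threshold over background (default 2).
#' @param merge_gap Maximum gap (bases) merged across (default 1000).
#' @param min_width Minimum peak width in bases (default 200).
#' @return data.frame of peaks (`chrom`, `start`, `end`; 0-based half-open),
#'   sorted and non-overlapping, class `dpc_peaks`.
#' @export
call_broad_peaks <- function(treatment, control = NULL, min_fold = 2,
                             merge_gap = 1000, min_width = 200) {
  stopifnot(inherits(treatment, "dpc_track"))
  if (!is.null(control) &&
      (control$bin_size != treatment$bin_size ||
       !identical(names(control$values), names(treatment$values)) ||
       !all(lengths(control$values) == lengths(treatment$values))))
    stop("grid error: treatment and control tracks on different bin grids")
  global_mean <- mean(unlist(treatment$values, use.names = FALSE))
  bs <- treatment$bin_size
  out <- lapply(names(treatment$values), function(chrom) {
    v <- treatment$values[[chrom]]
    bg <- if (is.null(control)) rep(global_mean, length(v))
    else control$values[[chrom]]
    flagged <- which(v >= min_fold * bg & v > 0)
    if (!length(flagged)) return(NULL)
    runs <- IRanges::reduce(
      IRanges::IRanges(start = (flagged - 1L) * bs + 1L, width = bs),
      min.gapwidth = merge_gap)
    runs <- runs[IRanges::width(runs) >= min_width]
    if (!length(runs)) return(NULL)
    data.frame(chrom = chrom,
               start = IRanges::start(runs) - 1L,
               end = pmin(IRanges::end(runs),
                          treatment$chrom_lengths[[chrom]]),
               stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(peaks))
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  structure(peaks, class = c("dpc_peaks", "data.frame"))
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end))
}

#' Chromatin-state fold enrichment of a peak list
#'
#' For each state s:
#' `(overlap_bases(s, peaks) / state_bases(s)) / (peak_bases / genome_bases)`.
#' Overlap is computed in base units on the merged peak set, so
#' double-covered bases count once. A state with zero bases in the
#' segmentation is reported as `NA` (undefined), never as zero.
#'
#' @param peaks Peak data.frame (`chrom`, `start`, `end`).
#' @param segmentation A `dpc_segmentation`.
#' @return Named numeric vector of fold enrichments, one per state in the
#'   segmentation's state set (1 = no enrichment).
#' @export
fold_enrichment <- function(peaks, segmentation) {
  states <- attr(segmentation, "state_set")
  genome_bases <- attr(segmentation, "genome_size")
  merged <- GenomicRanges::reduce(peaks_to_granges(peaks))
  peak_bases <- sum(GenomicRanges::width(merged))
  enrich <- setNames(rep(NA_real_, length(states)), states)
  if (peak_bases == 0) {
    enrich[] <- 0
    state_b <- tapply(segmentation$end - segmentation$start,
                      segmentation$state, sum)
    enrich[setdiff(states, names(state_b))] <- NA_real_
    return(enrich)
  }
  seg_gr <- GenomicRanges::GRanges(
    segmentation$chrom,
    IRanges::IRanges(start = segmentation$start + 1L, end = segmentation$end))
  for (s in states) {
    sel <- segmentation$state == s
    state_bases <- sum(segmentation$end[sel] - segmentation$start[sel])
    if (state_bases == 0) next  # stays NA: undefined, not zero
    ov <- GenomicRanges::intersect(GenomicRanges::reduce(seg_gr[sel]), merged)
    overlap_bases <- sum(GenomicRanges::width(ov))
    enrich[[s]] <- (overlap_bases / state_bases) /
      (peak_bases / genome_bases)
  }
  enrich
}

#' Enrichment matrix over conditions and replicates
#'
#' @param peak_lists Named list of peak data.frames; names of the form
#'   `"<condition>.<replicate>"` (e.g. `"T.1"`).
#' @param segmentation A `dpc_segmentation`.
#' @return Numeric matrix states x samples, class `dpc_enrichment`.
#' @export
enrichment_matrix <- function(peak_lists, segmentation) {
  m <- vapply(peak_lists, fold_enrichment, segmentation = segmentation,
              numeric(length(attr(segmentation, "state_set"))))
  structure(m, class = c("dpc_enrichment", "matrix", "array"))
}

#' Per-state paired comparison of two conditions' enrichments
#'
#' Columns of the enrichment matrix are paired by replicate index and each
#' state's replicate vectors are compared with a paired one-tailed t-test.
#' The direction is explicit: `"greater"` tests cond_b > cond_a (e.g.
#' formation, T > C), `"less"` tests cond_b < cond_a (e.g. removal, R < T).
#'
#' @param matrix A `dpc_enrichment` matrix with columns named
#'   `"<condition>.<replicate>"`.
#' @param cond_a,cond_b Condition labels.
#' @param direction `"greater"` or `"less"` for cond_b vs cond_a.
#' @return Named numeric vector of one-tailed p-values per state.
#' @export
compare_state_enrichment <- function(matrix, cond_a, cond_b,
                                     direction = c("greater", "less")) {
  direction <- match.arg(direction)
  cols_a <- grep(paste0("^", cond_a, "\\."), colnames(matrix), value = TRUE)
  cols_b <- grep(paste0("^", cond_b, "\\."), colnames(matrix), value = TRUE)
  rep_a <- sort(sub("^.*\\.", "", cols_a))
  rep_b <- sort(sub("^.*\\.", "", cols_b))
  if (!identical(rep_a, rep_b) || length(rep_a) < 2)
    stop("pairing error: conditions need identical replicate sets (>= 2)")
  cols_a <- paste(cond_a, rep_a, sep = ".")
  cols_b <- paste(cond_b, rep_b, sep = ".")
  vapply(rownames(matrix), function(s) {
    paired_one_tailed_t(matrix[s, cols_a], matrix[s, cols_b],
                        direction = direction)$p
  }, 0)
}

#' Spearman correlation of per-peak signals across tracks
#'
#' Samples up to `sample_size` peaks (seeded; all peaks, with a message, if
#' fewer are available), computes each track's mean signal over every
#' sampled peak, and returns the Spearman rank correlation matrix
#' (average-rank tie handling) between all track pairs. Zero-variance
#' signal vectors yield `NA` for their pairs (correlation undefined).
#'
#' @param peaks Peak data.frame.
#' @param tracks Named list of >= 2 `dpc_track` objects.
#' @param sample_size Number of peaks to sample.
#' @param seed Integer seed for the sampling.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
peak_signal_correlation <- function(peaks, tracks, sample_size = 1000,
                                    seed = 1L) {
  if (length(tracks) < 2) stop("need >= 2 tracks")
  n <- nrow(peaks)
  if (n == 0) stop("empty peak list")
  idx <- if (sample_size < n) {
    with_stream(seed, "peak_sample", expr = sort(sample.int(n, sample_size)))
  } else {
    if (sample_size > n)
      message(sprintf("sample_size %d > %d peaks available; using all peaks",
                      sample_size, n))
    seq_len(n)
  }
  sub <- peaks[idx, , drop = FALSE]
  sig <- vapply(tracks, function(tr) {
    vapply(seq_len(nrow(sub)), function(i) {
      v <- tr$values[[sub$chrom[i]]]
      b0 <- sub$start[i] %/% tr$bin_size + 1L
      b1 <- min((sub$end[i] - 1L) %/% tr$bin_size + 1L, length(v))
      mean(v[b0:b1])
    }, 0)
  }, numeric(nrow(sub)))
  suppressWarnings(rho <- cor(sig, method = "spearman"))
  zero_var <- apply(sig, 2, function(x) length(unique(x)) == 1)
  rho[zero_var, ] <- NA_real_
  rho[, zero_var] <- NA_real_
  diag(rho) <- 1
  rho
}
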