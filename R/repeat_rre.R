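#' Hard-trim reads to their 5' prefix
#'
#' Replaces each read by its first `keep` bases from the 5' end (the least
#' error-prone part of the read); reads shorter than `keep` are dropped and
#' the drop count reported in the `n_dropped` attribute.
#'
#' @param reads A `dpc_reads` data.frame (or any data.frame with `seq`).
#' @param keep Bases to keep (default 50).
#' @return The trimmed read set with attributes `read_length = keep`,
#'   `n_dropped`.
#' @export
hardtrim_reads <- function(reads, keep = 50) {
  stopifnot(keep >= 1)
  short <- nchar(reads$seq) < keep
  out <- reads[!short, , drop = FALSE]
  out$seq <- substr(out$seq, 1, keep)
  rownames(out) <- NULL
  attr(out, "read_length") <- as.integer(keep)
  attr(out, "n_dropped") <- sum(short)
  attr(out, "condition") <- attr(reads, "condition")
  attr(out, "replicate") <- attr(reads, "replicate")
  class(out) <- class(reads)
  out
}

# k-mer dictionary over a reference: every length-L substring of each target
# and of its reverse complement (when both_strands), mapped to target/group.
build_kmer_index <- function(reference, L, both_strands = TRUE) {
  recs <- lapply(names(reference$groups), function(grp) {
    lapply(reference$groups[[grp]], function(tname) {
      s <- reference$sequences[[tname]]
      n <- nchar(s)
      if (n < L) return(NULL)
      fwd <- substring(s, 1:(n - L + 1), L:n)
      km <- if (both_strands) unique(c(fwd, revcomp(fwd))) else unique(fwd)
      data.frame(kmer = km, target = tname, group = grp,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, unlist(recs, recursive = FALSE))
}

#' Count mismatch-free exact matches of trimmed reads per target group
#'
#' A read counts for a target iff it occurs as an exact substring of the
#' target sequence or (by default) its reverse complement -- equivalent to
#' zero-mismatch gap-free alignment for uniform-length reads; a single
#' substitution or indel makes the read unmatched. Reads matching targets in
#' more than one group are discarded as ambiguous and counted separately;
#' reads matching nothing are unmatched. Always:
#' `matched + ambiguous + unmatched = total`.
#'
#' @param reads Hard-trimmed `dpc_reads` (uniform length).
#' @param reference A `dpc_repeat_reference`.
#' @param both_strands Also match the reverse complement (unstranded
#'   libraries; default TRUE).
#' @return List: `group_counts` (named integer per group), `target_counts`,
#'   `n_ambiguous`, `n_unmatched`, `n_total`.
#' @export
exact_match_count <- function(reads, reference, both_strands = TRUE) {
  stopifnot(inherits(reference, "dpc_repeat_reference"))
  if (!length(reference$sequences)) stop("reference is empty")
  n_total <- nrow(reads)
  groups <- names(reference$groups)
  if (n_total == 0)
    return(list(group_counts = setNames(integer(length(groups)), groups),
                target_counts = setNames(integer(length(reference$sequences)),
                                         names(reference$sequences)),
                n_ambiguous = 0L, n_unmatched = 0L, n_total = 0L))
  L <- unique(nchar(reads$seq))
  if (length(L) != 1)
    stop("reads must be hard-trimmed to a uniform length before counting")
  idx <- build_kmer_index(reference, L, both_strands)
  # read -> set of (target, group) hits via k-mer lookup
  by_kmer <- split(seq_len(nrow(idx)), idx$kmer)
  hits_per_read <- by_kmer[reads$seq]
  n_groups_hit <- vapply(hits_per_read, function(h)
    if (is.null(h)) 0L else length(unique(idx$group[h])), 0L)
  unmatched <- n_groups_hit == 0
  ambiguous <- n_groups_hit > 1
  assigned <- !unmatched & !ambiguous
  group_of <- rep(NA_character_, n_total)
  group_of[assigned] <- vapply(hits_per_read[assigned],
                               function(h) idx$group[h[1]], "")
  group_counts <- setNames(integer(length(groups)), groups)
  tab <- table(group_of[assigned])
  group_counts[names(tab)] <- as.integer(tab)
  target_counts <- setNames(integer(length(reference$sequences)),
                            names(reference$sequences))
  if (any(assigned)) {
    tgt <- unlist(lapply(hits_per_read[assigned],
                         function(h) unique(idx$target[h])))
    ttab <- table(tgt)
    target_counts[names(ttab)] <- as.integer(ttab)
  }
  list(group_counts = group_counts, target_counts = target_counts,
       n_ambiguous = sum(ambiguous), n_unmatched = sum(unmatched),
       n_total = n_total)
}

#' Relative removal efficiency for one target group
#'
#' `RRE = filtered read count at T / filtered read count at R`, computed per
#' replicate and averaged; an RRE of ~1 means no preferential removal at the
#' locus, RRE > 1 preferential removal. Raw counts are used by default, as
#' sequencing libraries are prepared from equal DNA amounts; set
#' `depth_scale` to per-library totals to normalise instead.
#'
#' @param counts_T,counts_R Paired per-replicate filtered read counts.
#' @param depth_scale Optional list with `T` and `R` per-replicate library
#'   totals; when given, counts are scaled to a common depth first.
#' @return List: `rre_per_replicate`, `rre_mean`, `rre_sem`, `replicate_n`.
#' @export
compute_rre <- function(counts_T, counts_R, depth_scale = NULL) {
  if (length(counts_T) != length(counts_R))
    stop("pairing error: unequal replicate counts")
  if (any(counts_R == 0))
    stop(sprintf("RRE undefined: zero R count in replicate %s",
                 paste(which(counts_R == 0), collapse = ", ")))
  if (!is.null(depth_scale)) {
    counts_T <- counts_T / depth_scale$T
    counts_R <- counts_R / depth_scale$R
  }
  rre <- counts_T / counts_R
  agg <- aggregate_sem(rre)
  list(rre_per_replicate = rre, rre_mean = agg$mean, rre_sem = agg$sem,
       replicate_n = length(rre))
}

#' RRE comparison table across the repeat and control groups
#'
#' Tabulates group RREs with SEM and tests, by paired one-tailed t-test on
#' per-replicate RREs: Q4 controls > Q0 controls (transcription-coupled
#' removal) and repeat > Q0 controls (expected non-significant when the
#' repeat locus is not subject to transcription-coupled removal).
#'
#' @param rre_by_group Named list of [compute_rre()] results; must contain
#'   `rDNA`, `Q0_controls`, `Q4_controls`.
#' @return List: `table` (data.frame group/rre_mean/rre_sem/n),
#'   `p_q4_vs_q0`, `p_rdna_vs_q0`.
#' @export
rre_report <- function(rre_by_group) {
  need <- c("rDNA", "Q0_controls", "Q4_controls")
  if (!all(need %in% names(rre_by_group)))
    stop(sprintf("missing group(s): %s",
                 paste(setdiff(need, names(rre_by_group)), collapse = ", ")))
  ns <- vapply(rre_by_group[need], function(r) r$replicate_n, 0L)
  if (length(unique(ns)) != 1)
    stop("groups computed from different replicate structures")
  tab <- data.frame(
    group = need,
    rre_mean = vapply(rre_by_group[need], function(r) r$rre_mean, 0),
    rre_sem = vapply(rre_by_group[need], function(r) r$rre_sem, 0),
    n = ns, stringsAsFactors = FALSE, row.names = NULL)
  q0 <- rre_by_group$Q0_controls$rre_per_replicate
  list(table = tab,
       p_q4_vs_q0 = paired_one_tailed_t(
         q0, rre_by_group$Q4_controls$rre_per_replicate, "greater")$p,
       p_rdna_vs_q0 = paired_one_tailed_t(
         q0, rre_by_group$rDNA$rre_per_replicate, "greater")$p)
}
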