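#' Simulate a condition-tagged DPC fragment set
#'
#' Implements the formation/removal model:
#' * **C** (untreated control): fragments placed uniformly across the genome,
#'   Poisson counts per segmentation block at `baseline_intensity` per kb --
#'   spontaneous DPCs are state-independent.
#' * **T** (treated): Poisson counts per block at the block state's
#'   `state_intensity` per kb -- induced DPCs concentrate in the configured
#'   chromatin states.
#' * **R** (recovered): an independent thinning of the *paired* T draw for the
#'   same replicate (identical derived seed, so R is always a subset of its T
#'   draw). A fragment whose midpoint lies in the removal window of a gene in
#'   stratum q of genotype g is deleted with probability
#'   `quintile_removal[g, q] * w(d)`, where `d` is the distance downstream of
#'   the TSS in transcription direction and `w` decays linearly from 1 at the
#'   TSS to 0 at `tss_decay_bp` (w = 1 everywhere in the gene body when
#'   `tss_decay_bp` is `NULL`).
#'
#' Fragment lengths are uniform in `fragment_length_range`; all draws come
#' from a replicate/condition/genotype-specific stream derived from the master
#' seed, so any single fragment set is reproducible in isolation.
#'
#' @param genome Output of [build_toy_genome()].
#' @param config A [sim_config()] object.
#' @param condition One of `"C"`, `"T"`, `"R"`.
#' @param genotype Row name of `config$quintile_removal` (e.g. `"WT"`).
#' @param replicate Replicate index (1-based).
#' @return Object of class `dpc_fragments`: list with `fragments`
#'   (data.frame chrom/start/end, 0-based half-open), `condition`,
#'   `replicate`, `genotype`, `total_count`, `chrom_lengths`, and for R sets
#'   `paired_t_count` (size of the pre-thinning T draw).
#' @export
simulate_dpc_fragments <- function(genome, config, condition = c("T", "C", "R"),
                                   genotype = "WT", replicate = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "dpc_sim_config"))
  if (!genotype %in% rownames(config$quintile_removal))
    stop(sprintf("unknown genotype '%s': no removal parameters configured",
                 genotype))
  seg <- genome$segmentation

  draw <- function(intensity_per_kb) {
    # intensity_per_kb: vector aligned with segmentation rows
    widths <- seg$end - seg$start
    counts <- rpois(nrow(seg), intensity_per_kb * widths / 1000)
    idx <- rep.int(seq_len(nrow(seg)), counts)
    if (!length(idx))
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    len <- sample(seq(config$fragment_length_range[1],
                      config$fragment_length_range[2]),
                  length(idx), replace = TRUE)
    start <- seg$start[idx] +
      floor(runif(length(idx)) * pmax(1, widths[idx]))
    chrom <- seg$chrom[idx]
    chrom_len <- config$chrom_lengths[chrom]
    start <- pmin(start, chrom_len - len)  # clip at chromosome end
    start <- pmax(start, 0L)
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + len), stringsAsFactors = FALSE)
  }

  base_cond <- if (condition == "C") "C" else "T"
  frags <- with_stream(config$seed, "fragments", genotype, replicate, base_cond,
                       expr = {
    if (base_cond == "C") {
      draw(rep(config$baseline_intensity, nrow(seg)))
    } else {
      draw(unname(config$state_intensity[seg$state]))
    }
  })
  paired_t_count <- NULL

  if (condition == "R") {
    paired_t_count <- nrow(frags)
    p_remove <- removal_probability(frags, genome$genes, config, genotype)
    keep <- with_stream(config$seed, "thinning", genotype, replicate,
                        expr = runif(nrow(frags)) >= p_remove)
    frags <- frags[keep, , drop = FALSE]
    rownames(frags) <- NULL
  }

  out <- structure(list(
    fragments = frags, condition = condition, replicate = as.integer(replicate),
    genotype = genotype, total_count = nrow(frags),
    chrom_lengths = config$chrom_lengths
  ), class = "dpc_fragments")
  if (!is.null(paired_t_count)) out$paired_t_count <- paired_t_count
  out
}

# Per-fragment removal probability under the transcription-coupled model.
# Midpoint-in-window overlap; when a fragment lies in several genes' windows
# the maximum removal probability applies.
removal_probability <- function(frags, genes, config, genotype) {
  if (!nrow(frags)) return(numeric())
  removal <- config$quintile_removal[genotype, ]
  mid <- floor((frags$start + frags$end) / 2)
  # gene removal window = gene body [tss, tss + length) in transcription
  # direction, expressed as unstranded coordinates
  win_start <- ifelse(genes$strand == "+", genes$tss, genes$tss - genes$length)
  win_end <- ifelse(genes$strand == "+", genes$tss + genes$length, genes$tss)
  p <- numeric(nrow(frags))
  for (chrom in unique(frags$chrom)) {
    fi <- which(frags$chrom == chrom)
    gi <- which(genes$chrom == chrom)
    if (!length(gi)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = mid[fi] + 1L, width = 1L),
      IRanges::IRanges(start = win_start[gi] + 1L, end = win_end[gi]))
    if (!length(hits)) next
    f_idx <- fi[S4Vectors::queryHits(hits)]
    g_idx <- gi[S4Vectors::subjectHits(hits)]
    d <- ifelse(genes$strand[g_idx] == "+",
                mid[f_idx] - genes$tss[g_idx],
                genes$tss[g_idx] - mid[f_idx])
    w <- if (is.null(config$tss_decay_bp)) rep(1, length(d)) else
      pmax(0, 1 - d / config$tss_decay_bp)
    p_hit <- removal[genes$stratum[g_idx]] * w
    agg <- tapply(p_hit, f_idx, max)
    p[as.integer(names(agg))] <- pmax(p[as.integer(names(agg))], unname(agg))
  }
  p
}

#' @export
print.dpc_fragments <- function(x, ...) {
  cat(sprintf("DPC fragment set: %s / %s / replicate %d -- %d fragments\n",
              x$condition, x$genotype, x$replicate, x$total_count))
  invisible(x)
}
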