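#' Build the annotated toy genome
#'
#' Generates every static input of the pipeline from a configuration:
#' a chromatin-state segmentation partitioning each chromosome exactly into
#' labelled blocks, a gene table spanning all expression strata (including
#' non-expressed genes with FPKM 0), and a reconstructed repeat reference
#' (one canonical repeat plus non-transcribed and highly-transcribed control
#' gene panels).
#'
#' Genes are laid out at regular spacing with alternating strand, 10 per
#' stratum by default; FPKM values are drawn per stratum from log-uniform
#' ranges (Q0 exactly 0; Q1 0.1-1; Q2 1-10; Q3 10-100; Q4 100-1000) so that
#' rank-based stratification downstream recovers the design.
#'
#' @param config A [sim_config()] object.
#' @return List with components `segmentation` (class `dpc_segmentation`,
#'   a data.frame chrom/start/end/state with attribute `state_set`),
#'   `genes` (data.frame gene_id/chrom/strand/tss/length/fpkm/stratum),
#'   and `reference` (class `dpc_repeat_reference`, see
#'   [build_repeat_reference()]).
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "dpc_sim_config"))
  seg <- with_stream(config$seed, "segmentation",
                     expr = simulate_segmentation(config))
  genes <- with_stream(config$seed, "genes",
                       expr = simulate_gene_table(config))
  reference <- with_stream(config$seed, "reference",
                           expr = build_repeat_reference(config))
  list(segmentation = seg, genes = genes, reference = reference)
}

simulate_segmentation <- function(config) {
  states <- names(config$state_intensity)[seq_len(config$n_states)]
  if (length(states) < config$n_states)
    stop("state_intensity must name at least n_states states")
  rows <- lapply(names(config$chrom_lengths), function(chrom) {
    len <- config$chrom_lengths[[chrom]]
    # oversample block lengths, then truncate the partition at the chromosome end
    n_max <- ceiling(len / config$block_length_range[1]) + 1
    widths <- sample(seq(config$block_length_range[1],
                         config$block_length_range[2]), n_max, replace = TRUE)
    ends <- pmin(cumsum(widths), len)
    keep <- c(TRUE, head(ends, -1) < len)
    ends <- ends[keep]
    starts <- c(0, head(ends, -1))
    lab <- sample(states, length(ends), replace = TRUE)
    # guarantee every state appears at least once per genome draw
    data.frame(chrom = chrom, start = starts, end = ends, state = lab,
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, rows)
  missing <- setdiff(states, unique(seg$state))
  if (length(missing)) {
    # relabel random large blocks so the state set is complete
    idx <- sample(which(seg$end - seg$start >= config$block_length_range[1]),
                  length(missing))
    seg$state[idx] <- missing
  }
  structure(seg, state_set = states, genome_size = sum(config$chrom_lengths),
            class = c("dpc_segmentation", "data.frame"))
}

simulate_gene_table <- function(config) {
  strata <- paste0("Q", 0:4)
  n_total <- config$n_genes_per_stratum * length(strata)
  chroms <- names(config$chrom_lengths)
  per_chrom <- ceiling(n_total / length(chroms))
  spacing <- floor((config$chrom_lengths[[1]] - 2 * config$gene_length) /
                     per_chrom)
  if (spacing < config$gene_length)
    stop(sprintf(paste0("genome too short to place %d genes of length %d per ",
                        "chromosome: need >= %d b, have %d b"),
                 per_chrom, config$gene_length,
                 per_chrom * config$gene_length + 2 * config$gene_length,
                 config$chrom_lengths[[1]]))
  # FPKM ranges per stratum (log-uniform); Q0 exactly zero
  fpkm_lo <- c(Q0 = 0, Q1 = 0.1, Q2 = 1, Q3 = 10, Q4 = 100)
  fpkm_hi <- c(Q0 = 0, Q1 = 1, Q2 = 10, Q3 = 100, Q4 = 1000)
  stratum <- sample(rep(strata, each = config$n_genes_per_stratum))
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    chrom_i <- chroms[((i - 1) %/% per_chrom) + 1]
    slot <- (i - 1) %% per_chrom
    tss <- config$gene_length + slot * spacing +
      sample.int(max(1, spacing - config$gene_length), 1) - 1
    s <- stratum[i]
    fpkm <- if (s == "Q0") 0 else
      exp(runif(1, log(fpkm_lo[[s]]), log(fpkm_hi[[s]])))
    rows[[i]] <- data.frame(
      gene_id = sprintf("gene%03d", i), chrom = chrom_i,
      strand = sample(c("+", "-"), 1), tss = tss,
      length = config$gene_length, fpkm = fpkm, stratum = s,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  bad <- genes$tss < 0 | genes$tss >= config$chrom_lengths[genes$chrom]
  if (any(bad)) stop("internal: TSS placed outside chromosome bounds")
  genes
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a reconstructed repeat reference
#'
#' Emulates the reference used for repeat-locus quantification: one canonical
#' repeat sequence (analogue of the 13,357-base 45S pre-rRNA unit) plus two
#' control panels, 100 non-transcribed (Q0) and 100 highly transcribed (Q4)
#' gene sequences. All sequences are synthetic random DNA; sizes are scaled
#' down (canonical 13,357 b as in the real unit; controls 1 kb each) so that
#' exact-substring matching behaves as it would on the real reference.
#'
#' @param config A [sim_config()] object.
#' @param canonical_length Length of the canonical repeat sequence.
#' @param n_controls Sequences per control panel.
#' @param control_length Length of each control sequence.
#' @return Object of class `dpc_repeat_reference`: list with `sequences`
#'   (named character vector) and `groups` (named list mapping group label ->
#'   sequence names; groups `rDNA`, `Q0_controls`, `Q4_controls`).
#' @export
build_repeat_reference <- function(config, canonical_length = 13357,
                                   n_controls = 100, control_length = 1000) {
  seqs <- c(setNames(random_dna(canonical_length), "rDNA_45S_synthetic"),
            setNames(vapply(seq_len(n_controls), function(i) random_dna(control_length), ""),
                     sprintf("Q0_ctrl_%03d", seq_len(n_controls))),
            setNames(vapply(seq_len(n_controls), function(i) random_dna(control_length), ""),
                     sprintf("Q4_ctrl_%03d", seq_len(n_controls))))
  if (anyDuplicated(names(seqs))) stop("duplicate reference sequence names")
  structure(list(
    sequences = seqs,
    groups = list(rDNA = "rDNA_45S_synthetic",
                  Q0_controls = grep("^Q0_ctrl_", names(seqs), value = TRUE),
                  Q4_controls = grep("^Q4_ctrl_", names(seqs), value = TRUE))
  ), class = "dpc_repeat_reference")
}
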