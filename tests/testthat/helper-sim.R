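# Small configurations used across the suite: one 200-kb chromosome, 5 genes
# per stratum, 2 replicates. Keeps simulation-backed tests in the seconds.
small_config <- function(seed = 1L, n_replicates = 2, ...) {
  sim_config(genome_length = 2e5, n_chromosomes = 1, n_genes_per_stratum = 5,
             gene_length = 3000, n_replicates = n_replicates, seed = seed, ...)
}

# Hand-built fragment set on a toy single-chromosome genome.
manual_fragments <- function(starts, ends, chrom_len = 1000,
                             chrom = "chrT", condition = "T") {
  structure(list(
    fragments = data.frame(chrom = rep(chrom, length(starts)),
                           start = as.integer(starts),
                           end = as.integer(ends), stringsAsFactors = FALSE),
    condition = condition, replicate = 1L, genotype = "WT",
    total_count = length(starts),
    chrom_lengths = setNames(chrom_len, chrom)
  ), class = "dpc_fragments")
}

# Hand-built coverage track from per-chromosome value vectors.
manual_track <- function(values, bin_size = 10, total_fragments = 1000) {
  chrom_lengths <- setNames(vapply(values, length, 0L) * bin_size,
                            names(values))
  structure(list(bin_size = as.integer(bin_size), values = values,
                 total_fragments = total_fragments,
                 chrom_lengths = chrom_lengths),
            class = "dpc_track")
}

# Hand-built segmentation from parallel vectors.
manual_segmentation <- function(chrom, start, end, state,
                                state_set = unique(state)) {
  df <- data.frame(chrom = chrom, start = start, end = end, state = state,
                   stringsAsFactors = FALSE)
  structure(df, state_set = state_set,
            genome_size = sum(tapply(df$end, df$chrom, max)),
            class = c("dpc_segmentation", "data.frame"))
}

# Tiny repeat reference with explicit sequences.
manual_reference <- function(sequences, groups) {
  structure(list(sequences = sequences, groups = groups),
            class = "dpc_repeat_reference")
}

# Independent naive substring matcher: scans every target on both strands.
naive_match_groups <- function(seq, reference, both_strands = TRUE) {
  hits <- character()
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  for (grp in names(reference$groups)) {
    for (t in reference$groups[[grp]]) {
      s <- reference$sequences[[t]]
      if (grepl(seq, s, fixed = TRUE) ||
          (both_strands && grepl(rc(seq), s, fixed = TRUE)))
        hits <- c(hits, grp)
    }
  }
  unique(hits)
}
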