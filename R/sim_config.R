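#' Chromatin-state labels of the 18-state segmentation emulated by the simulator
#'
#' Labels follow the common 18-state chromatin-model vocabulary (active TSS,
#' flanking TSS, transcription, enhancer classes, ZNF/repeats, heterochromatin,
#' bivalent TSS/enhancer, Polycomb-repressed, quiescent).
#'
#' @return Character vector of 18 state labels.
#' @export
chromatin_states_18 <- function() {
  c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "Tx", "TxWk",
    "EnhG1", "EnhG2", "EnhA1", "EnhA2", "EnhWk", "ZNF_Rpts",
    "Het", "TssBiv", "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
}

#' Default per-state DPC formation intensities (T condition)
#'
#' Expected treated-condition fragments per kilobase for each chromatin state.
#' The defaults encode the observed formation pattern: highest intensities at
#' bivalent TSSs/enhancers and Polycomb-repressed states, elevated intensity at
#' strong transcription, weak enhancers and ZNF/repeats, lowest at quiescent
#' chromatin. Absolute scale is arbitrary (the assay reports relative
#' enrichment, not adducts per Mb).
#'
#' @return Named numeric vector over [chromatin_states_18()].
#' @export
default_state_intensity <- function() {
  c(TssA = 5, TssFlnk = 4, TssFlnkU = 4, TssFlnkD = 4,
    Tx = 6, TxWk = 3.5, EnhG1 = 3.5, EnhG2 = 3.5,
    EnhA1 = 4, EnhA2 = 4, EnhWk = 5, ZNF_Rpts = 5,
    Het = 2, TssBiv = 8, EnhBiv = 7, ReprPC = 7.5,
    ReprPCWk = 3, Quies = 1)
}

#' Default genotype x stratum removal fractions
#'
#' Fraction of treated-condition DPCs removed during recovery for fragments
#' overlapping genes of each expression stratum, per repair genotype. The
#' highly-transcribed (Q4) values are calibrated to the locus-specific qPCR
#' phenotypes: wild type 0.72, XPA knockout 0.40 (NER scaffold lost), CSB
#' knockout 0.10 (transcription-coupled initiation lost, baseline only), XPC
#' knockout 0.72 (global-genome sensor dispensable at transcribed loci).
#' Non-transcribed baseline 0.10 for every genotype; Q1-Q3 interpolate
#' linearly between baseline and the genotype's Q4 value.
#'
#' @return Numeric matrix, rows = genotypes (WT, XPA_KO, XPC_KO, CSB_KO),
#'   columns = strata Q0..Q4, entries in \[0, 1\].
#' @export
default_quintile_removal <- function() {
  strata <- paste0("Q", 0:4)
  genos <- c("WT", "XPA_KO", "XPC_KO", "CSB_KO")
  q4 <- c(WT = 0.72, XPA_KO = 0.40, XPC_KO = 0.72, CSB_KO = 0.10)
  baseline <- 0.10
  m <- t(vapply(genos, function(g) baseline + (q4[[g]] - baseline) * (0:4) / 4,
                numeric(5)))
  dimnames(m) <- list(genos, strata)
  m
}

#' Build a simulation configuration
#'
#' Collects every knob of the synthetic-data generator: toy-genome geometry,
#' per-state formation intensities for the treated (T) condition, the
#' state-independent baseline intensity for the untreated control (C), the
#' genotype x stratum removal fractions applied as thinning during recovery
#' (R), fragment sizing, replicate structure, and qPCR noise.
#'
#' @param genome_length Total genome size in bases, split equally across
#'   chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param n_states Number of chromatin states (default 18).
#' @param state_intensity Named numeric: expected T-condition fragments per kb
#'   per state. Names must cover the emitted state labels.
#' @param baseline_intensity Expected C-condition fragments per kb,
#'   state-independent (spontaneous DPCs are essentially uniform).
#' @param quintile_removal Numeric matrix genotype x stratum (Q0..Q4) of
#'   removal fractions in \[0, 1\].
#' @param fragment_length_range Length-2 integer vector, sonication fragment
#'   size window in bases (default 200-500).
#' @param n_replicates Independent replicates per condition.
#' @param n_genes_per_stratum Genes simulated per expression stratum.
#' @param gene_length Gene-body length in bases.
#' @param tss_decay_bp Width of the TSS-proximal removal window: the thinning
#'   probability decays linearly from its full value at the TSS to zero this
#'   many bases downstream. `NULL` disables the decay (flat removal over the
#'   whole gene body).
#' @param block_length_range Length-2 vector, segmentation block sizes.
#' @param read_length Repeat-locus read length (default 150, hard-trimmed to
#'   50 downstream).
#' @param read_error_rate Per-base substitution error rate for simulated reads.
#' @param ct_base_cycle Mean treated-sample qPCR cycle threshold.
#' @param ct_noise_sd Gaussian Ct noise, cycles.
#' @param reprogrammable_genes Character vector of gene ids whose expression
#'   state can be toggled between runs (transcriptional reprogramming, e.g.
#'   dexamethasone repression of a target locus).
#' @param seed Master integer seed; all randomness derives from it.
#'
#' @return Object of class `dpc_sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 2e6,
                       n_chromosomes = 4,
                       n_states = 18,
                       state_intensity = default_state_intensity(),
                       baseline_intensity = 0.5,
                       quintile_removal = default_quintile_removal(),
                       fragment_length_range = c(200L, 500L),
                       n_replicates = 3,
                       n_genes_per_stratum = 20,
                       gene_length = 8000,
                       tss_decay_bp = 10000,
                       block_length_range = c(500L, 4000L),
                       read_length = 150,
                       read_error_rate = 0.001,
                       ct_base_cycle = 25,
                       ct_noise_sd = 0.15,
                       reprogrammable_genes = character(),
                       seed = 1L) {
  stopifnot(genome_length > 0, n_chromosomes >= 1, n_states >= 1)
  if (any(state_intensity < 0) || baseline_intensity < 0)
    stop("all formation intensities must be >= 0")
  if (any(quintile_removal < 0) || any(quintile_removal > 1))
    stop("removal fractions must lie in [0, 1]")
  if (length(fragment_length_range) != 2 ||
      fragment_length_range[1] > fragment_length_range[2])
    stop("fragment_length_range must be (min, max) with min <= max")
  if (!is.null(tss_decay_bp) && tss_decay_bp <= 0)
    stop("tss_decay_bp must be positive or NULL")
  if (is.null(rownames(quintile_removal)) ||
      !identical(colnames(quintile_removal), paste0("Q", 0:4)))
    stop("quintile_removal needs genotype rownames and colnames Q0..Q4")
  seed <- as.integer(seed)

  chrom_len <- floor(genome_length / n_chromosomes)
  cfg <- structure(list(
    chrom_lengths = setNames(rep(chrom_len, n_chromosomes),
                             paste0("chr", seq_len(n_chromosomes))),
    n_states = as.integer(n_states),
    state_intensity = state_intensity,
    baseline_intensity = baseline_intensity,
    quintile_removal = quintile_removal,
    fragment_length_range = as.integer(fragment_length_range),
    n_replicates = as.integer(n_replicates),
    n_genes_per_stratum = as.integer(n_genes_per_stratum),
    gene_length = as.integer(gene_length),
    tss_decay_bp = tss_decay_bp,
    block_length_range = as.integer(block_length_range),
    read_length = as.integer(read_length),
    read_error_rate = read_error_rate,
    ct_base_cycle = ct_base_cycle,
    ct_noise_sd = ct_noise_sd,
    reprogrammable_genes = reprogrammable_genes,
    seed = seed
  ), class = "dpc_sim_config")
  cfg
}

#' @export
print.dpc_sim_config <- function(x, ...) {
  cat("DPC-seq simulation config\n")
  cat(sprintf("  genome: %d chromosome(s) x %s b, %d states\n",
              length(x$chrom_lengths),
              format(x$chrom_lengths[[1]], big.mark = ","), x$n_states))
  cat(sprintf("  genes: %d per stratum, length %d b\n",
              x$n_genes_per_stratum, x$gene_length))
  cat(sprintf("  intensities: baseline %.2f, state mean %.2f frag/kb\n",
              x$baseline_intensity, mean(x$state_intensity)))
  cat(sprintf("  replicates: %d   seed: %d\n", x$n_replicates, x$seed))
  invisible(x)
}

# Deterministic seed splitting: every (purpose, genotype, replicate, ...) tuple
# gets its own 31-bit stream seed derived from the master seed, so any output
# can be regenerated in isolation. Polynomial string hash mod (2^31 - 1).
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 2147483647
  as.integer((h + as.integer(master)) %% 2147483647)
}

# Run expr under a local, derived RNG seed without disturbing the caller's RNG.
with_stream <- function(master, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(master, ...))
  expr
}
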