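#' Run the formation/removal study end to end
#'
#' Simulates C/T/R fragment sets for each genotype and replicate from one
#' seeded configuration, then computes:
#' * the T/C total-fragment induction ratio (replicate mean);
#' * per-state fold-enrichment matrix over C/T/R peak lists (first genotype)
#'   with paired one-tailed p-values for formation (T > C) and removal
#'   (R < T);
#' * TSS-centred stratum profiles for T and R per genotype and the
#'   per-stratum percent signal loss over the TSS-proximal kilobase;
#' * position-wise -log10 p curves comparing the first two genotypes at Q0
#'   and Q4 (when two or more genotypes are given).
#'
#' @param config A [sim_config()] object.
#' @param genotypes Genotype labels (rows of `config$quintile_removal`).
#' @param window Metaprofile half-window in bases.
#' @param bin_size Coverage bin size in bases.
#' @param out_dir Optional directory; when given, writes the enrichment
#'   matrix, profiles and summary JSON there.
#' @return List: `summary` (headline statistics), `enrichment` (matrix),
#'   `enrichment_p`, `profiles`, `positionwise`, `genome`.
#' @export
run_formation_removal_study <- function(config, genotypes = c("WT", "XPA_KO"),
                                        window = 20000, bin_size = 10,
                                        out_dir = NULL) {
  genome <- build_toy_genome(config)
  assignment <- assign_quintiles(genome$genes, seed = config$seed)
  reps <- seq_len(config$n_replicates)

  frag <- list()
  for (g in genotypes)
    for (cond in c("C", "T", "R"))
      for (r in reps)
        frag[[paste(g, cond, r, sep = ".")]] <-
          simulate_dpc_fragments(genome, config, cond, g, r)

  g1 <- genotypes[1]
  induction <- mean(vapply(reps, function(r)
    frag[[paste(g1, "T", r, sep = ".")]]$total_count /
      frag[[paste(g1, "C", r, sep = ".")]]$total_count, 0))

  tracks <- lapply(frag, cpm_normalize, bin_size = bin_size)

  # Each condition is called against its own genome-wide mean: the untreated
  # track is far too sparse at desk scale to serve as a per-bin background
  # (most control bins are zero, which would flag every covered bin).
  peak_lists <- list()
  for (cond in c("C", "T", "R")) for (r in reps) {
    tr <- tracks[[paste(g1, cond, r, sep = ".")]]
    peak_lists[[paste(cond, r, sep = ".")]] <- call_broad_peaks(tr)
  }
  enrich <- enrichment_matrix(peak_lists, genome$segmentation)
  p_formation <- compare_state_enrichment(enrich, "C", "T", "greater")
  p_removal <- compare_state_enrichment(enrich, "T", "R", "less")

  profiles <- list()
  stratum_loss <- list()
  prox <- NULL
  for (g in genotypes) {
    mats <- list()
    for (cond in c("T", "R")) {
      merged <- merge_tracks(tracks[paste(g, cond, reps, sep = ".")])
      mats[[cond]] <- tss_matrix(merged, genome$genes, window)
      profiles[[g]][[cond]] <- quintile_profiles(mats[[cond]], assignment)
    }
    # percent signal loss over [TSS, TSS + 1 kb) per stratum
    if (is.null(prox)) {
      offs <- as.integer(colnames(mats$T))
      prox <- which(offs >= 0 & offs < 1000)
    }
    loss <- vapply(names(profiles[[g]]$T$curves), function(s) {
      t_sig <- mean(profiles[[g]]$T$curves[[s]][prox])
      r_sig <- mean(profiles[[g]]$R$curves[[s]][prox])
      100 * (1 - r_sig / t_sig)
    }, 0)
    stratum_loss[[g]] <- loss
  }

  positionwise <- NULL
  if (length(genotypes) >= 2) {
    g2 <- genotypes[2]
    mats_a <- lapply(reps, function(r)
      tss_matrix(tracks[[paste(g1, "R", r, sep = ".")]], genome$genes, window))
    mats_b <- lapply(reps, function(r)
      tss_matrix(tracks[[paste(g2, "R", r, sep = ".")]], genome$genes, window))
    positionwise <- list(
      Q0 = positionwise_compare(mats_a, mats_b, "Q0", assignment),
      Q4 = positionwise_compare(mats_a, mats_b, "Q4", assignment))
  }

  summary <- list(
    seed = config$seed,
    genotypes = genotypes,
    n_replicates = config$n_replicates,
    induction_ratio_t_over_c = induction,
    stratum_percent_signal_loss = stratum_loss,
    n_states_significant_formation = sum(p_formation < 0.05),
    n_states_significant_removal = sum(p_removal < 0.05))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(state = rownames(enrich), enrich, check.names = FALSE),
      file.path(out_dir, "enrichment_matrix.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(state = names(p_formation), p_formation, p_removal),
      file.path(out_dir, "enrichment_pvalues.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(summary = summary, enrichment = enrich,
       enrichment_p = list(formation = p_formation, removal = p_removal),
       profiles = profiles, positionwise = positionwise, genome = genome)
}

#' Run the repeat-locus removal study end to end
#'
#' Simulates treated (T) and recovered (R) read libraries over the
#' reconstructed repeat reference for each replicate, with per-group removal
#' fractions thinning the R-library abundances; hard-trims to 50 bases,
#' counts mismatch-free matches per group, and computes the RRE comparison
#' table.
#'
#' @param config A [sim_config()] object.
#' @param removal Named numeric: removal fraction per group (defaults:
#'   transcription-coupled removal at Q4 controls only).
#' @param depth Expected T-library reads per group.
#' @param trim_to 5' hard-trim length (default 50).
#' @param out_dir Optional output directory for the report TSV.
#' @return List: `report` (from [rre_report()]), `rre` (per-group
#'   [compute_rre()] results), `counts` (per-replicate group counts).
#' @export
run_repeat_study <- function(config,
                             removal = c(rDNA = 0, Q0_controls = 0,
                                         Q4_controls = 0.72),
                             depth = 1000, trim_to = 50, out_dir = NULL) {
  reference <- with_stream(config$seed, "reference",
                           expr = build_repeat_reference(config))
  groups <- names(reference$groups)
  if (!all(groups %in% names(removal)))
    stop("removal must name every reference group")
  reps <- seq_len(config$n_replicates)
  counts <- list()
  for (r in reps) {
    ab_T <- setNames(rep(depth, length(groups)), groups)
    ab_R <- ab_T * (1 - removal[groups])
    for (cond in c("T", "R")) {
      ab <- if (cond == "T") ab_T else ab_R
      reads <- simulate_repeat_reads(reference, config, ab, cond, r)
      trimmed <- hardtrim_reads(reads, trim_to)
      counts[[paste(cond, r, sep = ".")]] <-
        exact_match_count(trimmed, reference)$group_counts
    }
  }
  rre <- lapply(setNames(groups, groups), function(grp) {
    compute_rre(
      vapply(reps, function(r) counts[[paste("T", r, sep = ".")]][[grp]], 0L),
      vapply(reps, function(r) counts[[paste("R", r, sep = ".")]][[grp]], 0L))
  })
  report <- rre_report(rre)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report$table, file.path(out_dir, "rre_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(report = report, rre = rre, counts = counts)
}
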