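#' @name genomic-io
#' @title Readers and writers for the pipeline's file formats
#' @description
#' All formats use 0-based half-open coordinates (BED-native). Readers
#' validate strictly and reject malformed input with the offending line
#' number; they never silently repair. Gzip-compressed files are read
#' transparently.
NULL

read_text_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a BED file of genomic intervals
#'
#' @param path BED3/BED4/BED6 file (optionally gzipped). Blank lines and
#'   lines starting with `#`, `track` or `browser` are skipped.
#' @param expected_columns Minimum number of columns each data line must have.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`. Input order preserved.
#' @export
read_bed <- function(path, expected_columns = 3) {
  lines <- read_text_lines(path)
  keep <- !grepl("^\\s*$|^#|^track|^browser", lines)
  rows <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ln <- rows[i]
    if (length(p) < expected_columns)
      stop(sprintf("BED parse error at line %d: %d column(s), expected >= %d",
                   ln, length(p), expected_columns))
    start <- suppressWarnings(as.integer(p[2]))
    end <- suppressWarnings(as.integer(p[3]))
    if (is.na(start) || is.na(end))
      stop(sprintf("BED parse error at line %d: non-integer coordinates", ln))
    if (start < 0 || end <= start)
      stop(sprintf("BED parse error at line %d: end (%d) must exceed start (%d) >= 0",
                   ln, end, start))
    out[[i]] <- list(chrom = p[1], start = start, end = end,
                     name = if (length(p) >= 4) p[4] else NA_character_,
                     score = if (length(p) >= 5)
                       suppressWarnings(as.numeric(p[5])) else NA_real_,
                     strand = if (length(p) >= 6) p[6] else NA_character_)
  }
  df <- do.call(rbind.data.frame, c(out, stringsAsFactors = FALSE))
  if (!nrow(df))
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     name = character(), score = numeric(), strand = character(),
                     stringsAsFactors = FALSE)
  if (all(is.na(df$name))) df$name <- NULL
  if (!is.null(df$score) && all(is.na(df$score))) df$score <- NULL
  if (!is.null(df$strand) && all(is.na(df$strand))) df$strand <- NULL
  df
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- list(intervals$chrom, intervals$start, intervals$end)
  for (col in c("name", "score", "strand"))
    if (!is.null(intervals[[col]])) cols <- c(cols, list(intervals[[col]]))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene table
#'
#' Tab-separated with header `gene_id, chrom, strand, tss, length, fpkm`
#' (extra columns such as `stratum` are carried through).
#'
#' @param path TSV path (optionally gzipped).
#' @return data.frame of gene models, input order preserved.
#' @export
read_gene_table <- function(path) {
  lines <- read_text_lines(path)
  if (!length(lines)) stop("gene table is empty (no header row)")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("gene_id", "chrom", "strand", "tss", "length", "fpkm")
  if (!all(need %in% header))
    stop(sprintf("gene table header missing column(s): %s",
                 paste(setdiff(need, header), collapse = ", ")))
  body <- lines[-1]
  body <- body[!grepl("^\\s*$", body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts))
    if (length(parts[[i]]) != length(header))
      stop(sprintf("gene table parse error at line %d: %d field(s), expected %d",
                   i + 1, length(parts[[i]]), length(header)))
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- header
  df$tss <- as.integer(df$tss)
  df$length <- as.integer(df$length)
  df$fpkm <- as.numeric(df$fpkm)
  if (anyNA(df$tss) || anyNA(df$length) || anyNA(df$fpkm))
    stop("gene table parse error: non-numeric tss/length/fpkm")
  if (any(df$fpkm < 0)) stop("gene table parse error: negative fpkm")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene table parse error: strand must be '+' or '-'")
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop(sprintf("duplicated gene_id(s): %s", paste(dup, collapse = ", ")))
  df
}

#' Write a gene table as TSV
#' @param genes data.frame of gene models.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file
#'
#' Sequences are uppercased and restricted to the ACGTN alphabet.
#'
#' @param path FASTA path (optionally gzipped).
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  # BStringSet keeps letters verbatim (DNAStringSet silently drops invalid
  # codes, which would be a silent repair)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(nchar(seqs) == 0))
    stop(sprintf("FASTA format error: empty sequence record '%s'",
                 names(seqs)[which(nchar(seqs) == 0)[1]]))
  if (anyDuplicated(names(seqs)))
    stop("FASTA format error: duplicate sequence names")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(sprintf("FASTA format error: non-nucleotide characters in '%s'",
                 names(seqs)[which(bad)[1]]))
  seqs
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Rows are `(chrom, start, end, value)` at the track's bin size; runs of
#' equal value are merged when `merge_runs` is `TRUE`.
#'
#' @param track A `dpc_track` (see [cpm_normalize()]).
#' @param path Output path.
#' @param merge_runs Merge adjacent equal-valued bins into one row.
#' @export
write_bedgraph <- function(track, path, merge_runs = TRUE) {
  stopifnot(inherits(track, "dpc_track"))
  con <- file(path, "wt")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (merge_runs) {
      r <- rle(v)
      ends <- cumsum(r$lengths) * track$bin_size
      ends[length(ends)] <- min(ends[length(ends)], track$chrom_lengths[[chrom]])
      starts <- c(0, head(ends, -1))
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts, ends,
                         format(r$values, trim = TRUE)), con)
    } else {
      ends <- pmin(seq_along(v) * track$bin_size, track$chrom_lengths[[chrom]])
      starts <- (seq_along(v) - 1) * track$bin_size
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts, ends,
                         format(v, trim = TRUE)), con)
    }
  }
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' CSV with header columns `locus, genotype, replicate, ct_T, ct_R`.
#'
#' @param path CSV path.
#' @return data.frame of Ct records.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus", "genotype", "replicate", "ct_T", "ct_R")
  if (!all(need %in% names(df)))
    stop(sprintf("Ct table missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  if (!is.numeric(df$ct_T) || !is.numeric(df$ct_R) ||
      anyNA(df$ct_T) || anyNA(df$ct_R) ||
      any(!is.finite(df$ct_T)) || any(!is.finite(df$ct_R)))
    stop("Ct table parse error: ct_T/ct_R must be finite numbers")
  df
}

#' Write a qPCR Ct table as CSV
#' @param records data.frame of Ct records.
#' @param path Output path.
#' @export
write_ct_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fragment set as BED6
#'
#' The name field encodes `condition:replicate:genotype`.
#'
#' @param fragments A `dpc_fragments` object.
#' @param path Output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  stopifnot(inherits(fragments, "dpc_fragments"))
  df <- fragments$fragments
  df$name <- sprintf("%s:%d:%s", fragments$condition, fragments$replicate,
                     fragments$genotype)
  df$score <- 0
  df$strand <- "."
  write_bed(df, path)
}

#' Write a read set as FASTQ
#'
#' Uniform quality (the simulator models substitution errors directly, not
#' quality-dependent ones).
#'
#' @param reads A `dpc_reads` data.frame (`read_id`, `seq`).
#' @param path Output path.
#' @param quality_char Single quality character applied to every base.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$seq,
                           "+",
                           vapply(nchar(reads$seq), function(n)
                             strrep(quality_char, n), "")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with `read_id` and `seq` (qualities are not retained).
#' @export
read_reads_fastq <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) %% 4 != 0)
    stop(sprintf("FASTQ parse error: %d lines is not a multiple of 4",
                 length(lines)))
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(ids, "@"))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: header must start with '@'",
                 (bad[1] - 1) * 4 + 1))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: separator must start with '+'",
                 (bad[1] - 1) * 4 + 3))
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad))
    stop(sprintf("FASTQ parse error at line %d: quality length != read length",
                 (bad[1] - 1) * 4 + 4))
  data.frame(read_id = sub("^@", "", sub("\\s.*$", "", ids)),
             seq = toupper(seqs), stringsAsFactors = FALSE)
}
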