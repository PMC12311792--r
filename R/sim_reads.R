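#' Simulate reads from the repeat reference
#'
#' Draws reads of fixed length from the canonical repeat and control targets
#' with per-group abundances, on either strand, with uniform per-base
#' substitution errors. The target and group of origin are recorded so tests
#' can compare recovered counts against the truth.
#'
#' Per-group expected read counts are `depth * abundance[group]`; the realised
#' count is a Poisson draw (library sampling). The recovered-condition (R)
#' library is emulated by scaling a group's abundance by `1 - removal`
#' upstream of this function.
#'
#' @param reference A `dpc_repeat_reference` (see [build_repeat_reference()]).
#' @param config A [sim_config()] object (read length, error rate, seed).
#' @param abundance Named numeric: expected reads per group
#'   (names must be group labels of `reference$groups`).
#' @param condition Label stored on the read set (e.g. `"T"`, `"R"`).
#' @param replicate Replicate index (seeds the stream).
#' @return Object of class `dpc_reads`: data.frame with columns
#'   `read_id`, `seq`, `target`, `group`, `strand`, plus attributes
#'   `condition`, `replicate`, `read_length`.
#' @export
simulate_repeat_reads <- function(reference, config, abundance,
                                  condition = "T", replicate = 1L) {
  stopifnot(inherits(reference, "dpc_repeat_reference"))
  if (!all(names(abundance) %in% names(reference$groups)))
    stop("abundance names must be reference group labels")
  if (any(nchar(reference$sequences) == 0)) stop("empty reference sequence")
  L <- config$read_length
  if (L > min(nchar(reference$sequences[unlist(reference$groups[names(abundance)])])))
    stop(sprintf("read length %d exceeds the shortest target sequence", L))

  out <- with_stream(config$seed, "reads", condition, replicate, expr = {
    rows <- lapply(names(abundance), function(grp) {
      n <- rpois(1, abundance[[grp]])
      if (n == 0) return(NULL)
      targets <- sample(reference$groups[[grp]], n, replace = TRUE)
      tlen <- nchar(reference$sequences[targets])
      pos <- floor(runif(n) * (tlen - L + 1)) + 1
      raw <- substring(reference$sequences[targets], pos, pos + L - 1)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      raw[strand == "-"] <- revcomp(raw[strand == "-"])
      raw <- inject_errors(raw, config$read_error_rate)
      data.frame(seq = unname(raw), target = targets, group = grp,
                 strand = strand, stringsAsFactors = FALSE)
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  })
  if (is.null(out))
    out <- data.frame(seq = character(), target = character(),
                      group = character(), strand = character(),
                      stringsAsFactors = FALSE)
  out <- cbind(read_id = sprintf("read%06d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  structure(out, condition = condition, replicate = as.integer(replicate),
            read_length = L, class = c("dpc_reads", "data.frame"))
}

revcomp <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
}
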