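#' Percent DPC removal from a delta-Ct
#'
#' A lesion (here, a protein crosslink) blocks amplification of its template,
#' so lesion removal during recovery increases amplifiable template and
#' lowers the recovered-sample Ct shift. With
#' `delta_Ct = Ct_recovered - Ct_treated` on crosslink-enriched DNA,
#' `percent removal = [1 - 0.5^delta_Ct] * 100`. Replicates with a negative
#' delta-Ct are discarded (assay failure), per experiment, and the discard
#' count is always reported by [summarize_removal()].
#'
#' @param delta_ct Numeric vector of delta-Ct values (cycles).
#' @return Numeric vector of percent removal in `[0, 100)`; `NA` marks
#'   discarded (negative delta-Ct) entries.
#' @export
percent_removal <- function(delta_ct) {
  if (any(!is.finite(delta_ct))) stop("non-finite delta-Ct")
  out <- (1 - 0.5^delta_ct) * 100
  out[delta_ct < 0] <- NA_real_
  out
}

#' Summarise percent removal over replicate Ct records
#'
#' Transforms each replicate's delta-Ct to percent removal, applies the
#' negative-delta-Ct discard rule per replicate, then averages.
#'
#' @param records data.frame of Ct records with `ct_T`, `ct_R` (e.g. from
#'   [simulate_qpcr_ct()] or [read_ct_table()]).
#' @return List: `percent` (retained replicate values), `mean`, `sem`,
#'   `n_retained`, `n_discarded`.
#' @export
summarize_removal <- function(records) {
  if (any(!is.finite(records$ct_T)) || any(!is.finite(records$ct_R)) ||
      any(records$ct_T <= 0) || any(records$ct_R <= 0))
    stop("Ct values must be finite and positive")
  pct <- percent_removal(records$ct_R - records$ct_T)
  kept <- pct[!is.na(pct)]
  agg <- aggregate_sem(kept)
  list(percent = kept, mean = agg$mean, sem = agg$sem,
       n_retained = length(kept), n_discarded = sum(is.na(pct)))
}

#' Expression fold change by the 2^-ddCt method
#'
#' Target Ct is normalised to a housekeeping gene within each sample
#' (`dCt = Ct_target - Ct_housekeeping`), and the condition is compared to
#' the reference: `fold = 2^-(dCt_condition - dCt_reference)`.
#'
#' @param ct_target_cond,ct_housekeeping_cond Ct values in the condition.
#' @param ct_target_ref,ct_housekeeping_ref Ct values in the reference.
#' @return Fold change (1 = no change).
#' @export
ddct_fold_change <- function(ct_target_cond, ct_housekeeping_cond,
                             ct_target_ref, ct_housekeeping_ref) {
  vals <- c(ct_target_cond, ct_housekeeping_cond,
            ct_target_ref, ct_housekeeping_ref)
  if (any(!is.finite(vals))) stop("non-finite Ct value")
  dct_cond <- ct_target_cond - ct_housekeeping_cond
  dct_ref <- ct_target_ref - ct_housekeeping_ref
  2^-(dct_cond - dct_ref)
}

#' Paired one-tailed t-test
#'
#' On paired differences `d = y - x`: `t = mean(d) / (sd(d) / sqrt(n))` with
#' the n-1 sd denominator; p is the upper-tail Student-t probability with
#' `df = n - 1` for `direction = "greater"` (alternative: y > x), the lower
#' tail for `"less"`. Degenerate inputs (zero-variance differences) return
#' p = 1 when the mean difference is 0, and the limiting p = 0 flagged via
#' `degenerate = TRUE` otherwise.
#'
#' @param x,y Paired numeric vectors (equal length >= 2).
#' @param direction `"greater"` (y > x) or `"less"` (y < x).
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
paired_one_tailed_t <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop("pairing error: unequal lengths")
  if (length(x) < 2) stop("need >= 2 pairs")
  d <- y - x
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0)
      return(list(t = NA_real_, p = 1, df = n - 1, degenerate = TRUE))
    hit <- (direction == "greater" && mean(d) > 0) ||
      (direction == "less" && mean(d) < 0)
    return(list(t = sign(mean(d)) * Inf, p = if (hit) 0 else 1,
                df = n - 1, degenerate = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  p <- if (direction == "greater") pt(t_stat, df = n - 1, lower.tail = FALSE)
  else pt(t_stat, df = n - 1, lower.tail = TRUE)
  list(t = t_stat, p = p, df = n - 1, degenerate = FALSE)
}

#' Mean, SEM and n
#'
#' @param values Numeric vector (n >= 1).
#' @return List with `mean`, `sem` (`NA` at n = 1; sd uses the n-1
#'   denominator), `n`.
#' @export
aggregate_sem <- function(values) {
  if (!length(values)) stop("aggregation error: empty input")
  n <- length(values)
  list(mean = mean(values),
       sem = if (n == 1) NA_real_ else sd(values) / sqrt(n),
       n = n)
}
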