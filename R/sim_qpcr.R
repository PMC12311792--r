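#' Simulate paired treated/recovered qPCR cycle thresholds
#'
#' Inverse model of the delta-Ct percent-removal transform. For a locus with
#' true removal fraction `f`, lesion-blocked template at the recovered harvest
#' is a fraction `1 - f` of the treated harvest, so the recovered sample
#' crosses threshold `-log2(1 - f)` cycles later:
#' `Ct_R = Ct_T - log2(1 - f) + noise`. Applying the forward transform
#' `[1 - 0.5^(Ct_R - Ct_T)] * 100` to noise-free draws returns `100 f`
#' exactly.
#'
#' @param true_removal_fraction Removal fraction in `[0, 1)`.
#' @param n_replicates Number of replicate experiments.
#' @param noise_sd Gaussian Ct noise (cycles) added independently to each
#'   harvest's Ct.
#' @param seed Integer seed.
#' @param base_cycle Mean treated-sample Ct.
#' @param locus,genotype Labels carried into the output records.
#' @return data.frame of Ct records: `locus`, `genotype`, `replicate`,
#'   `ct_T`, `ct_R`.
#' @export
simulate_qpcr_ct <- function(true_removal_fraction, n_replicates = 5,
                             noise_sd = 0.15, seed = 1L, base_cycle = 25,
                             locus = "locus", genotype = "WT") {
  if (true_removal_fraction < 0 || true_removal_fraction >= 1)
    stop("true_removal_fraction must lie in [0, 1): Ct shift undefined at 1")
  shift <- -log2(1 - true_removal_fraction)
  with_stream(seed, "qpcr", locus, genotype, expr = {
    ct_t <- base_cycle + rnorm(n_replicates, 0, noise_sd)
    ct_r <- ct_t + shift + rnorm(n_replicates, 0, noise_sd)
    data.frame(locus = locus, genotype = genotype,
               replicate = seq_len(n_replicates),
               ct_T = ct_t, ct_R = ct_r, stringsAsFactors = FALSE)
  })
}
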