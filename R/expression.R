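#' Transcripts-per-million normalization
#'
#' Length-normalizes counts to rates (`count / length`), then scales the
#' rates to sum to one million: `TPM_i = 1e6 * rate_i / sum(rates)`.
#'
#' @param counts non-negative read counts per gene (or repeat locus).
#' @param lengths feature lengths in bp, all > 0.
#' @return Numeric vector of TPM values (sums to 1e6).
#' @export
tpm_normalize <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stop("'counts' and 'lengths' must have equal length")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (anyNA(lengths) || any(lengths <= 0)) stop("lengths must be > 0")
  if (all(counts == 0)) stop("all counts are zero; TPM undefined")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Fold change by the -ddCt method
#'
#' `dCt = Ct_target - Ct_reference` within each condition;
#' `ddCt = dCt_treated - dCt_control`; fold change `= 2^(-ddCt)`. All
#' arguments are qPCR cycle-threshold values and may be vectors
#' (recycled pairwise).
#'
#' @param ct_target_treated,ct_ref_treated Ct of the target and the
#'   reference gene in the treated condition.
#' @param ct_target_control,ct_ref_control same for the control condition.
#' @return Fold change(s), numeric.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  args <- list(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(vapply(args, function(a) anyNA(a) || any(!is.finite(a)), TRUE)))
    stop("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
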