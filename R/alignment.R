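#' Global pairwise alignment (Needleman-Wunsch, linear gaps)
#'
#' Computes a maximum-score global alignment of two DNA sequences under
#' additive scoring with a linear gap penalty. The traceback breaks ties
#' deterministically (diagonal, then gap-in-`b`, then gap-in-`a`), so the
#' returned alignment is reproducible across platforms. Defaults
#' (match +1, mismatch -1, gap -2) favour substitution over gapping, which
#' suits lightly diverged satellite copies.
#'
#' @param a,b non-empty DNA strings.
#' @param match,mismatch,gap scores (gap is the per-base penalty).
#' @return A `pairwise_alignment`: list with `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, and the column counts
#'   `matches`, `mismatches`, `gap_columns`.
#' @examples
#' needleman_wunsch("ACGT", "ACGT")$score  # 4
#' @export
needleman_wunsch <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != 1 || length(b) != 1 || is.na(a) || is.na(b) ||
      !nzchar(a) || !nzchar(b))
    stop("'a' and 'b' must be single non-empty sequences")
  res <- .nw_align_cpp(a, b, match, mismatch, gap)
  structure(res, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score ", format(x$score), ": ", x$matches,
      " matches, ", x$mismatches, " mismatches, ", x$gap_columns,
      " gap columns\n", sep = "")
  invisible(x)
}

#' Percent divergence of an aligned pair
#'
#' `100 * mismatches / (matches + mismatches)`: the substitution fraction
#' over aligned non-gap columns. Gap columns are excluded from the
#' denominator, and no multiple-hit (Kimura/CpG) correction is applied --
#' this is the plain substitution proportion a repeat annotation's
#' "% divergence" column approximates.
#'
#' @param aln a `pairwise_alignment`.
#' @return Percent divergence in `[0, 100]`.
#' @export
percent_divergence <- function(aln) {
  non_gap <- aln$matches + aln$mismatches
  if (non_gap == 0) stop("alignment has no non-gap columns")
  100 * aln$mismatches / non_gap
}

#' Iterative majority consensus of a sequence family
#'
#' Star-alignment consensus: the seed is the sequence whose length is
#' closest to the group median (deterministic, robust to truncated
#' copies). Each round aligns every sequence to the current consensus with
#' [needleman_wunsch()], stacks the consensus-anchored columns (insertions
#' relative to the consensus are ignored), and emits the per-column
#' majority base; columns in which half or more of the sequences carry a
#' gap are dropped. Iteration stops when the consensus is unchanged or
#' after `max_rounds`.
#'
#' @param sequences character vector of >= 2 DNA strings.
#' @param max_rounds maximum refinement rounds (default 5).
#' @param match,mismatch,gap alignment scores, see [needleman_wunsch()].
#' @return A `consensus_model`: list with `consensus` (DNA string),
#'   `column_frequencies` (4 x L count matrix over A,C,G,T from the final
#'   round; each column sums to the number of contributing non-gap
#'   sequences), and `rounds` used.
#' @export
build_consensus <- function(sequences, max_rounds = 5L,
                            match = 1, mismatch = -1, gap = -2) {
  sequences <- as.character(sequences)
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (any(!nzchar(sequences))) stop("empty sequence in input")
  lens <- nchar(sequences)
  med <- stats::median(lens)
  seed <- sequences[order(abs(lens - med), seq_along(lens))][1L]

  consensus <- seed
  freqs <- NULL
  rounds <- 0L
  bases <- c("A", "C", "G", "T")
  for (r in seq_len(max_rounds)) {
    rounds <- r
    L <- nchar(consensus)
    counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(bases, NULL))
    gaps <- integer(L)
    for (s in sequences) {
      aln <- needleman_wunsch(s, consensus, match, mismatch, gap)
      ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1L]]
      cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1L]]
      col_chars <- ca[cb != "-"]          # one entry per consensus column
      is_gap <- col_chars == "-"
      gaps <- gaps + is_gap
      idx <- match(col_chars, bases)
      ok <- which(!is.na(idx))
      counts[cbind(idx[ok], ok)] <- counts[cbind(idx[ok], ok)] + 1L
    }
    keep <- gaps / length(sequences) < 0.5
    maj <- bases[apply(counts[, keep, drop = FALSE], 2L, which.max)]
    new_consensus <- paste(maj, collapse = "")
    freqs <- counts[, keep, drop = FALSE]
    if (identical(new_consensus, consensus)) break
    consensus <- new_consensus
  }
  structure(list(consensus = consensus, column_frequencies = freqs,
                 rounds = rounds),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("<consensus_model> ", nchar(x$consensus), " bp consensus after ",
      x$rounds, " round(s)\n", sep = "")
  invisible(x)
}

#' Percent divergence of each copy from a consensus
#'
#' Aligns every sequence to the consensus and returns its percent
#' divergence over non-gap columns. Satellite copies usually span several
#' tandem units of the consensus; aligning such a copy to the bare unit
#' would let the alignment path jump between units and silently skip
#' substituted bases, biasing divergence towards zero. With
#' `tandem = TRUE` (default) the consensus is therefore tiled tandemly
#' and truncated to each copy's length before the global alignment, which
#' makes the estimate an unbiased substitution fraction for tandem-array
#' copies; set `tandem = FALSE` to align against the single unit as-is.
#'
#' @param sequences character vector of DNA strings.
#' @param consensus consensus DNA string (one repeat unit).
#' @param tandem tile the consensus to each copy's length (default `TRUE`).
#' @inheritParams needleman_wunsch
#' @return Numeric vector of divergences (0-100), one per sequence.
#' @export
copy_divergence <- function(sequences, consensus, tandem = TRUE,
                            match = 1, mismatch = -1, gap = -2) {
  consensus <- as.character(consensus)
  nc <- nchar(consensus)
  vapply(as.character(sequences), function(s) {
    ref <- consensus
    if (tandem && nchar(s) != nc) {
      ref <- substr(strrep(consensus, ceiling(nchar(s) / nc)), 1L,
                    max(nchar(s), 1L))
    }
    percent_divergence(needleman_wunsch(s, ref, match, mismatch, gap))
  }, 0, USE.NAMES = FALSE)
}
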