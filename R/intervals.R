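#' Merge overlapping and abutting intervals
#'
#' Returns the sorted, non-overlapping union of the input intervals,
#' ignoring strand. Abutting intervals (`[a,b)`, `[b,c)` in BED terms) are
#' merged even though they share no base. Metadata columns are dropped.
#'
#' @param x a `GRanges`.
#' @return A sorted disjoint `GRanges` covering the same bases.
#' @export
merge_intervals <- function(x) {
  GenomicRanges::reduce(x, ignore.strand = TRUE)
}

#' Count query intervals overlapping a reference set
#'
#' Counts the query intervals that share at least `min_overlap` bases with
#' the union of the reference set (each query interval counted at most
#' once). Overlap requires at least one shared base: abutting intervals do
#' not overlap. Strand is ignored throughout.
#'
#' @param query,reference `GRanges` objects.
#' @param min_overlap minimum number of shared bases (>= 1).
#' @return Integer count of overlapping query intervals.
#' @export
count_overlapping <- function(query, reference, min_overlap = 1L) {
  sum(shared_bases(query, reference) >= .check_min_overlap(min_overlap))
}

.check_min_overlap <- function(min_overlap) {
  if (!is.numeric(min_overlap) || length(min_overlap) != 1 ||
      is.na(min_overlap) || min_overlap < 1)
    stop("'min_overlap' must be a single integer >= 1")
  as.integer(min_overlap)
}

#' Shared bases between each query interval and a reference union
#'
#' @inheritParams count_overlapping
#' @return Integer vector, one total per query interval: the number of its
#'   bases covered by the merged reference set.
#' @export
shared_bases <- function(query, reference) {
  out <- integer(length(query))
  if (length(query) == 0 || length(reference) == 0) return(out)
  ref <- GenomicRanges::reduce(reference, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(query, ref, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  ov <- width(IRanges::pintersect(ranges(query)[queryHits(hits)],
                                  ranges(ref)[subjectHits(hits)]))
  agg <- rowsum(ov, queryHits(hits))
  out[as.integer(rownames(agg))] <- as.integer(agg[, 1L])
  out
}

#' Fraction of the genome covered by an interval set
#'
#' Merged covered bases divided by the total genome size G of the layout;
#' overlapping members are not double-counted.
#'
#' @param x a `GRanges`.
#' @param layout a `Seqinfo` layout; defaults to the `seqinfo` of `x`.
#' @return A real in `[0, 1]`.
#' @export
coverage_fraction <- function(x, layout = NULL) {
  layout <- .layout_of(x, layout)
  if (length(x) == 0) return(0)
  sum(as.numeric(width(GenomicRanges::reduce(x, ignore.strand = TRUE)))) /
    genome_size(layout)
}
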