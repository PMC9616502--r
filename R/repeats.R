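#' Extract repeat copy sequences from a genome
#'
#' Retrieves the DNA sequence of each interval from a genome
#' (`DNAStringSet`), reverse-complementing minus-strand copies by default
#' so that all sequences are in annotation orientation -- mixing
#' orientations would corrupt consensus building and divergence.
#'
#' @param genome a named `DNAStringSet` (one entry per chromosome).
#' @param copies a `GRanges` of repeat intervals.
#' @param orient reverse-complement minus-strand copies (default `TRUE`).
#' @return Character vector of sequences, one per copy.
#' @export
extract_repeat_sequences <- function(genome, copies, orient = TRUE) {
  chroms <- as.character(seqnames(copies))
  missing_chr <- setdiff(unique(chroms), names(genome))
  if (length(missing_chr))
    stop("chromosome missing from genome: ", missing_chr[1L])
  minus <- as.character(strand(copies)) == "-"
  vapply(seq_along(copies), function(i) {
    s <- subseq(genome[[chroms[i]]], start(copies)[i], end(copies)[i])
    if (orient && minus[i]) s <- reverseComplement(s)
    as.character(s)
  }, "")
}

#' Write labelled repeat copies as TSV
#'
#' Emits chrom, start (0-based), end, strand, length, divergence and bound
#' label, sorted by coordinate.
#'
#' @param copies a `GRanges` with `bound` and `divergence` columns.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_labeled_copies <- function(copies, path) {
  ord <- order(as.character(seqnames(copies)), start(copies), end(copies))
  copies <- copies[ord]
  df <- data.frame(
    chrom = as.character(seqnames(copies)),
    start = start(copies) - 1L,
    end = end(copies),
    strand = as.character(strand(copies)),
    length = width(copies),
    divergence = mcols(copies)$divergence,
    bound = mcols(copies)$bound)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
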