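#' Define a genome layout
#'
#' A genome layout names the chromosomes and their lengths; it is the
#' coordinate universe for interval placement, randomization and genome
#' coverage fractions. Represented as a [GenomeInfoDb::Seqinfo] object so
#' it plugs directly into `GRanges` validation.
#'
#' @param seqnames character vector of unique, non-empty chromosome names.
#' @param lengths integer vector of chromosome lengths in bp, all > 0.
#' @return A `Seqinfo` object.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(seqnames, lengths) {
  seqnames <- as.character(seqnames)
  lengths <- as.numeric(lengths)
  if (length(seqnames) == 0) stop("layout must contain at least one chromosome")
  if (length(seqnames) != length(lengths))
    stop("'seqnames' and 'lengths' must have equal length")
  if (anyNA(seqnames) || any(!nzchar(seqnames)))
    stop("chromosome names must be non-empty")
  if (anyDuplicated(seqnames))
    stop("duplicated chromosome name: ", seqnames[duplicated(seqnames)][1L])
  if (anyNA(lengths) || any(lengths <= 0) || any(lengths != round(lengths)))
    stop("chromosome lengths must be positive integers")
  GenomeInfoDb::Seqinfo(seqnames = seqnames, seqlengths = as.integer(lengths))
}

#' Total genome size of a layout
#'
#' @param layout a `Seqinfo` layout from [genome_layout()] or
#'   [read_chrom_sizes()].
#' @return Total genome length G in bp (numeric scalar).
#' @export
genome_size <- function(layout) {
  sum(as.numeric(GenomeInfoDb::seqlengths(layout)))
}

#' Read / write chrom.sizes files
#'
#' Standard two-column (name, length) tab-separated layout files.
#'
#' @param path file path.
#' @return `read_chrom_sizes` returns a `Seqinfo` layout;
#'   `write_chrom_sizes` invisibly returns `path`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("chrom.sizes needs two columns (name, length): ", path)
  genome_layout(tab[[1]], tab[[2]])
}

#' @rdname read_chrom_sizes
#' @param layout a `Seqinfo` layout.
#' @export
write_chrom_sizes <- function(layout, path) {
  lines <- sprintf("%s\t%d", GenomeInfoDb::seqnames(layout),
                   GenomeInfoDb::seqlengths(layout))
  writeLines(lines, path)
  invisible(path)
}

# layout of a GRanges, failing loudly when absent
.layout_of <- function(x, layout = NULL) {
  if (!is.null(layout)) return(layout)
  sl <- GenomeInfoDb::seqlengths(x)
  if (anyNA(sl)) stop("intervals carry no genome layout (missing seqlengths)")
  GenomeInfoDb::seqinfo(x)
}
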