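#' Read a BED file into a GRanges
#'
#' Reads BED3-BED6 (tab-separated, 0-based half-open) and returns a
#' `GRanges` in R's 1-based closed convention, validated against a genome
#' layout. Columns 4/5/6 become `name`, `score` and strand when present
#' (`"."` means missing / unstranded). `track`, `browser` and `#` comment
#' lines and blank lines are skipped. Malformed coordinates (non-integer,
#' start >= end, out of chromosome bounds) and chromosomes absent from the
#' layout are errors naming the offending line: silent drops would corrupt
#' enrichment denominators downstream.
#'
#' @param path BED file path.
#' @param layout a `Seqinfo` genome layout the intervals must live in.
#' @param extra_cols optional character vector naming columns 7+ to keep as
#'   metadata columns (read as character).
#' @return A `GRanges` with the layout as its `seqinfo`.
#' @seealso [write_bed()], [merge_intervals()]
#' @export
read_bed <- function(path, layout, extra_cols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  skip <- !nzchar(lines) | grepl("^(track|browser|#)", lines)
  lines <- lines[!skip]
  lineno <- lineno[!skip]
  if (length(lines) == 0) {
    return(GRanges(seqinfo = layout))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- lineno[which(nf < 3)[1L]]
    stop("line ", bad, ": fewer than 3 tab-separated columns")
  }
  if (!is.null(extra_cols) && any(nf < 6 + length(extra_cols))) {
    bad <- lineno[which(nf < 6 + length(extra_cols))[1L]]
    stop("line ", bad, ": expected ", 6 + length(extra_cols), " columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))

  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": non-integer coordinate")
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": start must satisfy 0 <= start < end")
  known <- GenomeInfoDb::seqnames(layout)
  bad <- which(!(chrom %in% known))
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": unknown chromosome '", chrom[bad[1L]], "'")
  lens <- GenomeInfoDb::seqlengths(layout)[chrom]
  bad <- which(end > lens)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": end ", end[bad[1L]],
         " exceeds length of ", chrom[bad[1L]])

  opt <- function(k) ifelse(nf >= k, vapply(fields, function(f)
    if (length(f) >= k) f[[k]] else ".", ""), ".")
  name <- opt(4L)
  score <- opt(5L)
  strand <- opt(6L)
  strand[!strand %in% c("+", "-")] <- "*"

  gr <- GRanges(chrom, IRanges(start + 1, end), strand = strand,
                seqinfo = layout)
  if (any(nf >= 4)) mcols(gr)$name <- ifelse(name == ".", NA_character_, name)
  if (any(nf >= 5)) mcols(gr)$score <-
      suppressWarnings(as.numeric(ifelse(score == ".", NA, score)))
  if (!is.null(extra_cols)) {
    for (k in seq_along(extra_cols))
      mcols(gr)[[extra_cols[k]]] <- vapply(fields, `[[`, "", 6L + k)
  }
  gr
}

#' Write a GRanges as a sorted BED file
#'
#' Emits BED coordinates in the 0-based half-open convention, sorted by
#' (chrom, start, end). If `name`, `score` or strand information is
#' present, six columns are written (missing values as `"."`, score 0);
#' otherwise three. Extra metadata columns named in `extra_cols` are
#' appended after column 6.
#'
#' @param x a `GRanges`.
#' @param path output file path.
#' @param extra_cols optional character vector of metadata column names to
#'   append.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path, extra_cols = NULL) {
  ord <- order(as.character(seqnames(x)), start(x), end(x))
  x <- x[ord]
  chrom <- as.character(seqnames(x))
  s0 <- format(start(x) - 1, scientific = FALSE, trim = TRUE)
  e0 <- format(end(x), scientific = FALSE, trim = TRUE)
  has_meta <- !is.null(mcols(x)$name) || !is.null(mcols(x)$score) ||
    any(as.character(strand(x)) != "*") || length(extra_cols)
  if (!has_meta) {
    lines <- paste(chrom, s0, e0, sep = "\t")
  } else {
    nm <- mcols(x)$name
    if (is.null(nm)) nm <- rep(NA_character_, length(x))
    nm <- ifelse(is.na(nm), ".", nm)
    sc <- mcols(x)$score
    if (is.null(sc)) sc <- rep(NA_real_, length(x))
    sc <- ifelse(is.na(sc), "0", sprintf("%.10g", sc))
    st <- as.character(strand(x))
    st[st == "*"] <- "."
    lines <- paste(chrom, s0, e0, nm, sc, st, sep = "\t")
    for (col in extra_cols) {
      v <- mcols(x)[[col]]
      v <- if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
      lines <- paste(lines, v, sep = "\t")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
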