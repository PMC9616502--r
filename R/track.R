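#' Coverage tracks
#'
#' A coverage track is a per-chromosome step function of non-negative
#' values (an `RleList` spanning every chromosome of the layout; positions
#' without an explicit run read as 0). Tracks are built from bedGraph
#' files or from `GRanges` runs with a `score` column.
#'
#' @param values an `RleList` (one run-length encoded vector per
#'   chromosome, full chromosome length) or a `GRanges` with a numeric
#'   `score` column.
#' @param layout a `Seqinfo` genome layout.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, layout) {
  if (is(values, "GRanges")) {
    if (is.null(mcols(values)$score)) stop("runs need a 'score' column")
    unknown <- setdiff(unique(as.character(seqnames(values))),
                       GenomeInfoDb::seqnames(layout))
    if (length(unknown))
      stop("run chromosome not in layout: ", unknown[1L])
    GenomeInfoDb::seqlevels(values) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(values) <- layout
    values <- GenomicRanges::coverage(values, weight = "score")
  }
  if (!is(values, "RleList")) stop("'values' must be an RleList or GRanges")
  want <- GenomeInfoDb::seqnames(layout)
  if (!all(want %in% names(values)))
    stop("track missing chromosomes: ",
         paste(setdiff(want, names(values)), collapse = ", "))
  values <- values[want]
  lens <- GenomeInfoDb::seqlengths(layout)
  if (!all(lengths(values) == lens))
    stop("track run lengths do not match chromosome lengths")
  values <- values * 1.0          # uniform double storage across sources
  structure(list(values = values, layout = layout), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$values, function(v) sum(as.numeric(v)), 0))
  cat("<coverage_track> ", length(x$values), " chromosomes, ",
      format(genome_size(x$layout), big.mark = ","), " bp, total signal ",
      format(tot, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Read a bedGraph coverage track
#'
#' Parses a bedGraph file (0-based half-open steps) via
#' `rtracklayer::import` and validates it against the layout. Optionally
#' rescales to counts-per-million, mirroring library-size scaled coverage.
#'
#' @param path bedGraph file path.
#' @param layout a `Seqinfo` genome layout.
#' @param scale_to_million if `TRUE`, multiply the track by
#'   `1e6 / total signal` (sum of per-base values) at load.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, layout, scale_to_million = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  unknown <- setdiff(unique(as.character(seqnames(gr))),
                     GenomeInfoDb::seqnames(layout))
  if (length(unknown))
    stop("bedGraph chromosome not in layout: ", unknown[1L])
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
  trk <- coverage_track(gr, layout)
  if (scale_to_million) trk <- scale_track(trk, 1e6 / track_total(trk))
  trk
}

#' Write a coverage track as bedGraph
#'
#' Runs with value 0 are omitted; output is sorted by chromosome then
#' start, deterministic at byte level for a given track.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    rl <- runLength(v); rv <- runValue(v)
    e <- cumsum(as.numeric(rl)); s <- e - rl
    keep <- rv != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%.0f\t%.0f\t%.10g", chrom, s[keep], e[keep],
                       rv[keep]), con)
  }
  invisible(path)
}

#' Total signal carried by a track
#' @param track a `coverage_track`.
#' @return Sum of per-base values over the genome.
#' @export
track_total <- function(track) {
  sum(vapply(track$values, function(v) sum(as.numeric(v)), 0))
}

#' Multiply a track by a constant
#' @param track a `coverage_track`.
#' @param factor positive scale factor.
#' @return A `coverage_track`.
#' @export
scale_track <- function(track, factor) {
  if (!is.numeric(factor) || factor <= 0) stop("'factor' must be > 0")
  coverage_track(track$values * factor, track$layout)
}

# Per-base values over [start0, end0) in 0-based half-open coordinates,
# zero-padded where the window leaves the chromosome.
.track_window <- function(track, chrom, start0, end0) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  L <- length(v)
  lo <- max(start0, 0); hi <- min(end0, L)
  mid <- if (hi > lo) as.numeric(v[(lo + 1):hi]) else numeric(0)
  c(numeric(max(0, -start0)), mid, numeric(max(0, end0 - hi)))
}

#' Per-base fold-enrichment track (signal over control)
#'
#' Computes `(signal + pseudocount) / (control + pseudocount)` per base on
#' the union of the two tracks' breakpoints -- the usual IgG normalization
#' of antibody-targeted coverage. The default pseudocount is 1% of the
#' control track's mean non-zero value, a scale-aware guard against
#' division blow-ups where the control is empty; pass an explicit value to
#' override.
#'
#' @param signal,control `coverage_track` objects on the same layout.
#' @param pseudocount positive real added to both tracks; `NULL` for the
#'   scale-aware default.
#' @return A `coverage_track` of per-base ratios.
#' @export
fold_enrichment_track <- function(signal, control, pseudocount = NULL) {
  if (!identical(names(signal$values), names(control$values)))
    stop("signal and control tracks cover different chromosome sets")
  if (is.null(pseudocount)) {
    nz_sum <- track_total(control)
    nz_n <- sum(vapply(control$values, function(v) sum(as.numeric(v > 0)), 0))
    pseudocount <- if (nz_n > 0) 0.01 * nz_sum / nz_n else 1
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("'pseudocount' must be > 0")
  ratio <- (signal$values + pseudocount) / (control$values + pseudocount)
  coverage_track(ratio, signal$layout)
}
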