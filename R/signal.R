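#' Extract a features-by-bins signal matrix
#'
#' For every feature, retrieves the mean per-base track value in fixed
#' `bin_size` windows across the upstream flank, in `body_bins` equal-width
#' segments across the feature body (features of any length are scaled to
#' the same number of body bins; fractional base boundaries are handled by
#' linear weighting), and in fixed windows across the downstream flank.
#' Flank positions falling outside the chromosome read as 0. When
#' `strand_oriented` is `TRUE`, rows of minus-strand features are reversed
#' so that column 1 is always the 5' end.
#'
#' @param track a `coverage_track`.
#' @param features a `GRanges` of features (rows).
#' @param flank flank size in bp on each side; must be a multiple of
#'   `bin_size`. May be 0.
#' @param bin_size flank bin width in bp (default 100).
#' @param body_bins number of equal-width bins the body is scaled to.
#' @param strand_oriented reverse rows of minus-strand features.
#' @return A `signal_matrix`: list with `matrix` (features x bins),
#'   `bin_size`, `flank`, `body_bins`, `strand_oriented` and the `features`.
#' @export
extract_signal_matrix <- function(track, features, flank = 1000L,
                                  bin_size = 100L, body_bins = 10L,
                                  strand_oriented = TRUE) {
  if (bin_size < 1) stop("'bin_size' must be >= 1")
  if (flank < 0 || flank %% bin_size != 0)
    stop("'flank' must be a non-negative multiple of 'bin_size'")
  if (body_bins < 1) stop("'body_bins' must be >= 1")
  missing_chr <- setdiff(unique(as.character(seqnames(features))),
                         names(track$values))
  if (length(missing_chr))
    stop("feature chromosome missing from track: ", missing_chr[1L])
  n_flank <- flank %/% bin_size
  ncol_out <- 2L * n_flank + body_bins
  mat <- matrix(0, nrow = length(features), ncol = ncol_out)
  chroms <- as.character(seqnames(features))
  s0 <- start(features) - 1L
  e0 <- end(features)
  minus <- as.character(strand(features)) == "-"
  for (i in seq_along(features)) {
    v <- .track_window(track, chroms[i], s0[i] - flank, e0[i] + flank)
    up <- if (n_flank > 0)
      colMeans(matrix(v[seq_len(flank)], nrow = bin_size)) else numeric(0)
    dn <- if (n_flank > 0)
      colMeans(matrix(v[(length(v) - flank + 1):length(v)],
                      nrow = bin_size)) else numeric(0)
    body <- .fractional_bin_means(v[(flank + 1):(length(v) - flank)],
                                  body_bins)
    row <- c(up, body, dn)
    if (strand_oriented && minus[i]) row <- rev(row)
    mat[i, ] <- row
  }
  labs <- c(if (n_flank) paste0("u", seq_len(n_flank)),
            paste0("b", seq_len(body_bins)),
            if (n_flank) paste0("d", seq_len(n_flank)))
  colnames(mat) <- labs
  rn <- mcols(features)$name
  if (is.null(rn) || anyNA(rn) || anyDuplicated(rn)) {
    rn <- sprintf("%s:%d-%d", chroms, s0, e0)
  }
  rownames(mat) <- make.unique(rn)
  structure(list(matrix = mat, bin_size = as.integer(bin_size),
                 flank = as.integer(flank), body_bins = as.integer(body_bins),
                 strand_oriented = strand_oriented, features = features),
            class = "signal_matrix")
}

# Mean per-base value over k equal-width (possibly fractional-bp) segments
# of v, via linear interpolation of the cumulative sum.
.fractional_bin_means <- function(v, k) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  C <- function(x) {                       # integral of the step fn on [0,x)
    f <- floor(x)
    frac <- x - f
    add <- ifelse(frac > 0, frac * v[pmin(f + 1, n)], 0)
    cs[f + 1] + add
  }
  edges <- seq(0, n, length.out = k + 1)
  diff(C(edges)) / (n / k)
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", nrow(x$matrix), " features x ", ncol(x$matrix),
      " bins (flank ", x$flank, " bp / bin ", x$bin_size, " bp / body ",
      x$body_bins, " bins)\n", sep = "")
  invisible(x)
}

#' Trimmed-mean signal profile
#'
#' Per bin (column), values beyond the top and bottom `trim_fraction`
#' percentiles are excluded and the rest averaged. Percentiles use the
#' nearest-rank convention: with n rows, the lowest and highest
#' `ceiling(n * trim_fraction / 100)` ranks define the cutoff values and
#' rows strictly outside the closed cutoff band are dropped, so a
#' symmetric trim drops symmetric counts. `trim_fraction = 0` is the
#' ordinary column mean.
#'
#' @param m a `signal_matrix`.
#' @param trim_fraction percentile trimmed from each side, in `[0, 50)`.
#'   Default 0.5.
#' @return A `profile_curve`: list with `profile` (one value per bin) and
#'   the matrix geometry.
#' @export
trimmed_mean_profile <- function(m, trim_fraction = 0.5) {
  if (!is.numeric(trim_fraction) || trim_fraction < 0 || trim_fraction >= 50)
    stop("'trim_fraction' must be in [0, 50)")
  mat <- m$matrix
  if (nrow(mat) == 0) stop("empty signal matrix")
  prof <- apply(mat, 2L, .trimmed_mean, q = trim_fraction / 100)
  structure(list(profile = prof, trim_fraction = trim_fraction,
                 bin_size = m$bin_size, flank = m$flank,
                 body_bins = m$body_bins),
            class = "profile_curve")
}

.trimmed_mean <- function(x, q) {
  n <- length(x)
  k <- ceiling(n * q)
  if (k < 1) return(mean(x))
  s <- sort(x)
  lo <- s[k]
  hi <- s[n + 1 - k]
  mean(x[x >= lo & x <= hi])
}

#' @export
print.profile_curve <- function(x, ...) {
  cat("<profile_curve> ", length(x$profile), " bins, trim ",
      x$trim_fraction, "% each side; peak ",
      format(max(x$profile), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Plot a signal profile curve
#'
#' Minimal base-graphics rendering of a trimmed-mean profile, flanks
#' shaded by vertical guides at the body boundaries.
#'
#' @param x a `profile_curve`.
#' @param ... passed to [graphics::plot()].
#' @exportS3Method graphics::plot
plot.profile_curve <- function(x, ...) {
  n_flank <- x$flank %/% x$bin_size
  graphics::plot(seq_along(x$profile), x$profile, type = "l",
                 xlab = "bin", ylab = "trimmed mean signal", ...)
  if (n_flank > 0)
    graphics::abline(v = c(n_flank + 0.5, n_flank + x$body_bins + 0.5),
                     lty = 2, col = "grey50")
  invisible(x)
}

#' Per-feature mean signal
#'
#' Row-wise mean over the body bins only (flank bins are display context,
#' not part of the feature), one value per feature: the statistic behind
#' per-feature signal boxplots.
#'
#' @param m a `signal_matrix`.
#' @return Named numeric vector, one mean per feature.
#' @export
per_feature_mean <- function(m) {
  if (nrow(m$matrix) == 0) stop("empty signal matrix")
  n_flank <- m$flank %/% m$bin_size
  body <- m$matrix[, (n_flank + 1):(n_flank + m$body_bins), drop = FALSE]
  rowMeans(body)
}

#' Row order by descending mean signal
#'
#' The heatmap row ordering (strongest features first): row indices of a
#' signal matrix sorted by descending row mean over body bins, ties by
#' original order.
#'
#' @param m a `signal_matrix`.
#' @return Integer vector of row indices.
#' @export
signal_row_order <- function(m) {
  order(-per_feature_mean(m), seq_len(nrow(m$matrix)))
}

#' Select the top-k peaks by score
#'
#' The `k` highest-scoring intervals; ties broken by (chrom, start)
#' ascending. `k >= n` returns the full set (sorted by the same rule).
#'
#' @param peaks a `GRanges` with a numeric, non-missing `score` column.
#' @param k number of peaks to keep (>= 1).
#' @return A `GRanges` of the selected peaks.
#' @export
top_k_peaks <- function(peaks, k) {
  sc <- mcols(peaks)$score
  if (is.null(sc) || !is.numeric(sc) || anyNA(sc))
    stop("peaks must carry numeric, non-missing scores")
  if (!is.numeric(k) || length(k) != 1 || k < 1) stop("'k' must be >= 1")
  ord <- order(-sc, as.character(seqnames(peaks)), start(peaks))
  peaks[ord[seq_len(min(k, length(peaks)))]]
}

#' Write a signal matrix as TSV
#'
#' @param m a `signal_matrix`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_signal_matrix <- function(m, path) {
  df <- data.frame(feature = rownames(m$matrix), m$matrix,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
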