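# Naive per-base / enumeration oracles, deliberately independent of the
# package's implementation paths, plus small fixture generators.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# GRanges from 0-based half-open coordinates (BED convention)
gr0 <- function(chrom, start0, end0, layout = NULL, strand = "*", ...) {
  g <- if (is.null(layout))
    GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  else
    GRanges(chrom, IRanges(start0 + 1, end0), strand = strand,
            seqinfo = layout)
  extras <- list(...)
  for (nm in names(extras)) mcols(g)[[nm]] <- extras[[nm]]
  g
}

# random interval set on a single- or multi-chromosome layout
rand_intervals <- function(n, layout, max_width = 500) {
  chroms <- GenomeInfoDb::seqnames(layout)
  L <- GenomeInfoDb::seqlengths(layout)
  ch <- sample(chroms, n, replace = TRUE, prob = L)
  w <- sample.int(max_width, n, replace = TRUE)
  w <- pmin(w, L[ch])
  s0 <- floor(runif(n) * (L[ch] - w + 1))
  gr0(ch, s0, s0 + w, layout)
}

# per-base boolean cover of a GRanges, one logical vector per chromosome
per_base_cover <- function(x, layout) {
  L <- GenomeInfoDb::seqlengths(layout)
  cov <- lapply(L, function(len) logical(len))
  for (i in seq_along(x)) {
    ch <- as.character(seqnames(x))[i]
    cov[[ch]][start(x)[i]:end(x)[i]] <- TRUE
  }
  cov
}

oracle_merge <- function(x, layout) {
  cov <- per_base_cover(x, layout)
  out <- NULL
  for (ch in names(cov)) {
    r <- rle(cov[[ch]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1
    keep <- r$values
    if (any(keep)) {
      g <- GRanges(ch, IRanges(s[keep], e[keep]))
      out <- if (is.null(out)) g else c(out, g)
    }
  }
  if (is.null(out)) out <- GRanges()
  seqinfo(out) <- layout
  out
}

oracle_count_overlapping <- function(query, reference, layout,
                                     min_overlap = 1) {
  cov <- per_base_cover(reference, layout)
  n <- 0L
  for (i in seq_along(query)) {
    ch <- as.character(seqnames(query))[i]
    shared <- sum(cov[[ch]][start(query)[i]:end(query)[i]])
    if (shared >= min_overlap) n <- n + 1L
  }
  n
}

oracle_coverage_fraction <- function(x, layout) {
  cov <- per_base_cover(x, layout)
  sum(vapply(cov, sum, 0)) / sum(as.numeric(GenomeInfoDb::seqlengths(layout)))
}

# exhaustive enumeration of all global alignments (no DP): max score
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) +
                    if (ca[i] == cb[j]) match else mismatch)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(ca), length(cb))
}

# sort-based trimmed mean (nearest-rank cutoffs, strict exclusion)
oracle_trimmed_mean <- function(x, trim_percent) {
  n <- length(x)
  k <- ceiling(n * trim_percent / 100)
  if (k < 1) return(mean(x))
  s <- sort(x)
  mean(x[x >= s[k] & x <= s[n + 1 - k]])
}

# per-base track vector over a whole chromosome
track_vector <- function(track, chrom) as.numeric(track$values[[chrom]])

# per-base signal-matrix row with explicit fractional weights
oracle_signal_row <- function(v_genome, s0, e0, flank, bin_size, body_bins) {
  at <- function(pos0) {                 # value at 0-based position
    if (pos0 < 0 || pos0 >= length(v_genome)) 0 else v_genome[pos0 + 1]
  }
  flank_bins <- function(from0) {
    vapply(seq_len(flank / bin_size), function(b) {
      mean(vapply(seq(from0 + (b - 1) * bin_size,
                      length.out = bin_size), at, 0))
    }, 0)
  }
  up <- if (flank > 0) flank_bins(s0 - flank) else numeric(0)
  dn <- if (flank > 0) flank_bins(e0) else numeric(0)
  W <- e0 - s0
  bw <- W / body_bins
  body <- vapply(seq_len(body_bins), function(b) {
    a <- (b - 1) * bw
    z <- b * bw
    tot <- 0
    for (p in floor(a):ceiling(z - 1e-12)) {   # base p covers [p, p+1)
      lo <- max(a, p); hi <- min(z, p + 1)
      if (hi > lo) tot <- tot + (hi - lo) * at(s0 + p)
    }
    tot / bw
  }, 0)
  c(up, body, dn)
}

# three-way per-base occupancy classification
oracle_occupancy <- function(a_reps, b_reps, support, layout) {
  count_cover <- function(reps) {
    tot <- lapply(GenomeInfoDb::seqlengths(layout), function(l) integer(l))
    for (r in reps) {
      cov <- per_base_cover(reduce(r), layout)
      for (ch in names(tot)) tot[[ch]] <- tot[[ch]] + cov[[ch]]
    }
    tot
  }
  ca <- count_cover(a_reps)
  cb <- count_cover(b_reps)
  out <- list()
  for (ch in names(ca)) {
    pa <- ca[[ch]] >= support
    pb <- cb[[ch]] >= support
    out[[ch]] <- list(a_only = pa & !pb, b_only = pb & !pa,
                      shared = pa & pb)
  }
  out
}

cover_of <- function(gr, layout) per_base_cover(gr, layout)

# per-base widest-interval class assignment, then subset fractions
oracle_repeat_fractions <- function(subset, annotation, layout) {
  ch_lens <- GenomeInfoDb::seqlengths(layout)
  assign <- lapply(ch_lens, function(l) character(l))
  width_at <- lapply(ch_lens, function(l) numeric(l))
  cls <- as.character(mcols(annotation)$class)
  w <- width(annotation)
  for (i in order(-w, cls, seq_along(annotation), decreasing = TRUE)) {
    # iterate so that the *winning* (widest, then class-name) writes last
    ch <- as.character(seqnames(annotation))[i]
    idx <- start(annotation)[i]:end(annotation)[i]
    assign[[ch]][idx] <- cls[i]
    width_at[[ch]][idx] <- w[i]
  }
  sub_cov <- per_base_cover(subset, layout)
  tot <- sum(vapply(sub_cov, sum, 0))
  classes <- sort(unique(cls))
  fr <- stats::setNames(numeric(length(classes)), classes)
  un <- 0
  for (ch in names(sub_cov)) {
    sel <- sub_cov[[ch]]
    a <- assign[[ch]][sel]
    for (cl in classes) fr[cl] <- fr[cl] + sum(a == cl)
    un <- un + sum(a == "")
  }
  list(fractions = fr / tot, unannotated = un / tot, total_bp = tot)
}
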