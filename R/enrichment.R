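#' Add-one empirical p-value
#'
#' `p = (1 + b) / (1 + N)` where `b` is the number of randomizations whose
#' overlap statistic strictly exceeds the observed one among `N`
#' randomizations. The add-one correction appears in both numerator and
#' denominator, so the minimum attainable p-value is `1 / (N + 1)` (e.g.
#' 0.000999 at N = 1000) and p can never be 0.
#'
#' @param b exceedance count, `0 <= b <= N`.
#' @param N number of randomizations, `>= 1`.
#' @return The empirical p-value in `[1/(1+N), 1]`.
#' @export
empirical_p <- function(b, N) {
  if (!is.numeric(N) || length(N) != 1 || is.na(N) || N < 1 ||
      N != round(N))
    stop("'N' must be a single integer >= 1")
  if (!is.numeric(b) || length(b) != 1 || is.na(b) || b < 0 || b > N ||
      b != round(b))
    stop("'b' must be an integer in 0..N")
  (1 + b) / (1 + N)
}

#' Length-preserving interval randomization
#'
#' Draws one uniform placement per query interval, preserving its length
#' exactly. `same_chromosome` keeps each interval on its own chromosome
#' (preserves chromosome-level composition, the conservative choice for
#' clustered satellites); `genome_wide` picks a chromosome with
#' probability proportional to its number of valid start positions, so a
#' 1-bp interval lands uniformly over the genome. Randomized intervals
#' may overlap each other. Uses R's global RNG stream.
#'
#' @param query a `GRanges`.
#' @param layout a `Seqinfo` layout; defaults to the `seqinfo` of `query`.
#' @param mode `"same_chromosome"` (default) or `"genome_wide"`.
#' @return A `GRanges` of randomized placements (unstranded, no metadata).
#' @export
randomize_intervals <- function(query, layout = NULL,
                                mode = c("same_chromosome", "genome_wide")) {
  mode <- match.arg(mode)
  layout <- .layout_of(query, layout)
  ref <- .randomizer(query, layout, mode)
  pl <- ref$draw()
  GRanges(ref$chrom_names[pl$chrom], IRanges(pl$start0 + 1, width = ref$w),
          seqinfo = layout)
}

# Closure that vector-draws one randomized placement set per call, in the
# representation used by the fast overlap counter.
.randomizer <- function(query, layout, mode) {
  chrom_names <- GenomeInfoDb::seqnames(layout)
  L <- as.numeric(GenomeInfoDb::seqlengths(layout))
  names(L) <- chrom_names
  w <- as.numeric(width(query))
  n <- length(w)
  if (mode == "same_chromosome") {
    ci <- match(as.character(seqnames(query)), chrom_names)
    valid <- L[ci] - w + 1
    if (any(valid < 1))
      stop("interval of length ", w[which(valid < 1)[1L]],
           " does not fit its chromosome")
    draw <- function() {
      list(chrom = ci, start0 = floor(runif(n) * valid))
    }
  } else {
    groups <- split(seq_len(n), w)
    for (g in groups) {
      if (!any(L >= w[g[1L]]))
        stop("interval of length ", w[g[1L]],
             " does not fit any chromosome")
    }
    draw <- function() {
      ci <- integer(n); s0 <- numeric(n)
      for (g in groups) {
        wg <- w[g[1L]]
        valid <- pmax(L - wg + 1, 0)
        idx <- sample.int(length(L), length(g), replace = TRUE,
                          prob = valid)
        ci[g] <- idx
        s0[g] <- floor(runif(length(g)) * valid[idx])
      }
      list(chrom = ci, start0 = s0)
    }
  }
  list(draw = draw, w = w, chrom_names = chrom_names)
}

# Reference set indexed for O(log n) shared-base queries: per chromosome,
# sorted disjoint 0-based runs plus cumulative covered lengths.
.index_reference <- function(reference, layout) {
  chrom_names <- GenomeInfoDb::seqnames(layout)
  ref <- GenomicRanges::reduce(reference, ignore.strand = TRUE)
  by <- split(ranges(ref), factor(as.character(seqnames(ref)),
                                  levels = chrom_names))
  lapply(by, function(r) {
    s0 <- start(r) - 1
    e0 <- as.numeric(end(r))
    list(s0 = as.numeric(s0), e0 = e0, cum0 = c(0, cumsum(e0 - s0)))
  })
}

# Shared bases of intervals (chrom index, 0-based [s0, e0)) with an
# indexed reference; vectorized per chromosome.
.shared_with_index <- function(chrom, s0, e0, index) {
  out <- numeric(length(s0))
  for (k in unique(chrom)) {
    idx <- index[[k]]
    sel <- chrom == k
    if (length(idx$s0) == 0) next
    C <- function(x) {
      j <- findInterval(x, idx$s0)
      res <- numeric(length(x))
      pos <- j > 0
      jj <- j[pos]
      res[pos] <- idx$cum0[jj] +
        pmin(pmax(x[pos] - idx$s0[jj], 0), idx$e0[jj] - idx$s0[jj])
      res
    }
    out[sel] <- C(e0[sel]) - C(s0[sel])
  }
  out
}

#' Expected overlap count under genome-proportional placement
#'
#' `E = |query| x coverage_fraction(reference)`: the expected number of
#' overlapping query intervals if each landed on a uniformly chosen
#' genomic base. This deliberately ignores the finite width of query
#' intervals (a wide interval has a slightly higher true hit
#' probability); the bias is documented, not corrected, because the O/E
#' ratio is defined on the covered-proportion basis.
#'
#' @param query,reference `GRanges` objects; `reference` non-empty.
#' @param layout a `Seqinfo` layout; defaults to the `seqinfo` of `query`.
#' @return Expected overlap count (real).
#' @export
expected_overlap <- function(query, reference, layout = NULL) {
  if (length(reference) == 0)
    stop("empty reference: observed/expected ratio undefined")
  layout <- .layout_of(query, layout)
  length(query) * coverage_fraction(reference, layout)
}

#' Randomization test of peak-feature overlap
#'
#' Computes the observed overlap statistic `O` between query and
#' reference, re-draws the query `N` times with length-preserving uniform
#' placements ([randomize_intervals()] semantics), counts the
#' randomizations whose statistic strictly exceeds `O` (ties do not count
#' against the query), and reports the add-one empirical p-value
#' `(1 + b) / (1 + N)` together with the expected count `E` and the
#' observed/expected ratio. Fully reproducible from `seed`: randomization
#' `i` consumes its own pre-derived RNG substream, so results do not
#' depend on execution order.
#'
#' @param query,reference `GRanges` objects.
#' @param layout a `Seqinfo` layout; defaults to the `seqinfo` of `query`.
#' @param N number of randomizations (default 1000).
#' @param mode randomization mode, see [randomize_intervals()].
#' @param min_overlap minimum shared bases for a query interval to count
#'   as overlapping (default 1).
#' @param seed integer seed for the randomizations.
#' @param statistic `"count"` (number of query intervals with >=
#'   `min_overlap` shared bases; default) or `"bases"` (total shared bp).
#' @return An `enrichment_result`: list with `O`, `E`, `ratio`, `b`, `N`,
#'   `p`, `seed`, `mode`, `min_overlap`, `statistic`, `n_query`.
#' @export
run_enrichment_test <- function(query, reference, layout = NULL, N = 1000L,
                                mode = c("same_chromosome", "genome_wide"),
                                min_overlap = 1L, seed = 1L,
                                statistic = c("count", "bases")) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  min_overlap <- .check_min_overlap(min_overlap)
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N))
    stop("'N' must be a single integer >= 1")
  layout <- .layout_of(query, layout)
  if (length(reference) == 0)
    stop("empty reference: observed/expected ratio undefined")
  index <- .index_reference(reference, layout)
  chrom_names <- GenomeInfoDb::seqnames(layout)

  stat_of <- function(chrom, s0, e0) {
    sh <- .shared_with_index(chrom, s0, e0, index)
    if (statistic == "count") sum(sh >= min_overlap) else sum(sh)
  }
  O <- stat_of(match(as.character(seqnames(query)), chrom_names),
               start(query) - 1, as.numeric(end(query)))

  rnd <- .randomizer(query, layout, mode)
  old_seed <- .save_rng_state()
  on.exit(.restore_rng_state(old_seed))
  set.seed(seed)
  iter_seeds <- sample.int(2147483646L, N)
  Oi <- numeric(N)
  for (i in seq_len(N)) {
    set.seed(iter_seeds[i])
    pl <- rnd$draw()
    Oi[i] <- stat_of(pl$chrom, pl$start0, pl$start0 + rnd$w)
  }
  b <- sum(Oi > O)
  E <- expected_overlap(query, reference, layout)
  structure(list(O = O, E = E, ratio = if (E > 0) O / E else NA_real_,
                 b = b, N = as.integer(N), p = empirical_p(b, N),
                 seed = as.integer(seed), mode = mode,
                 min_overlap = min_overlap, statistic = statistic,
                 n_query = length(query)),
            class = "enrichment_result")
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> O = ", x$O, ", E = ", format(x$E, digits = 4),
      ", O/E = ", format(x$ratio, digits = 4), "\n  b = ", x$b, " of N = ",
      x$N, " randomizations exceed O; p = ", format(x$p, digits = 4),
      " (one-sided, add-one)\n  mode = ", x$mode, ", min_overlap = ",
      x$min_overlap, ", statistic = ", x$statistic, ", seed = ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::as.data.frame
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(O = x$O, E = x$E, ratio = x$ratio, b = x$b, N = x$N, p = x$p,
             seed = x$seed, mode = x$mode, min_overlap = x$min_overlap,
             statistic = x$statistic, n_query = x$n_query)
}
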