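#' Occupancy subsets of two peak-set conditions
#'
#' A peak region is "present" in a condition when it is covered by at
#' least `min_replicate_support` of that condition's (individually merged)
#' replicate peak sets, with one shared base sufficing. The merged
#' supported-peak universe is then partitioned into three disjoint interval
#' sets: present in condition A only, in condition B only, or shared.
#'
#' @param a_replicates,b_replicates lists of `GRanges`, one per replicate.
#' @param min_replicate_support replicates that must support a base
#'   (default 2; must not exceed either condition's replicate count).
#' @param layout a `Seqinfo` layout; defaults to the `seqinfo` of the
#'   first replicate.
#' @return An `occupancy_subsets` object: list with `a_only`, `b_only`,
#'   `shared` (disjoint `GRanges`), the per-condition presence sets and
#'   the support threshold.
#' @export
occupancy_subsets <- function(a_replicates, b_replicates,
                              min_replicate_support = 2L, layout = NULL) {
  if (!length(a_replicates) || !length(b_replicates))
    stop("each condition needs at least one replicate peak set")
  if (min_replicate_support < 1 ||
      min_replicate_support > min(length(a_replicates), length(b_replicates)))
    stop("'min_replicate_support' must be in 1..min(replicate counts)")
  layout <- .layout_of(a_replicates[[1L]], layout)

  presence <- function(reps) {
    cov <- Reduce(`+`, lapply(reps, function(r) {
      r <- GenomicRanges::reduce(r, ignore.strand = TRUE)
      GenomeInfoDb::seqlevels(r) <- GenomeInfoDb::seqnames(layout)
      GenomeInfoDb::seqinfo(r) <- layout
      GenomicRanges::coverage(r)
    }))
    gr <- as(cov >= min_replicate_support, "GRanges")
    sort(gr[mcols(gr)$score])[, NULL]
  }
  pa <- presence(a_replicates)
  pb <- presence(b_replicates)
  shared <- GenomicRanges::intersect(pa, pb, ignore.strand = TRUE)
  a_only <- GenomicRanges::setdiff(pa, pb, ignore.strand = TRUE)
  b_only <- GenomicRanges::setdiff(pb, pa, ignore.strand = TRUE)
  structure(list(a_only = a_only, b_only = b_only, shared = shared,
                 presence_a = pa, presence_b = pb,
                 min_replicate_support = as.integer(min_replicate_support),
                 layout = layout),
            class = "occupancy_subsets")
}

#' @export
print.occupancy_subsets <- function(x, ...) {
  bp <- function(g) sum(as.numeric(width(g)))
  cat("<occupancy_subsets> support >= ", x$min_replicate_support,
      " replicates\n  a_only: ", length(x$a_only), " regions / ",
      bp(x$a_only), " bp\n  b_only: ", length(x$b_only), " regions / ",
      bp(x$b_only), " bp\n  shared: ", length(x$shared), " regions / ",
      bp(x$shared), " bp\n", sep = "")
  invisible(x)
}

# Resolve possibly nested/overlapping class annotations into disjoint
# pieces, each base assigned to the widest covering interval (ties by
# class name, then input order).
.resolve_classes <- function(annotation, class_col = "class") {
  cls <- mcols(annotation)[[class_col]]
  if (is.null(cls)) stop("annotation needs a '", class_col, "' column")
  cls <- as.character(cls)
  pieces <- GenomicRanges::disjoin(annotation, with.revmap = TRUE,
                                   ignore.strand = TRUE)
  rv <- mcols(pieces)$revmap
  w <- width(annotation)
  pick <- vapply(as.list(rv), function(idx) {
    idx[order(-w[idx], cls[idx], idx)][1L]
  }, 0L)
  mcols(pieces)$class <- cls[pick]
  mcols(pieces)$revmap <- NULL
  pieces
}

#' Repeat-class length fractions of occupancy subsets
#'
#' For each subset, the fraction of its total length overlapped by each
#' repeat class. Nested or overlapping annotation intervals are first
#' resolved per base by widest-interval precedence, so classes partition
#' the annotated space and fractions (plus the `unannotated` remainder)
#' sum to one.
#'
#' @param subsets an `occupancy_subsets` object, or a named list of
#'   `GRanges`.
#' @param annotation a `GRanges` with a `class` metadata column.
#' @param class_col name of the class column (default `"class"`).
#' @return A data.frame: one row per subset, one column per class plus
#'   `unannotated` and `total_bp`.
#' @export
repeat_fraction_of_subsets <- function(subsets, annotation,
                                       class_col = "class") {
  if (inherits(subsets, "occupancy_subsets"))
    subsets <- list(a_only = subsets$a_only, b_only = subsets$b_only,
                    shared = subsets$shared)
  pieces <- .resolve_classes(annotation, class_col)
  # enumerate classes from the raw annotation: a class overshadowed
  # everywhere by wider intervals still gets a (zero) column
  classes <- sort(unique(as.character(mcols(annotation)[[class_col]])))
  out <- matrix(0, nrow = length(subsets), ncol = length(classes) + 2,
                dimnames = list(names(subsets),
                                c(classes, "unannotated", "total_bp")))
  for (i in seq_along(subsets)) {
    sub <- GenomicRanges::reduce(subsets[[i]], ignore.strand = TRUE)
    tot <- sum(as.numeric(width(sub)))
    out[i, "total_bp"] <- tot
    if (tot == 0) { out[i, "unannotated"] <- 0; next }
    covered <- 0
    for (cl in classes) {
      ov <- GenomicRanges::intersect(
        sub, pieces[mcols(pieces)$class == cl], ignore.strand = TRUE)
      bp <- sum(as.numeric(width(ov)))
      out[i, cl] <- bp / tot
      covered <- covered + bp
    }
    out[i, "unannotated"] <- (tot - covered) / tot
  }
  as.data.frame(out)
}
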