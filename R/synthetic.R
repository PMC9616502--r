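#' Configuration for the synthetic satellite dataset
#'
#' Bundles and validates every parameter of the generator. The defaults
#' describe the study conditions the package is tested under: a five
#' chromosome genome in which two chromosomes carry clustered arrays of
#' factor-bound satellite copies that are long (mean 2500 bp) and lightly
#' diverged (5% substitutions), while unbound copies are scattered
#' genome-wide, shorter (mean 800 bp) and more diverged (15%); peaks cover
#' bound copies; coverage tracks are Poisson-sampled with a configurable
#' enrichment over feature classes ("control" high, "depleted" low) plus a
#' flat IgG-like control; an RNA-like track uses the same machinery over
#' all repeat loci.
#'
#' @param seed integer master seed; it fans out to one deterministic
#'   substream per component (consensus, copies, placement, genome,
#'   peaks, each track, counts), so adding a track never perturbs copy
#'   placement.
#' @param chromosomes named integer vector of chromosome lengths.
#' @param consensus optional DNA string; when `NULL` a random consensus of
#'   `consensus_length` bp is drawn from the consensus substream.
#' @param consensus_length length of the generated consensus (default 300).
#' @param n_bound,n_unbound copy counts per truth class.
#' @param array_chromosomes chromosomes receiving the clustered bound
#'   arrays (default 2 of the 5).
#' @param bound_length_mean,bound_length_sd,unbound_length_mean,unbound_length_sd
#'   per-class copy length distributions in bp (normal, clamped at 50 bp).
#' @param bound_divergence,unbound_divergence per-base substitution
#'   probabilities.
#' @param indel_rate per-base probability of a single-base indel (equal
#'   insertion/deletion split).
#' @param peak_recall fraction of bound copies receiving a peak.
#' @param peak_fpr fraction of unbound copies receiving a spurious peak.
#' @param peak_replicates number of binding-peak replicates.
#' @param depleted_retention fraction of bound copies whose peak survives
#'   in the "depleted" condition peak sets.
#' @param track_specs named list of tracks: each a
#'   `list(features = "bound"|"all", enrichment = factor >= 0)`.
#' @param background_rate mean background coverage per base (> 0).
#' @param library_scale multiplicative library-size scale for tracks.
#' @param min_copy_gap,max_copy_gap inter-copy gap range inside arrays, bp.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    chromosomes = c(chr1 = 300000L, chr2 = 300000L, chr3 = 300000L,
                    chr4 = 300000L, chr5 = 300000L),
    consensus = NULL, consensus_length = 300L,
    n_bound = 100L, n_unbound = 200L,
    array_chromosomes = c("chr2", "chr5"),
    bound_length_mean = 2500, bound_length_sd = 200,
    unbound_length_mean = 800, unbound_length_sd = 200,
    bound_divergence = 0.05, unbound_divergence = 0.15,
    indel_rate = 0.002,
    peak_recall = 1, peak_fpr = 0, peak_replicates = 2L,
    depleted_retention = 0.4,
    track_specs = list(
      H3K9me3_control = list(features = "bound", enrichment = 8),
      H3K9me3_depleted = list(features = "bound", enrichment = 3),
      IgG = list(features = "bound", enrichment = 1),
      RNA_control = list(features = "all", enrichment = 2),
      RNA_depleted = list(features = "all", enrichment = 6)),
    background_rate = 2, library_scale = 1,
    min_copy_gap = 200L, max_copy_gap = 2000L) {
  cfg <- list(seed = as.integer(seed), chromosomes = chromosomes,
              consensus = consensus,
              consensus_length = as.integer(consensus_length),
              n_bound = as.integer(n_bound),
              n_unbound = as.integer(n_unbound),
              array_chromosomes = array_chromosomes,
              bound_length_mean = bound_length_mean,
              bound_length_sd = bound_length_sd,
              unbound_length_mean = unbound_length_mean,
              unbound_length_sd = unbound_length_sd,
              bound_divergence = bound_divergence,
              unbound_divergence = unbound_divergence,
              indel_rate = indel_rate, peak_recall = peak_recall,
              peak_fpr = peak_fpr,
              peak_replicates = as.integer(peak_replicates),
              depleted_retention = depleted_retention,
              track_specs = track_specs,
              background_rate = background_rate,
              library_scale = library_scale,
              min_copy_gap = as.integer(min_copy_gap),
              max_copy_gap = as.integer(max_copy_gap))
  .validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

.validate_synthetic_config <- function(cfg) {
  probs <- c("bound_divergence", "unbound_divergence", "indel_rate",
             "peak_recall", "peak_fpr", "depleted_retention")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      stop("'", p, "' must be a probability in [0, 1]")
  }
  pos <- c("bound_length_mean", "unbound_length_mean", "background_rate",
           "library_scale", "consensus_length")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop("'", p, "' must be > 0")
  }
  if (is.null(names(cfg$chromosomes)) || any(cfg$chromosomes <= 0))
    stop("'chromosomes' must be a named vector of positive lengths")
  if (!all(cfg$array_chromosomes %in% names(cfg$chromosomes)))
    stop("'array_chromosomes' must be a subset of the chromosome names")
  if (cfg$n_bound < 1 || cfg$n_unbound < 1)
    stop("need at least one copy per truth class")
  if (!is.null(cfg$consensus) &&
      grepl("[^ACGT]", toupper(as.character(cfg$consensus))))
    stop("'consensus' must be an ACGT string")
  for (ts in cfg$track_specs) {
    if (!is.list(ts) || is.null(ts$enrichment) || ts$enrichment < 0 ||
        !ts$features %in% c("bound", "all"))
      stop("each track spec needs features in {bound, all} and ",
           "enrichment >= 0")
  }
  invisible(cfg)
}

.BASES <- c("A", "C", "G", "T")

#' Mutate a satellite copy away from its consensus
#'
#' Builds a sequence by tandem repetition of the consensus truncated to
#' `target_length`, then applies i.i.d. substitutions (each mutated base
#' becomes one of the three other bases, uniformly) and single-base
#' indels with equal insertion/deletion probability. Uses R's global RNG
#' stream. The realized substitution count is returned so the generator
#' can record the true per-copy divergence.
#'
#' @param consensus non-empty ACGT string.
#' @param substitution_p,indel_rate per-base probabilities in `[0, 1]`.
#' @param target_length length in bp of the pre-indel template (>= 1).
#' @return A list: `sequence` (DNA string), `substitutions` (realized
#'   count), `template_length`.
#' @export
mutate_from_consensus <- function(consensus, substitution_p, indel_rate,
                                  target_length) {
  consensus <- toupper(as.character(consensus))
  if (!nzchar(consensus)) stop("'consensus' must be non-empty")
  if (target_length < 1) stop("'target_length' must be >= 1")
  if (substitution_p < 0 || substitution_p > 1 ||
      indel_rate < 0 || indel_rate > 1)
    stop("probabilities must be in [0, 1]")
  n <- as.integer(target_length)
  reps <- ceiling(n / nchar(consensus))
  chars <- strsplit(strrep(consensus, reps), "", fixed = TRUE)[[1L]][1:n]

  sub_idx <- which(runif(n) < substitution_p)
  if (length(sub_idx)) {
    cur <- match(chars[sub_idx], .BASES)
    shift <- sample.int(3L, length(sub_idx), replace = TRUE)
    chars[sub_idx] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  }

  u <- runif(n)
  del <- u < indel_rate / 2
  ins <- u >= indel_rate / 2 & u < indel_rate
  ins_pos <- which(ins)
  if (length(ins_pos) || any(del)) {
    ins_bases <- .BASES[sample.int(4L, length(ins_pos), replace = TRUE)]
    keep_pos <- which(!del)
    all_pos <- c(ins_pos - 0.5, keep_pos)
    all_chars <- c(ins_bases, chars[keep_pos])
    chars <- all_chars[order(all_pos)]
  }
  list(sequence = paste(chars, collapse = ""),
       substitutions = length(sub_idx), template_length = n)
}

#' Simulate a Poisson coverage track
#'
#' Per-base expected coverage is `background_rate` outside the feature
#' set and `background_rate * enrichment` inside it; counts are sampled
#' independently per base from a Poisson, run-length encoded, and
#' multiplied by `library_scale`. Uses R's global RNG stream; a fixed
#' seed gives a byte-identical bedGraph.
#'
#' @param features a `GRanges` of enriched features.
#' @param enrichment fold enrichment inside features (>= 0).
#' @param background_rate mean background coverage per base (> 0).
#' @param library_scale multiplicative scale applied to sampled counts.
#' @param layout a `Seqinfo` layout; defaults to the `seqinfo` of
#'   `features`.
#' @return A `coverage_track`.
#' @export
simulate_coverage_track <- function(features, enrichment,
                                    background_rate = 1, library_scale = 1,
                                    layout = NULL) {
  if (enrichment < 0) stop("'enrichment' must be >= 0")
  if (background_rate <= 0) stop("'background_rate' must be > 0")
  layout <- .layout_of(features, layout)
  feats <- GenomicRanges::reduce(features, ignore.strand = TRUE)
  GenomeInfoDb::seqlevels(feats) <- GenomeInfoDb::seqnames(layout)
  GenomeInfoDb::seqinfo(feats) <- layout
  mask <- GenomicRanges::coverage(feats)
  vals <- S4Vectors::endoapply(mask, function(m) {
    lambda <- background_rate * (1 + (enrichment - 1) * as.numeric(m > 0))
    Rle(rpois(length(lambda), lambda) * library_scale)
  })
  coverage_track(vals, layout)
}

# Derive k deterministic substream seeds from one master seed.
.substream_seeds <- function(seed, k) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  sample.int(2147483646L, k)
}

#' Generate a complete synthetic satellite dataset
#'
#' Draws the consensus, the per-copy sequences (lengths, substitutions,
#' indels), places bound copies in clustered arrays on the array
#' chromosomes and unbound copies genome-wide (all copies disjoint, by
#' rejection sampling with a retry cap), embeds the copies in a random
#' background genome, assigns peaks per replicate and condition, samples
#' the coverage tracks and the per-locus count table, and optionally
#' writes everything to `dir` (FASTA, BED, bedGraph, TSV, chrom.sizes).
#' Fixed seed implies byte-identical outputs.
#'
#' @param cfg a `synthetic_config`.
#' @param dir optional output directory; created if missing.
#' @return A `synthetic_dataset`: list with `layout`, `genome`
#'   (`DNAStringSet`), `repeats` (`GRanges` with `name`, `bound`,
#'   `divergence` truth, `class`), `consensus`, `peaks`
#'   (`$binding` replicate list, `$conditions$control` / `$depleted`
#'   replicate lists), `tracks` (named list of `coverage_track`),
#'   `counts` (data.frame), `truth` (data.frame), `config`, and `files`
#'   (paths, when written).
#' @export
generate_dataset <- function(cfg = synthetic_config(), dir = NULL) {
  if (!inherits(cfg, "synthetic_config")) cfg <- do.call(synthetic_config, cfg)
  layout <- genome_layout(names(cfg$chromosomes), cfg$chromosomes)
  n_tracks <- length(cfg$track_specs)
  ss <- .substream_seeds(cfg$seed, 7L + n_tracks)
  names(ss) <- c("consensus", "copies", "placement", "genome", "peaks",
                 "counts", "spare", names(cfg$track_specs))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))

  # consensus ----------------------------------------------------------
  consensus <- cfg$consensus
  if (is.null(consensus)) {
    set.seed(ss[["consensus"]])
    consensus <- paste(.BASES[sample.int(4L, cfg$consensus_length,
                                         replace = TRUE)], collapse = "")
  } else {
    consensus <- toupper(as.character(consensus))
  }

  # per-copy sequences --------------------------------------------------
  set.seed(ss[["copies"]])
  n_total <- cfg$n_bound + cfg$n_unbound
  bound <- rep(c(TRUE, FALSE), c(cfg$n_bound, cfg$n_unbound))
  target_len <- pmax(50L, round(c(
    rnorm(cfg$n_bound, cfg$bound_length_mean, cfg$bound_length_sd),
    rnorm(cfg$n_unbound, cfg$unbound_length_mean, cfg$unbound_length_sd))))
  sub_p <- ifelse(bound, cfg$bound_divergence, cfg$unbound_divergence)
  muts <- lapply(seq_len(n_total), function(i)
    mutate_from_consensus(consensus, sub_p[i], cfg$indel_rate,
                          target_len[i]))
  seqs <- vapply(muts, `[[`, "", "sequence")
  true_div <- vapply(muts, function(m)
    100 * m$substitutions / m$template_length, 0)
  lens <- nchar(seqs)

  # placement -----------------------------------------------------------
  set.seed(ss[["placement"]])
  placed <- .place_copies(cfg, layout, lens, bound)
  strands <- sample(c("+", "-"), n_total, replace = TRUE)
  repeats <- GRanges(placed$chrom, IRanges(placed$start0 + 1,
                                           width = lens),
                     strand = strands, seqinfo = layout)
  mcols(repeats)$name <- sprintf("rep_%04d", seq_len(n_total))
  mcols(repeats)$bound <- bound
  mcols(repeats)$divergence <- true_div
  mcols(repeats)$class <- "satellite"

  # genome --------------------------------------------------------------
  set.seed(ss[["genome"]])
  genome <- DNAStringSet(vapply(
    GenomeInfoDb::seqnames(layout), function(ch)
      paste(.BASES[sample.int(4L, GenomeInfoDb::seqlengths(layout)[[ch]],
                              replace = TRUE)], collapse = ""),
    "", USE.NAMES = TRUE))
  embedded <- ifelse(strands == "-",
                     vapply(seqs, function(s) as.character(
                       reverseComplement(DNAString(s))), ""),
                     seqs)
  for (ch in unique(placed$chrom)) {
    sel <- placed$chrom == ch
    genome[[ch]] <- Biostrings::replaceAt(
      genome[[ch]],
      IRanges(placed$start0[sel] + 1, width = lens[sel]),
      DNAStringSet(embedded[sel]))
  }

  # peaks ---------------------------------------------------------------
  set.seed(ss[["peaks"]])
  base_peaks <- granges(repeats)
  binding <- lapply(seq_len(cfg$peak_replicates), function(r) {
    take <- ifelse(bound, runif(n_total) < cfg$peak_recall,
                   runif(n_total) < cfg$peak_fpr)
    pk <- base_peaks[take]
    strand(pk) <- "*"
    mcols(pk)$name <- sprintf("peak_r%d_%04d", r, seq_len(sum(take)))
    mcols(pk)$score <- rpois(sum(take), 100) + 1
    pk
  })
  control_set <- base_peaks[bound]
  strand(control_set) <- "*"
  n_keep <- round(cfg$depleted_retention * cfg$n_bound)
  depleted_set <- sort(control_set[sample.int(cfg$n_bound, n_keep)])
  conditions <- list(
    control = rep(list(control_set), cfg$peak_replicates),
    depleted = rep(list(depleted_set), cfg$peak_replicates))

  # tracks --------------------------------------------------------------
  tracks <- list()
  for (nm in names(cfg$track_specs)) {
    spec <- cfg$track_specs[[nm]]
    feats <- if (spec$features == "bound") repeats[bound] else repeats
    set.seed(ss[[nm]])
    tracks[[nm]] <- simulate_coverage_track(
      feats, spec$enrichment, cfg$background_rate, cfg$library_scale,
      layout)
  }

  # counts --------------------------------------------------------------
  set.seed(ss[["counts"]])
  rna <- cfg$track_specs[vapply(cfg$track_specs, function(s)
    s$features == "all", TRUE)]
  lam <- function(enr) cfg$background_rate * enr * lens / 100
  counts <- data.frame(name = mcols(repeats)$name, length = lens)
  if (length(rna) >= 2) {
    counts$count_control <- rpois(n_total, lam(rna[[1L]]$enrichment))
    counts$count_depleted <- rpois(n_total, lam(rna[[2L]]$enrichment))
  } else {
    counts$count <- rpois(n_total, lam(1))
  }

  truth <- data.frame(
    name = mcols(repeats)$name,
    chrom = as.character(seqnames(repeats)),
    start = start(repeats) - 1L, end = end(repeats),
    strand = strands, length = lens, bound = bound,
    divergence = true_div)

  ds <- structure(list(layout = layout, genome = genome, repeats = repeats,
                       consensus = consensus, peaks = list(
                         binding = binding, conditions = conditions),
                       tracks = tracks, counts = counts, truth = truth,
                       config = cfg, files = NULL),
                  class = "synthetic_dataset")
  if (!is.null(dir)) ds$files <- .write_dataset(ds, dir)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> seed ", x$config$seed, ": ",
      length(x$genome), " chromosomes (",
      format(genome_size(x$layout), big.mark = ","), " bp), ",
      sum(mcols(x$repeats)$bound), " bound + ",
      sum(!mcols(x$repeats)$bound), " unbound copies, ",
      length(x$tracks), " tracks\n", sep = "")
  invisible(x)
}

# Disjoint placement: bound copies as clustered arrays on the array
# chromosomes, unbound copies scattered by rejection sampling.
.place_copies <- function(cfg, layout, lens, bound) {
  chrom_names <- GenomeInfoDb::seqnames(layout)
  L <- as.numeric(GenomeInfoDb::seqlengths(layout))
  names(L) <- chrom_names
  n <- length(lens)
  chrom <- character(n)
  start0 <- numeric(n)

  bi <- which(bound)
  arr <- cfg$array_chromosomes
  per <- split(bi, rep_len(seq_along(arr), length(bi)))
  occupied <- stats::setNames(
    rep(list(data.frame(s = numeric(0), e = numeric(0))), length(L)),
    chrom_names)
  for (k in seq_along(arr)) {
    ch <- arr[k]
    idx <- per[[k]]
    gaps <- sample(cfg$min_copy_gap:cfg$max_copy_gap, length(idx),
                   replace = TRUE)
    total <- sum(lens[idx]) + sum(gaps)
    if (total > L[ch])
      stop("bound array does not fit ", ch, ": requires ", total,
           " bp but only ", L[ch], " bp available")
    origin <- floor(runif(1) * (L[ch] - total + 1))
    s <- origin + cumsum(as.numeric(gaps)) +
      c(0, cumsum(as.numeric(lens[idx])))[seq_along(idx)]
    chrom[idx] <- ch
    start0[idx] <- s
    occupied[[ch]] <- data.frame(s = s, e = s + lens[idx])
  }

  ui <- which(!bound)
  for (i in ui) {
    w <- lens[i]
    ok <- FALSE
    for (try in seq_len(200L)) {
      ci <- sample.int(length(L), 1L, prob = pmax(L - w + 1, 0))
      ch <- chrom_names[ci]
      s <- floor(runif(1) * (L[ch] - w + 1))
      occ <- occupied[[ch]]
      if (!nrow(occ) || !any(s < occ$e & s + w > occ$s)) {
        chrom[i] <- ch
        start0[i] <- s
        occupied[[ch]] <- rbind(occ, data.frame(s = s, e = s + w))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place all copies: ", sum(lens), " bp requested in a ",
           sum(L), " bp genome; increase chromosome lengths")
  }
  list(chrom = chrom, start0 = start0)
}

.write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  files <- list()
  files$chrom_sizes <- write_chrom_sizes(ds$layout, p("genome.chrom.sizes"))
  writeXStringSet(ds$genome, p("genome.fa"))
  files$genome <- p("genome.fa")
  writeXStringSet(DNAStringSet(c(consensus = ds$consensus)),
                  p("consensus_truth.fa"))
  files$consensus <- p("consensus_truth.fa")

  rep_out <- ds$repeats
  mcols(rep_out)$score <- 0
  mcols(rep_out)$label <- ifelse(mcols(rep_out)$bound, "bound", "unbound")
  files$repeats <- write_bed(rep_out, p("repeats.bed"),
                             extra_cols = c("label", "divergence"))
  for (r in seq_along(ds$peaks$binding))
    files[[paste0("peaks_binding_rep", r)]] <-
      write_bed(ds$peaks$binding[[r]], p(sprintf("peaks_binding_rep%d.bed", r)))
  for (cond in names(ds$peaks$conditions))
    for (r in seq_along(ds$peaks$conditions[[cond]]))
      files[[paste0("peaks_", cond, "_rep", r)]] <-
        write_bed(ds$peaks$conditions[[cond]][[r]],
                  p(sprintf("peaks_%s_rep%d.bed", cond, r)))
  for (nm in names(ds$tracks))
    files[[paste0("track_", nm)]] <-
      write_bedgraph(ds$tracks[[nm]], p(paste0(nm, ".bedGraph")))
  write.table(ds$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files$truth <- p("truth.tsv")
  write.table(ds$counts, p("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files$counts <- p("counts.tsv")
  files
}
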