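lay <- genome_layout("chr1", 50000)

rand_track <- function(layout = lay, max_val = 20) {
  runs <- rand_intervals(40, layout, max_width = 800)
  mcols(runs)$score <- sample.int(max_val, 40, replace = TRUE)
  coverage_track(runs, layout)
}

test_that("bedGraph tracks round-trip byte-identically", {
  set.seed(51)
  trk <- rand_track()
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(trk, f)
  trk2 <- read_bedgraph(f, lay)
  expect_identical(trk$values, trk2$values)
  f2 <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(trk2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("library scaling rescales the total to one million", {
  set.seed(52)
  trk <- rand_track()
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(trk, f)
  scaled <- read_bedgraph(f, lay, scale_to_million = TRUE)
  expect_equal(track_total(scaled), 1e6)
})

test_that("fold-enrichment equals the per-base ratio oracle", {
  set.seed(53)
  # trivial cases
  sig <- rand_track()
  one <- fold_enrichment_track(sig, sig, pseudocount = 1)
  expect_true(all(vapply(one$values, function(v)
    all(runValue(v) == 1), TRUE)))
  ctl0 <- coverage_track(RleList(chr1 = Rle(0, 50000)), lay)
  sig9 <- coverage_track(RleList(chr1 = Rle(9, 50000)), lay)
  ten <- fold_enrichment_track(sig9, ctl0, pseudocount = 1)
  expect_equal(unique(runValue(ten$values$chr1)), 10)
  # random tracks vs naive per-base computation
  for (i in 1:100) {
    a <- rand_track()
    b <- rand_track()
    fe <- fold_enrichment_track(a, b, pseudocount = 0.5)
    va <- track_vector(a, "chr1"); vb <- track_vector(b, "chr1")
    expect_equal(track_vector(fe, "chr1"), (va + 0.5) / (vb + 0.5),
                 tolerance = 1e-9)
  }
})

test_that("signal matrix cells equal the per-base oracle", {
  set.seed(54)
  # constant track: every cell equals the constant
  const <- coverage_track(RleList(chr1 = Rle(3.5, 50000)), lay)
  feats <- gr0("chr1", c(10000, 30000), c(12000, 30500), lay)
  m <- extract_signal_matrix(const, feats, flank = 500, bin_size = 100,
                             body_bins = 7)
  expect_true(all(abs(m$matrix - 3.5) < 1e-12))
  expect_equal(ncol(m$matrix), 5 + 7 + 5)
  # random step tracks vs fractional-weight oracle
  for (i in 1:100) {
    trk <- rand_track()
    v <- track_vector(trk, "chr1")
    w <- sample(50:900, 1)
    s0 <- sample(0:(50000 - w), 1)
    bb <- sample(3:9, 1)
    m1 <- extract_signal_matrix(trk, gr0("chr1", s0, s0 + w, lay),
                                flank = 300, bin_size = 100,
                                body_bins = bb, strand_oriented = FALSE)
    expect_equal(as.numeric(m1$matrix[1, ]),
                 oracle_signal_row(v, s0, s0 + w, 300, 100, bb),
                 tolerance = 1e-9)
  }
})

test_that("minus-strand rows are reversed when strand-oriented", {
  set.seed(55)
  trk <- rand_track()
  plus <- gr0("chr1", 20000, 21000, lay, strand = "+")
  minus <- gr0("chr1", 20000, 21000, lay, strand = "-")
  mp <- extract_signal_matrix(trk, plus, flank = 400, body_bins = 5)
  mm <- extract_signal_matrix(trk, minus, flank = 400, body_bins = 5)
  expect_equal(as.numeric(mm$matrix[1, ]), rev(as.numeric(mp$matrix[1, ])))
  moff <- extract_signal_matrix(trk, minus, flank = 400, body_bins = 5,
                                strand_oriented = FALSE)
  expect_equal(moff$matrix, mp$matrix)
  # flanks beyond the chromosome edge read as zero
  edge <- gr0("chr1", 0, 500, lay)
  me <- extract_signal_matrix(trk, edge, flank = 300, body_bins = 2)
  expect_equal(as.numeric(me$matrix[1, 1:3]), c(0, 0, 0))
})

test_that("trimmed means follow the nearest-rank sort oracle", {
  m <- list(matrix = matrix(rep(1:10, each = 3), nrow = 3), flank = 0L,
            bin_size = 100L, body_bins = 10L)
  class(m) <- "signal_matrix"
  expect_equal(trimmed_mean_profile(m, 0)$profile,
               unname(colMeans(m$matrix)))
  # identical rows: profile equals the row
  expect_equal(unname(trimmed_mean_profile(m, 10)$profile), as.numeric(1:10))
  # symmetric set, symmetric trim preserves the mean
  mm <- list(matrix = matrix(1:1000, ncol = 1), flank = 0L,
             bin_size = 100L, body_bins = 1L)
  class(mm) <- "signal_matrix"
  expect_equal(unname(trimmed_mean_profile(mm, 0.5)$profile), 500.5)
  # random columns vs sort-based oracle, incl. heavy outlier
  set.seed(56)
  for (i in 1:50) {
    x <- c(rnorm(99), if (i %% 2) 1e6 else rnorm(1))
    mo <- list(matrix = matrix(x, ncol = 1), flank = 0L, bin_size = 100L,
               body_bins = 1L)
    class(mo) <- "signal_matrix"
    tf <- sample(c(0.5, 1, 5, 20), 1)
    expect_equal(unname(trimmed_mean_profile(mo, tf)$profile),
                 oracle_trimmed_mean(x, tf), tolerance = 1e-12)
  }
  expect_error(trimmed_mean_profile(m, 50), "\\[0, 50\\)")
})

test_that("outlier influence under trimming never exceeds the untrimmed case", {
  set.seed(57)
  base <- matrix(rnorm(200 * 4), 200, 4)
  spoiled <- base
  spoiled[1, ] <- 1e5
  for (tf in c(0, 0.5, 2, 10)) {
    mk <- function(mat) structure(list(matrix = mat, flank = 0L,
                                       bin_size = 100L, body_bins = 4L),
                                  class = "signal_matrix")
    delta <- abs(trimmed_mean_profile(mk(spoiled), tf)$profile -
                   trimmed_mean_profile(mk(base), tf)$profile)
    delta0 <- abs(colMeans(spoiled) - colMeans(base))
    expect_true(all(delta <= delta0 + 1e-9))
  }
})

test_that("per-feature means cover body bins only and match the oracle", {
  set.seed(58)
  trk <- rand_track()
  feats <- rand_intervals(30, lay, max_width = 600)
  m <- extract_signal_matrix(trk, feats, flank = 300, body_bins = 5,
                             strand_oriented = FALSE)
  fm <- per_feature_mean(m)
  v <- track_vector(trk, "chr1")
  for (i in seq_along(feats)) {
    row <- oracle_signal_row(v, start(feats)[i] - 1, end(feats)[i],
                             300, 100, 5)
    expect_equal(unname(fm[i]), mean(row[4:8]), tolerance = 1e-9)
  }
  # constant track: the mean is the constant
  const <- coverage_track(RleList(chr1 = Rle(2, 50000)), lay)
  mc <- extract_signal_matrix(const, feats, flank = 300, body_bins = 5)
  expect_true(all(abs(per_feature_mean(mc) - 2) < 1e-12))
})

test_that("top-k selection follows scores with coordinate tie-breaks", {
  pk <- gr0("chr1", c(10, 30, 50), c(20, 40, 60), lay, score = c(5, 3, 9))
  got <- top_k_peaks(pk, 2)
  expect_equal(mcols(got)$score, c(9, 5))
  expect_equal(length(top_k_peaks(pk, 10)), 3L)
  expect_error(top_k_peaks(gr0("chr1", 1, 2, lay), 1), "score")
  # ties resolved by (chrom, start) ascending, against a sort oracle
  set.seed(59)
  n <- 1000
  peaks <- rand_intervals(n, genome_layout(c("chr1", "chr2"),
                                           c(50000, 50000)))
  mcols(peaks)$score <- sample.int(50, n, replace = TRUE)
  k <- 100
  got <- top_k_peaks(peaks, k)
  ord <- order(-mcols(peaks)$score, as.character(seqnames(peaks)),
               start(peaks))
  expect_identical(granges(got), granges(peaks[ord[1:k]]))
})

test_that("occupancy subsets partition the supported universe", {
  a <- gr0("chr1", c(100, 500), c(300, 700), lay)
  b <- gr0("chr1", c(200, 900), c(400, 1000), lay)
  # identical single replicates: all shared
  s1 <- occupancy_subsets(list(a), list(a), 1)
  expect_equal(length(s1$a_only), 0L)
  expect_equal(length(s1$b_only), 0L)
  expect_equal(sum(width(s1$shared)), sum(width(a)))
  # fully disjoint
  s2 <- occupancy_subsets(list(gr0("chr1", 0, 100, lay)),
                          list(gr0("chr1", 200, 300, lay)), 1)
  expect_equal(length(s2$shared), 0L)
  expect_equal(sum(width(s2$a_only)), 100)
  expect_equal(sum(width(s2$b_only)), 100)
  expect_error(occupancy_subsets(list(a), list(b), 2), "replicate")
})

test_that("occupancy subsets match the per-base three-way oracle", {
  set.seed(60)
  lay10 <- genome_layout("chr1", 10000)
  for (i in 1:30) {
    a_reps <- lapply(1:3, function(j) rand_intervals(10, lay10, 400))
    b_reps <- lapply(1:2, function(j) rand_intervals(10, lay10, 400))
    supp <- sample(1:2, 1)
    s <- occupancy_subsets(a_reps, b_reps, supp, lay10)
    o <- oracle_occupancy(a_reps, b_reps, supp, lay10)
    for (nm in c("a_only", "b_only", "shared")) {
      got <- per_base_cover(s[[nm]], lay10)$chr1
      expect_identical(got, o$chr1[[nm]], info = paste(i, nm))
    }
    # disjoint and exhaustive over the supported universe
    expect_equal(sum(width(s$a_only)) + sum(width(s$b_only)) +
                   sum(width(s$shared)),
                 sum(width(merge_intervals(c(s$presence_a, s$presence_b)))))
  }
})

test_that("repeat-class fractions match the per-base precedence oracle", {
  lay10 <- genome_layout("chr1", 10000)
  # subset inside a single class
  ann <- gr0("chr1", c(0, 5000), c(2000, 6000), lay10,
             class = c("LINE", "satellite"))
  sub <- list(x = gr0("chr1", 100, 900, lay10))
  fr <- repeat_fraction_of_subsets(sub, ann)
  expect_equal(fr["x", "LINE"], 1)
  expect_equal(fr["x", "unannotated"], 0)
  # no overlap: everything unannotated
  fr0 <- repeat_fraction_of_subsets(list(x = gr0("chr1", 8000, 9000, lay10)),
                                    ann)
  expect_equal(fr0["x", "unannotated"], 1)
  # random nested annotations vs oracle
  set.seed(61)
  for (i in 1:30) {
    ann <- rand_intervals(15, lay10, 800)
    mcols(ann)$class <- sample(c("LINE", "SINE", "satellite"), 15, TRUE)
    subs <- list(s1 = rand_intervals(8, lay10, 500),
                 s2 = rand_intervals(8, lay10, 500))
    fr <- repeat_fraction_of_subsets(subs, ann)
    for (nm in names(subs)) {
      o <- oracle_repeat_fractions(subs[[nm]], ann, lay10)
      for (cl in names(o$fractions))
        expect_equal(fr[nm, cl], unname(o$fractions[cl]),
                     tolerance = 1e-9, info = paste(i, nm, cl))
      expect_equal(fr[nm, "unannotated"], o$unannotated, tolerance = 1e-9)
      expect_lte(sum(fr[nm, setdiff(colnames(fr), "total_bp")]), 1 + 1e-9)
    }
  }
})

test_that("TPM follows the rate formula and conserves one million", {
  expect_equal(tpm_normalize(5, 100), 1e6)
  expect_equal(tpm_normalize(c(3, 3, 3), c(70, 70, 70)), rep(1e6 / 3, 3))
  expect_equal(tpm_normalize(c(10, 20), c(1000, 4000)),
               c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  set.seed(62)
  cts <- rpois(50, 40)
  lens <- sample(200:5000, 50)
  expect_equal(sum(tpm_normalize(cts, lens)), 1e6)
  expect_error(tpm_normalize(c(0, 0), c(1, 1)), "zero")
})

test_that("-ddCt fold changes follow the 2^-ddCt rule", {
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1)
  expect_equal(ddct_fold_change(19, 15, 20, 15), 2)
  expect_equal(ddct_fold_change(20, 15, 22, 15), 4)
  expect_error(ddct_fold_change(NA, 1, 1, 1), "finite")
})
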