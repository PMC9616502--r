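test_that("add-one empirical p-value is exact at its boundaries", {
  expect_equal(empirical_p(0, 1000), 1 / 1001)       # 0.000999...
  expect_equal(round(empirical_p(0, 1000), 6), 0.000999)
  expect_equal(empirical_p(1000, 1000), 1)
  expect_equal(empirical_p(99, 999), 0.1)
  expect_error(empirical_p(5, 4), "0..N")
  expect_error(empirical_p(0, 0), ">= 1")
  expect_error(empirical_p(-1, 10), "0..N")
})

test_that("randomized placements preserve lengths and fit chromosomes", {
  lay <- genome_layout(c("chr1", "chr2"), c(10000, 4000))
  set.seed(31)
  q <- rand_intervals(100, lay, max_width = 300)
  for (mode in c("same_chromosome", "genome_wide")) {
    r <- randomize_intervals(q, lay, mode = mode)
    expect_equal(sort(width(r)), sort(width(q)))
    expect_true(all(start(r) >= 1))
    expect_true(all(end(r) <= seqlengths(lay)[as.character(seqnames(r))]))
    if (mode == "same_chromosome")
      expect_equal(as.character(seqnames(r)), as.character(seqnames(q)))
  }
  # single valid position is forced
  lay1 <- genome_layout("chr1", 100)
  forced <- randomize_intervals(gr0("chr1", 0, 100, lay1), lay1)
  expect_equal(start(forced), 1)
  expect_equal(end(forced), 100)
  # an interval that fits exactly is fine; one that fits nowhere errors
  lay2 <- genome_layout(c("chrA", "chrB"), c(50, 40))
  fits <- gr0("chrA", 0, 50, lay2)
  expect_equal(width(randomize_intervals(fits, lay2)), 50)
  big <- GRanges("chrA", IRanges(1, 60))
  expect_error(randomize_intervals(big, lay2, mode = "genome_wide"),
               "does not fit")
})

test_that("randomized starts are uniform over valid positions", {
  lay <- genome_layout("chr1", 2000)
  q <- gr0("chr1", 0, 100, lay)   # valid starts 0..1900 (1901 positions)
  set.seed(32)
  starts <- vapply(1:10000, function(i)
    start(randomize_intervals(q, lay)) - 1L, 0L)
  bins <- cut(starts, breaks = seq(0, 1901, length.out = 21),
              include.lowest = TRUE, right = FALSE)
  chi <- stats::chisq.test(table(bins))
  expect_gt(chi$p.value, 0.01)
})

test_that("expected overlap follows the covered-proportion formula", {
  lay <- genome_layout("chr1", 100000)
  q <- rand_intervals(100, lay)
  ref <- gr0("chr1", 0, 5000, lay)       # 5% of the genome
  expect_equal(expected_overlap(q, ref, lay), 5)
  expect_equal(expected_overlap(q, gr0("chr1", 0, 100000, lay), lay), 100)
  expect_error(expected_overlap(q, GRanges(seqinfo = lay), lay),
               "empty reference")
})

test_that("expected overlap matches Monte-Carlo for point queries", {
  lay <- genome_layout(c("chr1", "chr2"), c(60000, 40000))
  set.seed(33)
  ref <- merge_intervals(rand_intervals(40, lay, max_width = 2000))
  npt <- 200
  q <- rand_intervals(npt, lay, max_width = 1)
  q <- GRanges(seqnames(q), IRanges(start(q), width = 1), seqinfo = lay)
  E <- expected_overlap(q, ref, lay)
  set.seed(34)
  iters <- 500                          # 500 x 200 = 1e5 point placements
  O <- vapply(seq_len(iters), function(i)
    count_overlapping(randomize_intervals(q, lay, "genome_wide"), ref),
    0L)
  expect_lt(abs(mean(O) - E) / E, 0.02)
})

test_that("enrichment test fields are consistent and seed-reproducible", {
  lay <- genome_layout("chr1", 100000)
  set.seed(35)
  ref <- rand_intervals(30, lay)
  q <- rand_intervals(20, lay)
  r1 <- run_enrichment_test(q, ref, lay, N = 200, seed = 99)
  r2 <- run_enrichment_test(q, ref, lay, N = 200, seed = 99)
  expect_identical(r1, r2)
  expect_equal(r1$p, (1 + r1$b) / (1 + r1$N))
  expect_gte(r1$p, 1 / (1 + r1$N))
  expect_lte(r1$p, 1)
  expect_equal(r1$ratio, r1$O / r1$E)
  expect_equal(r1$O, count_overlapping(q, ref))
  # degenerate saturation: query = reference = whole-genome tiling
  tile <- gr0("chr1", seq(0, 99999, 1000), seq(1000, 100000, 1000), lay)
  rs <- run_enrichment_test(tile, tile, lay, N = 50, seed = 1)
  expect_equal(rs$O, length(tile))
  expect_equal(rs$b, 0L)
})

test_that("maximal containment forces the minimum attainable p-value", {
  lay <- genome_layout("chr1", 1000000)
  ref <- gr0("chr1", seq(0, 9) * 100000, seq(0, 9) * 100000 + 10000, lay)
  q <- gr0("chr1", seq(0, 9) * 100000 + 4000,
           seq(0, 9) * 100000 + 5000, lay)
  res <- run_enrichment_test(q, ref, lay, N = 1000, seed = 4242)
  expect_equal(res$O, 10L)
  expect_equal(res$b, 0L)
  expect_equal(res$p, 1 / 1001)
})

test_that("null data give calibrated p-values and O/E near 1", {
  lay <- genome_layout("chr1", 100000)
  set.seed(36)
  ref <- merge_intervals(rand_intervals(30, lay, max_width = 1000))
  nrun <- 100
  res <- lapply(seq_len(nrun), function(i) {
    q <- rand_intervals(20, lay, max_width = 1)
    run_enrichment_test(q, ref, lay, N = 100, seed = 1000 + i)
  })
  p <- vapply(res, `[[`, 0, "p")
  ratio <- vapply(res, `[[`, 0, "ratio")
  expect_lt(mean(p <= 0.05), 0.12)
  expect_gt(mean(p <= 0.5), 0.3)
  expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("shared-bases statistic is available behind a flag", {
  lay <- genome_layout("chr1", 10000)
  q <- gr0("chr1", c(0, 5000), c(100, 5100), lay)
  ref <- gr0("chr1", 50, 5050, lay)
  r <- run_enrichment_test(q, ref, lay, N = 10, seed = 1,
                           statistic = "bases")
  expect_equal(r$O, sum(shared_bases(q, ref)))
})
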