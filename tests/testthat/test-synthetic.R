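# small configuration used across generator tests
small_cfg <- function(seed = 1, ...) {
  synthetic_config(
    seed = seed,
    chromosomes = c(chr1 = 60000L, chr2 = 60000L, chr3 = 60000L,
                    chr4 = 60000L, chr5 = 60000L),
    n_bound = 20L, n_unbound = 40L,
    array_chromosomes = c("chr2", "chr5"),
    bound_length_mean = 600, bound_length_sd = 60,
    unbound_length_mean = 300, unbound_length_sd = 40,
    ...)
}

test_that("mutation honours the zero-noise and saturated boundaries", {
  cons <- "ACGTACGTAC"
  set.seed(41)
  m0 <- mutate_from_consensus(cons, 0, 0, 25)
  expect_equal(m0$sequence, substr(strrep(cons, 3), 1, 25))
  expect_equal(m0$substitutions, 0L)
  m1 <- mutate_from_consensus(cons, 1, 0, 30)
  tmpl <- strsplit(strrep(cons, 3), "")[[1]]
  expect_equal(sum(strsplit(m1$sequence, "")[[1]] == tmpl), 0L)
  expect_error(mutate_from_consensus(cons, 0.1, 0, 0), "target_length")
})

test_that("realized mismatch fraction follows the binomial law", {
  cons <- paste(rep("ACGT", 25), collapse = "")   # 100 bp unit
  set.seed(42)
  m <- mutate_from_consensus(cons, 0.05, 0, 10000)
  phat <- m$substitutions / 10000
  expect_lt(abs(phat - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("coverage simulation matches its Poisson design", {
  lay <- genome_layout("chr1", 40000)
  feats <- gr0("chr1", c(5000, 20000), c(11000, 26000), lay)  # 12 kb inside
  set.seed(43)
  trk <- simulate_coverage_track(feats, enrichment = 8,
                                 background_rate = 2, layout = lay)
  v <- track_vector(trk, "chr1")
  inside <- c(5001:11000, 20001:26000)
  r <- mean(v[inside]) / mean(v[-inside])
  expect_gt(r, 6.5)
  expect_lt(r, 9.5)
  # enrichment 1 is a null: difference within 3 SE
  set.seed(44)
  t0 <- simulate_coverage_track(feats, enrichment = 1,
                                background_rate = 2, layout = lay)
  v0 <- track_vector(t0, "chr1")
  se <- sqrt(2 / length(inside) + 2 / (40000 - length(inside)))
  expect_lt(abs(mean(v0[inside]) - mean(v0[-inside])), 3 * se)
})

test_that("a fixed seed reproduces every output byte-identically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(small_cfg(seed = 7), dir = d1)
  generate_dataset(small_cfg(seed = 7), dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  expect_gt(length(f1), 10)
})

test_that("generated annotation matches the configured design", {
  ds <- generate_dataset(small_cfg(seed = 8))
  rep <- ds$repeats
  expect_equal(length(rep), 60L)                       # count contract
  expect_true(all(start(rep) >= 1))
  expect_true(all(end(rep) <=
                    seqlengths(ds$layout)[as.character(seqnames(rep))]))
  # copies are pairwise disjoint
  expect_true(all(width(merge_intervals(rep)) >= 0))
  expect_equal(sum(width(merge_intervals(rep))), sum(width(rep)))
  # bound copies clustered on the array chromosomes
  bnd <- rep[mcols(rep)$bound]
  frac_on_arrays <- mean(as.character(seqnames(bnd)) %in%
                           c("chr2", "chr5"))
  expect_gte(frac_on_arrays, 0.9)
  # genome carries the copy sequences in annotated orientation
  seqs <- extract_repeat_sequences(ds$genome, rep)
  expect_identical(nchar(seqs), width(rep))
  # length means within 3 SE of the configuration
  expect_lt(abs(mean(width(bnd)) - 600), 3 * 60 / sqrt(length(bnd)) + 1)
  ubd <- rep[!mcols(rep)$bound]
  expect_lt(abs(mean(width(ubd)) - 300), 3 * 40 / sqrt(length(ubd)) + 1)
})

test_that("perfect peak recall lets classification recover truth exactly", {
  ds <- generate_dataset(small_cfg(seed = 9, peak_recall = 1, peak_fpr = 0))
  called <- classify_copies(ds$repeats,
                            merge_intervals(ds$peaks$binding[[1]]))
  expect_identical(mcols(called)$bound, ds$truth$bound)
})

test_that("true divergence recorded by the generator is recovered by alignment", {
  ds <- generate_dataset(small_cfg(seed = 10))
  seqs <- extract_repeat_sequences(ds$genome, ds$repeats)
  d <- copy_divergence(seqs, ds$consensus)
  bnd <- ds$truth$bound
  expect_lt(abs(mean(d[bnd]) - 5), 1.5)
  expect_lt(abs(mean(d[!bnd]) - 15), 2.5)
  expect_gt(stats::cor(d, ds$truth$divergence), 0.95)
})

test_that("oversized requests fail with an informative error", {
  cfg <- synthetic_config(chromosomes = c(chr1 = 20000L, chr2 = 20000L),
                          array_chromosomes = "chr1",
                          n_bound = 50L, n_unbound = 10L,
                          bound_length_mean = 2000, bound_length_sd = 10)
  expect_error(generate_dataset(cfg), "does not fit|could not place")
})

test_that("configuration validation rejects bad probabilities and specs", {
  expect_error(synthetic_config(bound_divergence = 1.2), "probability")
  expect_error(synthetic_config(peak_recall = -0.1), "probability")
  expect_error(synthetic_config(background_rate = 0), "> 0")
  expect_error(synthetic_config(array_chromosomes = "chrZ"), "subset")
  expect_error(synthetic_config(track_specs = list(x = list(
    features = "nope", enrichment = 2))), "track spec")
})
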