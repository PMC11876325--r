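test_that("half-open abutment does not count as overlap", {
  q <- interval_set("chr1", 0, 100)
  s <- interval_set("chr1", 100, 200)
  expect_equal(count_overlapping(q, s)$n_overlapping, 0L)
  # one shared base is enough
  s2 <- interval_set("chr1", 99, 200)
  expect_equal(count_overlapping(q, s2)$n_overlapping, 1L)
})

test_that("overlap counting matches the worked toy example", {
  q <- interval_set(c("chr1", "chr1", "chr2"), c(0, 150, 10),
                    c(100, 250, 20))
  s <- interval_set("chr1", 90, 160)
  res <- count_overlapping(q, s)
  expect_equal(res$n_overlapping, 2L)
  expect_equal(res$n_query, 3L)
  expect_equal(res$percent, 200 / 3)
})

test_that("overlap counting equals the all-pairs brute force", {
  set.seed(42)
  for (i in 1:150) {
    qi <- random_instance(sample.int(15, 1L))
    si <- random_instance(sample.int(15, 1L))
    q <- interval_set(qi$chrom, qi$s0, qi$e)
    s <- interval_set(si$chrom, si$s0, si$e)
    expect_equal(count_overlapping(q, s)$n_overlapping,
                 brute_overlap_count(qi$chrom, qi$s0, qi$e,
                                     si$chrom, si$s0, si$e))
  }
})

test_that("adding a subject interval never decreases the overlap count", {
  set.seed(7)
  qi <- random_instance(25)
  q <- interval_set(qi$chrom, qi$s0, qi$e)
  si <- random_instance(12)
  count <- 0L
  for (j in seq_along(si$chrom)) {
    s <- interval_set(si$chrom[1:j], si$s0[1:j], si$e[1:j])
    new <- count_overlapping(q, s)$n_overlapping
    expect_gte(new, count)
    count <- new
  }
})

test_that("joint peaks keep the coordinates of the first set", {
  a <- interval_set(c("chr1", "chr1", "chr2"), c(0, 150, 10), c(100, 250, 20),
                    label = "rad55")
  b <- interval_set("chr1", 90, 160, label = "csm2")
  jp <- joint_peaks(a, b)
  expect_length(jp, 2L)
  expect_equal(GenomicRanges::start(jp), c(1L, 151L))
  expect_equal(S4Vectors::metadata(jp)$label, "rad55 & csm2")
  # disjoint sets give nothing; nested sets give everything
  expect_length(joint_peaks(a, interval_set("chr2", 500, 600)), 0L)
  wide <- interval_set(c("chr1", "chr2"), c(0, 0), c(400, 700))
  expect_length(joint_peaks(a, wide), 3L)
})

test_that("shuffling preserves count, chromosomes and length multiset", {
  set.seed(11)
  gi <- random_instance(30)
  s <- interval_set(gi$chrom, gi$s0, gi$e)
  g <- toy_genome()
  for (mode in c("uniform", "shift")) {
    sh <- shuffle_intervals(s, g, mode = mode)
    expect_length(sh, 30L)
    expect_equal(as.character(GenomeInfoDb::seqnames(sh)),
                 as.character(GenomeInfoDb::seqnames(s)))
    expect_equal(sort(GenomicRanges::width(sh)),
                 sort(GenomicRanges::width(s)))
    expect_true(all(GenomicRanges::start(sh) >= 1))
    expect_true(all(GenomicRanges::end(sh) <=
                      unclass(g)[as.character(GenomeInfoDb::seqnames(sh))]))
  }
})

test_that("an interval as long as its chromosome can only start at 0", {
  g <- ratecov::genome(c(chrA = 500))
  full <- interval_set("chrA", 0, 500)
  set.seed(3)
  sh <- shuffle_intervals(full, g)
  expect_equal(GenomicRanges::start(sh), 1L)
  expect_error(shuffle_intervals(interval_set("chrA", 0, 501), g), "longer")
})

test_that("shuffled start positions are uniform on the chromosome", {
  g <- ratecov::genome(c(chrA = 1000))
  one <- interval_set("chrA", 0, 100)
  set.seed(19)
  starts <- replicate(10000, GenomicRanges::start(shuffle_intervals(one, g)))
  # 901 possible starts binned into 10 cells of near-equal width
  bins <- cut(starts, breaks = seq(0.5, 901.5, length.out = 11))
  expect_gt(suppressWarnings(chisq.test(table(bins))$p.value), 0.001)
})

test_that("a subject covering the whole genome pins the test at p = 1", {
  g <- toy_genome()
  q <- interval_set(c("chr1", "chr2"), c(10, 50), c(200, 300))
  s <- interval_set(c("chr1", "chr2"), c(0, 0), c(1000, 800))
  res <- overlap_permutation_test(q, s, g, n_perm = 200, seed = 4)
  expect_equal(res$observed, 2L)
  expect_true(all(res$null_counts == 2L))
  expect_equal(res$p_empirical, 1)
  expect_true(is.na(res$z))  # degenerate null sd
})

test_that("the permutation test is bit-reproducible and seed-sensitive", {
  set.seed(23)
  gi <- random_instance(40)
  si <- random_instance(15)
  q <- interval_set(gi$chrom, gi$s0, gi$e)
  s <- interval_set(si$chrom, si$s0, si$e)
  g <- toy_genome()
  r1 <- overlap_permutation_test(q, s, g, n_perm = 500, seed = 8)
  r2 <- overlap_permutation_test(q, s, g, n_perm = 500, seed = 8)
  r3 <- overlap_permutation_test(q, s, g, n_perm = 500, seed = 9)
  expect_identical(r1, r2)
  expect_false(identical(r1$null_counts, r3$null_counts))
  # permutation-kernel observed count agrees with the public counter
  expect_equal(r1$observed, count_overlapping(q, s)$n_overlapping)
})

test_that("p-values are invariant to chromosome relabeling", {
  sim <- simulate_genome_with_peaks(
    genome = ratecov::genome(c(c1 = 40000, c2 = 60000)),
    n_features = 20, feature_length = 150, n_peaks = 60, peak_length = 120,
    pi = 0.8, seed = 31)
  g2 <- ratecov::genome(c(alpha = 40000, beta = 60000))
  relabel <- function(gr) {
    map <- c(c1 = "alpha", c2 = "beta")
    interval_set(map[as.character(GenomeInfoDb::seqnames(gr))],
                 GenomicRanges::start(gr) - 1, GenomicRanges::end(gr))
  }
  r1 <- overlap_permutation_test(sim$peaks, sim$features, sim$genome,
                                 n_perm = 400, seed = 6)
  r2 <- overlap_permutation_test(relabel(sim$peaks), relabel(sim$features),
                                 g2, n_perm = 400, seed = 6)
  expect_equal(r1$p_empirical, r2$p_empirical)
  expect_identical(r1$null_counts, r2$null_counts)
})

test_that("planted enrichment is detected; depletion flag flips the tail", {
  sim <- simulate_genome_with_peaks(pi = 0.9, seed = 17)
  res <- overlap_permutation_test(sim$peaks, sim$features, sim$genome,
                                  n_perm = 1000, seed = 18)
  expect_lte(res$p_empirical, 0.01)
  res_dep <- overlap_permutation_test(sim$peaks, sim$features, sim$genome,
                                      n_perm = 1000, seed = 18,
                                      alternative = "less")
  expect_equal(res_dep$p_empirical, 1)
})
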