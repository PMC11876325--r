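rer_from_rows <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), sprintf("b%d", seq_len(ncol(m))))
  m
}

test_that("erc_pair matches a textbook Pearson + Fisher evaluation", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  b <- c(2, 1, 4, 3, 6, 5, 8, 7)
  rer <- rer_from_rows(ga = a, gb = b)
  res <- erc_pair(rer, "ga", "gb", k = 0, min_branches = 5)
  r_hand <- textbook_pearson(a, b)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$n, 8L)
  expect_true(res$valid)
  expect_equal(res$erc, atanh(r_hand) * sqrt(8 - 3), tolerance = 1e-12)
})

test_that("perfect correlation is clamped to keep erc finite", {
  set.seed(2)
  v <- rnorm(20)
  rer <- rer_from_rows(ga = v, gb = v)
  res <- erc_pair(rer, "ga", "gb", k = 0, r_clamp = 1e-6)
  expect_equal(res$erc, atanh(1 - 1e-6) * sqrt(17), tolerance = 1e-12)
})

test_that("zero correlation gives erc exactly zero", {
  rer <- rer_from_rows(ga = c(1, 2, 3, 4), gb = c(1, -1, -1, 1))
  res <- erc_pair(rer, "ga", "gb", k = 0, min_branches = 4)
  expect_equal(res$r, 0)
  expect_equal(res$erc, 0)
})

test_that("erc is antisymmetric under negating one vector", {
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(15)
    b <- rnorm(15)
    rer <- rer_from_rows(ga = a, gb = b, gneg = -b)
    e1 <- erc_pair(rer, "ga", "gb", k = 0)$erc
    e2 <- erc_pair(rer, "ga", "gneg", k = 0)$erc
    expect_equal(e2, -e1, tolerance = 1e-12)
  }
})

test_that("shared branches are those non-missing in both genes", {
  a <- c(1, 2, NA, 4, 5, 6)
  b <- c(6, NA, 3, 2, 1, 0)
  rer <- rer_from_rows(ga = a, gb = b)
  res <- erc_pair(rer, "ga", "gb", k = 0, min_branches = 4)
  expect_equal(res$n, 4L)
  shared <- c(1, 4, 5, 6)
  expect_equal(res$r, textbook_pearson(a[shared], b[shared]),
               tolerance = 1e-12)
  expect_error(erc_pair(rer, "ga", "nope"), "not in RER matrix")
})

test_that("validity rules: branch count and constant vectors", {
  rer <- rer_from_rows(ga = c(1, 2, 3, 4, 5), gb = c(2, 4, 5, 3, 1),
                       gc = rep(1, 5))
  expect_false(erc_pair(rer, "ga", "gb", min_branches = 10)$valid)
  expect_true(is.na(erc_pair(rer, "ga", "gb", min_branches = 10)$erc))
  expect_true(erc_pair(rer, "ga", "gb", k = 0, min_branches = 5)$valid)
  # constant vector has no correlation
  res <- erc_pair(rer, "ga", "gc", k = 0, min_branches = 5)
  expect_false(res$valid)
  expect_true(is.na(res$erc))
  # Winsorization itself can flatten a vector: n = 5 <= 2k+1 with k = 3
  res2 <- erc_pair(rer, "ga", "gb", k = 3, min_branches = 5)
  expect_false(res2$valid)
})

test_that("erc_matrix equals looped erc_pair calls and is symmetric", {
  set.seed(21)
  rer <- matrix(rnorm(10 * 30), 10, 30,
                dimnames = list(sprintf("g%02d", 1:10),
                                sprintf("b%d", 1:30)))
  rer[sample(length(rer), 40)] <- NA
  m <- erc_matrix(rer, k = 3, min_branches = 10)
  expect_true(isSymmetric(m$values))
  expect_true(all(is.na(diag(m$values))))
  for (i in 1:9) for (j in (i + 1):10) {
    res <- erc_pair(rer, rownames(rer)[i], rownames(rer)[j],
                    k = 3, min_branches = 10)
    expect_identical(m$values[i, j],
                     if (res$valid) res$erc else NA_real_)
    expect_identical(m$n_branches[i, j], res$n)
  }
})

test_that("between-set pair enumeration reproduces complex combinatorics", {
  genes <- c(sprintf("shu%d", 1:4), sprintf("cmg%02d", 1:11),
             sprintf("mcm%d", 1:6))
  V <- matrix(rnorm(21 * 21), 21, 21, dimnames = list(genes, genes))
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  diag(V) <- NA
  m <- make_erc_matrix(V)
  shu <- complex_set("SHU", genes[1:4])
  cmg <- complex_set("CMG", genes[5:15])
  mcm <- complex_set("MCM", genes[16:21])
  expect_equal(nrow(between_set_values(m, shu, cmg)), 44L)
  expect_equal(nrow(between_set_values(m, shu, mcm)), 24L)
  # within-set: C(3,2) unordered pairs
  trio <- complex_set("T", genes[1:3])
  expect_equal(nrow(between_set_values(m, trio, trio)), 3L)
  # overlapping sets de-duplicate
  ab <- complex_set("AB", genes[1:4])
  cd <- complex_set("CD", genes[3:6])
  pairs <- between_set_values(m, ab, cd)
  # 16 crossings minus 2 self-pairs minus the duplicated (g3,g4)/(g4,g3)
  expect_equal(nrow(pairs), 13L)
  key <- with(pairs, ifelse(gene_a < gene_b, paste(gene_a, gene_b),
                            paste(gene_b, gene_a)))
  expect_false(any(duplicated(key)))
  expect_warning(
    between_set_values(m, complex_set("X", c(genes[1], "ghost")), cmg),
    "absent")
})

test_that("sampled permutation p converges to the exhaustive-null p", {
  set.seed(77)
  genes <- sprintf("g%d", 1:7)
  V <- matrix(rnorm(49, sd = 1), 7, 7, dimnames = list(genes, genes))
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  diag(V) <- NA
  m <- make_erc_matrix(V)
  a <- complex_set("A", genes[1:2])
  b <- complex_set("B", genes[3:4])
  universe <- genes[3:7]

  observed <- mean(V[1:2, 3:4])
  subsets <- utils::combn(universe, 2, simplify = FALSE)
  null_ex <- vapply(subsets, function(s) mean(V[1:2, s]), numeric(1))
  # exhaustive exceedance fraction; the sampled estimate converges to it
  # (the +1 corrections on both sides shrink as O(1/n))
  frac_ex <- mean(null_ex >= observed)

  n_perm <- 4000L
  res <- complex_permutation_test(m, a, b, n_perm = n_perm, seed = 5)
  expect_equal(res$observed_stat, observed, tolerance = 1e-12)
  expect_lt(abs(res$p_empirical - frac_ex),
            2 / sqrt(n_perm) + 2 / (n_perm + 1))
})

test_that("an observed value above every null gives the +1-corrected floor", {
  genes <- sprintf("g%d", 1:12)
  V <- matrix(0, 12, 12, dimnames = list(genes, genes))
  V[1:3, 4:6] <- 10; V[4:6, 1:3] <- 10  # a-b pairs dominate everything
  diag(V) <- NA
  m <- make_erc_matrix(V)
  # universe restricted to background genes: by default b's members may
  # re-enter the null, which here would occasionally re-draw b itself
  res <- complex_permutation_test(m, complex_set("A", genes[1:3]),
                                  complex_set("B", genes[4:6]),
                                  n_perm = 1000, seed = 3,
                                  universe = genes[7:12])
  expect_equal(res$p_empirical, 1 / 1001)
  expect_equal(res$n_pairs, 9L)
})

test_that("permutation test is reproducible and validates its universe", {
  set.seed(14)
  genes <- sprintf("g%d", 1:8)
  V <- matrix(rnorm(64), 8, 8, dimnames = list(genes, genes))
  V[lower.tri(V)] <- t(V)[lower.tri(V)]
  diag(V) <- NA
  m <- make_erc_matrix(V)
  a <- complex_set("A", genes[1:5])
  b <- complex_set("B", genes[6:8])
  r1 <- complex_permutation_test(m, a, b, n_perm = 200, seed = 9)
  r2 <- complex_permutation_test(m, a, b, n_perm = 200, seed = 9)
  expect_identical(r1, r2)
  expect_error(
    complex_permutation_test(m, complex_set("A", genes[1:6]),
                             complex_set("B", genes[7:8]),
                             universe = genes[7L]),
    "universe")
})
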