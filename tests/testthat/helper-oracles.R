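# Independent oracles used across tests. These deliberately avoid the code
# paths they are checking.

# all-pairs interval overlap count: how many of (chrom, s0, e) query rows
# share >= 1 base with any subject row, using raw 0-based half-open arithmetic
brute_overlap_count <- function(qc, qs0, qe, sc, ss0, se) {
  hits <- 0L
  for (i in seq_along(qc)) {
    any_hit <- FALSE
    for (j in seq_along(sc)) {
      if (qc[i] == sc[j] && qs0[i] < se[j] && ss0[j] < qe[i]) {
        any_hit <- TRUE
        break
      }
    }
    if (any_hit) hits <- hits + 1L
  }
  hits
}

# textbook Pearson correlation from first principles
textbook_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# hand-rolled erc_matrix object for permutation-machinery tests
make_erc_matrix <- function(values, n_branches = NULL) {
  genes <- rownames(values)
  if (is.null(n_branches))
    n_branches <- matrix(20L, nrow(values), ncol(values),
                         dimnames = dimnames(values))
  structure(list(genes = genes, values = values, n_branches = n_branches,
                 k = 3L, min_branches = 10L, r_clamp = 1e-6),
            class = "erc_matrix")
}

# small genome for interval tests
toy_genome <- function() ratecov::genome(c(chr1 = 1000, chr2 = 800))

# random small interval-set instance as raw BED-style vectors
random_instance <- function(n, chroms = c("chr1", "chr2"), L = 1000,
                            max_w = 120) {
  chrom <- sample(chroms, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  s0 <- vapply(w, function(wi) sample.int(L - wi + 1, 1L) - 1L, integer(1))
  list(chrom = chrom, s0 = s0, e = s0 + w)
}
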