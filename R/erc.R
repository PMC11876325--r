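#' Evolutionary rate covariation between two genes
#'
#' Restricts both genes' RER vectors to their shared branches (non-missing in
#' both), Winsorizes each restricted vector, computes the Pearson correlation
#' r, and returns the Fisher-transformed, branch-count-scaled statistic
#' \deqn{erc = \mathrm{atanh}(r)\sqrt{n - 3}}
#' which is approximately standard normal under independence, so values from
#' pairs with different shared-branch counts are directly comparable and the
#' range is the whole real line rather than [-1, 1]. r is clamped to
#' \eqn{[-1 + r_{clamp},\ 1 - r_{clamp}]} before the transform so erc stays
#' finite.
#'
#' A pair is \code{valid} only when it has at least \code{min_branches}
#' shared branches, more than 3 (so the scale factor is real and positive),
#' and both Winsorized vectors are non-constant; invalid pairs carry
#' \code{erc = NA}.
#'
#' @param rer RER matrix (genes x branches, NA missing).
#' @param gene_a,gene_b Gene identifiers (rownames of \code{rer}).
#' @param k Winsorization depth per tail (default 3).
#' @param min_branches Minimum shared branches for a valid pair (default 10).
#' @param r_clamp Distance from +/-1 at which r is clamped (default 1e-6).
#' @return An \code{erc_result}: list with \code{gene_a}, \code{gene_b},
#'   \code{r}, \code{n}, \code{erc}, \code{valid}.
#' @export
erc_pair <- function(rer, gene_a, gene_b, k = 3L, min_branches = 10L,
                     r_clamp = 1e-6) {
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(rer)) stop("gene '", g, "' not in RER matrix",
                                    call. = FALSE)
  va <- rer[gene_a, ]
  vb <- rer[gene_b, ]
  shared <- which(!is.na(va) & !is.na(vb))
  res <- .erc_core(va[shared], vb[shared], k, min_branches, r_clamp)
  structure(c(list(gene_a = gene_a, gene_b = gene_b), res),
            class = "erc_result")
}

# shared-branch vectors already restricted; returns r, n, erc, valid
.erc_core <- function(a, b, k, min_branches, r_clamp) {
  n <- length(a)
  r <- NA_real_
  if (n >= 2L) {
    wa <- winsorize(a, k)
    wb <- winsorize(b, k)
    if (stats::sd(wa) > 0 && stats::sd(wb) > 0)
      r <- stats::cor(wa, wb)
  }
  valid <- n >= min_branches && n > 3L && !is.na(r)
  erc <- NA_real_
  if (valid) {
    rc <- min(max(r, -1 + r_clamp), 1 - r_clamp)
    erc <- atanh(rc) * sqrt(n - 3)
  }
  list(r = r, n = n, erc = erc, valid = valid)
}

#' @export
print.erc_result <- function(x, ...) {
  cat(sprintf("erc_result %s ~ %s: r = %.4f over n = %d branches, erc = %s%s\n",
              x$gene_a, x$gene_b, x$r, x$n,
              ifelse(is.na(x$erc), "NA", sprintf("%.4f", x$erc)),
              if (x$valid) "" else " (invalid)"))
  invisible(x)
}

#' All-pairs ERC matrix
#'
#' Computes \code{\link{erc_pair}} for every unordered pair of the requested
#' genes. The diagonal is NA (a gene against itself is undefined), and the
#' matrix is symmetric by construction.
#'
#' @param rer RER matrix.
#' @param genes Genes to include (default: all rows of \code{rer}).
#' @inheritParams erc_pair
#' @return An \code{erc_matrix}: list with \code{genes}, \code{values}
#'   (symmetric gene x gene erc, NA diagonal and NA where invalid) and
#'   \code{n_branches} (symmetric shared-branch counts).
#' @export
erc_matrix <- function(rer, genes = rownames(rer), k = 3L, min_branches = 10L,
                       r_clamp = 1e-6) {
  missing <- setdiff(genes, rownames(rer))
  if (length(missing))
    stop("gene '", missing[1L], "' not in RER matrix", call. = FALSE)
  g <- length(genes)
  sub <- rer[genes, , drop = FALSE]
  pres <- !is.na(sub)
  values <- matrix(NA_real_, g, g, dimnames = list(genes, genes))
  nb <- matrix(0L, g, g, dimnames = list(genes, genes))
  if (g >= 2L) {
    for (i in seq_len(g - 1L)) {
      vi <- sub[i, ]
      pi_ <- pres[i, ]
      for (j in (i + 1L):g) {
        shared <- which(pi_ & pres[j, ])
        res <- .erc_core(vi[shared], sub[j, shared], k, min_branches, r_clamp)
        values[i, j] <- values[j, i] <- res$erc
        nb[i, j] <- nb[j, i] <- res$n
      }
    }
  }
  structure(list(genes = genes, values = values, n_branches = nb,
                 k = as.integer(k), min_branches = as.integer(min_branches),
                 r_clamp = r_clamp),
            class = "erc_matrix")
}

#' @export
print.erc_matrix <- function(x, ...) {
  cat("erc_matrix:", length(x$genes), "genes,",
      sum(!is.na(x$values[upper.tri(x$values)])), "valid pairs\n")
  invisible(x)
}

#' Between-set ERC values
#'
#' Enumerates every unordered pair with one member in complex \code{a} and
#' one in complex \code{b} (self-pairs excluded; pairs are de-duplicated when
#' the complexes share members) and extracts their erc values from the
#' matrix. This is the "each dot is one protein pair" layout used to compare
#' a query complex against another complex.
#'
#' @param m An \code{erc_matrix}.
#' @param a,b \code{complex_set} objects.
#' @param warn_absent Warn about members absent from the matrix (dropped).
#' @return Data frame with columns \code{gene_a}, \code{gene_b}, \code{erc},
#'   \code{n_branches}; one row per pair.
#' @export
between_set_values <- function(m, a, b, warn_absent = TRUE) {
  stopifnot(inherits(m, "erc_matrix"),
            inherits(a, "complex_set"), inherits(b, "complex_set"))
  am <- intersect(a$members, m$genes)
  bm <- intersect(b$members, m$genes)
  absent <- setdiff(union(a$members, b$members), m$genes)
  if (length(absent) && warn_absent)
    warning("dropped members absent from matrix: ",
            paste(absent, collapse = ", "), call. = FALSE)
  pairs <- expand.grid(gene_a = am, gene_b = bm, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  key <- ifelse(pairs$gene_a < pairs$gene_b,
                paste(pairs$gene_a, pairs$gene_b),
                paste(pairs$gene_b, pairs$gene_a))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  if (nrow(pairs) == 0L)
    stop("no pairs between '", a$name, "' and '", b$name, "'", call. = FALSE)
  idx <- cbind(match(pairs$gene_a, m$genes), match(pairs$gene_b, m$genes))
  pairs$erc <- m$values[idx]
  pairs$n_branches <- m$n_branches[idx]
  rownames(pairs) <- NULL
  pairs
}

#' Complex-vs-complex permutation test
#'
#' Tests whether the mean between-set erc of complexes \code{a} and \code{b}
#' exceeds what random gene sets achieve. The observed statistic is the mean
#' erc over all valid a-b pairs. Each permutation replaces \code{b} with a
#' random gene set of the same size drawn (without replacement) from the
#' universe — all matrix genes except members of \code{a} — and recomputes
#' the same mean; under this null the expectation is zero covariation. The
#' one-sided upper-tail empirical p-value uses the +1 correction
#' \deqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}
#' so p is never exactly zero.
#'
#' @param m An \code{erc_matrix}.
#' @param a Query \code{complex_set} (held fixed).
#' @param b Comparison \code{complex_set} (replaced in permutations).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param universe Optional character vector overriding the null universe.
#' @return A \code{complex_test}: list with \code{complex_a},
#'   \code{complex_b}, \code{n_pairs}, \code{observed_stat},
#'   \code{null_mean}, \code{null_sd}, \code{p_empirical},
#'   \code{n_permutations}, \code{seed}, and the \code{null_stats} vector.
#' @export
complex_permutation_test <- function(m, a, b, n_perm = 1000L, seed = 1L,
                                     universe = NULL) {
  stopifnot(inherits(m, "erc_matrix"), n_perm >= 1L)
  vals <- between_set_values(m, a, b, warn_absent = TRUE)
  observed <- mean(vals$erc, na.rm = TRUE)
  if (is.na(observed))
    stop("no valid erc value between '", a$name, "' and '", b$name, "'",
         call. = FALSE)

  am <- intersect(a$members, m$genes)
  bm <- intersect(b$members, m$genes)
  if (is.null(universe)) universe <- setdiff(m$genes, am)
  universe <- intersect(universe, m$genes)
  nb <- length(bm)
  if (length(universe) < nb)
    stop("universe (", length(universe), ") smaller than |b| (", nb, ")",
         call. = FALSE)

  ai <- match(am, m$genes)
  ui <- match(universe, m$genes)
  vsub <- m$values[ai, , drop = FALSE]  # |a| x G slice, row lookups are cheap
  set.seed(seed)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    bs <- ui[sample.int(length(ui), nb)]
    mean(vsub[, bs], na.rm = TRUE)
  }, numeric(1))

  p <- (1 + sum(null_stats >= observed, na.rm = TRUE)) / (1 + n_perm)
  structure(list(complex_a = a$name, complex_b = b$name,
                 n_pairs = nrow(vals), observed_stat = observed,
                 null_mean = mean(null_stats, na.rm = TRUE),
                 null_sd = stats::sd(null_stats),
                 p_empirical = p, n_permutations = as.integer(n_perm),
                 seed = seed, null_stats = null_stats),
            class = "complex_test")
}

#' @export
print.complex_test <- function(x, ...) {
  cat(sprintf(paste0("complex_test %s vs %s: n_pairs = %d, observed mean erc",
                     " = %.4f\n  null %.4f +/- %.4f over %d permutations,",
                     " p = %.4g (seed %s)\n"),
              x$complex_a, x$complex_b, x$n_pairs, x$observed_stat,
              x$null_mean, x$null_sd, x$n_permutations, x$p_empirical,
              format(x$seed)))
  invisible(x)
}

#' Tidy one-row summary of a complex test
#'
#' @param x A \code{complex_test}.
#' @return One-row data frame (null_stats dropped), suitable for
#'   \code{\link{write_results_tsv}}.
#' @export
as.data.frame.complex_test <- function(x, ...) {
  data.frame(complex_a = x$complex_a, complex_b = x$complex_b,
             n_pairs = x$n_pairs, observed_stat = x$observed_stat,
             null_mean = x$null_mean, null_sd = x$null_sd,
             p_empirical = x$p_empirical, n_perm = x$n_permutations,
             seed = x$seed, stringsAsFactors = FALSE)
}
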