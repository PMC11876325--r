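#' Simulate a random rooted species tree
#'
#' Random binary topology (sequential random joins) with branch lengths drawn
#' i.i.d. Exponential with the given mean, in substitutions/site. A rooted
#' binary tree over n species has 2n - 2 branches.
#'
#' @param n_species Number of leaf taxa (>= 3). Default 40, a typical
#'   medium-depth clade panel.
#' @param branch_length_mean Mean branch length (default 0.1
#'   substitutions/site).
#' @param seed Integer seed.
#' @return A \code{species_tree}; tips are labelled \code{sp01, sp02, ...}.
#' @export
simulate_species_tree <- function(n_species = 40L, branch_length_mean = 0.1,
                                  seed = 1L) {
  if (n_species < 3L) stop("n_species must be >= 3", call. = FALSE)
  stopifnot(branch_length_mean > 0)
  set.seed(seed)
  phy <- ape::rtree(n_species,
                    tip.label = sprintf("sp%02d", seq_len(n_species)))
  phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / branch_length_mean)
  species_tree(phy)
}

#' Simulate per-gene branch lengths with planted complex covariation
#'
#' Generates a genes x branches matrix under a multiplicative rate model:
#' \deqn{l_{g,b} = s_g\, m_b\, e^{\sigma(\rho f_{c(g),b} +
#'   \sqrt{1-\rho^2}\,\varepsilon_{g,b})}}
#' where \eqn{m_b} are the species-tree branch lengths, \eqn{s_g} are
#' log-uniform gene scales, \eqn{\varepsilon} is i.i.d. standard normal
#' noise, and genes belonging to the same complex additionally share a
#' per-branch factor \eqn{f} with weight \eqn{\rho}. Two members of a complex
#' with correlation strength \eqn{\rho} thus have log-rate correlation
#' \eqn{\rho^2}; background genes (\eqn{\rho = 0}) are independent. This is
#' the phenomenon ERC is built to detect: co-functional genes accelerating
#' and decelerating together across the phylogeny. Cells are set missing
#' independently with probability \code{missing_frac} (genes left with no
#' observation are re-drawn).
#'
#' @param tree A \code{species_tree} supplying the reference branch lengths.
#' @param n_genes Number of genes (default 200).
#' @param complexes List of \code{list(name=, members=, rho=)} where
#'   \code{members} are gene indices in \code{1:n_genes} (member sets must be
#'   disjoint) and \code{rho} is in [0, 1]. An optional \code{group} field
#'   makes complexes with the same group share one latent factor, planting
#'   covariation *between* complexes (co-evolving complexes); by default each
#'   complex has its own factor.
#' @param sigma Lognormal noise sd on the log scale (default 0.4).
#' @param gene_scale_range Bounds for the log-uniform gene scales (default
#'   \code{c(0.5, 2)}).
#' @param missing_frac Per-cell missingness probability (default 0.05).
#' @param seed Integer seed.
#' @return A \code{sim_blm}: list with \code{matrix} (genes \code{g001...} x
#'   branch ids, NA for missing), \code{complexes} (named list of
#'   \code{\link{complex_set}} with member gene names), and \code{params}.
#' @export
simulate_branch_lengths <- function(tree, n_genes = 200L, complexes = list(),
                                    sigma = 0.4,
                                    gene_scale_range = c(0.5, 2),
                                    missing_frac = 0.05, seed = 1L) {
  stopifnot(inherits(tree, "species_tree"), n_genes >= 1L, sigma >= 0,
            length(gene_scale_range) == 2L, all(gene_scale_range > 0),
            missing_frac >= 0, missing_frac < 1)
  members_all <- unlist(lapply(complexes, `[[`, "members"))
  if (anyDuplicated(members_all))
    stop("complex member sets must be disjoint", call. = FALSE)
  if (length(members_all) && (any(members_all < 1) ||
                              any(members_all > n_genes)))
    stop("complex members must index genes in 1:n_genes", call. = FALSE)
  for (cx in complexes)
    if (cx$rho < 0 || cx$rho > 1) stop("rho must be in [0, 1]", call. = FALSE)

  m <- tree$branch_lengths
  B <- length(m)
  genes <- sprintf("g%03d", seq_len(n_genes))
  set.seed(seed)
  s <- exp(stats::runif(n_genes, log(gene_scale_range[1L]),
                        log(gene_scale_range[2L])))
  e <- matrix(stats::rnorm(n_genes * B), n_genes, B)
  groups <- vapply(complexes, function(cx)
    if (is.null(cx$group)) cx$name else cx$group, character(1))
  factors <- list()  # one latent per-branch factor per group
  for (gname in unique(groups)) factors[[gname]] <- stats::rnorm(B)
  for (ci in seq_along(complexes)) {
    cx <- complexes[[ci]]
    f <- factors[[groups[ci]]]
    idx <- cx$members
    e[idx, ] <- cx$rho * matrix(f, length(idx), B, byrow = TRUE) +
      sqrt(1 - cx$rho^2) * e[idx, , drop = FALSE]
  }
  l <- (s %o% m) * exp(sigma * e)
  dimnames(l) <- list(genes, names(m))
  if (missing_frac > 0) {
    mask <- matrix(stats::runif(n_genes * B) < missing_frac, n_genes, B)
    full <- which(rowSums(!mask) == 0L)
    for (g in full) mask[g, sample.int(B, 1L)] <- FALSE
    l[mask] <- NA_real_
  }
  csets <- lapply(complexes, function(cx)
    complex_set(cx$name, genes[cx$members]))
  names(csets) <- vapply(complexes, `[[`, character(1), "name")
  structure(list(matrix = l, complexes = csets,
                 params = list(n_genes = n_genes, sigma = sigma,
                               gene_scale_range = gene_scale_range,
                               missing_frac = missing_frac, seed = seed)),
            class = "sim_blm")
}

#' @export
print.sim_blm <- function(x, ...) {
  cat("sim_blm:", nrow(x$matrix), "genes x", ncol(x$matrix), "branches;",
      length(x$complexes), "planted complex(es); seed",
      format(x$params$seed), "\n")
  invisible(x)
}

#' A budding-yeast-like genome
#'
#' Sixteen nuclear chromosomes with sacCer3 lengths, the default stage for
#' the enrichment simulator.
#'
#' @return A \code{genome}.
#' @export
yeast_genome <- function() {
  genome(c(chrI = 230218, chrII = 813184, chrIII = 316620, chrIV = 1531933,
           chrV = 576874, chrVI = 270161, chrVII = 1090940, chrVIII = 562643,
           chrIX = 439888, chrX = 745751, chrXI = 666816, chrXII = 1078177,
           chrXIII = 924431, chrXIV = 784333, chrXV = 1091291,
           chrXVI = 948066))
}

#' Simulate a genome with features and a peak set of planted enrichment
#'
#' Features (e.g. replication origins) are placed uniformly without mutual
#' overlap by rejection sampling. Each peak is, with probability \code{pi},
#' centered uniformly within a randomly chosen feature (clipped to its
#' chromosome, which still guarantees the peak covers the chosen position);
#' otherwise it is placed uniformly on the genome. \code{pi = 0} is the
#' no-enrichment null matching the random-genome shuffle exactly;
#' \code{pi = 1} puts every peak on a feature.
#'
#' Defaults mirror the scale of a yeast ChIP-seq experiment: the sacCer3
#' karyotype, 350 origin-like features of 200 bp, 605 peaks of 250 bp.
#'
#' @param genome A \code{genome} (default \code{\link{yeast_genome}()}).
#' @param n_features,feature_length Feature count and fixed length in bp.
#' @param n_peaks,peak_length Peak count and fixed length in bp.
#' @param pi Probability a peak is planted at a feature, in [0, 1]
#'   (default 0.5, moderate enrichment).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap per feature; exceeded density
#'   raises an error suggesting fewer/shorter features.
#' @return List with \code{genome}, \code{features} (\code{GRanges}),
#'   \code{peaks} (\code{GRanges}), \code{pi}, \code{seed}.
#' @export
simulate_genome_with_peaks <- function(genome = yeast_genome(),
                                       n_features = 350L,
                                       feature_length = 200L,
                                       n_peaks = 605L, peak_length = 250L,
                                       pi = 0.5, seed = 1L,
                                       max_tries = 1000L) {
  stopifnot(inherits(genome, "genome"), pi >= 0, pi <= 1,
            feature_length >= 1L, peak_length >= 1L,
            n_features >= 1L, n_peaks >= 1L)
  L <- unclass(genome)
  if (feature_length > min(L) || peak_length > min(L))
    stop("feature/peak length exceeds the shortest chromosome", call. = FALSE)
  if (n_features * feature_length > sum(L))
    stop("features do not fit in the genome", call. = FALSE)
  set.seed(seed)

  # uniform over genome positions: chromosome chosen prop. to placeable span
  span <- L - feature_length + 1
  fchrom <- character(n_features)
  fstart0 <- numeric(n_features)
  placed_by_chrom <- lapply(names(L), function(x) numeric(0))
  names(placed_by_chrom) <- names(L)
  for (i in seq_len(n_features)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(names(L), 1L, prob = span)
      st <- pmin(floor(stats::runif(1) * span[[ch]]), span[[ch]] - 1)
      prev <- placed_by_chrom[[ch]]
      if (!length(prev) ||
          all(st + feature_length <= prev | st >= prev + feature_length)) {
        fchrom[i] <- ch
        fstart0[i] <- st
        placed_by_chrom[[ch]] <- c(prev, st)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place feature ", i, " after ", max_tries,
           " tries; lower the feature density", call. = FALSE)
  }
  features <- interval_set(fchrom, fstart0, fstart0 + feature_length,
                           label = "features", genome = genome)

  pspan <- L - peak_length + 1
  at_feature <- stats::runif(n_peaks) < pi
  pchrom <- character(n_peaks)
  pstart0 <- numeric(n_peaks)
  for (i in seq_len(n_peaks)) {
    if (at_feature[i]) {
      j <- sample.int(n_features, 1L)
      ch <- fchrom[j]
      center <- fstart0[j] + floor(stats::runif(1) * feature_length)
      st <- center - floor(peak_length / 2)
      st <- min(max(st, 0), L[[ch]] - peak_length)
    } else {
      ch <- sample(names(L), 1L, prob = pspan)
      st <- pmin(floor(stats::runif(1) * pspan[[ch]]), pspan[[ch]] - 1)
    }
    pchrom[i] <- ch
    pstart0[i] <- st
  }
  peaks <- interval_set(pchrom, pstart0, pstart0 + peak_length,
                        label = "peaks", genome = genome)
  list(genome = genome, features = features, peaks = peaks, pi = pi,
       seed = seed)
}
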