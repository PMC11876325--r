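#' Fit a relative-evolutionary-rate reference model
#'
#' The reference model separates a genes x branches matrix of branch lengths
#' \eqn{l_{g,b}} into a per-branch reference length \eqn{m_b} (the
#' genome-wide expectation for that branch, a trimmed mean over genes) and a
#' per-gene scale \eqn{s_g} (the gene's overall rate relative to the
#' reference, \eqn{s_g = \sum_b l_{g,b} / \sum_b m_b} over the gene's present
#' branches). Branches observed in too few genes carry no stable reference
#' and are dropped from the model.
#'
#' @param blm Numeric matrix, genes x branches, NA for missing.
#' @param trim_frac Fraction trimmed from each tail when averaging a branch's
#'   lengths across genes (default 0.1); robust to a few fast/slow outlier
#'   genes per branch.
#' @param min_genes_per_branch Minimum non-missing observations for a branch
#'   to be retained (default 3).
#' @param epsilon Pseudo-length added to numerator and denominator of the RER
#'   log-ratio (default 1e-6 substitutions/site); keeps zero-length branches
#'   finite.
#' @return An object of class \code{rer_model}: list with \code{master}
#'   (named \eqn{m_b} over retained branches), \code{scales} (named
#'   \eqn{s_g}), \code{branches}, \code{epsilon}, \code{trim_frac},
#'   \code{min_genes_per_branch}.
#' @export
fit_rer_model <- function(blm, trim_frac = 0.1, min_genes_per_branch = 3L,
                          epsilon = 1e-6) {
  .check_blm(blm)
  stopifnot(trim_frac >= 0, trim_frac < 0.5, epsilon >= 0)
  all_missing <- rownames(blm)[rowSums(!is.na(blm)) == 0L]
  if (length(all_missing))
    stop("gene '", all_missing[1L], "' has no branch lengths", call. = FALSE)

  n_obs <- colSums(!is.na(blm))
  keep <- n_obs >= min_genes_per_branch
  m <- apply(blm[, keep, drop = FALSE], 2L, function(col)
    mean(col[!is.na(col)], trim = trim_frac))
  pos <- m > 0
  m <- m[pos]
  branches <- colnames(blm)[keep][pos]
  names(m) <- branches
  if (length(branches) == 0L)
    stop("no branch retained: increase data or lower min_genes_per_branch",
         call. = FALSE)

  sub <- blm[, branches, drop = FALSE]
  present <- !is.na(sub)
  num <- rowSums(sub, na.rm = TRUE)
  den <- as.vector(present %*% m)
  if (any(den == 0))
    stop("gene '", rownames(blm)[which(den == 0)[1L]],
         "' has no observation on a retained branch", call. = FALSE)
  s <- num / den
  names(s) <- rownames(blm)
  if (any(s <= 0))
    stop("gene '", names(s)[which(s <= 0)[1L]], "' has non-positive scale",
         call. = FALSE)

  structure(list(master = m, scales = s, branches = branches,
                 epsilon = epsilon, trim_frac = trim_frac,
                 min_genes_per_branch = as.integer(min_genes_per_branch)),
            class = "rer_model")
}

#' @export
print.rer_model <- function(x, ...) {
  cat("rer_model:", length(x$scales), "genes,", length(x$branches),
      "retained branches; trim_frac =", x$trim_frac,
      "epsilon =", x$epsilon, "\n")
  invisible(x)
}

#' Refit gene scales against a fixed reference
#'
#' Recomputes the per-gene scales \eqn{s_g} for a (possibly different,
#' column-compatible) branch-length matrix while keeping the per-branch
#' reference \eqn{m_b} fixed — e.g. to project new genes onto an existing
#' model. Because \eqn{s_g} is linear in the gene's lengths, multiplying one
#' gene's row by a constant rescales only its own \eqn{s_g} and leaves its
#' RER row unchanged.
#'
#' @param model An \code{rer_model}.
#' @param blm Numeric matrix whose columns cover the model's branches.
#' @return An \code{rer_model} with updated \code{scales}.
#' @export
refit_scales <- function(model, blm) {
  stopifnot(inherits(model, "rer_model"))
  .check_blm(blm)
  branches <- model$branches
  if (!all(branches %in% colnames(blm)))
    stop("matrix does not cover the model's branches", call. = FALSE)
  sub <- blm[, branches, drop = FALSE]
  present <- !is.na(sub)
  den <- as.vector(present %*% model$master)
  if (any(den == 0))
    stop("gene '", rownames(blm)[which(den == 0)[1L]],
         "' has no observation on a retained branch", call. = FALSE)
  model$scales <- stats::setNames(rowSums(sub, na.rm = TRUE) / den,
                                  rownames(blm))
  model
}

#' Compute relative evolutionary rates
#'
#' \deqn{RER_{g,b} = \log\frac{l_{g,b} + \epsilon}{s_g m_b + \epsilon}}
#'
#' The log-ratio is the gene's branch-specific deviation from its expected
#' length once both the branch's genome-wide rate and the gene's overall
#' scale are removed: 0 means "exactly as expected", positive means the gene
#' evolved unusually fast on that branch. Cells missing in the input, and
#' branches dropped by the model, are NA.
#'
#' @param blm Numeric matrix, genes x branches, NA for missing.
#' @param model An \code{rer_model}; by default fitted from \code{blm}.
#' @param ... Passed to \code{\link{fit_rer_model}} when \code{model} is NULL.
#' @return Numeric matrix of the same shape as \code{blm} (all input columns
#'   retained; dropped branches are all-NA).
#' @export
compute_rer <- function(blm, model = NULL, ...) {
  .check_blm(blm)
  if (is.null(model)) model <- fit_rer_model(blm, ...)
  stopifnot(inherits(model, "rer_model"))
  missing_genes <- setdiff(rownames(blm), names(model$scales))
  if (length(missing_genes))
    stop("gene '", missing_genes[1L], "' not in model", call. = FALSE)
  branches <- intersect(colnames(blm), model$branches)

  rer <- matrix(NA_real_, nrow = nrow(blm), ncol = ncol(blm),
                dimnames = dimnames(blm))
  l <- blm[, branches, drop = FALSE]
  expected <- outer(model$scales[rownames(blm)], model$master[branches])
  rer[, branches] <- log((l + model$epsilon) / (expected + model$epsilon))
  rer
}

#' Winsorize a numeric vector
#'
#' Replaces the \code{k} largest values by the (k+1)-th largest and the
#' \code{k} smallest by the (k+1)-th smallest (both tails), preserving input
#' order. This caps the influence of extreme branch rates that would
#' otherwise dominate a Pearson correlation. When the vector has at most
#' \code{2k + 1} elements the two caps meet and every value becomes the
#' median.
#'
#' @param v Finite numeric vector.
#' @param k Number of values condensed in each tail (default 3).
#' @return Numeric vector, same length and order as \code{v}.
#' @examples
#' winsorize(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 100), k = 3)
#' @export
winsorize <- function(v, k = 3L) {
  if (length(k) != 1L || is.na(k) || k < 0)
    stop("k must be a single non-negative integer", call. = FALSE)
  k <- as.integer(k)
  if (any(!is.finite(v))) stop("v must be finite", call. = FALSE)
  n <- length(v)
  if (n == 0L || k == 0L) return(v)
  if (n <= 2L * k + 1L) return(rep(stats::median(v), n))
  s <- sort(v)
  pmin(pmax(v, s[k + 1L]), s[n - k])
}

.check_blm <- function(blm) {
  if (!is.matrix(blm) || !is.numeric(blm))
    stop("expected a numeric genes x branches matrix", call. = FALSE)
  if (is.null(rownames(blm)) || is.null(colnames(blm)))
    stop("matrix needs gene rownames and branch colnames", call. = FALSE)
  if (nrow(blm) == 0L || ncol(blm) == 0L)
    stop("empty matrix", call. = FALSE)
  if (any(blm < 0, na.rm = TRUE))
    stop("branch lengths must be nonnegative", call. = FALSE)
  invisible(TRUE)
}
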