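#' @keywords internal
.new_run_dir <- function(out_dir) {
  if (file.exists(out_dir) && length(list.files(out_dir, all.files = TRUE,
                                                no.. = TRUE)))
    stop("output directory '", out_dir,
         "' exists and is not empty; refusing to overwrite", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  normalizePath(out_dir)
}

.write_manifest <- function(out_dir, subcommand, params, seed, inputs,
                            outputs, t0) {
  digests <- if (length(inputs)) as.list(tools::md5sum(unlist(inputs)))
             else list()
  manifest <- list(tool = "ratecov", version = .ratecov_version(),
                   subcommand = subcommand, parameters = params, seed = seed,
                   input_digests = digests,
                   outputs = as.list(basename(unlist(outputs))),
                   wall_time_sec = round(as.numeric(Sys.time()) - t0, 3))
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)  # atomic publish
  path
}

#' Run the full ERC workflow
#'
#' simulate (or load) branch lengths -> RER -> all-pairs ERC -> one
#' permutation test per requested complex pair, writing per-pair values, the
#' test summaries, a long-format table of between-set erc values (one row
#' per protein pair, ready for violin plots) and a JSON run manifest to a
#' fresh output directory.
#'
#' @param config List. Either \code{simulation = list(...)} (arguments for
#'   \code{\link{simulate_species_tree}} /
#'   \code{\link{simulate_branch_lengths}}) or \code{matrix_tsv =} and
#'   \code{complexes_tsv =} paths. \code{tests} is a list of
#'   \code{c(complex_a, complex_b)} name pairs (default: first complex
#'   against each of the others). Optional \code{erc = list(k, min_branches,
#'   r_clamp)}, \code{rer = list(trim_frac, min_genes_per_branch, epsilon)},
#'   \code{n_perm} (default 1000) and \code{seed} (default 1).
#' @param out_dir Output directory; must not already contain files.
#' @return List with \code{erc} (the \code{erc_matrix}), \code{tests}
#'   (list of \code{complex_test}), \code{outputs} (paths) and
#'   \code{manifest} (path), invisibly.
#' @export
run_erc_pipeline <- function(config, out_dir) {
  t0 <- as.numeric(Sys.time())
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_perm <- if (is.null(config$n_perm)) 1000L else as.integer(config$n_perm)
  inputs <- character(0)

  if (!is.null(config$matrix_tsv)) {
    if (is.null(config$complexes_tsv))
      stop("config$complexes_tsv is required with matrix_tsv", call. = FALSE)
    for (p in c(config$matrix_tsv, config$complexes_tsv))
      if (!file.exists(p)) stop("input not found: ", p, call. = FALSE)
    blm <- read_matrix_tsv(config$matrix_tsv)
    complexes <- read_complexes(config$complexes_tsv)
    inputs <- c(config$matrix_tsv, config$complexes_tsv)
  } else if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    tree <- do.call(simulate_species_tree, c(
      sim_cfg[intersect(names(sim_cfg),
                        c("n_species", "branch_length_mean"))],
      list(seed = seed)))
    sim <- do.call(simulate_branch_lengths, c(
      list(tree = tree),
      sim_cfg[intersect(names(sim_cfg),
                        c("n_genes", "complexes", "sigma",
                          "gene_scale_range", "missing_frac"))],
      list(seed = seed + 1L)))
    blm <- sim$matrix
    complexes <- sim$complexes
  } else {
    stop("config needs either simulation or matrix_tsv/complexes_tsv",
         call. = FALSE)
  }
  if (length(complexes) < 2L)
    stop("need at least two complexes to test", call. = FALSE)

  out_dir <- .new_run_dir(out_dir)
  rer_args <- config$rer
  model <- do.call(fit_rer_model, c(list(blm = blm), rer_args))
  rer <- compute_rer(blm, model)
  erc_args <- config$erc
  m <- do.call(erc_matrix, c(list(rer = rer), erc_args))

  tests <- config$tests
  if (is.null(tests))
    tests <- lapply(names(complexes)[-1L],
                    function(b) c(names(complexes)[1L], b))
  results <- list()
  long <- list()
  pair_seed <- seed
  for (tt in tests) {
    a <- complexes[[tt[1L]]]
    b <- complexes[[tt[2L]]]
    if (is.null(a) || is.null(b))
      stop("complex-test stage: unknown complex in test (",
           paste(tt, collapse = " vs "), ")", call. = FALSE)
    pair_seed <- pair_seed + 1L
    res <- complex_permutation_test(m, a, b, n_perm = n_perm,
                                    seed = pair_seed)
    results[[paste(tt, collapse = "_vs_")]] <- res
    vals <- between_set_values(m, a, b, warn_absent = FALSE)
    vals$complex_a <- a$name
    vals$complex_b <- b$name
    long[[length(long) + 1L]] <- vals
  }

  pairs_df <- do.call(rbind, long)[, c("complex_a", "complex_b", "gene_a",
                                       "gene_b", "erc", "n_branches")]
  f_pairs <- file.path(out_dir, "between_set_erc.tsv")
  write_results_tsv(pairs_df, f_pairs, seed = seed)
  f_tests <- file.path(out_dir, "complex_tests.tsv")
  write_results_tsv(do.call(rbind, lapply(results, as.data.frame)),
                    f_tests, seed = seed)
  f_matrix <- file.path(out_dir, "erc_matrix.tsv")
  write_matrix_tsv(m$values, f_matrix, seed = seed)
  outputs <- c(f_pairs, f_tests, f_matrix)
  manifest <- .write_manifest(out_dir, "pipeline-erc",
                              params = list(n_perm = n_perm,
                                            rer = rer_args, erc = erc_args,
                                            tests = tests,
                                            simulation = config$simulation),
                              seed = seed, inputs = inputs,
                              outputs = outputs, t0 = t0)
  invisible(list(erc = m, tests = results, outputs = outputs,
                 manifest = manifest))
}

#' Run the overlap-enrichment workflow
#'
#' load (or simulate) genome, features and peaks -> random-genome
#' permutation test, writing the test summary, a null-count histogram table
#' (the bar-distribution data shape) and a JSON run manifest.
#'
#' @param config List. Either \code{simulation = list(...)} (arguments for
#'   \code{\link{simulate_genome_with_peaks}}) or paths \code{query_bed},
#'   \code{subject_bed} (or \code{subject_gff3} + \code{feature_types}) and
#'   \code{genome_tsv}. Optional \code{n_perm} (default 10000), \code{seed}
#'   (default 1), \code{alternative}.
#' @param out_dir Output directory; must not already contain files.
#' @return List with \code{test} (the \code{enrichment_test}),
#'   \code{outputs}, \code{manifest}, invisibly.
#' @export
run_enrichment_pipeline <- function(config, out_dir) {
  t0 <- as.numeric(Sys.time())
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_perm <- if (is.null(config$n_perm)) 10000L else as.integer(config$n_perm)
  alternative <- if (is.null(config$alternative)) "greater"
                 else config$alternative
  inputs <- character(0)

  if (!is.null(config$query_bed)) {
    if (is.null(config$genome_tsv))
      stop("config$genome_tsv is required with query_bed", call. = FALSE)
    paths <- c(config$query_bed, config$genome_tsv,
               config$subject_bed, config$subject_gff3)
    for (p in paths) if (!file.exists(p)) stop("input not found: ", p,
                                               call. = FALSE)
    g <- read_genome_table(config$genome_tsv)
    query <- read_bed(config$query_bed, genome = g)
    subject <- if (!is.null(config$subject_bed))
      read_bed(config$subject_bed, genome = g)
    else if (!is.null(config$subject_gff3))
      read_gff3_features(config$subject_gff3,
                         feature_types = config$feature_types, genome = g)
    else stop("config needs subject_bed or subject_gff3", call. = FALSE)
    inputs <- paths
  } else if (!is.null(config$simulation)) {
    sim <- do.call(simulate_genome_with_peaks,
                   c(config$simulation, list(seed = seed)))
    g <- sim$genome
    query <- sim$peaks
    subject <- sim$features
  } else {
    stop("config needs either simulation or query_bed/subject/genome paths",
         call. = FALSE)
  }

  out_dir <- .new_run_dir(out_dir)
  test <- overlap_permutation_test(query, subject, g, n_perm = n_perm,
                                   seed = seed, alternative = alternative)
  f_test <- file.path(out_dir, "enrichment_test.tsv")
  write_results_tsv(as.data.frame(test), f_test, seed = seed)
  hist_df <- as.data.frame(table(null_count = test$null_counts),
                           stringsAsFactors = FALSE)
  names(hist_df) <- c("null_count", "n_genomes")
  f_hist <- file.path(out_dir, "null_histogram.tsv")
  write_results_tsv(hist_df, f_hist, seed = seed)
  outputs <- c(f_test, f_hist)
  manifest <- .write_manifest(out_dir, "pipeline-enrich",
                              params = list(n_perm = n_perm,
                                            alternative = alternative,
                                            simulation = config$simulation),
                              seed = seed, inputs = inputs,
                              outputs = outputs, t0 = t0)
  invisible(list(test = test, outputs = outputs, manifest = manifest))
}
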