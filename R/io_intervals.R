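#' Read a BED file of genomic intervals
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' convention of \code{GRanges} by \pkg{rtracklayer}; overlap semantics are
#' unchanged (a BED interval abutting another at a shared boundary shares no
#' base with it, and the corresponding GRanges do not overlap). Strand is
#' dropped: peaks and origin annotations are unstranded here.
#'
#' @param path BED3+ file.
#' @param label Set label stored in \code{S4Vectors::metadata()}; defaults to
#'   the file name.
#' @param genome Optional genome (named lengths, see
#'   \code{\link{read_genome_table}}); if given, chromosome names are checked
#'   and sequence lengths attached.
#' @return A \code{GRanges}.
#' @export
read_bed <- function(path, label = basename(path), genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  w0 <- which(GenomicRanges::width(gr) == 0L)
  if (length(w0))
    stop("record ", w0[1L], " in '", path, "': start >= end", call. = FALSE)
  .finish_intervals(gr, label, genome)
}

#' Read features from a GFF3 file
#'
#' GFF3 coordinates are 1-based closed, matching \code{GRanges} natively; the
#' feature length equals \code{end - start + 1}. Records are filtered on
#' column 3 (type).
#'
#' @param path GFF3 file.
#' @param feature_types Character vector of feature types to keep (e.g.
#'   \code{"ARS"}); \code{NULL} keeps everything.
#' @param label Set label; defaults to the file name.
#' @param genome Optional genome for validation.
#' @return A \code{GRanges} (possibly empty).
#' @export
read_gff3_features <- function(path, feature_types = NULL,
                               label = basename(path), genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_types))
    gr <- gr[as.character(gr$type) %in% feature_types]
  .finish_intervals(gr, label, genome)
}

.finish_intervals <- function(gr, label, genome) {
  GenomicRanges::strand(gr) <- "*"
  if (!is.null(genome)) {
    bad <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(genome))
    if (length(bad))
      stop("unknown chromosome(s): ", paste(unique(bad), collapse = ", "),
           call. = FALSE)
    over <- which(GenomicRanges::end(gr) >
                    unclass(genome)[as.character(GenomeInfoDb::seqnames(gr))])
    if (length(over))
      stop("interval ", over[1L], " extends beyond its chromosome",
           call. = FALSE)
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(
      as.integer(unclass(genome)), names(genome))
  }
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Construct an interval set from vectors of BED-style coordinates
#'
#' Convenience constructor using the BED convention (0-based start, exclusive
#' end); mainly used by simulators and tests.
#'
#' @param chrom Chromosome names.
#' @param start0 0-based inclusive starts.
#' @param end End positions (exclusive).
#' @param label Set label.
#' @param genome Optional genome for validation.
#' @return A \code{GRanges}.
#' @export
interval_set <- function(chrom, start0, end, label = "intervals",
                         genome = NULL) {
  if (any(!is.finite(start0)) || any(!is.finite(end)))
    stop("non-finite coordinates", call. = FALSE)
  if (any(start0 != floor(start0)) || any(end != floor(end)))
    stop("non-integer coordinates", call. = FALSE)
  bad <- which(start0 >= end | start0 < 0)
  if (length(bad))
    stop("interval ", bad[1L], ": need 0 <= start < end", call. = FALSE)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end))
  .finish_intervals(gr, label, genome)
}

#' Write intervals to BED
#'
#' Emits BED3 (or BED6 when names/scores are present) in 0-based half-open
#' coordinates, preceded by a commented provenance line.
#'
#' @param gr A \code{GRanges}.
#' @param path Output file.
#' @param seed Optional seed recorded in the header comment.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(gr, path, seed = NULL) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm)) {
    df$name <- nm
    df$score <- if (is.null(gr$score)) 0 else gr$score
    df$strand <- "."
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Format: \code{name TAB length} per line (the UCSC chrom.sizes layout).
#'
#' @param path chrom.sizes file.
#' @return Named numeric vector of chromosome lengths, class \code{genome}.
#' @export
read_genome_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("chrom.sizes needs 'name<TAB>length'", call. = FALSE)
  genome(stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]])))
}

#' Construct a genome from named chromosome lengths
#'
#' @param lengths Named numeric vector, one entry per chromosome.
#' @return The validated vector with class \code{genome}.
#' @export
genome <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosomes must be named", call. = FALSE)
  if (anyDuplicated(names(lengths)))
    stop("duplicate chromosome name: ",
         names(lengths)[duplicated(names(lengths))][1L], call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers", call. = FALSE)
  structure(stats::setNames(as.numeric(unname(lengths)), names(lengths)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "chromosomes,", format(sum(x), big.mark = ","),
      "bp\n")
  invisible(x)
}

#' Write a chromosome-sizes table
#'
#' @param g A \code{genome}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_genome_table <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(), con)
  writeLines(paste(names(g), format(unclass(g), scientific = FALSE,
                                    trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' Write a results table to TSV with a provenance header
#'
#' @param df A data frame.
#' @param path Output file.
#' @param seed Optional seed recorded in the header comment.
#' @return \code{path}, invisibly.
#' @export
write_results_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(seed), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  invisible(path)
}
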