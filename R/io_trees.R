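#' Read a species tree from a Newick file
#'
#' Parses a single rooted Newick tree and indexes every branch by its clade:
#' the sorted set of descendant leaf taxa. This clade index is the stable
#' branch identifier used to project gene trees onto a common branch set, so
#' that "shared branches" between genes are well defined regardless of node
#' ordering or file layout.
#'
#' @param path Path to a Newick file containing exactly one tree.
#' @return An object of class \code{species_tree}: a list with elements
#'   \code{phylo} (the \pkg{ape} tree), \code{tips} (leaf labels),
#'   \code{branch_ids} (character vector, one per branch, in \code{phylo}
#'   edge order) and \code{branch_lengths} (named by \code{branch_ids}).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:2):0.5,C:3);", tf)
#' tr <- read_species_tree(tf)
#' tr$branch_lengths[["A|B"]]  # 0.5
#' @export
read_species_tree <- function(path) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop("malformed Newick in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(phy)) stop("malformed Newick in '", path, "': no tree parsed",
                         call. = FALSE)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("expected a single tree in '", path, "', found ", length(phy),
           call. = FALSE)
    phy <- phy[[1L]]
  }
  species_tree(phy)
}

#' Build a species_tree object from an ape phylo
#'
#' @param phy A rooted \code{phylo} object with branch lengths on every edge.
#' @return A \code{species_tree} (see \code{\link{read_species_tree}}).
#' @export
species_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels in tree", call. = FALSE)
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      any(!is.finite(phy$edge.length)))
    stop("every branch must carry a finite length", call. = FALSE)
  if (any(phy$edge.length < 0))
    stop("negative branch length in tree", call. = FALSE)
  ids <- .edge_branch_ids(phy)
  if (anyDuplicated(ids))
    stop("branch ids are not unique (tree is not a proper rooted tree)",
         call. = FALSE)
  bl <- phy$edge.length
  names(bl) <- ids
  structure(list(phylo = phy, tips = phy$tip.label, branch_ids = ids,
                 branch_lengths = bl),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", length(x$tips), "taxa,", length(x$branch_ids),
      "branches\n")
  invisible(x)
}

#' Write a species tree to Newick
#'
#' Branch lengths are rendered with 10 significant digits so that
#' write-then-read round-trips reproduce the branch_id to length mapping
#' exactly at that precision.
#'
#' @param tree A \code{species_tree}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_species_tree <- function(tree, path) {
  stopifnot(inherits(tree, "species_tree"))
  ape::write.tree(tree$phylo, file = path, digits = 10)
  invisible(path)
}

# descendant-tip clade per edge, postorder accumulation over the edge matrix
.edge_branch_ids <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  desc <- vector("list", nnode)
  desc[seq_len(ntip)] <- as.list(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  vapply(phy$edge[, 2L],
         function(nd) paste(sort(desc[[nd]]), collapse = "|"),
         character(1))
}

#' Project gene trees onto a species tree's branch set
#'
#' Reads a file with one record per line, \code{gene_id TAB newick}, and maps
#' each gene tree's branches onto the master branch index by descendant leaf
#' set. For a gene with taxon set S, each master branch's clade is restricted
#' to S; a master branch receives the length of the gene-tree branch whose
#' clade equals that restriction, provided the restriction is non-empty, is a
#' proper subset of S, and identifies the master branch uniquely. Master
#' branches whose restricted clades collide (taxa pruned so two master
#' branches merge into one gene-tree branch) are missing (NA) for that gene,
#' as are branches with no taxa left.
#'
#' @param path Gene-trees file (\code{gene_id TAB newick} per line; blank
#'   lines and lines starting with \code{#} are skipped).
#' @param species_tree A \code{species_tree} giving the master branch index.
#' @return A numeric matrix, genes x master branches, with NA for missing;
#'   rownames are gene ids, colnames are branch ids.
#' @export
read_gene_trees <- function(path, species_tree) {
  stopifnot(inherits(species_tree, "species_tree"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("no gene records in '", path, "'", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("line ", bad[1L], ": expected 'gene_id<TAB>newick'", call. = FALSE)
  genes <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene_id: ", genes[duplicated(genes)][1L], call. = FALSE)
  nwk <- vapply(parts, `[[`, character(1), 2L)

  bids <- species_tree$branch_ids
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(bids),
                dimnames = list(genes, bids))
  master_clades <- strsplit(bids, "|", fixed = TRUE)
  for (i in seq_along(genes)) {
    g <- tryCatch(ape::read.tree(text = nwk[i]),
                  error = function(e) stop("gene '", genes[i],
                                           "': malformed Newick: ",
                                           conditionMessage(e), call. = FALSE))
    if (is.null(g)) stop("gene '", genes[i], "': malformed Newick", call. = FALSE)
    out[i, ] <- .map_gene_tree(g, genes[i], species_tree, master_clades)
  }
  out
}

.map_gene_tree <- function(g, gene, master, master_clades) {
  taxa <- g$tip.label
  unknown <- setdiff(taxa, master$tips)
  if (length(unknown))
    stop("gene '", gene, "': taxa not in species tree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(g$edge.length) || length(g$edge.length) != nrow(g$edge) ||
      any(!is.finite(g$edge.length)))
    stop("gene '", gene, "': every branch must carry a finite length",
         call. = FALSE)

  # master clades restricted to this gene's taxon set
  restr <- vapply(master_clades, function(cl) {
    paste(sort(intersect(cl, taxa)), collapse = "|")
  }, character(1))
  full <- paste(sort(taxa), collapse = "|")
  usable <- nzchar(restr) & restr != full
  # unambiguous = restriction identifies exactly one master branch
  tab <- table(restr[usable])
  unambig <- usable & restr %in% names(tab)[tab == 1L]

  gene_ids <- .edge_branch_ids(g)
  # topology compatibility: gene clades must coincide with the distinct
  # restricted master clades (the restriction of a binary tree is binary)
  expected <- unique(restr[usable])
  if (!setequal(gene_ids, expected))
    stop("gene '", gene, "': topology incompatible with species tree",
         call. = FALSE)

  row <- rep(NA_real_, length(master_clades))
  idx <- match(restr, gene_ids)
  take <- unambig & !is.na(idx)
  row[take] <- g$edge.length[idx[take]]
  row
}

#' Read a branch-length or RER matrix from TSV
#'
#' Expects a header row \code{gene_id TAB <branch ids...>}; missing cells are
#' the literal string \code{NA}. Lines starting with \code{#} are ignored.
#'
#' @param path TSV file.
#' @return Numeric matrix with gene rownames and branch-id colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, na.strings = "NA",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix TSV needs a gene_id column plus branches",
                          call. = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene_id: ", genes[duplicated(genes)][1L], call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a matrix to TSV
#'
#' Values are rendered with \code{\%.17g} so that
#' \code{read_matrix_tsv(write_matrix_tsv(m))} reproduces \code{m} bit-exactly;
#' missing values are written as \code{NA}. A commented provenance line with
#' the package version (and seed, if given) is prepended.
#'
#' @param m Numeric matrix with rownames (genes) and colnames (branch ids).
#' @param path Output file.
#' @param seed Optional seed recorded in the header comment.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(m, path, seed = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.header_comment(seed), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) {
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t")
  })
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read protein-complex membership lists
#'
#' File format: one complex per line, \code{name TAB member1,member2,...}.
#'
#' @param path Complexes file.
#' @return Named list of \code{complex_set} objects.
#' @export
read_complexes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("line ", bad[1L], ": expected 'name<TAB>member1,member2,...'",
         call. = FALSE)
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate complex name: ", nms[duplicated(nms)][1L], call. = FALSE)
  out <- lapply(seq_along(nms), function(i) {
    complex_set(nms[i], strsplit(parts[[i]][2L], ",", fixed = TRUE)[[1L]])
  })
  names(out) <- nms
  out
}

#' Construct a protein-complex membership set
#'
#' @param name Complex name.
#' @param members Character vector of gene/protein identifiers.
#' @return A \code{complex_set}: list with \code{name} and \code{members}.
#' @export
complex_set <- function(name, members) {
  members <- trimws(members)
  members <- members[nzchar(members)]
  if (length(members) == 0L)
    stop("complex '", name, "' has no members", call. = FALSE)
  if (anyDuplicated(members))
    stop("complex '", name, "' has duplicate members", call. = FALSE)
  structure(list(name = name, members = members), class = "complex_set")
}

#' @export
print.complex_set <- function(x, ...) {
  cat("complex_set '", x$name, "': ", paste(x$members, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
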