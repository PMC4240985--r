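#' Multiple sequence alignment container
#'
#' Light S3 container used throughout the package: a character matrix of
#' single upper-case nucleotide states (rows = taxa, columns = sites) over
#' the alphabet `A,C,G,T,N,-`, with a locus id and a genome tag.
#'
#' @param x a character matrix of single characters, or a character vector
#'   of equal-length sequence strings (named, or labelled via `labels`).
#' @param labels taxon labels; defaults to names/rownames of `x`.
#' @param locus locus identifier.
#' @param genome `"nuclear"` or `"chloroplast"`.
#' @return an object of class `multiple_alignment`.
#' @export
multiple_alignment <- function(x, labels = NULL, locus = "locus",
                               genome = c("nuclear", "chloroplast")) {
  genome <- match.arg(genome)
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(labels)) labels <- names(x)
    if (is.null(labels)) labels <- paste0("seq", seq_along(x))
    n <- nchar(x)
    if (length(unique(n)) != 1L)
      stop("alignment rows must have equal length (got ",
           paste(sort(unique(n)), collapse = ", "), ")")
    x <- do.call(rbind, strsplit(x, ""))
    rownames(x) <- labels
  } else if (is.matrix(x)) {
    if (!is.null(labels)) rownames(x) <- labels
    if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
  } else {
    stop("x must be a character matrix or character vector")
  }
  x[] <- toupper(x)
  if (nrow(x) < 2L) stop("an alignment needs at least 2 rows")
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  bad <- setdiff(unique(as.vector(x)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad) > 0)
    stop("invalid characters in alignment: ", paste(bad, collapse = ", "))
  structure(x, class = c("multiple_alignment", "matrix"),
            locus = locus, genome = genome)
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> locus=%s genome=%s  %d taxa x %d bp\n",
              attr(x, "locus"), attr(x, "genome"), nrow(x), ncol(x)))
  invisible(x)
}

is_alignment <- function(x) inherits(x, "multiple_alignment")

check_alignment <- function(aln) {
  if (!is_alignment(aln)) stop("not a multiple_alignment object")
  if (nrow(aln) < 2L) stop("alignment has fewer than 2 rows")
  invisible(aln)
}

#' Extract alignment rows as sequence strings
#' @param aln a `multiple_alignment`.
#' @return named character vector of sequence strings.
#' @export
alignment_strings <- function(aln) {
  out <- apply(unclass(aln), 1L, paste, collapse = "")
  names(out) <- rownames(aln)
  out
}

#' Read an aligned (or unaligned) FASTA file
#'
#' Labels and residues are preserved, with case normalised to upper.
#'
#' @param path path to a FASTA file.
#' @param aligned if `TRUE` (default) rows must be equal length and a
#'   `multiple_alignment` is returned; otherwise a named character vector.
#' @param locus,genome passed to [multiple_alignment()].
#' @return a `multiple_alignment` or named character vector.
#' @export
read_fasta <- function(path, aligned = TRUE, locus = NULL,
                       genome = "nuclear") {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  labs <- names(dna)
  if (anyDuplicated(labs))
    stop("duplicate labels in ", path, ": ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  names(seqs) <- labs
  if (!aligned) return(seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("ragged rows in ", path, " where an alignment was expected")
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  multiple_alignment(seqs, locus = locus, genome = genome)
}

#' Write sequences to FASTA
#' @param x a `multiple_alignment` or named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is_alignment(x)) x <- alignment_strings(x)
  if (is.null(names(x))) stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(x), "\n", x), con)
  invisible(path)
}

#' Concatenate loci into a supermatrix
#'
#' Columns are appended in input order; taxa missing from a locus are padded
#' with `N`. Partition boundaries are recorded in the `partitions` attribute.
#'
#' @param loci list of `multiple_alignment` objects.
#' @param genome genome tag for the result.
#' @return a `multiple_alignment` with a `partitions` attribute
#'   (data.frame: locus, start, end).
#' @export
concatenate <- function(loci, genome = "nuclear") {
  stopifnot(length(loci) >= 1)
  lapply(loci, check_alignment)
  taxa <- unique(unlist(lapply(loci, rownames)))
  widths <- vapply(loci, ncol, integer(1))
  out <- matrix("N", nrow = length(taxa), ncol = sum(widths),
                dimnames = list(taxa, NULL))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  for (i in seq_along(loci)) {
    a <- loci[[i]]
    out[rownames(a), starts[i]:ends[i]] <- unclass(a)
  }
  res <- multiple_alignment(out, locus = "concatenated", genome = genome)
  attr(res, "partitions") <- data.frame(
    locus = vapply(loci, function(a) attr(a, "locus"), character(1)),
    start = starts, end = ends)
  res
}

#' Read a Newick tree file
#' @param path path to a Newick file.
#' @return an ape `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  tr
}

#' Write a tree to a Newick file
#'
#' Support values (node labels) and branch lengths are preserved; unrooted
#' trees are serialised with the stored basal trifurcation.
#'
#' @param tree an ape `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
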