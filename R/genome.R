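#' Construct a genome object
#'
#' A genome is a named set of nucleotide sequences over the alphabet
#' `{A, C, G, T, N}`. Internally it is a named character vector with a
#' `source` attribute; all coordinates used against it are 0-based,
#' half-open.
#'
#' @param sequences named character vector of nucleotide sequences.
#' @param source provenance string, a file path or `"synthetic"`.
#' @return an object of class `genome`.
#' @export
genome <- function(sequences, source = "synthetic") {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named")
  sequences <- toupper(unlist(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("alphabet restricted to {A,C,G,T,N}; offending sequence: ",
         names(sequences)[bad][1L])
  structure(sequences, source = source, class = "genome")
}

#' Read a genome from a FASTA file
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return a [genome()] object.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  genome(stats::setNames(as.character(x), names(x)), source = path)
}

#' Write a genome to FASTA
#'
#' @param g a [genome()] object.
#' @param path output path.
#' @export
write_genome_fasta <- function(g, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(g)), filepath = path)
  invisible(path)
}

#' Extract a subsequence by 0-based half-open interval
#'
#' @param g a [genome()] object.
#' @param id sequence identifier.
#' @param start,end 0-based half-open genomic interval.
#' @return nucleotide string.
#' @export
get_subseq <- function(g, id, start, end) {
  if (!id %in% names(g)) stop("sequence not found: ", id)
  n <- nchar(g[[id]])
  if (start < 0 || end > n || start > end) stop("coordinate overflow")
  substr(g[[id]], start + 1L, end)
}

#' Reverse-complement a nucleotide string
#'
#' N is self-complementary.
#'
#' @param x nucleotide string.
#' @return reverse complement of `x`.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d sequence(s) [%s]\n", length(x), attr(x, "source")))
  for (id in names(x)) cat(sprintf("  %s: %d nt\n", id, nchar(x[[id]])))
  invisible(x)
}
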