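#' Construct a reference gene model
#'
#' A gene model is the exon structure of one coding transcript: ordered
#' coding exons (genomic 0-based half-open intervals), per-exon CDS phases
#' and the strand. Exons are stored in transcription order; for minus-strand
#' genes that is decreasing genomic position, and sequence extraction
#' reverse-complements, so every downstream module sees plus-strand
#' transcription order (single code path for frame arithmetic).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome / scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open genomic intervals), one row per exon, in transcription order.
#' @param start_codon_cds_pos CDS coordinate of the start codon (normally 0).
#' @return an object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `exons`, `cds_phases` (phase of each exon, computed),
#'   `cds_length`, `start_codon_cds_pos` and `stop_codon_cds_pos`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       start_codon_cds_pos = 0L) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  lens <- exons[, 2] - exons[, 1]
  if (any(lens <= 0)) stop("malformed reference model: empty exon")
  gstart <- exons[, 1]
  ord_ok <- if (strand == "+") all(diff(gstart) > 0) else all(diff(gstart) < 0)
  if (nrow(exons) > 1 && !ord_ok)
    stop("exons must be non-overlapping and in transcription order")
  # non-overlap in genomic coordinates
  gs <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(gs) > 1 && any(gs[-1, 1] < gs[-nrow(gs), 2]))
    stop("exons must be non-overlapping")
  total <- sum(lens)
  if (total %% 3L != 0L) stop("malformed reference model: CDS length ",
                              total, " is not a multiple of 3")
  phases <- as.integer(cumsum(c(0L, lens[-length(lens)])) %% 3L)
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exons = exons, exon_lengths = as.integer(lens),
    cds_phases = phases, cds_length = as.integer(total),
    cds_offsets = as.integer(cumsum(c(0L, lens[-length(lens)]))),
    start_codon_cds_pos = as.integer(start_codon_cds_pos),
    stop_codon_cds_pos = as.integer(total - 3L)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s), %d exon(s), CDS %d nt\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), x$cds_length))
  invisible(x)
}

#' Load a gene model from GFF3 + FASTA
#'
#' Reads the CDS features of one gene from a GFF3 annotation and checks them
#' against the genomic FASTA. Minus-strand genes are normalized at load time
#' so exon order is transcription order.
#'
#' @param gff3_path GFF3 file containing CDS features whose `ID` or `Parent`
#'   attribute matches `gene_id`.
#' @param fasta_path genomic FASTA containing the annotated chromosome.
#' @param gene_id the gene to load.
#' @return a list with elements `model` ([gene_model()]) and `genome`
#'   ([genome()]).
#' @export
load_gene_model <- function(gff3_path, fasta_path, gene_id) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  g <- read_genome_fasta(fasta_path)
  cds <- gr[gr$type == "CDS"]
  meta <- S4Vectors::mcols(cds)
  hit <- rep(FALSE, length(cds))
  for (field in c("ID", "Parent", "gene_id")) {
    if (field %in% names(meta)) {
      v <- meta[[field]]
      hit <- hit | vapply(v, function(el) gene_id %in% unlist(el), logical(1))
    }
  }
  cds <- cds[hit]
  if (length(cds) == 0) stop("gene not found: ", gene_id)
  chrom <- as.character(GenomicRanges::seqnames(cds))[1]
  strand <- as.character(BiocGenerics::strand(cds))[1]
  if (!strand %in% c("+", "-")) strand <- "+"
  # GFF3 is 1-based closed; convert to 0-based half-open
  ex <- cbind(start = BiocGenerics::start(cds) - 1L, end = BiocGenerics::end(cds))
  ex <- ex[order(ex[, 1], decreasing = (strand == "-")), , drop = FALSE]
  model <- gene_model(gene_id, chrom, strand, ex)
  if (!chrom %in% names(g)) stop("chromosome not in FASTA: ", chrom)
  list(model = model, genome = g)
}

#' Write a gene model as GFF3
#'
#' Emits `gene` and `CDS` features (1-based closed coordinates, per the GFF3
#' convention) for a predicted or reference annotation.
#'
#' @param model a [gene_model()].
#' @param path output path.
#' @export
write_gene_model_gff3 <- function(model, path) {
  ex <- model$exons
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tgenloss\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            model$chrom, min(ex[, 1]) + 1L, max(ex[, 2]), model$strand,
            model$gene_id),
    sprintf("%s\tgenloss\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
            model$chrom, ex[, 1] + 1L, ex[, 2], model$strand,
            model$cds_phases, model$gene_id, seq_len(nrow(ex)),
            model$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Extract the coding sequence of a model from a genome
#'
#' Concatenates exon sequences in transcription order; minus-strand exons
#' are reverse-complemented.
#'
#' @param model a [gene_model()].
#' @param g a [genome()].
#' @return nucleotide string of length `model$cds_length`.
#' @export
extract_cds <- function(model, g) {
  parts <- vapply(seq_len(nrow(model$exons)), function(i) {
    s <- get_subseq(g, model$chrom, model$exons[i, 1], model$exons[i, 2])
    if (model$strand == "-") revcomp(s) else s
  }, character(1))
  paste0(parts, collapse = "")
}

#' Translate a coding sequence
#'
#' Standard genetic code. Internal and terminal stop codons are rendered as
#' `*`; any codon containing N translates to `X`. A trailing partial codon
#' is ignored and flagged via the `partial` attribute.
#'
#' @param cds nucleotide string, length >= 3.
#' @return amino-acid string with attribute `partial` (logical).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) < 3) stop("CDS shorter than one codon")
  n <- nchar(cds) %/% 3L
  partial <- (nchar(cds) %% 3L) != 0L
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  code <- Biostrings::GENETIC_CODE
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X",
               unname(code[codons]))
  aa[is.na(aa)] <- "X"
  structure(paste0(aa, collapse = ""), partial = partial)
}

#' Map a CDS coordinate to a genomic position
#'
#' @param model a [gene_model()].
#' @param cds_pos 0-based CDS coordinate(s).
#' @return 0-based genomic position(s) of those CDS bases.
#' @export
cds_to_genomic <- function(model, cds_pos) {
  stopifnot(all(cds_pos >= 0), all(cds_pos < model$cds_length))
  vapply(as.integer(cds_pos), function(p) {
    i <- findInterval(p, model$cds_offsets)
    off <- p - model$cds_offsets[i]
    if (model$strand == "+") model$exons[i, 1] + off
    else model$exons[i, 2] - 1L - off
  }, integer(1))
}

#' CDS coordinate to exon index
#'
#' @param model a [gene_model()].
#' @param cds_pos 0-based CDS coordinate(s).
#' @return 1-based exon index containing each position.
#' @export
cds_to_exon <- function(model, cds_pos) {
  findInterval(as.integer(cds_pos), model$cds_offsets)
}

#' Mirror a gene model onto the reverse-complemented genome
#'
#' Utility for strand-symmetry checks: returns the same gene annotated on
#' the opposite strand of the reverse-complemented chromosome, so that
#' [extract_cds()] yields an identical CDS.
#'
#' @param model a [gene_model()].
#' @param g a [genome()].
#' @return list with mirrored `model` and `genome`.
#' @export
mirror_model <- function(model, g) {
  L <- nchar(g[[model$chrom]])
  ex <- cbind(start = L - model$exons[, 2], end = L - model$exons[, 1])
  g2 <- genome(stats::setNames(
    vapply(names(g), function(id) revcomp(g[[id]]), character(1)),
    names(g)), source = attr(g, "source"))
  m2 <- gene_model(model$gene_id, model$chrom,
                   if (model$strand == "+") "-" else "+",
                   ex, model$start_codon_cds_pos)
  list(model = m2, genome = g2)
}
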