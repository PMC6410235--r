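#' Scan a sequence for assembly-gap runs
#'
#' Maximal runs of N of at least `min_run` bases, as 0-based half-open
#' intervals. Single ambiguous bases are not assembly gaps, hence the run
#' threshold (default 10).
#'
#' @param seq nucleotide string.
#' @param min_run minimum run length reported.
#' @return data.frame with columns `start`, `end`.
#' @export
scan_gaps <- function(seq, min_run = 10L) {
  if (nchar(seq) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  m <- gregexpr(sprintf("N{%d,}", min_run), seq)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

#' Read a BED-like annotation table
#'
#' Tab-separated with columns `gene_symbol`, `chrom`, `start`, `end`,
#' `strand`, `biotype` (0-based half-open coordinates).
#'
#' @param path TSV path.
#' @return data.frame sorted by (chrom, start).
#' @export
read_annotation_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_symbol", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(x)))
    stop("annotation table must have columns: ",
         paste(need, collapse = ", "))
  x[order(x$chrom, x$start), , drop = FALSE]
}

#' Write a BED-like annotation table
#' @param table annotation data.frame.
#' @param path TSV path.
#' @export
write_annotation_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collect the protein-coding flanking context of a gene
#'
#' The `n` nearest protein-coding genes on each side of the target gene, in
#' genomic order; non-coding entries are skipped and do not count. Lists
#' shorter than `n` (contig edge) are flagged truncated.
#'
#' @param table annotation data.frame (see [read_annotation_table()]).
#' @param gene target gene symbol (case-insensitive).
#' @param n flanking genes per side (default 5).
#' @param species_id label carried into the block.
#' @return object of class `synteny_block` with fields `species_id`,
#'   `target_gene`, `upstream`, `downstream` (gene symbols, genomic order),
#'   `truncated_upstream`, `truncated_downstream`, `target_state` (unset:
#'   `NA`) and `interval_n_runs`.
#' @export
flanking_context <- function(table, gene, n = 5L, species_id = "reference") {
  hit <- which(toupper(table$gene_symbol) == toupper(gene))
  if (length(hit) == 0) stop("reference gene missing: ", gene)
  hit <- hit[1]
  tab <- table[table$chrom == table$chrom[hit], , drop = FALSE]
  tab <- tab[order(tab$start), , drop = FALSE]
  pos <- which(toupper(tab$gene_symbol) == toupper(gene))[1]
  coding <- tab$biotype == "protein_coding"
  up_idx <- which(coding & seq_len(nrow(tab)) < pos)
  dn_idx <- which(coding & seq_len(nrow(tab)) > pos)
  up <- utils::tail(up_idx, n)
  dn <- utils::head(dn_idx, n)
  structure(list(
    species_id = species_id, target_gene = gene,
    upstream = tab$gene_symbol[up],      # genomic order, leftmost first
    downstream = tab$gene_symbol[dn],
    truncated_upstream = length(up) < n,
    truncated_downstream = length(dn) < n,
    target_state = NA_character_,
    interval_n_runs = data.frame(start = integer(0), end = integer(0))
  ), class = "synteny_block")
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("<synteny_block> %s / %s: [%s] > %s < [%s] state: %s\n",
              x$species_id, x$target_gene,
              paste(x$upstream, collapse = ","), x$target_gene,
              paste(x$downstream, collapse = ","), x$target_state))
  invisible(x)
}

#' Classify target-locus presence from synteny
#'
#' Locates the reference block's direct neighbours in a query annotation
#' and classifies the target state: `present` when the gene mapping has at
#' least one mapped exon; `remnant` when only sub-threshold alignments or
#' residual exon seeds exist in the inter-neighbour interval;
#' `absent_gapped` when the interval carries an assembly-gap run (missing
#' sequence, not evidence of deletion); `absent_complete` when the interval
#' is gap-free and yields no trace of the gene.
#'
#' @param ref_block reference [flanking_context()] block.
#' @param query_table query-species annotation data.frame.
#' @param query_genome query [genome()].
#' @param query_chrom chromosome to inspect in the query.
#' @param mapping the species' [map_gene()] result (may be `NULL`).
#' @param model,ref_genome reference gene model + genome for residual-seed
#'   screening (optional; skipped when `NULL`).
#' @param scheme a [scoring_scheme()].
#' @param min_run minimum N-run length treated as an assembly gap.
#' @param min_seed_support seed-cluster support (shared k-mers on one
#'   diagonal) required to call residual sequence a remnant, in addition
#'   to the 5%-of-exon-k-mers floor; a chance k-mer collision is not a
#'   remnant.
#' @param species_id label for the block.
#' @return a `synteny_block` with `target_state` and `interval_n_runs` set.
#' @export
compare_synteny <- function(ref_block, query_table, query_genome,
                            query_chrom, mapping = NULL, model = NULL,
                            ref_genome = NULL, scheme = scoring_scheme(),
                            min_run = 10L, min_seed_support = 3L,
                            species_id = "query") {
  left_sym <- utils::tail(ref_block$upstream, 1)
  right_sym <- utils::head(ref_block$downstream, 1)
  find <- function(sym) {
    i <- which(toupper(query_table$gene_symbol) == toupper(sym) &
                 query_table$chrom == query_chrom)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  li <- find(left_sym); ri <- find(right_sym)
  if (is.na(li) || is.na(ri))
    stop("synteny indeterminate: direct neighbour missing in query (",
         left_sym, "/", right_sym, ")")
  iv <- c(query_table$end[li], query_table$start[ri])
  if (iv[1] > iv[2]) iv <- c(query_table$end[ri], query_table$start[li])
  seg <- get_subseq(query_genome, query_chrom, iv[1], iv[2])
  runs <- scan_gaps(seg, min_run)
  runs$start <- runs$start + iv[1]; runs$end <- runs$end + iv[1]

  n_mapped <- if (is.null(mapping)) 0L else
    sum(vapply(mapping$alignments, function(a)
      identical(a$status, "mapped"), logical(1)))
  low_id <- if (is.null(mapping)) FALSE else
    any(vapply(mapping$alignments, function(a)
      identical(a$status, "low_identity"), logical(1)))

  state <- if (n_mapped > 0) {
    "present"
  } else if (low_id) {
    "remnant"
  } else {
    seeded <- FALSE
    if (!is.null(model) && !is.null(ref_genome) &&
        nchar(seg) >= scheme$word_size) {
      for (i in seq_len(nrow(model$exons))) {
        ex <- get_subseq(ref_genome, model$chrom, model$exons[i, 1],
                         model$exons[i, 2])
        if (model$strand == "-") ex <- revcomp(ex)
        sc <- seed_candidates(ex, seg, scheme)
        need <- max(min_seed_support,
                    solid_seed_support(nchar(ex), scheme$word_size))
        if (any(sc$support >= need)) {
          seeded <- TRUE; break
        }
      }
    }
    if (seeded) "remnant"
    else if (nrow(runs) > 0) "absent_gapped"
    else "absent_complete"
  }
  out <- ref_block
  out$species_id <- species_id
  out$target_state <- state
  out$interval_n_runs <- if (state == "absent_complete")
    data.frame(start = integer(0), end = integer(0)) else runs
  out
}

#' Tabular synteny report
#'
#' @param blocks list of `synteny_block` objects.
#' @return data.frame, one row per block.
#' @export
synteny_report <- function(blocks) {
  do.call(rbind, lapply(blocks, function(b) data.frame(
    species_id = b$species_id, target_gene = b$target_gene,
    upstream = paste(b$upstream, collapse = ","),
    downstream = paste(b$downstream, collapse = ","),
    target_state = b$target_state,
    n_gap_runs = nrow(b$interval_n_runs))))
}
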