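#' Construct a read set
#'
#' One read set per sequencing project or individual sample.
#'
#' @param sample_id non-empty sample label.
#' @param seqs character vector of read sequences.
#' @param ids read identifiers (generated when missing).
#' @param quals optional quality strings.
#' @return object of class `read_set`.
#' @export
read_set <- function(sample_id, seqs, ids = NULL, quals = NULL) {
  stopifnot(nzchar(sample_id))
  if (is.null(ids)) ids <- sprintf("%s_read%05d", sample_id, seq_along(seqs))
  structure(list(sample_id = sample_id,
                 reads = data.frame(read_id = ids, seq = toupper(seqs),
                                    qual = if (is.null(quals)) NA_character_
                                           else quals,
                                    stringsAsFactors = FALSE)),
            class = "read_set")
}

#' Read a read set from FASTQ or FASTA
#'
#' @param path FASTQ (`.fq`/`.fastq`) or FASTA file.
#' @param sample_id sample label (defaults to the file name).
#' @return a [read_set()].
#' @export
read_reads <- function(path, sample_id = basename(path)) {
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq"
         else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  read_set(sample_id, as.character(x), ids = names(x))
}

#' Write a read set as FASTQ
#'
#' @param rs a [read_set()].
#' @param path output path.
#' @export
write_reads_fastq <- function(rs, path) {
  seqs <- Biostrings::DNAStringSet(rs$reads$seq)
  names(seqs) <- rs$reads$read_id
  quals <- rs$reads$qual
  if (anyNA(quals))
    quals <- vapply(nchar(rs$reads$seq),
                    function(n) paste(rep("I", n), collapse = ""),
                    character(1))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

# identity of a semi-global read alignment over the read's span: gaps count
# against identity (mirrors read-filtering practice)
read_identity <- function(aln_cols_ref, aln_cols_tgt, read, window) {
  rb <- strsplit(read, "", fixed = TRUE)[[1]]
  wb <- strsplit(window, "", fixed = TRUE)[[1]]
  both <- !is.na(aln_cols_ref) & !is.na(aln_cols_tgt)
  m <- sum(rb[aln_cols_ref[both]] == wb[aln_cols_tgt[both]] &
             rb[aln_cols_ref[both]] != "N" & wb[aln_cols_tgt[both]] != "N")
  m / length(aln_cols_ref)
}

align_read <- function(read, window, scheme) {
  al <- .gotoh_semiglobal(read, window, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend)
  al$identity <- read_identity(al$ref_idx, al$tgt_idx, read, window)
  al
}

#' Validate a mutation call against raw reads
#'
#' Implements assembly-independent confirmation: every read is aligned (in
#' both orientations) to a reference haplotype and a mutant haplotype of the
#' locus; reads whose best identity falls below `min_identity` are filtered
#' out; a surviving read supports the allele of its higher-scoring haplotype
#' (equal scores: read ignored as ambiguous), and only counts if it spans
#' the event plus at least `flank` bases on both sides. The mutation is
#' `confirmed` when at least `min_samples` distinct samples each contribute
#' at least `min_reads` spanning mutant reads; with usable reads but too few
#' supporting samples it is `unconfirmed`; with no read sets at all,
#' `insufficient_data`.
#'
#' @param region list with `ref_seq`, `mut_seq` (the two haplotype windows),
#'   `ref_interval`, `mut_interval` (0-based half-open event intervals
#'   within each window; zero-length for a deletion junction in the mutant).
#' @param readsets list of [read_set()] objects.
#' @param scheme a [scoring_scheme()].
#' @param min_identity read filter threshold (default 0.95).
#' @param flank required spanning margin in nt (default 10).
#' @param min_samples samples required for confirmation (default 2).
#' @param min_reads spanning mutant reads required per sample (default 1).
#' @return list of class `read_support`: per-sample counts
#'   (`spanning_mutant`, `spanning_reference`, `filtered_out`),
#'   `supporting_samples` and `verdict`.
#' @export
validate_mutation <- function(region, readsets, scheme = scoring_scheme(),
                              min_identity = 0.95, flank = 10L,
                              min_samples = 2L, min_reads = 1L) {
  if (length(readsets) == 0) {
    return(structure(list(per_sample = data.frame(),
                          supporting_samples = character(0),
                          verdict = "insufficient_data",
                          note = "no read sets"),
                     class = "read_support"))
  }
  span_ref <- c(max(0L, region$ref_interval[1] - flank),
                min(nchar(region$ref_seq), region$ref_interval[2] + flank))
  span_mut <- c(max(0L, region$mut_interval[1] - flank),
                min(nchar(region$mut_seq), region$mut_interval[2] + flank))
  rows <- lapply(readsets, function(rs) {
    n_mut <- n_ref <- n_filt <- 0L
    for (seq in rs$reads$seq) {
      best <- NULL
      for (orient in c(seq, revcomp(seq))) {
        ar <- align_read(orient, region$ref_seq, scheme)
        am <- align_read(orient, region$mut_seq, scheme)
        cand <- if (ar$score >= am$score) list(a = ar, hap = "ref",
                                               other = am$score)
                else list(a = am, hap = "mut", other = ar$score)
        if (is.null(best) || cand$a$score > best$a$score) best <- cand
      }
      if (best$a$identity < min_identity) { n_filt <- n_filt + 1L; next }
      if (best$a$score == best$other) next          # ambiguous allele
      span <- if (best$hap == "mut") span_mut else span_ref
      covers <- best$a$subject_start <= span[1] &&
        best$a$subject_end >= span[2]
      if (!covers) next
      if (best$hap == "mut") n_mut <- n_mut + 1L else n_ref <- n_ref + 1L
    }
    data.frame(sample_id = rs$sample_id, spanning_mutant = n_mut,
               spanning_reference = n_ref, filtered_out = n_filt)
  })
  per_sample <- do.call(rbind, rows)
  supporting <- per_sample$sample_id[per_sample$spanning_mutant >= min_reads]
  verdict <- if (length(supporting) >= min_samples) "confirmed"
             else "unconfirmed"
  note <- if (verdict == "unconfirmed" && length(readsets) == 1L)
    "single sample" else ""
  structure(list(per_sample = per_sample,
                 supporting_samples = as.character(supporting),
                 verdict = verdict, note = note),
            class = "read_support")
}

#' @export
print.read_support <- function(x, ...) {
  cat(sprintf("<read_support> verdict: %s (%d supporting sample(s))\n",
              x$verdict, length(x$supporting_samples)))
  invisible(x)
}

#' Build ref/mut haplotype windows for a mutation call
#'
#' Cuts a window of the target genome around the call and reconstructs the
#' reference-allele haplotype by reverting the event, so reads can be
#' assigned to either allele.
#'
#' @param call one-row mutation-call data.frame (with target coordinates).
#' @param target target chromosome sequence.
#' @param flank window flank around the event (default 150 nt).
#' @return a `region` list as consumed by [validate_mutation()], or `NULL`
#'   when the call carries no target coordinates.
#' @export
mutation_region <- function(call, target, flank = 150L) {
  if (is.na(call$target_start) || is.na(call$target_end)) return(NULL)
  if (call$type %in% c("exon_deletion", "exon_missing_gap")) return(NULL)
  s <- max(0L, call$target_start - flank)
  e <- min(nchar(target), call$target_end + flank)
  mut <- substring(target, s + 1L, e)
  ev <- c(call$target_start - s, call$target_end - s)  # within window
  is_del <- call$type %in% c("frameshift_deletion", "inframe_deletion")
  is_ins <- call$type %in% c("frameshift_insertion", "inframe_insertion")
  if (is_del) {
    ref <- paste0(substring(mut, 1L, ev[1]), call$ref_allele,
                  substring(mut, ev[2] + 1L, nchar(mut)))
    ref_iv <- c(ev[1], ev[1] + call$length)
  } else if (is_ins) {
    ref <- paste0(substring(mut, 1L, ev[1]),
                  substring(mut, ev[2] + 1L, nchar(mut)))
    ref_iv <- c(ev[1], ev[1])
  } else {
    alt <- gsub("-", "", call$alt_allele, fixed = TRUE)
    ref <- paste0(substring(mut, 1L, ev[1]), call$ref_allele,
                  substring(mut, ev[2] + 1L, nchar(mut)))
    ref_iv <- c(ev[1], ev[1] + nchar(call$ref_allele))
  }
  list(ref_seq = ref, mut_seq = mut, ref_interval = ref_iv,
       mut_interval = ev)
}
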