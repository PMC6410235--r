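STOP_CODONS <- c("TAA", "TAG", "TGA")

MUTATION_TYPES <- c("premature_stop", "frameshift_deletion",
                    "frameshift_insertion", "inframe_deletion",
                    "inframe_insertion", "start_loss",
                    "splice_donor_noncanonical",
                    "splice_acceptor_noncanonical", "exon_deletion",
                    "exon_missing_gap")

# Hard ORF-disrupting classes: sufficient on their own for pseudogene status.
HARD_CALL_TYPES <- c("premature_stop", "frameshift_deletion",
                     "frameshift_insertion", "start_loss",
                     "splice_donor_noncanonical",
                     "splice_acceptor_noncanonical", "exon_deletion")

new_call <- function(species_id, gene_id, type, exon_index, cds_pos, length,
                     ref_allele, alt_allele, frame_consequence = "none",
                     fs_context = FALSE, target_start = NA_integer_,
                     target_end = NA_integer_, note = "") {
  data.frame(species_id = species_id, gene_id = gene_id, type = type,
             exon_index = as.integer(exon_index),
             cds_pos = as.integer(cds_pos), length = as.integer(length),
             ref_allele = ref_allele, alt_allele = alt_allele,
             frame_consequence = frame_consequence, fs_context = fs_context,
             target_start = as.integer(target_start),
             target_end = as.integer(target_end), note = note,
             stringsAsFactors = FALSE)
}

#' An empty mutation-call table
#'
#' @return zero-row data.frame with the mutation-call columns.
#' @export
empty_calls <- function() {
  new_call(character(0), character(0), character(0), integer(0), integer(0),
           integer(0), character(0), character(0), character(0), logical(0),
           integer(0), integer(0), character(0))
}

bind_calls <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(parts) == 0) return(empty_calls())
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# --- indel left-normalization (VCF-style, against the reference CDS) -------

# Shift a deletion of length L at 0-based CDS position p to its leftmost
# equivalent placement: allowed while the base before the deletion equals
# the last deleted base.
normalize_deletion <- function(ref_cds, p, L) {
  while (p > 0 && substring(ref_cds, p, p) == substring(ref_cds, p + L, p + L))
    p <- p - 1L
  list(pos = as.integer(p), allele = substring(ref_cds, p + 1L, p + L))
}

# Shift an insertion of sequence S before 0-based CDS position p leftwards,
# rotating S as it passes identical flanking bases.
normalize_insertion <- function(ref_cds, p, S) {
  L <- nchar(S)
  while (p > 0 && substring(ref_cds, p, p) == substring(S, L, L)) {
    S <- paste0(substring(ref_cds, p, p), substring(S, 1L, L - 1L))
    p <- p - 1L
  }
  list(pos = as.integer(p), allele = S)
}

# --- per-alignment gap-run extraction --------------------------------------

# Maximal gap runs of one mapped exon alignment, in CDS coordinates.
# kind "D": target-side gap (deletion in the species); "I": reference-side
# gap (insertion). Adjacent runs separated by >= 1 aligned column are
# separate events.
indel_runs <- function(aln, model, target) {
  ri <- aln$ref_idx; ti <- aln$tgt_idx
  off <- model$cds_offsets[aln$exon_index]
  kind <- ifelse(is.na(ti), "D", ifelse(is.na(ri), "I", "M"))
  r <- rle(kind)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  for (g in which(r$values != "M")) {
    cols <- starts[g]:ends[g]
    if (r$values[g] == "D") {
      cds0 <- off + ri[cols[1]] - 1L
      prev_t <- if (cols[1] > 1) {
        pt <- ti[seq_len(cols[1] - 1L)]
        pt <- pt[!is.na(pt)]
        if (length(pt)) pt[length(pt)] else NA_integer_
      } else NA_integer_
      junction <- if (!is.na(prev_t)) aln$window_offset + prev_t
                  else aln$target_start
      out[[length(out) + 1L]] <- data.frame(
        kind = "D", cds_pos = cds0, length = length(cols),
        seq = NA_character_, tstart = junction, tend = junction)
    } else {
      nxt <- cols[length(cols)] + 1L
      cds0 <- if (nxt <= length(ri) && !is.na(ri[nxt]))
        off + ri[nxt] - 1L else off + model$exon_lengths[aln$exon_index]
      tpos <- ti[cols]
      bases <- substring(target, aln$window_offset + tpos,
                         aln$window_offset + tpos)
      out[[length(out) + 1L]] <- data.frame(
        kind = "I", cds_pos = cds0, length = length(cols),
        seq = paste0(bases, collapse = ""),
        tstart = aln$window_offset + tpos[1] - 1L,
        tend = aln$window_offset + tpos[length(tpos)])
    }
  }
  if (length(out) == 0)
    data.frame(kind = character(0), cds_pos = integer(0),
               length = integer(0), seq = character(0), tstart = integer(0),
               tend = integer(0))
  else do.call(rbind, out)
}

#' Call insertion/deletion mutations from one exon alignment
#'
#' Each maximal gap run is one indel event: a target-side gap is a deletion,
#' a reference-side gap an insertion. Events are classified by length mod 3
#' (frameshift vs in-frame) and left-normalized VCF-style against the
#' reference CDS so that identical events match across species regardless of
#' alignment-dependent gap placement. `frame_consequence` here reflects the
#' cumulative frame along this exon alone; [call_mutations()] recomputes it
#' across the whole CDS.
#'
#' @param aln a mapped [align_exon()] result (status `"mapped"`).
#' @param model the reference [gene_model()].
#' @param ref_cds reference CDS string (from [extract_cds()]).
#' @param target target chromosome sequence (plain string).
#' @param species_id species label for the calls.
#' @return mutation-call data.frame (possibly zero rows).
#' @export
call_indels <- function(aln, model, ref_cds, target, species_id = "target") {
  if (!identical(aln$status, "mapped"))
    stop("cannot call on unmapped exon")
  runs <- indel_runs(aln, model, target)
  if (nrow(runs) == 0) return(empty_calls())
  calls <- lapply(seq_len(nrow(runs)), function(i) {
    r <- runs[i, ]
    if (r$kind == "D") {
      nz <- normalize_deletion(ref_cds, r$cds_pos, r$length)
      type <- if (r$length %% 3L == 0L) "inframe_deletion"
              else "frameshift_deletion"
      new_call(species_id, model$gene_id, type,
               cds_to_exon(model, nz$pos), nz$pos, r$length,
               nz$allele, "-", target_start = r$tstart, target_end = r$tend)
    } else {
      nz <- normalize_insertion(ref_cds, r$cds_pos, r$seq)
      type <- if (r$length %% 3L == 0L) "inframe_insertion"
              else "frameshift_insertion"
      exl <- cds_to_exon(model, min(nz$pos, model$cds_length - 1L))
      new_call(species_id, model$gene_id, type, exl, nz$pos, r$length,
               "-", nz$allele, target_start = r$tstart, target_end = r$tend)
    }
  })
  out <- do.call(bind_calls, calls)
  assign_frame_consequence(out)
}

# Cumulative frame bookkeeping over a set of indel calls (sorted by CDS
# position): an event leaving the frame shifted is shift+1/shift+2; an event
# returning a shifted frame to 0 is "restored"; everything else "none".
assign_frame_consequence <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  idx <- which(calls$type %in% c("frameshift_deletion", "inframe_deletion",
                                 "frameshift_insertion", "inframe_insertion"))
  if (length(idx) == 0) return(calls)
  o <- idx[order(calls$cds_pos[idx])]
  cum <- 0L
  for (i in o) {
    delta <- if (grepl("insertion", calls$type[i])) calls$length[i]
             else -calls$length[i]
    before <- ((cum %% 3L) + 3L) %% 3L
    cum <- cum + delta
    after <- ((cum %% 3L) + 3L) %% 3L
    own <- calls$length[i] %% 3L
    # shifting events are labelled by their own length mod 3; the signed
    # running total decides whether the frame is intact or restored
    calls$frame_consequence[i] <-
      if (own == 0L) "none"
      else if (after == 0L) "restored"
      else paste0("shift+", own)
  }
  calls
}

# --- projection of the target onto the reference CDS grid ------------------

# Per-CDS-position target base ("-" where deleted, NA where the exon is not
# mapped), target positions, and indel events, pooled over mapped exons.
project_cds <- function(mapping, model, target) {
  n <- model$cds_length
  tb <- rep(NA_character_, n)
  tp <- rep(NA_integer_, n)
  ins <- del <- list()
  for (aln in mapping$alignments) {
    if (!identical(aln$status, "mapped")) next
    off <- model$cds_offsets[aln$exon_index]
    ri <- aln$ref_idx; ti <- aln$tgt_idx
    m <- !is.na(ri)
    cds <- off + ri[m]
    tpos <- ti[m]
    has_t <- !is.na(tpos)
    tb[cds[has_t]] <- substring(target, aln$window_offset + tpos[has_t],
                                aln$window_offset + tpos[has_t])
    tp[cds[has_t]] <- aln$window_offset + tpos[has_t]
    tb[cds[!has_t]] <- "-"
    runs <- indel_runs(aln, model, target)
    if (nrow(runs)) {
      ins[[length(ins) + 1L]] <- runs[runs$kind == "I", ]
      del[[length(del) + 1L]] <- runs[runs$kind == "D", ]
    }
  }
  list(tb = tb, tp = tp,
       ins = if (length(ins)) do.call(rbind, ins) else NULL,
       del = if (length(del)) do.call(rbind, del) else NULL)
}

# net frame shift accumulated strictly upstream of CDS position c
shift_before <- function(proj, c) {
  s <- 0L
  if (!is.null(proj$ins) && nrow(proj$ins))
    s <- s + sum(proj$ins$length[proj$ins$cds_pos <= c])
  if (!is.null(proj$del) && nrow(proj$del))
    s <- s - sum(proj$del$length[proj$del$cds_pos < c])
  s
}

#' Call premature stop codons
#'
#' Target codons are read on the reference codon grid: a reference codon is
#' inspected only where all three of its bases are mapped and aligned
#' (no gaps or insertions within the codon) and the cumulative frame at the
#' codon start is intact (no shift, or a restored one). Any stop codon
#' strictly before the reference stop yields one call. Stops arising
#' downstream of an uncompensated frameshift are reported separately with
#' `fs_context = TRUE` (the first stop per shifted run), never as
#' independent events.
#'
#' @param mapping a [map_gene()] result.
#' @param model the reference [gene_model()].
#' @param ref_cds reference CDS string.
#' @param target target chromosome sequence.
#' @param species_id species label.
#' @return mutation-call data.frame.
#' @export
call_premature_stops <- function(mapping, model, ref_cds, target,
                                 species_id = "target") {
  proj <- project_cds(mapping, model, target)
  tb <- proj$tb
  ncod <- model$cds_length %/% 3L
  calls <- list()
  for (k in seq_len(ncod - 1L) - 1L) {      # exclude the reference stop
    c0 <- 3L * k
    bases <- tb[(c0 + 1L):(c0 + 3L)]
    if (anyNA(bases) || any(bases == "-")) next
    if (!is.null(proj$ins) && nrow(proj$ins) &&
        any(proj$ins$cds_pos %in% c(c0 + 1L, c0 + 2L))) next
    if (shift_before(proj, c0) %% 3L != 0L) next
    codon <- paste0(bases, collapse = "")
    if (codon %in% STOP_CODONS) {
      calls[[length(calls) + 1L]] <- new_call(
        species_id, model$gene_id, "premature_stop",
        cds_to_exon(model, c0), c0, 3L,
        substring(ref_cds, c0 + 1L, c0 + 3L), codon,
        target_start = proj$tp[c0 + 1L] - 1L,
        target_end = proj$tp[c0 + 3L])
    }
  }
  # first stop downstream of each uncompensated frameshift, flagged
  calls <- c(calls, fs_context_stops(proj, model, ref_cds, species_id))
  do.call(bind_calls, calls)
}

fs_context_stops <- function(proj, model, ref_cds, species_id) {
  ev <- rbind(
    if (!is.null(proj$ins) && nrow(proj$ins))
      data.frame(pos = proj$ins$cds_pos, delta = proj$ins$length),
    if (!is.null(proj$del) && nrow(proj$del))
      data.frame(pos = proj$del$cds_pos, delta = -proj$del$length))
  if (is.null(ev) || nrow(ev) == 0) return(list())
  ev <- ev[order(ev$pos), , drop = FALSE]
  cum <- cumsum(ev$delta)
  out <- list()
  for (i in seq_len(nrow(ev))) {
    if (cum[i] %% 3L == 0L) next
    if (i > 1 && cum[i - 1] %% 3L != 0L) next   # not the run opener
    run_end <- model$cds_length
    for (j in seq_len(nrow(ev))[-seq_len(i)]) {
      if (cum[j] %% 3L == 0L) { run_end <- ev$pos[j]; break }
    }
    q <- ev$pos[i]
    # read target triplets in the shifted mutant frame
    repeat {
      if (q + 2L >= run_end || q + 3L > model$cds_length) break
      bases <- proj$tb[(q + 1L):(q + 3L)]
      if (anyNA(bases) || any(bases == "-")) { q <- q + 3L; next }
      m <- (q + shift_before(proj, q)) %% 3L
      if (m != 0L) { q <- q + (3L - m); next }
      codon <- paste0(bases, collapse = "")
      if (codon %in% STOP_CODONS) {
        out[[length(out) + 1L]] <- new_call(
          species_id, model$gene_id, "premature_stop",
          cds_to_exon(model, q), q, 3L,
          substring(ref_cds, q + 1L, q + 3L), codon,
          frame_consequence = "shifted", fs_context = TRUE,
          target_start = proj$tp[q + 1L] - 1L, target_end = proj$tp[q + 3L],
          note = "downstream of uncompensated frameshift")
        break
      }
      q <- q + 3L
    }
  }
  out
}

#' Check the start codon
#'
#' Calls `start_loss` when the three target bases aligned to the reference
#' ATG are not ATG; gaps count as loss. When the start-containing exon is
#' not mapped no call is made and the result carries
#' `attr(, "indeterminate") = TRUE`.
#'
#' @inheritParams call_premature_stops
#' @return mutation-call data.frame (zero or one row).
#' @export
check_start_codon <- function(mapping, model, target,
                              species_id = "target") {
  k <- cds_to_exon(model, model$start_codon_cds_pos)
  aln <- mapping$alignments[[k]]
  if (!identical(aln$status, "mapped")) {
    out <- empty_calls()
    attr(out, "indeterminate") <- TRUE
    attr(out, "note") <- "indeterminate start"
    return(out)
  }
  proj <- project_cds(mapping, model, target)
  p <- model$start_codon_cds_pos
  bases <- proj$tb[(p + 1L):(p + 3L)]
  bases[is.na(bases)] <- "-"
  alt <- paste0(bases, collapse = "")
  if (alt == "ATG") return(empty_calls())
  new_call(species_id, model$gene_id, "start_loss", k, p, 3L, "ATG", alt,
           target_start = if (!is.na(proj$tp[p + 1L])) proj$tp[p + 1L] - 1L
                          else NA_integer_,
           target_end = proj$tp[p + 3L])
}

#' Check splice-site dinucleotides
#'
#' For each inferred intron between consecutive mapped exons, inspects the
#' first two (donor) and last two (acceptor) intronic bases. Canonical sites
#' are GT/AG only; a GC donor is still non-canonical but annotated
#' `"GC-AG minor"`. N at either position yields no call (indeterminate).
#'
#' @inheritParams call_premature_stops
#' @return mutation-call data.frame.
#' @export
check_splice_sites <- function(mapping, model, target,
                               species_id = "target") {
  alns <- mapping$alignments
  calls <- list()
  for (i in seq_len(length(alns) - 1L)) {
    a <- alns[[i]]; b <- alns[[i + 1L]]
    if (!identical(a$status, "mapped") || !identical(b$status, "mapped"))
      next
    if (b$target_start < a$target_end + 4L) next   # no resolvable intron
    donor <- substring(target, a$target_end + 1L, a$target_end + 2L)
    acceptor <- substring(target, b$target_start - 1L, b$target_start)
    bnd <- model$cds_offsets[i + 1L]
    if (!grepl("N", donor, fixed = TRUE) && donor != "GT") {
      calls[[length(calls) + 1L]] <- new_call(
        species_id, model$gene_id, "splice_donor_noncanonical", i, bnd, 2L,
        "GT", donor, target_start = a$target_end,
        target_end = a$target_end + 2L,
        note = if (donor == "GC") "GC-AG minor" else "")
    }
    if (!grepl("N", acceptor, fixed = TRUE) && acceptor != "AG") {
      calls[[length(calls) + 1L]] <- new_call(
        species_id, model$gene_id, "splice_acceptor_noncanonical", i + 1L,
        bnd, 2L, "AG", acceptor, target_start = b$target_start - 2L,
        target_end = b$target_start)
    }
  }
  do.call(bind_calls, calls)
}

#' Call whole-exon losses
#'
#' For each exon the mapper could not place: `exon_deletion` when both
#' flanking exons are mapped and the intervening target interval carries no
#' assembly-gap run and no residual exon seeds; `exon_missing_gap` when the
#' interval contains an N run of at least `min_run`, when residual seeds
#' suggest a remnant, or when the exon sits at a gene terminus with no
#' flanking anchor on one side (assembly truncation cannot be excluded).
#'
#' @inheritParams call_premature_stops
#' @param ref_genome reference [genome()] (for residual-seed screening).
#' @param scheme a [scoring_scheme()].
#' @param min_run minimum N-run length treated as an assembly gap.
#' @return mutation-call data.frame.
#' @export
call_exon_loss <- function(mapping, model, ref_genome, target,
                           scheme = scoring_scheme(), min_run = 10L,
                           species_id = "target") {
  alns <- mapping$alignments
  mapped_idx <- which(vapply(alns, function(a)
    identical(a$status, "mapped"), logical(1)))
  calls <- list()
  for (i in seq_along(alns)) {
    if (!alns[[i]]$status %in% c("missing_no_gap", "missing_in_gap")) next
    left <- mapped_idx[mapped_idx < i]
    right <- mapped_idx[mapped_idx > i]
    off <- model$cds_offsets[i]
    len <- model$exon_lengths[i]
    if (!length(left) || !length(right)) {
      iv <- project_interval(alns, i, left, right, nchar(target))
      calls[[length(calls) + 1L]] <- new_call(
        species_id, model$gene_id, "exon_missing_gap", i, off, len, "", "-",
        target_start = if (is.null(iv)) NA_integer_ else iv[1],
        target_end = if (is.null(iv)) NA_integer_ else iv[2],
        note = "no flanking anchor")
      next
    }
    iv <- c(alns[[max(left)]]$target_end, alns[[min(right)]]$target_start)
    seg <- substring(target, iv[1] + 1L, iv[2])
    runs <- scan_gaps(seg, min_run)
    exon_seq <- get_subseq(ref_genome, model$chrom,
                           model$exons[i, 1], model$exons[i, 2])
    if (model$strand == "-") exon_seq <- revcomp(exon_seq)
    seeds <- if (nchar(seg) >= scheme$word_size)
      seed_candidates(exon_seq, seg, scheme) else
      data.frame(support = integer(0))
    seeds <- seeds[seeds$support >=
                     solid_seed_support(nchar(exon_seq), scheme$word_size),
                   , drop = FALSE]
    if (nrow(runs) > 0) {
      calls[[length(calls) + 1L]] <- new_call(
        species_id, model$gene_id, "exon_missing_gap", i, off, len, "", "-",
        target_start = iv[1], target_end = iv[2])
    } else if (nrow(seeds) > 0) {
      calls[[length(calls) + 1L]] <- new_call(
        species_id, model$gene_id, "exon_missing_gap", i, off, len, "", "-",
        target_start = iv[1], target_end = iv[2], note = "remnant_hits")
    } else {
      calls[[length(calls) + 1L]] <- new_call(
        species_id, model$gene_id, "exon_deletion", i, off, len, "", "-",
        target_start = iv[1], target_end = iv[2])
    }
  }
  do.call(bind_calls, calls)
}

#' Call all ORF-relevant mutations for one species x gene
#'
#' Aggregates [call_indels()] (all mapped exons, with genome-wide cumulative
#' frame bookkeeping), [call_premature_stops()], [check_start_codon()],
#' [check_splice_sites()] and [call_exon_loss()] into one mutation table.
#'
#' @param mapping a [map_gene()] result.
#' @param model the reference [gene_model()].
#' @param ref_genome reference [genome()].
#' @param target_genome target [genome()].
#' @param scheme a [scoring_scheme()].
#' @param species_id species label (defaults to the mapping's).
#' @return mutation-call data.frame sorted by CDS position.
#' @export
call_mutations <- function(mapping, model, ref_genome, target_genome,
                           scheme = scoring_scheme(),
                           species_id = mapping$species_id) {
  target <- target_genome[[mapping$target_id]]
  ref_cds <- extract_cds(model, ref_genome)
  indels <- lapply(mapping$alignments, function(a) {
    if (identical(a$status, "mapped"))
      call_indels(a, model, ref_cds, target, species_id)
    else empty_calls()
  })
  out <- bind_calls(
    do.call(bind_calls, indels),
    call_premature_stops(mapping, model, ref_cds, target, species_id),
    check_start_codon(mapping, model, target, species_id),
    check_splice_sites(mapping, model, target, species_id),
    call_exon_loss(mapping, model, ref_genome, target, scheme,
                   species_id = species_id))
  out <- assign_frame_consequence(out)
  out[order(out$cds_pos, out$type), , drop = FALSE]
}

#' Write a mutation table as TSV
#'
#' CDS positions are converted to the 1-based convention for human-readable
#' output.
#'
#' @param calls mutation-call data.frame.
#' @param path output path.
#' @export
write_mutation_tsv <- function(calls, path) {
  out <- calls
  out$cds_pos <- out$cds_pos + 1L
  if (!is.null(out$target_start)) out$target_start <- out$target_start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
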