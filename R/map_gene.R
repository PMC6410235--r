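#' Project a reference gene model onto a target genomic sequence
#'
#' Each reference exon is independently seeded ([seed_candidates()]) and
#' aligned ([align_exon()]) in the target; the best-scoring placement is
#' kept. Exons whose best alignment falls below the identity threshold are
#' `low_identity`; exons with no seeds are `missing_in_gap` when at least
#' `gap_frac` of the expected target interval (projected from the nearest
#' mapped flanking exons) is N, otherwise `missing_no_gap`. Overlapping
#' placements are resolved by keeping the higher-scoring exon and remapping
#' the other against its remaining candidates.
#'
#' @param model a [gene_model()] (reference).
#' @param ref_genome the reference [genome()] the model annotates.
#' @param target_genome target [genome()].
#' @param target_id sequence in `target_genome` to search.
#' @param scheme a [scoring_scheme()].
#' @param min_identity acceptance threshold for calling an exon mapped
#'   (fraction of matched columns, default 0.60: tolerant of
#'   cross-species divergence while rejecting spurious windows).
#' @param gap_frac N fraction of the projected interval above which a
#'   missing exon is considered to sit in an assembly gap.
#' @param max_candidates candidate windows to evaluate per exon.
#' @param species_id label carried into the mapping.
#' @return an object of class `gene_mapping`: fields `species_id`,
#'   `gene_id`, `target_id`, `alignments` (one [align_exon()] result or
#'   missing-exon record per exon, in transcription order) and `colinear`.
#' @export
map_gene <- function(model, ref_genome, target_genome, target_id,
                     scheme = scoring_scheme(), min_identity = 0.60,
                     gap_frac = 0.30, max_candidates = 5L,
                     species_id = target_id) {
  if (!target_id %in% names(target_genome))
    stop("target sequence not found: ", target_id)
  target <- target_genome[[target_id]]
  nex <- nrow(model$exons)
  exon_seqs <- vapply(seq_len(nex), function(i) {
    s <- get_subseq(ref_genome, model$chrom,
                    model$exons[i, 1], model$exons[i, 2])
    if (model$strand == "-") revcomp(s) else s
  }, character(1))

  per_exon <- vector("list", nex)
  for (i in seq_len(nex)) {
    cand <- seed_candidates(exon_seqs[i], target, scheme)
    if (nrow(cand) == 0) {
      per_exon[[i]] <- list(best = NULL, alternatives = list())
      next
    }
    chain <- find_chain(cand)
    cand <- utils::head(cand, max_candidates)
    alns <- lapply(seq_len(nrow(cand)), function(j) {
      w <- substr(target, cand$start[j] + 1L, cand$end[j])
      a <- align_exon(exon_seqs[i], w, scheme, exon_index = i,
                      window_offset = cand$start[j])
      a$seed_support <- cand$support[j]
      a
    })
    sc <- vapply(alns, `[[`, numeric(1), "score")
    st <- vapply(alns, `[[`, integer(1), "target_start")
    o <- order(-sc, st)
    if (!is.null(chain)) {
      # collinear seed clusters imply a long structural indel: piecewise
      # seed-anchored alignment instead of one semi-global pass
      best <- chain_align(exon_seqs[i], target, chain, scheme,
                          exon_index = i,
                          wstart = min(chain$start),
                          wend = max(chain$end))
      per_exon[[i]] <- list(best = best, alternatives = alns[o])
    } else {
      per_exon[[i]] <- list(best = alns[[o[1]]],
                            alternatives = alns[o[-1]])
    }
  }

  # overlap resolution: keep higher score, retry loser on its alternatives
  repeat {
    placed <- which(!vapply(per_exon, function(e) is.null(e$best), logical(1)))
    if (length(placed) < 2) break
    iv <- t(vapply(placed, function(i)
      c(per_exon[[i]]$best$target_start, per_exon[[i]]$best$target_end),
      integer(2)))
    conflict <- NULL
    for (a in seq_along(placed)) for (b in seq_along(placed)) {
      if (a < b && iv[a, 1] < iv[b, 2] && iv[b, 1] < iv[a, 2]) {
        conflict <- c(placed[a], placed[b]); break
      }
    }
    if (is.null(conflict)) break
    sa <- per_exon[[conflict[1]]]$best$score
    sb <- per_exon[[conflict[2]]]$best$score
    loser <- if (sa >= sb) conflict[2] else conflict[1]
    winner <- setdiff(conflict, loser)
    wiv <- c(per_exon[[winner]]$best$target_start,
             per_exon[[winner]]$best$target_end)
    alts <- Filter(function(a)
      a$target_end <= wiv[1] || a$target_start >= wiv[2],
      per_exon[[loser]]$alternatives)
    per_exon[[loser]]$best <- if (length(alts)) alts[[1]] else NULL
    per_exon[[loser]]$alternatives <- if (length(alts)) alts[-1] else list()
  }

  alignments <- vector("list", nex)
  for (i in seq_len(nex)) {
    b <- per_exon[[i]]$best
    if (!is.null(b) && !isTRUE(b$chained))
      b <- trim_noise_tails(b, exon_seqs[i], target, scheme)
    # a sub-threshold alignment only counts as a remnant (low_identity)
    # when backed by solid seeding; a window seeded by a chance k-mer
    # collision is no placement at all
    need <- solid_seed_support(nchar(exon_seqs[i]), scheme$word_size)
    if (!is.null(b) && b$identity < min_identity &&
        !isTRUE(b$chained) &&
        (is.null(b$seed_support) || b$seed_support < need))
      b <- NULL
    if (!is.null(b)) {
      b$status <- if (b$identity >= min_identity) "mapped" else "low_identity"
      alignments[[i]] <- b
    } else {
      alignments[[i]] <- structure(list(
        exon_index = i, score = NA_integer_, identity = NA_real_,
        ref_idx = NULL, tgt_idx = NULL, window_offset = NA_integer_,
        target_start = NA_integer_, target_end = NA_integer_,
        status = "missing_no_gap"), class = "exon_alignment")
    }
  }

  # refine missing statuses via the interval projected from mapped flanks
  mapped_idx <- which(vapply(alignments, function(a) a$status == "mapped",
                             logical(1)))
  for (i in seq_len(nex)) {
    if (alignments[[i]]$status %in% c("mapped", "low_identity")) next
    left <- mapped_idx[mapped_idx < i]
    right <- mapped_idx[mapped_idx > i]
    proj <- project_interval(alignments, i, left, right, nchar(target))
    alignments[[i]]$projected <- proj
    if (!is.null(proj)) {
      seg <- substr(target, proj[1] + 1L, proj[2])
      nfrac <- if (nchar(seg) > 0)
        sum(strsplit(seg, "", fixed = TRUE)[[1]] == "N") / nchar(seg) else 0
      alignments[[i]]$status <-
        if (nfrac >= gap_frac) "missing_in_gap" else "missing_no_gap"
    }
  }

  starts <- vapply(alignments[mapped_idx], `[[`, integer(1), "target_start")
  ends <- vapply(alignments[mapped_idx], `[[`, integer(1), "target_end")
  colinear <- length(mapped_idx) <= 1 ||
    (all(diff(starts) > 0) && all(starts[-1] >= ends[-length(ends)]))

  structure(list(species_id = species_id, gene_id = model$gene_id,
                 target_id = target_id, alignments = alignments,
                 colinear = colinear),
            class = "gene_mapping")
}

# expected target interval of exon i, projected from nearest mapped flanks
project_interval <- function(alignments, i, left, right, target_len) {
  if (length(left) && length(right)) {
    c(alignments[[max(left)]]$target_end,
      alignments[[min(right)]]$target_start)
  } else if (length(left)) {
    c(alignments[[max(left)]]$target_end, target_len)
  } else if (length(right)) {
    c(0L, alignments[[min(right)]]$target_start)
  } else NULL
}

#' @export
print.gene_mapping <- function(x, ...) {
  cat(sprintf("<gene_mapping> %s / %s on %s (colinear: %s)\n",
              x$species_id, x$gene_id, x$target_id, x$colinear))
  for (a in x$alignments)
    cat(sprintf("  exon %d: %s%s\n", a$exon_index, a$status,
                if (a$status %in% c("mapped", "low_identity"))
                  sprintf(" [%d,%d) id %.3f", a$target_start, a$target_end,
                          a$identity) else ""))
  invisible(x)
}

#' Tabular summary of a gene mapping
#'
#' One row per exon: interval (1-based closed in output, per reporting
#' convention), identity, score, status.
#'
#' @param mapping a [map_gene()] result.
#' @return data.frame.
#' @export
mapping_summary <- function(mapping) {
  do.call(rbind, lapply(mapping$alignments, function(a) data.frame(
    species_id = mapping$species_id, gene_id = mapping$gene_id,
    exon = a$exon_index,
    target_start = if (is.na(a$target_start)) NA_integer_
                   else a$target_start + 1L,
    target_end = a$target_end,
    identity = a$identity, score = a$score, status = a$status)))
}
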