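#' Alignment scoring scheme
#'
#' Defaults are blastn-like: match +2, mismatch -3, gap open -5, gap extend
#' -2, seeding word size 10. A gap of length L costs
#' `gap_open + (L-1) * gap_extend`. Columns involving N score 0 (neither
#' match nor mismatch) and never count as identity, so assembly gaps can
#' neither create nor mask mutations.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open gap-opening score (<= gap_extend < 0).
#' @param gap_extend gap-extension score (< 0).
#' @param word_size exact k-mer length used for seeding (>= 4).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, word_size = 10L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= gap_extend, gap_extend < 0,
            word_size >= 4)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size)),
            class = "scoring_scheme")
}

#' Find candidate placements of an exon in a target sequence by k-mer seeding
#'
#' Exact shared k-mers between exon and target are clustered by alignment
#' diagonal (within a band); each cluster yields one candidate interval,
#' expanded by a flank of the exon length on each side. Candidates are
#' sorted by diagonal support (number of seed hits, descending); ties are
#' broken by leftmost target start.
#'
#' @param exon_seq exon nucleotide string (length >= `word_size`).
#' @param target target nucleotide string.
#' @param scheme a [scoring_scheme()].
#' @param band diagonal band width for merging seeds.
#' @return data.frame with columns `start`, `end` (0-based half-open
#'   candidate interval, flank included), `support`, `seed_start`,
#'   `seed_end` (unexpanded seed extent). Zero rows when nothing seeds.
#' @export
seed_candidates <- function(exon_seq, target, scheme = scoring_scheme(),
                            band = 16L) {
  k <- scheme$word_size
  L <- nchar(exon_seq)
  m <- nchar(target)
  empty <- data.frame(start = integer(0), end = integer(0),
                      support = integer(0), seed_start = integer(0),
                      seed_end = integer(0))
  if (L < k || m < k) return(empty)
  qk <- substring(exon_seq, 1:(L - k + 1L), k:L)
  tk <- substring(target, 1:(m - k + 1L), k:m)
  # positions of each target k-mer, keyed by k-mer
  idx <- match(qk, tk)                      # quick reject when nothing shared
  shared <- unique(qk[!is.na(idx)])
  if (length(shared) == 0) return(empty)
  tpos_by_kmer <- split(seq_along(tk), tk)
  hits_q <- integer(0); hits_t <- integer(0)
  for (q in seq_along(qk)) {
    tp <- tpos_by_kmer[[qk[q]]]
    if (!is.null(tp)) {
      hits_q <- c(hits_q, rep.int(q, length(tp)))
      hits_t <- c(hits_t, tp)
    }
  }
  if (length(hits_q) == 0) return(empty)
  d <- hits_t - hits_q
  o <- order(d, hits_t)
  d <- d[o]; hq <- hits_q[o]; ht <- hits_t[o]
  grp <- cumsum(c(1L, as.integer(diff(d) > band)))
  res <- do.call(rbind, lapply(split(seq_along(grp), grp), function(ii) {
    s <- min(ht[ii]) - 1L                  # to 0-based
    e <- max(ht[ii]) + k - 1L
    qs <- min(hq[ii]) - 1L
    qe <- max(hq[ii]) + k - 1L
    # window flanks sized by the unseeded query remainder on each side:
    # enough to place the rest of the exon, no room to drift
    data.frame(start = max(0L, s - qs - 30L),
               end = min(m, e + (L - qe) + 30L),
               support = length(ii), seed_start = s, seed_end = e,
               q_start = qs, q_end = qe,
               diag = stats::median(d[ii]))
  }))
  res <- res[order(-res$support, res$seed_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Align one exon within a genomic window
#'
#' Semi-global affine-gap alignment under the Gotoh three-state recurrence:
#' global in the exon, free end-gaps in the window. Traceback is
#' deterministic (tie order diagonal > up > left), so identical inputs yield
#' byte-identical alignments.
#'
#' @param exon_seq exon nucleotide string.
#' @param window nucleotide string of the candidate genomic window.
#' @param scheme a [scoring_scheme()].
#' @param exon_index optional exon number carried in the result.
#' @param window_offset 0-based offset of `window` within its chromosome;
#'   reported `target_start`/`target_end` are absolute.
#' @return an object of class `exon_alignment` with fields `exon_index`,
#'   `score`, `identity` (matched columns / total columns; N never counts as
#'   a match), `ref_idx` / `tgt_idx` (per-column 1-based indices, NA at
#'   gaps; `tgt_idx` absolute would overflow ints for huge genomes so it is
#'   window-relative plus `window_offset`), `target_start`, `target_end`
#'   (0-based half-open, absolute) and `status` (set by [map_gene()]).
#' @export
align_exon <- function(exon_seq, window, scheme = scoring_scheme(),
                       exon_index = NA_integer_, window_offset = 0L) {
  stopifnot(nchar(exon_seq) > 0, nchar(window) > 0)
  al <- .gotoh_semiglobal(exon_seq, window, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend)
  rb <- strsplit(exon_seq, "", fixed = TRUE)[[1]]
  wb <- strsplit(window, "", fixed = TRUE)[[1]]
  ri <- al$ref_idx; ti <- al$tgt_idx
  both <- !is.na(ri) & !is.na(ti)
  rc <- rb[ri[both]]; wc <- wb[ti[both]]
  matched <- sum(rc == wc & rc != "N" & wc != "N")
  structure(list(
    exon_index = as.integer(exon_index),
    score = al$score,
    identity = matched / length(ri),
    ref_idx = ri,
    tgt_idx = ti,
    window_offset = as.integer(window_offset),
    target_start = as.integer(window_offset + al$subject_start),
    target_end = as.integer(window_offset + al$subject_end),
    status = "mapped"
  ), class = "exon_alignment")
}

# raw segment alignment: columns as 1-based indices into pattern/subject,
# degenerate segments handled without the DP
align_segment <- function(pattern, subject, scheme, free_begin, free_end) {
  np <- nchar(pattern); ns <- nchar(subject)
  if (np == 0 && ns == 0)
    return(list(ref_idx = integer(0), tgt_idx = integer(0)))
  if (np == 0)
    return(list(ref_idx = rep(NA_integer_, ns), tgt_idx = seq_len(ns)))
  if (ns == 0)
    return(list(ref_idx = seq_len(np), tgt_idx = rep(NA_integer_, np)))
  al <- .gotoh_semiglobal(pattern, subject, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          free_begin, free_end)
  list(ref_idx = al$ref_idx, tgt_idx = al$tgt_idx,
       subject_start = al$subject_start, subject_end = al$subject_end)
}

# affine re-scoring of a finished column list
score_columns <- function(ref_idx, tgt_idx, exon_seq, target, scheme) {
  if (length(ref_idx) == 0) return(list(score = 0L, identity = 0))
  rb <- strsplit(exon_seq, "", fixed = TRUE)[[1]]
  tb <- strsplit(target, "", fixed = TRUE)[[1]]
  kind <- ifelse(is.na(tgt_idx), "D", ifelse(is.na(ref_idx), "I", "M"))
  both <- kind == "M"
  rc <- rb[ref_idx[both]]; tc <- tb[tgt_idx[both]]
  isn <- rc == "N" | tc == "N"
  sub_score <- sum(ifelse(isn, 0L,
                          ifelse(rc == tc, scheme$match, scheme$mismatch)))
  r <- rle(kind)
  gaps <- r$lengths[r$values != "M"]
  gap_score <- if (length(gaps))
    sum(scheme$gap_open + (gaps - 1L) * scheme$gap_extend) else 0L
  list(score = as.integer(sub_score + gap_score),
       identity = sum(rc == tc & !isn) / length(kind))
}

# Seed-anchored chained alignment for long structural indels. With
# blastn-like scores, extending one gap costs more per column than drifting
# through unrelated sequence, so a single semi-global pass shreds long
# deletions into noise (the reason blastn reports them as separate local
# hits). When collinear seed clusters imply a diagonal jump of at least
# `long_gap`, the exon is aligned piecewise instead: each seed block and
# each inter-block segment is aligned under hard end constraints, and the
# concatenated columns yield the structural indel as one clean gap run.
chain_align <- function(exon_seq, target, chain, scheme,
                        exon_index = NA_integer_, wstart = 0L,
                        wend = nchar(target)) {
  # joint overlap trimming keeps blocks on their exact-match diagonals
  n <- nrow(chain)
  for (j in seq_len(n - 1L)) {
    ov <- max(chain$q_end[j] - chain$q_start[j + 1L],
              chain$seed_end[j] - chain$seed_start[j + 1L], 0L)
    chain$q_end[j] <- chain$q_end[j] - ov
    chain$seed_end[j] <- chain$seed_end[j] - ov
  }
  L <- nchar(exon_seq)
  ref_cols <- integer(0); tgt_cols <- integer(0)
  push <- function(seg, q_off, t_off) {
    ref_cols <<- c(ref_cols, seg$ref_idx + q_off)
    tgt_cols <<- c(tgt_cols, seg$tgt_idx + t_off)
  }
  # leading overhang: free subject start, pinned at the first seed
  if (chain$q_start[1] > 0L) {
    sub0 <- max(wstart, chain$seed_start[1] - 2L * chain$q_start[1] - 20L)
    seg <- align_segment(substring(exon_seq, 1L, chain$q_start[1]),
                         substring(target, sub0 + 1L, chain$seed_start[1]),
                         scheme, TRUE, FALSE)
    push(seg, 0L, sub0)
  }
  for (j in seq_len(n)) {
    seg <- align_segment(
      substring(exon_seq, chain$q_start[j] + 1L, chain$q_end[j]),
      substring(target, chain$seed_start[j] + 1L, chain$seed_end[j]),
      scheme, FALSE, FALSE)
    push(seg, chain$q_start[j], chain$seed_start[j])
    if (j < n) {
      seg <- align_segment(
        substring(exon_seq, chain$q_end[j] + 1L, chain$q_start[j + 1L]),
        substring(target, chain$seed_end[j] + 1L,
                  chain$seed_start[j + 1L]),
        scheme, FALSE, FALSE)
      push(seg, chain$q_end[j], chain$seed_end[j])
    }
  }
  # trailing overhang: pinned at the last seed, free subject end
  if (chain$q_end[n] < L) {
    sub1 <- min(wend, chain$seed_end[n] + 2L * (L - chain$q_end[n]) + 20L)
    seg <- align_segment(substring(exon_seq, chain$q_end[n] + 1L, L),
                         substring(target, chain$seed_end[n] + 1L, sub1),
                         scheme, FALSE, TRUE)
    push(seg, chain$q_end[n], chain$seed_end[n])
  }
  sc <- score_columns(ref_cols, tgt_cols, exon_seq, target, scheme)
  tt <- tgt_cols[!is.na(tgt_cols)]
  structure(list(
    exon_index = as.integer(exon_index), score = sc$score,
    identity = sc$identity, ref_idx = ref_cols, tgt_idx = tgt_cols,
    window_offset = 0L,
    target_start = as.integer(min(tt) - 1L),
    target_end = as.integer(max(tt)),
    status = "mapped", chained = TRUE
  ), class = "exon_alignment")
}

# X-drop-style terminal trimming. The pattern-global recurrence must spend
# every exon base, so when an exon end has no true homolog in the window
# the optimal path strings it through unrelated sequence (at these scores a
# random alignment approaches LCS density, ~65% identity). A terminal
# segment scoring below -min_drop over at least min_cols columns is such
# noise: its exon bases are re-emitted as a terminal deletion run and its
# window bases returned to the free overhang. Genuine diverged ends score
# positive and are never touched. Returns NULL when nothing alignable
# remains.
trim_noise_tails <- function(aln, exon_seq, target, scheme,
                             min_cols = 15L, min_drop = 15L) {
  ri <- aln$ref_idx; ti <- aln$tgt_idx
  n <- length(ri)
  if (n < min_cols) return(aln)
  rb <- strsplit(exon_seq, "", fixed = TRUE)[[1]]
  tb <- strsplit(target, "", fixed = TRUE)[[1]]
  kind <- ifelse(is.na(ti), "D", ifelse(is.na(ri), "I", "M"))
  colsc <- numeric(n)
  m <- kind == "M"
  rc <- rb[ri[m]]
  tc <- tb[aln$window_offset + ti[m]]
  colsc[m] <- ifelse(rc == "N" | tc == "N", 0,
                     ifelse(rc == tc, scheme$match, scheme$mismatch))
  run_start <- c(TRUE, kind[-1] != kind[-n])
  g <- kind != "M"
  colsc[g] <- ifelse(run_start[g], scheme$gap_open, scheme$gap_extend)

  cut_lead <- 0L
  cum <- cumsum(colsc)
  i <- which.min(cum)
  if (cum[i] <= -min_drop && i >= min_cols) cut_lead <- i
  cut_tail <- 0L
  cum2 <- cumsum(rev(colsc))
  j <- which.min(cum2)
  if (cum2[j] <= -min_drop && j >= min_cols && (n - j) >= cut_lead)
    cut_tail <- j
  if (cut_lead == 0L && cut_tail == 0L) return(aln)

  keep <- seq_len(n) > cut_lead & seq_len(n) <= n - cut_tail
  lead_ref <- ri[seq_len(cut_lead)]
  tail_ref <- if (cut_tail > 0) ri[(n - cut_tail + 1L):n] else integer(0)
  new_ri <- c(lead_ref[!is.na(lead_ref)], ri[keep],
              tail_ref[!is.na(tail_ref)])
  new_ti <- c(rep(NA_integer_, sum(!is.na(lead_ref))), ti[keep],
              rep(NA_integer_, sum(!is.na(tail_ref))))
  if (all(is.na(new_ti))) return(NULL)
  aln$ref_idx <- new_ri
  aln$tgt_idx <- new_ti
  tt <- aln$window_offset + new_ti[!is.na(new_ti)]
  aln$target_start <- as.integer(min(tt) - 1L)
  aln$target_end <- as.integer(max(tt))
  sc <- score_columns(new_ri, new_ti + aln$window_offset, exon_seq,
                      target, scheme)
  aln$score <- sc$score
  aln$identity <- sc$identity
  aln
}

# seed support required before a sub-threshold alignment counts as evidence
# of the exon (a remnant): at least 5% of the exon's k-mers on one
# diagonal, never fewer than 3 (one chance k-mer collision is noise)
solid_seed_support <- function(exon_len, word_size) {
  max(3L, as.integer(ceiling(0.05 * (exon_len - word_size + 1L))))
}

# greedy collinear chain anchored on the best-supported cluster; returns
# NULL unless >= 2 solid clusters imply a diagonal jump >= long_gap
find_chain <- function(cand, min_support = 3L, long_gap = 30L,
                       slack = 10L) {
  cc <- cand[cand$support >= min_support, , drop = FALSE]
  if (nrow(cc) < 2) return(NULL)
  cc <- cc[order(cc$q_start), , drop = FALSE]
  base <- which.max(cc$support)
  chain_idx <- base
  j <- base
  for (i in rev(seq_len(base - 1L))) {     # extend left
    if (cc$q_end[i] <= cc$q_start[j] + slack &&
        cc$seed_end[i] <= cc$seed_start[j] + slack) {
      chain_idx <- c(i, chain_idx); j <- i
    }
  }
  j <- base
  for (i in seq_len(nrow(cc))[-seq_len(base)]) {   # extend right
    if (cc$q_start[i] >= cc$q_end[j] - slack &&
        cc$seed_start[i] >= cc$seed_end[j] - slack) {
      chain_idx <- c(chain_idx, i); j <- i
    }
  }
  if (length(chain_idx) < 2) return(NULL)
  chain <- cc[chain_idx, , drop = FALSE]
  jumps <- abs(diff(chain$seed_start - chain$q_start))
  if (all(jumps < long_gap)) return(NULL)
  chain
}

#' @export
print.exon_alignment <- function(x, ...) {
  cat(sprintf(
    "<exon_alignment> exon %s: [%d,%d) score %d identity %.3f status %s\n",
    x$exon_index, x$target_start, x$target_end, x$score, x$identity,
    x$status))
  invisible(x)
}
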