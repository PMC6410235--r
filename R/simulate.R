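SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste0, collapse = ""),
  STOP_CODONS)

make_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random open reading frame: ATG + sense codons + TAA
random_orf <- function(n_codons) {
  paste0("ATG", paste0(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                       collapse = ""), "TAA")
}

#' Generate a reference gene locus
#'
#' Builds one synthetic chromosome holding a multi-exon coding gene with
#' canonical GT/AG introns, flanked on each side by `n_neighbors`
#' single-exon protein-coding neighbour genes (for synteny analyses) plus
#' two non-coding features adjacent to the target. The CDS is random sense
#' codons with an ATG start and a single terminal stop, so the reference
#' translates with exactly one `*`, at the end.
#'
#' @param n_exons number of coding exons.
#' @param exon_lengths per-exon CDS lengths (sum must be a multiple of 3).
#' @param intron_lengths `n_exons - 1` intron lengths (>= 20).
#' @param seed integer seed fixing all randomness.
#' @param gene_id gene identifier.
#' @param upstream_symbols,downstream_symbols neighbour gene symbols in
#'   genomic order (the last upstream / first downstream symbol is the
#'   direct neighbour).
#' @param neighbor_length,spacer_length layout parameters (nt).
#' @return list with `model` ([gene_model()]), `genome` ([genome()]),
#'   `annotation` (BED-like data.frame including the target gene) and `cds`.
#' @export
generate_reference_gene <- function(n_exons, exon_lengths, intron_lengths,
                                    seed = 1L, gene_id = "gene1",
                                    upstream_symbols = paste0("UPS", 5:1),
                                    downstream_symbols = paste0("DNS", 1:5),
                                    neighbor_length = 300L,
                                    spacer_length = 250L) {
  stopifnot(length(exon_lengths) == n_exons,
            length(intron_lengths) == n_exons - 1L)
  if (sum(exon_lengths) %% 3L != 0L)
    stop("total CDS length must be a multiple of 3")
  if (any(exon_lengths < 3L)) stop("exon lengths must be >= 3")
  if (n_exons > 1L && any(intron_lengths < 20L))
    stop("intron lengths must be >= 20")
  set.seed(make_seed(seed, 17L))

  chrom <- paste0("locus_", gene_id)
  n_codons <- sum(exon_lengths) %/% 3L
  cds <- random_orf(n_codons)

  seq_parts <- character(0)
  ann <- list()
  pos <- 0L
  add <- function(s) {
    seq_parts[[length(seq_parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  add_gene <- function(symbol, biotype, len) {
    start <- pos
    body <- if (biotype == "protein_coding") random_orf(len %/% 3L)
            else random_dna(len)
    add(body)
    ann[[length(ann) + 1L]] <<- data.frame(
      gene_symbol = symbol, chrom = chrom, start = start,
      end = start + nchar(body), strand = "+", biotype = biotype)
  }

  add(random_dna(spacer_length))
  for (sym in upstream_symbols) {
    add_gene(sym, "protein_coding", neighbor_length)
    add(random_dna(spacer_length))
  }
  add_gene(paste0(gene_id, "_asRNA"), "lncRNA", 120L)
  add(random_dna(spacer_length))

  # the target gene: exons split from the CDS, GT..AG introns
  exon_iv <- matrix(0L, n_exons, 2)
  cds_off <- cumsum(c(0L, exon_lengths[-n_exons]))
  gene_start <- pos
  for (i in seq_len(n_exons)) {
    exon_iv[i, 1] <- pos
    add(substring(cds, cds_off[i] + 1L, cds_off[i] + exon_lengths[i]))
    exon_iv[i, 2] <- pos
    if (i < n_exons)
      add(paste0("GT", random_dna(intron_lengths[i] - 4L), "AG"))
  }
  ann[[length(ann) + 1L]] <- data.frame(
    gene_symbol = gene_id, chrom = chrom, start = gene_start, end = pos,
    strand = "+", biotype = "protein_coding")

  add(random_dna(spacer_length))
  add_gene(paste0(gene_id, "_lnc2"), "lncRNA", 100L)
  add(random_dna(spacer_length))
  for (sym in downstream_symbols) {
    add_gene(sym, "protein_coding", neighbor_length)
    add(random_dna(spacer_length))
  }

  g <- genome(stats::setNames(paste0(seq_parts, collapse = ""), chrom))
  annotation <- do.call(rbind, ann)
  annotation <- annotation[order(annotation$start), , drop = FALSE]
  rownames(annotation) <- NULL
  model <- gene_model(gene_id, chrom, "+", exon_iv)
  list(model = model, genome = g, annotation = annotation, cds = cds)
}

# --- event specs -> genomic edits ------------------------------------------

# one row of the planted-event table -> a root-coordinate edit operation
spec_to_edit <- function(spec, model) {
  ex <- model$exons
  if (spec$type %in% c("premature_stop", "start_loss")) {
    g <- cds_to_genomic(model, spec$cds_pos)
    return(data.frame(gstart = g, gend = g + 3L, repl = spec$alt))
  }
  if (spec$type %in% c("frameshift_deletion", "inframe_deletion")) {
    g <- cds_to_genomic(model, spec$cds_pos)
    return(data.frame(gstart = g, gend = g + spec$length, repl = ""))
  }
  if (spec$type %in% c("frameshift_insertion", "inframe_insertion")) {
    g <- cds_to_genomic(model, spec$cds_pos)
    return(data.frame(gstart = g, gend = g, repl = spec$alt))
  }
  if (spec$type == "splice_acceptor_noncanonical") {
    k <- spec$exon_index                 # acceptor preceding exon k
    return(data.frame(gstart = ex[k, 1] - 2L, gend = ex[k, 1],
                      repl = spec$alt))
  }
  if (spec$type == "splice_donor_noncanonical") {
    k <- spec$exon_index                 # donor following exon k
    return(data.frame(gstart = ex[k, 2], gend = ex[k, 2] + 2L,
                      repl = spec$alt))
  }
  if (spec$type == "exon_deletion") {
    k <- spec$exon_index
    f <- 40L
    return(data.frame(gstart = ex[k, 1] - f, gend = ex[k, 2] + f,
                      repl = ""))
  }
  if (spec$type == "gene_deletion") {
    return(data.frame(gstart = spec$gstart, gend = spec$gend, repl = ""))
  }
  stop("unknown spec type: ", spec$type)
}

# shift a root-coordinate point through a set of edits (for annotation and
# mask lifting); edits given in ascending root order
lift_point <- function(pos, edits) {
  if (nrow(edits) == 0) return(pos)
  vapply(pos, function(p) {
    delta <- 0L
    for (i in seq_len(nrow(edits))) {
      if (edits$gend[i] <= p) {
        delta <- delta + nchar(edits$repl[i]) -
          (edits$gend[i] - edits$gstart[i])
      } else if (edits$gstart[i] < p) {
        return(edits$gstart[i] + delta)    # point inside a deletion
      }
    }
    p + delta
  }, numeric(1)) |> as.integer()
}

# a structural deletion (exon- or locus-scale, >= 50 nt) swallows point
# events nested inside it: descent can stack a whole-exon loss on top of an
# ancestral indel. Overlapping point events remain conflicts.
prune_edits <- function(edits) {
  if (nrow(edits) < 2) return(edits)
  span <- edits$gend - edits$gstart
  drop <- rep(FALSE, nrow(edits))
  for (i in seq_len(nrow(edits))) for (j in seq_len(nrow(edits))) {
    if (i == j || drop[j]) next
    if (edits$repl[j] == "" && span[j] >= 50L && span[j] > span[i] &&
        edits$gstart[j] <= edits$gstart[i] &&
        edits$gend[i] <= edits$gend[j])
      drop[i] <- TRUE
  }
  edits[!drop, , drop = FALSE]
}

apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0) return(seq)
  edits <- edits[order(edits$gstart), , drop = FALSE]
  if (nrow(edits) > 1 &&
      any(edits$gstart[-1] < edits$gend[-nrow(edits)]))
    stop("conflicting specs: overlapping edits on one lineage")
  for (i in rev(seq_len(nrow(edits)))) {
    seq <- paste0(substring(seq, 1L, edits$gstart[i]), edits$repl[i],
                  substring(seq, edits$gend[i] + 1L, nchar(seq)))
  }
  seq
}

mask_with_n <- function(seq, start, end) {
  start <- max(0L, start); end <- min(nchar(seq), end)
  if (end <= start) return(seq)
  paste0(substring(seq, 1L, start), strrep("N", end - start),
         substring(seq, end + 1L, nchar(seq)))
}

# canonical truth row (the call the pipeline is expected to emit) for one
# planted spec
spec_truth_row <- function(spec, model, ref_cds) {
  t <- spec$type
  if (t %in% c("frameshift_deletion", "inframe_deletion")) {
    nz <- normalize_deletion(ref_cds, spec$cds_pos, spec$length)
    return(new_call("", model$gene_id, t, cds_to_exon(model, nz$pos),
                    nz$pos, spec$length, nz$allele, "-"))
  }
  if (t %in% c("frameshift_insertion", "inframe_insertion")) {
    nz <- normalize_insertion(ref_cds, spec$cds_pos, spec$alt)
    return(new_call("", model$gene_id, t,
                    cds_to_exon(model, min(nz$pos, model$cds_length - 1L)),
                    nz$pos, nchar(nz$allele), "-", nz$allele))
  }
  if (t == "premature_stop")
    return(new_call("", model$gene_id, t, cds_to_exon(model, spec$cds_pos),
                    spec$cds_pos, 3L,
                    substring(ref_cds, spec$cds_pos + 1L, spec$cds_pos + 3L),
                    spec$alt))
  if (t == "start_loss")
    return(new_call("", model$gene_id, t, cds_to_exon(model, 0L), 0L, 3L,
                    "ATG", spec$alt))
  if (t == "splice_acceptor_noncanonical")
    return(new_call("", model$gene_id, t, spec$exon_index,
                    model$cds_offsets[spec$exon_index], 2L, "AG", spec$alt))
  if (t == "splice_donor_noncanonical")
    return(new_call("", model$gene_id, t, spec$exon_index,
                    model$cds_offsets[spec$exon_index + 1L], 2L, "GT",
                    spec$alt))
  if (t == "exon_deletion")
    return(new_call("", model$gene_id, t, spec$exon_index,
                    model$cds_offsets[spec$exon_index],
                    model$exon_lengths[spec$exon_index], "", "-"))
  if (t == "gene_deletion")
    return(new_call("", model$gene_id, t, NA_integer_, NA_integer_,
                    spec$gend - spec$gstart, "", "-"))
  stop("unknown spec type: ", t)
}

#' Evolve a reference locus over a species tree with planted mutations
#'
#' The root sequence is copied down a rooted tree. On each branch,
#' `Poisson(rate x length)` random substitutions are drawn (shared by all
#' descendant leaves — descent with modification), then the branch's planted
#' mutation specs are applied; species-level assembly gaps are painted as N
#' runs last. All planted coordinates are root (reference) coordinates;
#' edits on one lineage must not overlap. Besides the leaf genomes the
#' evolver emits, per leaf, the truth table of every planted mutation it
#' inherited, each row annotated with whether the analysis pipeline can in
#' principle observe it (events in masked, deleted or heavily eroded exons,
#' in deleted loci, or in terminal exons without flanking anchors cannot be
#' recovered and are marked unobservable, with a reason).
#'
#' @param ref output of [generate_reference_gene()].
#' @param tree rooted `phylo` tree (internal labels name clades).
#' @param specs data.frame of planted events: columns `branch`, `type`,
#'   `exon_index`, `cds_pos`, `length`, `alt` and (gene deletions only)
#'   `gstart`, `gend`.
#' @param masks data.frame of assembly gaps: columns `branch` (leaf or
#'   clade label), `gstart`, `gend` (root coordinates).
#' @param rate per-site, per-branch substitution rate.
#' @param seed integer seed.
#' @return list with `genomes` (named list of leaf [genome()]s),
#'   `annotations` (named list of lifted BED-like tables, target gene row
#'   dropped where the locus is deleted), `truth` (pooled truth table) and
#'   `chrom`.
#' @export
evolve_on_tree <- function(ref, tree, specs, masks = NULL, rate = 0,
                           seed = 1L) {
  model <- ref$model
  chrom <- model$chrom
  root_seq <- ref$genome[[chrom]]
  L <- nchar(root_seq)
  ref_cds <- ref$cds
  leaves <- tree$tip.label
  if (is.null(masks))
    masks <- data.frame(branch = character(0), gstart = integer(0),
                        gend = integer(0))

  # per-branch substitution draws, ordered root -> tips
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  node_tips <- function(node) {
    if (node <= ntip) tree$tip.label[node]
    else ape::extract.clade(tree, node)$tip.label
  }
  bl <- if (!is.null(tree_cw$edge.length)) tree_cw$edge.length
        else rep(1, nrow(tree_cw$edge))
  set.seed(make_seed(seed, 29L))
  branch_subs <- lapply(seq_len(nrow(tree_cw$edge)), function(e) {
    n <- stats::rpois(1, rate * L * bl[e])
    if (n == 0)
      return(data.frame(pos = integer(0), base = character(0)))
    pos <- sample.int(L, n, replace = TRUE)
    old <- substring(root_seq, pos, pos)
    base <- vapply(old, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    data.frame(pos = pos, base = base)
  })
  edge_tips <- lapply(tree_cw$edge[, 2], node_tips)

  # resolve spec and mask branches to leaf sets
  spec_leaves <- lapply(seq_len(nrow(specs)), function(i)
    clade_species(tree, specs$branch[i]))
  mask_leaves <- lapply(seq_len(nrow(masks)), function(i)
    clade_species(tree, masks$branch[i]))

  genomes <- list(); annotations <- list(); truth <- list()
  for (leaf in leaves) {
    inh <- which(vapply(spec_leaves, function(s) leaf %in% s, logical(1)))
    inh_specs <- specs[inh, , drop = FALSE]
    edits <- if (nrow(inh_specs))
      do.call(rbind, lapply(seq_len(nrow(inh_specs)), function(i)
        spec_to_edit(inh_specs[i, ], model)))
    else data.frame(gstart = integer(0), gend = integer(0),
                    repl = character(0))
    edits <- prune_edits(edits[order(edits$gstart), , drop = FALSE])

    seq <- root_seq
    for (e in seq_along(branch_subs)) {     # root-to-tip order: later wins
      if (!leaf %in% edge_tips[[e]]) next
      bs <- branch_subs[[e]]
      for (j in seq_len(nrow(bs)))
        substr(seq, bs$pos[j], bs$pos[j]) <- bs$base[j]
    }
    seq <- apply_edits(seq, edits)
    mi <- which(vapply(mask_leaves, function(s) leaf %in% s, logical(1)))
    for (i in mi) {
      iv <- lift_point(c(masks$gstart[i], masks$gend[i]), edits)
      seq <- mask_with_n(seq, iv[1], iv[2])
    }
    genomes[[leaf]] <- genome(stats::setNames(seq, chrom))

    # lifted annotation; drop the target gene where its locus is deleted
    ann <- ref$annotation
    ann$start <- lift_point(ann$start, edits)
    ann$end <- lift_point(ann$end, edits)
    gene_deleted <- any(inh_specs$type == "gene_deletion")
    if (gene_deleted)
      ann <- ann[ann$gene_symbol != model$gene_id, , drop = FALSE]
    annotations[[leaf]] <- ann

    if (nrow(inh_specs)) {
      tr <- do.call(bind_calls, lapply(seq_len(nrow(inh_specs)),
        function(i) spec_truth_row(inh_specs[i, ], model, ref_cds)))
      tr$species_id <- leaf
      obs <- truth_observability(inh_specs, tr, model,
                                 masks[mi, , drop = FALSE])
      tr$observable <- obs$observable
      tr$reason <- obs$reason
      truth[[leaf]] <- tr
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(truth)) rownames(truth) <- NULL
  list(genomes = genomes, annotations = annotations, truth = truth,
       chrom = chrom)
}

# which planted events can the pipeline observe for this leaf?
truth_observability <- function(inh_specs, tr, model, leaf_masks) {
  nex <- nrow(model$exons)
  gene_deleted <- any(inh_specs$type == "gene_deletion")
  masked <- rep(FALSE, nex)
  for (k in seq_len(nex)) {
    if (nrow(leaf_masks) == 0) break
    ivs <- model$exons[k, ]
    masked[k] <- any(leaf_masks$gstart < ivs[2] & leaf_masks$gend > ivs[1])
  }
  deleted <- rep(FALSE, nex)
  del_specs <- inh_specs[inh_specs$type == "exon_deletion", , drop = FALSE]
  if (nrow(del_specs)) deleted[del_specs$exon_index] <- TRUE
  eroded <- rep(FALSE, nex)
  for (k in seq_len(nex)) {
    dl <- inh_specs$type %in% c("frameshift_deletion", "inframe_deletion") &
      !is.na(inh_specs$exon_index) & inh_specs$exon_index == k
    if (any(dl) &&
        sum(inh_specs$length[dl]) / model$exon_lengths[k] > 0.4)
      eroded[k] <- TRUE
  }
  available <- !(masked | deleted | eroded)

  indels <- inh_specs[inh_specs$type %in%
    c("frameshift_deletion", "inframe_deletion", "frameshift_insertion",
      "inframe_insertion"), , drop = FALSE]
  shift_ok <- function(pos) {
    if (nrow(indels) == 0) return(TRUE)
    up <- indels$cds_pos < pos
    d <- ifelse(grepl("insertion", indels$type[up]), indels$length[up],
                -indels$length[up])
    sum(d) %% 3L == 0L
  }

  n <- nrow(tr)
  observable <- rep(TRUE, n); reason <- rep("", n)
  for (i in seq_len(n)) {
    t <- tr$type[i]; k <- tr$exon_index[i]
    if (gene_deleted && t != "gene_deletion") {
      observable[i] <- FALSE; reason[i] <- "locus_deleted"; next
    }
    if (t == "gene_deletion") {
      observable[i] <- FALSE; reason[i] <- "synteny_level"; next
    }
    if (t == "exon_deletion") {
      anchors <- any(available[seq_len(nex) < k]) &&
        any(available[seq_len(nex) > k])
      if (!anchors) {
        observable[i] <- FALSE; reason[i] <- "no_flanking_anchor"
      } else if (masked[k]) {
        observable[i] <- FALSE; reason[i] <- "exon_masked"
      }
      next
    }
    if (t == "splice_donor_noncanonical") {
      if (!(available[k] && k < nex && available[k + 1L])) {
        observable[i] <- FALSE; reason[i] <- "flank_exon_unavailable"
      }
      next
    }
    if (t == "splice_acceptor_noncanonical") {
      if (!(available[k] && k > 1L && available[k - 1L])) {
        observable[i] <- FALSE; reason[i] <- "flank_exon_unavailable"
      }
      next
    }
    if (!available[k]) {
      observable[i] <- FALSE
      reason[i] <- if (masked[k]) "exon_masked"
                   else if (deleted[k]) "exon_deleted" else "exon_eroded"
      next
    }
    if (t == "premature_stop" && !shift_ok(tr$cds_pos[i])) {
      observable[i] <- FALSE; reason[i] <- "frameshift_context"
    }
  }
  list(observable = observable, reason = reason)
}

#' Simulate sequencing read sets from a haplotype
#'
#' Uniform start positions, fixed read length, independent per-base
#' substitution errors, random orientation; one seeded stream per sample so
#' samples are independent "sequencing projects".
#'
#' @param haplotype nucleotide string.
#' @param n_samples number of read sets.
#' @param depth mean coverage per sample.
#' @param read_length read length (<= haplotype length).
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @param sample_prefix sample id prefix.
#' @return list of [read_set()] objects.
#' @export
simulate_reads <- function(haplotype, n_samples = 2L, depth = 20,
                           read_length = 100L, error_rate = 0.005,
                           seed = 1L, sample_prefix = "SRA") {
  Lh <- nchar(haplotype)
  stopifnot(depth > 0, read_length <= Lh)
  lapply(seq_len(n_samples), function(s) {
    set.seed(make_seed(seed, 1000L + s))
    n_reads <- ceiling(depth * Lh / read_length)
    starts <- sample.int(Lh - read_length + 1L, n_reads, replace = TRUE)
    seqs <- substring(haplotype, starts, starts + read_length - 1L)
    fwd <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
    seqs <- vapply(seq_len(n_reads), function(i) {
      x <- seqs[i]
      nerr <- stats::rbinom(1, read_length, error_rate)
      if (nerr > 0) {
        at <- sample.int(read_length, nerr)
        for (p in at) {
          old <- substring(x, p, p)
          if (old == "N") next
          substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
      if (fwd[i]) x else revcomp(x)
    }, character(1))
    read_set(sprintf("%s%02d", sample_prefix, s), seqs)
  })
}
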