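#' Parse a rooted species tree from newick text
#'
#' Thin wrapper around [ape::read.tree()] that validates the result:
#' unique leaf labels, a rooted topology, internal labels preserved.
#'
#' @param text newick string.
#' @return an `ape` `phylo` object.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) {
    # locate the offending position for the error message
    depth <- 0L
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    pos <- length(chars)
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      if (chars[i] == ")") depth <- depth - 1L
      if (depth < 0L) { pos <- i; break }
    }
    stop("malformed newick near position ", pos)
  }
  if (anyDuplicated(tree$tip.label))
    stop("leaf labels must be unique")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Leaves descending from a named clade
#'
#' @param tree a rooted `phylo` tree with internal node labels.
#' @param label an internal node label, or a leaf label.
#' @return character vector of leaf names in that clade.
#' @export
clade_species <- function(tree, label) {
  if (label %in% tree$tip.label) return(label)
  if (is.null(tree$node.label) || !label %in% tree$node.label)
    stop("unknown clade label: ", label)
  node <- ape::Ntip(tree) + which(tree$node.label == label)
  ape::extract.clade(tree, node)$tip.label
}

#' Group equivalent mutation calls across species
#'
#' Exact-key grouping on (gene, type, exon, CDS position, length, alt
#' allele); calls must already be left-normalized (as [call_indels()]
#' emits them). Species whose mapping is unmapped at the event's exon are
#' listed as indeterminate for the group, not as absent. Calls flagged as
#' frameshift consequences and `exon_missing_gap` records are not grouped.
#' An optional tolerance of one codon for premature stops (default off)
#' merges stop calls within +/- 3 nt.
#'
#' @param calls mutation-call data.frame pooled over species.
#' @param mappings named list of [map_gene()] results (one per species),
#'   used to identify indeterminate species; optional.
#' @param stop_tolerance merge premature stops within one codon
#'   (default `FALSE`).
#' @return data.frame with one row per shared-mutation group: the key
#'   columns plus `n_carriers`, and list columns `carriers` and
#'   `indeterminate`.
#' @export
match_mutations <- function(calls, mappings = NULL, stop_tolerance = FALSE) {
  keep <- !calls$fs_context & calls$type != "exon_missing_gap"
  x <- calls[keep, , drop = FALSE]
  if (nrow(x) == 0)
    return(data.frame(gene_id = character(0), type = character(0),
                      exon_index = integer(0), cds_pos = integer(0),
                      length = integer(0), alt_allele = character(0),
                      n_carriers = integer(0)))
  key_pos <- x$cds_pos
  if (stop_tolerance) {
    s <- x$type == "premature_stop"
    key_pos[s] <- (key_pos[s] %/% 3L) %/% 1L  # codon index; +/-1 merged below
  }
  key <- paste(x$gene_id, x$type, x$exon_index, key_pos, x$length,
               x$alt_allele, sep = "|")
  if (stop_tolerance) {
    # collapse stop keys whose codon indices differ by at most 1
    s <- which(x$type == "premature_stop")
    if (length(s) > 1) {
      codons <- x$cds_pos[s] %/% 3L
      o <- s[order(codons)]
      oc <- sort(codons)
      cl <- cumsum(c(1L, as.integer(diff(oc) > 1L)))
      key[o] <- paste(x$gene_id[o], x$type[o], x$exon_index[o],
                      paste0("c", cl), x$length[o], x$alt_allele[o],
                      sep = "|")
    }
  }
  groups <- lapply(split(seq_len(nrow(x)), key), function(ii) {
    carriers <- sort(unique(x$species_id[ii]))
    exon <- x$exon_index[ii][1]
    indet <- character(0)
    if (!is.null(mappings)) {
      for (sp in names(mappings)) {
        if (sp %in% carriers) next
        a <- mappings[[sp]]$alignments[[exon]]
        if (!identical(a$status, "mapped")) indet <- c(indet, sp)
      }
    }
    out <- data.frame(gene_id = x$gene_id[ii][1], type = x$type[ii][1],
                      exon_index = exon, cds_pos = x$cds_pos[ii][1],
                      length = x$length[ii][1],
                      alt_allele = x$alt_allele[ii][1],
                      n_carriers = length(carriers))
    out$carriers <- list(carriers)
    out$indeterminate <- list(indet)
    out
  })
  out <- do.call(rbind, groups)
  rownames(out) <- NULL
  out[order(out$gene_id, out$cds_pos), , drop = FALSE]
}

#' Place a shared mutation on its branch of origin (Dollo parsimony)
#'
#' Under a single-origin, no-reversal model the mutation arose on the edge
#' above the most recent common ancestor of its carriers. Descendants of
#' that ancestor that are neither carriers nor indeterminate are reported as
#' conflicts (possible independent origin or missed call) rather than
#' silently accepted. Indeterminate species never influence the MRCA.
#'
#' @param carriers character vector of carrier species (leaf labels).
#' @param tree rooted `phylo` tree.
#' @param indeterminate species with no data at the event position.
#' @return list with `node` (MRCA node id), `branch_label` (the MRCA's
#'   label: leaf name or internal node label, `""` if unnamed),
#'   `parent` (node id above, NA at the root), `clade` (leaves under the
#'   branch) and `conflicts`.
#' @export
assign_to_branch <- function(carriers, tree, indeterminate = character(0)) {
  if (length(carriers) == 0) stop("no carriers")
  unknown <- setdiff(carriers, tree$tip.label)
  if (length(unknown)) stop("unknown species: ",
                            paste(unknown, collapse = ", "))
  ntip <- ape::Ntip(tree)
  if (length(unique(carriers)) == 1L) {
    node <- match(carriers[1], tree$tip.label)
    clade <- carriers[1]
  } else {
    node <- ape::getMRCA(tree, unique(carriers))
    clade <- ape::extract.clade(tree, node)$tip.label
  }
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  label <- if (node <= ntip) tree$tip.label[node]
           else if (!is.null(tree$node.label)) tree$node.label[node - ntip]
           else ""
  conflicts <- setdiff(clade, union(carriers, indeterminate))
  list(node = node,
       branch_label = label,
       parent = if (length(parent)) parent else NA_integer_,
       clade = clade,
       conflicts = sort(conflicts))
}

#' Assign every shared-mutation group to a tree branch
#'
#' @param groups output of [match_mutations()].
#' @param tree rooted `phylo` tree.
#' @return `groups` with added columns `branch_label`, `n_conflicts` and a
#'   list column `conflicts`.
#' @export
assign_groups <- function(groups, tree) {
  if (nrow(groups) == 0) {
    groups$branch_label <- character(0)
    groups$n_conflicts <- integer(0)
    return(groups)
  }
  res <- lapply(seq_len(nrow(groups)), function(i)
    assign_to_branch(groups$carriers[[i]], tree,
                     groups$indeterminate[[i]]))
  groups$branch_label <- vapply(res, `[[`, character(1), "branch_label")
  groups$conflicts <- lapply(res, `[[`, "conflicts")
  groups$n_conflicts <- vapply(groups$conflicts, length, integer(1))
  groups
}

#' Write shared-mutation groups as TSV
#'
#' @param groups output of [assign_groups()].
#' @param path output path.
#' @export
write_groups_tsv <- function(groups, path) {
  flat <- groups
  for (col in c("carriers", "indeterminate", "conflicts"))
    if (col %in% names(flat))
      flat[[col]] <- vapply(flat[[col]], paste, character(1), collapse = ",")
  flat$cds_pos <- flat$cds_pos + 1L
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
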