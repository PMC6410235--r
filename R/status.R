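#' Classify the coding status of one species x gene
#'
#' Decision order: (1) no mapped exon — `lost` when synteny shows a
#' complete, gap-free locus without the gene (`absent_complete`),
#' `inconclusive` when gaps or remnants prevent the call; (2) any hard
#' ORF-disrupting call (premature stop, frameshift, non-canonical splice
#' site, start loss, exon deletion) — `pseudogene`; (3) only in-frame
#' indels, but removing at least `min_inframe_codons` codons in total or
#' covering a critical residue — `likely_pseudogene`; (4) every exon mapped
#' and zero calls — `intact`; (5) otherwise `inconclusive`.
#'
#' Read validation never changes the verdict (mutations found in assemblies
#' are reported even where confirmation was impossible); it only sets the
#' `validated` flag.
#'
#' @param mapping a [map_gene()] result.
#' @param calls mutation-call data.frame for the same species x gene
#'   (optionally with a `validation` column).
#' @param synteny a `synteny_block` with `target_state` set, or `NULL`.
#' @param critical_codons 1-based reference codon indices whose loss
#'   abolishes function (e.g. an active-site residue).
#' @param min_inframe_codons in-frame damage threshold (default 4 codons).
#' @return object of class `gene_status`: `species_id`, `gene_id`,
#'   `status`, `evidence` (the calls), `synteny_state`, `validated`,
#'   `notes`.
#' @export
classify_gene_status <- function(mapping, calls, synteny = NULL,
                                 critical_codons = integer(),
                                 min_inframe_codons = 4L) {
  if (nrow(calls) > 0 &&
      any(calls$species_id != mapping$species_id))
    stop("species mismatch between mapping and calls")
  n_mapped <- sum(vapply(mapping$alignments, function(a)
    identical(a$status, "mapped"), logical(1)))
  all_mapped <- n_mapped == length(mapping$alignments)
  validated <- "validation" %in% names(calls) &&
    any(calls$validation == "confirmed", na.rm = TRUE)
  notes <- character(0)

  live <- calls[!calls$fs_context, , drop = FALSE]
  hard <- live[live$type %in% HARD_CALL_TYPES, , drop = FALSE]
  inframe <- live[live$type %in% c("inframe_deletion", "inframe_insertion"),
                  , drop = FALSE]

  # critical-residue annotation on deletions
  if (length(critical_codons) > 0 && nrow(live) > 0) {
    dels <- which(live$type %in% c("inframe_deletion",
                                   "frameshift_deletion", "exon_deletion"))
    for (i in dels) {
      cod <- (live$cds_pos[i] %/% 3L + 1L):
        ((live$cds_pos[i] + live$length[i] - 1L) %/% 3L + 1L)
      if (length(intersect(cod, critical_codons)) > 0)
        notes <- c(notes, sprintf("active-site loss (%s exon %d)",
                                  live$type[i], live$exon_index[i]))
    }
  }

  status <- if (n_mapped == 0) {
    st <- if (!is.null(synteny)) synteny$target_state else NA_character_
    if (identical(st, "absent_complete")) "lost"
    else {
      if (identical(st, "remnant")) notes <- c(notes, "remnant sequence")
      "inconclusive"
    }
  } else if (nrow(hard) > 0) {
    "pseudogene"
  } else if (nrow(inframe) > 0 &&
             (sum(inframe$length) %/% 3L >= min_inframe_codons ||
              length(notes) > 0)) {
    "likely_pseudogene"
  } else if (all_mapped && nrow(calls) == 0) {
    "intact"
  } else {
    "inconclusive"
  }

  structure(list(species_id = mapping$species_id,
                 gene_id = mapping$gene_id, status = status,
                 evidence = calls,
                 synteny_state = if (is.null(synteny)) NA_character_
                                 else synteny$target_state,
                 validated = validated, notes = notes),
            class = "gene_status")
}

#' @export
print.gene_status <- function(x, ...) {
  cat(sprintf("<gene_status> %s / %s: %s%s\n", x$species_id, x$gene_id,
              x$status, if (x$validated) " [validated]" else ""))
  invisible(x)
}

#' Run the full gene-loss pipeline on a simulated scenario
#'
#' For every species: exon mapping, mutation calling, synteny
#' classification, read-based validation of point mutations (reads are
#' simulated from each species' own mutant locus, using the scenario's
#' per-species sequencing-sample counts), and status classification; then
#' cross-species mutation grouping and Dollo branch assignment on the
#' scenario tree.
#'
#' @param scenario a [melatonin_fixture()]-style scenario.
#' @param scheme a [scoring_scheme()].
#' @param validate simulate reads and validate calls (default `TRUE`).
#' @param read_depth,read_length,read_error read-simulation parameters per
#'   sample.
#' @param min_identity_read read filter threshold for validation.
#' @param min_samples samples required to confirm a mutation.
#' @param min_identity mapped-exon acceptance threshold.
#' @return list of class `gene_loss_result`: `mappings`, `calls` (pooled,
#'   with `validation` and `n_supporting` columns), `synteny` (blocks +
#'   `synteny_table`), `groups` (with branch assignments), `status`
#'   (per-species `gene_status` objects) and `status_table`.
#' @export
run_scenario <- function(scenario, scheme = scoring_scheme(),
                         validate = TRUE, read_depth = 20,
                         read_length = 100L, read_error = 0.005,
                         min_identity_read = 0.95, min_samples = 2L,
                         min_identity = 0.60) {
  model <- scenario$model
  ref_block <- flanking_context(scenario$ref_annotation, scenario$gene_id,
                                species_id = "reference")
  mappings <- list(); all_calls <- list(); blocks <- list()
  statuses <- list()
  for (sp in scenario$species) {
    tgt <- scenario$genomes[[sp]]
    mapping <- map_gene(model, scenario$ref_genome, tgt, scenario$chrom,
                        scheme, min_identity = min_identity,
                        species_id = sp)
    calls <- call_mutations(mapping, model, scenario$ref_genome, tgt,
                            scheme, species_id = sp)
    block <- compare_synteny(ref_block, scenario$annotations[[sp]], tgt,
                             scenario$chrom, mapping, model,
                             scenario$ref_genome, scheme, species_id = sp)
    calls$validation <- rep("not_assessed", nrow(calls))
    calls$n_supporting <- rep(NA_integer_, nrow(calls))
    if (validate && nrow(calls) > 0) {
      n_samp <- scenario$sra_samples[[sp]]
      target_seq <- tgt[[scenario$chrom]]
      for (i in seq_len(nrow(calls))) {
        if (calls$fs_context[i]) next
        region <- mutation_region(calls[i, ], target_seq)
        if (is.null(region)) next
        readsets <- if (n_samp > 0)
          simulate_reads(region$mut_seq, n_samples = n_samp,
                         depth = read_depth, read_length = read_length,
                         error_rate = read_error,
                         seed = make_seed(scenario$seed,
                                          match(sp, scenario$species) *
                                            1000L + i),
                         sample_prefix = paste0(sp, "_S"))
          else list()
        sup <- validate_mutation(region, readsets, scheme,
                                 min_identity = min_identity_read,
                                 min_samples = min_samples)
        calls$validation[i] <- sup$verdict
        calls$n_supporting[i] <- length(sup$supporting_samples)
      }
    }
    statuses[[sp]] <- classify_gene_status(
      mapping, calls, block, critical_codons = scenario$critical_codons)
    mappings[[sp]] <- mapping
    all_calls[[sp]] <- calls
    blocks[[sp]] <- block
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  groups <- assign_groups(match_mutations(calls, mappings), scenario$tree)
  status_table <- do.call(rbind, lapply(statuses, function(s) data.frame(
    species_id = s$species_id, gene_id = s$gene_id, status = s$status,
    synteny_state = s$synteny_state, validated = s$validated,
    n_calls = nrow(s$evidence))))
  rownames(status_table) <- NULL
  structure(list(mappings = mappings, calls = calls,
                 synteny = blocks, synteny_table = synteny_report(blocks),
                 groups = groups, status = statuses,
                 status_table = status_table, scenario = scenario),
            class = "gene_loss_result")
}

#' @export
print.gene_loss_result <- function(x, ...) {
  cat(sprintf("<gene_loss_result> %s: %d call(s), %d shared group(s)\n",
              x$scenario$gene_id, nrow(x$calls), nrow(x$groups)))
  print(x$status_table)
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' Mutation TSV, shared-group TSV, synteny TSV, status matrix TSV and JSON.
#'
#' @param result a [run_scenario()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mutation_tsv(result$calls, file.path(dir, "mutations.tsv"))
  write_groups_tsv(result$groups, file.path(dir, "shared_groups.tsv"))
  utils::write.table(result$synteny_table, file.path(dir, "synteny.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$status_table, file.path(dir, "status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$status_table,
                       file.path(dir, "status.json"), dataframe = "rows",
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Run all four melatonin-gene scenarios and assemble the status matrix
#'
#' Convenience driver reproducing the study-wide species x gene verdict
#' matrix from the built-in fixtures.
#'
#' @param seed integer seed.
#' @param genes genes to run (default all four).
#' @param ... passed to [run_scenario()].
#' @return list with `results` (per gene) and `matrix` (wide data.frame,
#'   species x gene).
#' @export
run_melatonin_study <- function(seed = 1L, genes = MELATONIN_GENES, ...) {
  results <- lapply(genes, function(g)
    run_scenario(melatonin_fixture(g, seed = seed), ...))
  names(results) <- genes
  tabs <- lapply(results, function(r)
    r$status_table[, c("species_id", "status")])
  mat <- Reduce(function(a, b) merge(a, b, by = "species_id"),
                Map(function(t, g) stats::setNames(t, c("species_id", g)),
                    tabs, names(tabs)))
  list(results = results, matrix = mat)
}
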