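fake_mapping <- function(statuses, species = "sp", gene = "g") {
  structure(list(species_id = species, gene_id = gene,
                 alignments = lapply(seq_along(statuses), function(i)
                   list(exon_index = i, status = statuses[i])),
                 colinear = TRUE),
            class = "gene_mapping")
}

fake_block <- function(state) {
  structure(list(species_id = "sp", target_gene = "g",
                 upstream = "L", downstream = "R", target_state = state,
                 interval_n_runs = data.frame()),
            class = "synteny_block")
}

fake_call <- function(type, len = 1L, cds = 10L, validation = NULL) {
  out <- data.frame(species_id = "sp", gene_id = "g", type = type,
                    exon_index = 1L, cds_pos = cds, length = len,
                    ref_allele = "A", alt_allele = "-",
                    frame_consequence = "none", fs_context = FALSE,
                    target_start = NA_integer_, target_end = NA_integer_,
                    note = "")
  if (!is.null(validation)) out$validation <- validation
  out
}

test_that("status decision order matches the classification rules", {
  mapped3 <- fake_mapping(rep("mapped", 3))
  none3 <- fake_mapping(rep("missing_no_gap", 3))

  # (1) no mapped exon: synteny decides lost vs inconclusive
  expect_equal(classify_gene_status(none3, empty_calls(),
                                    fake_block("absent_complete"))$status,
               "lost")
  expect_equal(classify_gene_status(none3, empty_calls(),
                                    fake_block("absent_gapped"))$status,
               "inconclusive")
  expect_equal(classify_gene_status(none3, empty_calls(),
                                    fake_block("remnant"))$status,
               "inconclusive")

  # (2) any hard disrupting call: pseudogene
  for (t in c("premature_stop", "frameshift_deletion", "start_loss",
              "splice_acceptor_noncanonical", "exon_deletion"))
    expect_equal(classify_gene_status(mapped3, fake_call(t))$status,
                 "pseudogene", info = t)

  # (3) in-frame damage: >= 4 codons removed, or a critical residue
  expect_equal(classify_gene_status(
    mapped3, fake_call("inframe_deletion", len = 12L))$status,
    "likely_pseudogene")
  expect_equal(classify_gene_status(
    mapped3, fake_call("inframe_deletion", len = 3L))$status,
    "inconclusive")
  crit <- classify_gene_status(mapped3,
                               fake_call("inframe_deletion", len = 3L,
                                         cds = 30L),
                               critical_codons = 11L)
  expect_equal(crit$status, "likely_pseudogene")
  expect_match(crit$notes, "active-site loss")

  # (4) clean complete mapping: intact; (5) otherwise inconclusive
  expect_equal(classify_gene_status(mapped3, empty_calls())$status,
               "intact")
  part <- fake_mapping(c("mapped", "missing_in_gap", "mapped"))
  expect_equal(classify_gene_status(part, empty_calls())$status,
               "inconclusive")

  expect_error(classify_gene_status(mapped3, fake_call("premature_stop") |>
                                      transform(species_id = "other")),
               "species mismatch")
})

test_that("no gene with a confirmed hard call is ever intact; verdicts pure", {
  mapped3 <- fake_mapping(rep("mapped", 3))
  s <- classify_gene_status(mapped3,
                            fake_call("premature_stop",
                                      validation = "confirmed"))
  expect_equal(s$status, "pseudogene")
  expect_true(s$validated)
  # validation never changes the verdict, only the flag
  s2 <- classify_gene_status(mapped3,
                             fake_call("premature_stop",
                                       validation = "unconfirmed"))
  expect_equal(s2$status, "pseudogene")
  expect_false(s2$validated)
  # purity: same inputs, same verdict
  expect_equal(classify_gene_status(mapped3, fake_call("start_loss")),
               classify_gene_status(mapped3, fake_call("start_loss")))
})

test_that("the pipeline covers the full species grid and is reproducible", {
  sc <- mini_scenario()
  res <- run_scenario(sc, validate = FALSE)
  expect_setequal(res$status_table$species_id, c("A", "B", "C", "D"))
  expect_equal(res$status_table$status[match(c("A", "B", "C", "D"),
                                             res$status_table$species_id)],
               c("pseudogene", "pseudogene", "intact", "intact"))
  # the shared stop groups on the AB branch
  g <- res$groups[res$groups$type == "premature_stop", ]
  expect_equal(g$branch_label, "AB")
  expect_setequal(g$carriers[[1]], c("A", "B"))
  # reruns are byte-identical
  res2 <- run_scenario(sc, validate = FALSE)
  expect_identical(res$calls, res2$calls)
  expect_identical(res$status_table, res2$status_table)

  # report bundle on disk
  d <- tempfile()
  write_reports(res, d)
  expect_true(all(file.exists(file.path(
    d, c("mutations.tsv", "shared_groups.tsv", "synteny.tsv",
         "status.tsv", "status.json")))))
  tab <- utils::read.table(file.path(d, "status.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(nrow(tab), 4L)
  unlink(d, recursive = TRUE)
})

test_that("read validation integrates into the pipeline verdicts", {
  sc <- mini_scenario()
  res <- run_scenario(sc, validate = TRUE)
  st <- res$calls[res$calls$type == "premature_stop" &
                    !res$calls$fs_context, ]
  expect_true(all(st$validation == "confirmed"))
  expect_true(all(res$status_table$validated[
    res$status_table$species_id %in% c("A", "B")]))
})
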