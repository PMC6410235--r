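test_that("indel classification follows length mod 3, exhaustively 1..30", {
  ref <- toy_gene(seed = 17L)
  ex <- ref$model$exons
  for (L in 1:30) {
    # deletion of L nt inside exon 2
    g <- toy_g(ref, 130L)
    tg <- edit_locus(ref, g, g + L, "")
    res <- map_and_call(ref, tg)
    dels <- res$calls[grepl("deletion", res$calls$type) &
                        res$calls$type != "exon_deletion", ]
    expect_equal(nrow(dels), 1L, info = paste("del", L))
    expect_equal(dels$length, L)
    expect_equal(dels$type,
                 if (L %% 3 == 0) "inframe_deletion"
                 else "frameshift_deletion")
    # insertion of L random nt at the same point
    ins_seq <- random_seq(L)
    tg2 <- edit_locus(ref, g, g, ins_seq)
    res2 <- map_and_call(ref, tg2)
    ins <- res2$calls[grepl("insertion", res2$calls$type), ]
    expect_equal(nrow(ins), 1L, info = paste("ins", L))
    expect_equal(ins$length, L)
    expect_equal(ins$type,
                 if (L %% 3 == 0) "inframe_insertion"
                 else "frameshift_insertion")
  }
})

test_that("indels are left-normalized to their minimal CDS position", {
  # build a CDS with a known homopolymer and verify against brute force
  ref <- toy_gene(seed = 19L)
  cds <- ref$cds
  # plant AAAA at cds 150..154 by rewriting reference and target
  g <- toy_g(ref, 150L)
  ref$genome <- edit_locus(ref, g, g + 4L, "AAAA")
  ref$cds <- paste0(substring(cds, 1, 150), "AAAA",
                    substring(cds, 155, nchar(cds)))
  # delete the *last* A: caller must report the leftmost placement
  tg <- edit_locus(ref, g + 3L, g + 4L, "")
  res <- map_and_call(ref, tg)
  del <- res$calls[res$calls$type == "frameshift_deletion", ]
  expect_equal(nrow(del), 1L)
  # brute force: smallest p where deleting ref[p] yields the target CDS
  target_cds <- paste0(substring(ref$cds, 1, 153),
                       substring(ref$cds, 155, nchar(ref$cds)))
  equiv <- vapply(seq_len(nchar(ref$cds)), function(p)
    paste0(substring(ref$cds, 1, p - 1),
           substring(ref$cds, p + 1, nchar(ref$cds))) == target_cds,
    logical(1))
  expect_equal(del$cds_pos, min(which(equiv)) - 1L)
  # idempotence: normalizing the normalized call changes nothing
  nz <- genloss:::normalize_deletion(ref$cds, del$cds_pos, 1L)
  expect_equal(nz$pos, del$cds_pos)
})

test_that("premature stops are called on the reference codon grid", {
  ref <- toy_gene(seed = 23L)
  # force codon 25 (cds 72..74) to TGG, then mutate target to TGA
  g <- toy_g(ref, 72L)
  ref$genome <- edit_locus(ref, g, g + 3L, "TGG")
  ref$cds <- paste0(substring(ref$cds, 1, 72), "TGG",
                    substring(ref$cds, 76, nchar(ref$cds)))
  tg <- edit_locus(ref, g + 2L, g + 3L, "A")
  res <- map_and_call(ref, tg)
  stops <- res$calls[res$calls$type == "premature_stop", ]
  expect_equal(nrow(stops), 1L)
  expect_equal(stops$cds_pos, 72L)      # codon 25 starts at 24 * 3
  expect_equal(stops$ref_allele, "TGG")
  expect_equal(stops$alt_allele, "TGA")
  expect_false(stops$fs_context)
  # identical target: no stop calls
  res0 <- map_and_call(ref, ref$genome)
  expect_equal(sum(res0$calls$type == "premature_stop"), 0L)
})

test_that("stops downstream of an uncompensated frameshift are flagged", {
  ref <- toy_gene(seed = 29L)
  # 1-nt deletion at cds 90 shifts the frame for the rest of exon 1..2
  g <- toy_g(ref, 90L)
  tg <- edit_locus(ref, g, g + 1L, "")
  res <- map_and_call(ref, tg)
  stops <- res$calls[res$calls$type == "premature_stop", ]
  # consistency: every reported stop downstream of the shift is flagged,
  # none is emitted as an independent call
  if (nrow(stops) > 0) {
    down <- stops$cds_pos > 90L
    expect_true(all(stops$fs_context[down]))
  }
  succeed()
})

test_that("start-codon checks call start_loss, gaps count as loss", {
  ref <- toy_gene(seed = 31L)
  # intact start: no call
  res0 <- map_and_call(ref, ref$genome)
  expect_equal(sum(res0$calls$type == "start_loss"), 0L)
  # ATG -> GTG
  tg <- edit_locus(ref, toy_g(ref, 0L), toy_g(ref, 0L) + 1L, "G")
  res <- map_and_call(ref, tg)
  sl <- res$calls[res$calls$type == "start_loss", ]
  expect_equal(nrow(sl), 1L)
  expect_equal(sl$alt_allele, "GTG")
  # start codon inside a deletion: alleles show the gap
  tg2 <- edit_locus(ref, toy_g(ref, 0L), toy_g(ref, 0L) + 3L, "")
  res2 <- map_and_call(ref, tg2)
  sl2 <- res2$calls[res2$calls$type == "start_loss", ]
  expect_equal(nrow(sl2), 1L)
  expect_equal(sl2$ref_allele, "ATG")
  # the alignment may shift the gap within equivalent placements, but the
  # start codon must show deleted positions and not read ATG
  expect_match(sl2$alt_allele, "-")
  # start exon unmapped: indeterminate, no call
  ex <- ref$model$exons
  tg3 <- edit_locus(ref, ex[1, 1] - 20L, ex[1, 2] + 20L,
                    strrep("N", 139L))
  m3 <- map_gene(ref$model, ref$genome, tg3, ref$model$chrom)
  out <- check_start_codon(m3, ref$model, tg3[[ref$model$chrom]])
  expect_equal(nrow(out), 0L)
  expect_true(attr(out, "indeterminate"))
})

test_that("splice sites are canonical GT/AG only, with GC-AG annotated", {
  ref <- toy_gene(seed = 37L)
  # untouched introns: no calls
  res0 <- map_and_call(ref, ref$genome)
  expect_equal(sum(grepl("splice", res0$calls$type)), 0L)
  ex <- ref$model$exons
  # acceptor AG -> AA before exon 3
  tg <- edit_locus(ref, ex[3, 1] - 1L, ex[3, 1], "A")
  res <- map_and_call(ref, tg)
  acc <- res$calls[res$calls$type == "splice_acceptor_noncanonical", ]
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$exon_index, 3L)
  expect_equal(acc$alt_allele, "AA")
  # donor GT -> GC after exon 1: non-canonical but annotated GC-AG minor
  tg2 <- edit_locus(ref, ex[1, 2] + 1L, ex[1, 2] + 2L, "C")
  res2 <- map_and_call(ref, tg2)
  don <- res2$calls[res2$calls$type == "splice_donor_noncanonical", ]
  expect_equal(nrow(don), 1L)
  expect_equal(don$exon_index, 1L)
  expect_equal(don$alt_allele, "GC")
  expect_equal(don$note, "GC-AG minor")
  # N at the site: indeterminate, no call
  tg3 <- edit_locus(ref, ex[1, 2], ex[1, 2] + 2L, "NN")
  res3 <- map_and_call(ref, tg3)
  expect_equal(sum(grepl("splice", res3$calls$type)), 0L)
})

test_that("whole-exon loss distinguishes deletion from assembly gaps", {
  ref <- toy_gene(seed = 41L)
  ex <- ref$model$exons
  # clean deletion of exon 2 with N-free flanks
  tg <- edit_locus(ref, ex[2, 1] - 40L, ex[2, 2] + 40L, "")
  res <- map_and_call(ref, tg)
  loss <- res$calls[res$calls$type == "exon_deletion", ]
  expect_equal(nrow(loss), 1L)
  expect_equal(loss$exon_index, 2L)
  # exon 2 swallowed by a 500-N assembly gap
  tg2 <- edit_locus(ref, ex[2, 1] - 40L, ex[2, 2] + 40L, strrep("N", 500))
  res2 <- map_and_call(ref, tg2)
  expect_equal(sum(res2$calls$type == "exon_deletion"), 0L)
  expect_equal(sum(res2$calls$type == "exon_missing_gap" &
                     res2$calls$exon_index == 2L), 1L)
  # terminal exon absent with the sequence ending right there:
  # truncation cannot be excluded
  tg3_seq <- substr(ref$genome[[ref$model$chrom]], 1, ex[3, 1] - 10L)
  tg3 <- genome(stats::setNames(tg3_seq, ref$model$chrom))
  res3 <- map_and_call(ref, tg3)
  expect_equal(sum(res3$calls$type == "exon_deletion"), 0L)
  expect_equal(sum(res3$calls$type == "exon_missing_gap" &
                     res3$calls$exon_index == 3L), 1L)
})

test_that("calling on an unmapped exon alignment is an error", {
  ref <- toy_gene(seed = 43L)
  ex <- ref$model$exons
  tg <- edit_locus(ref, ex[2, 1], ex[2, 2], strrep("N", 200))
  m <- map_gene(ref$model, ref$genome, tg, ref$model$chrom)
  expect_error(call_indels(m$alignments[[2]], ref$model, ref$cds,
                           tg[[ref$model$chrom]]),
               "cannot call on unmapped exon")
})

test_that("a 12-nt and a 19-nt deletion get the published classifications", {
  ref <- toy_gene(exon_lengths = c(150L, 150L, 150L),
                  intron_lengths = c(300L, 300L), seed = 47L)
  g1 <- toy_g(ref, 180L)
  tg <- edit_locus(ref, g1, g1 + 12L, "")
  res <- map_and_call(ref, tg)
  d <- res$calls[res$calls$type == "inframe_deletion", ]
  expect_equal(d$length, 12L)
  expect_equal(d$frame_consequence, "none")

  g2 <- toy_g(ref, 30L)
  tg2 <- edit_locus(ref, g2, g2 + 19L, "")
  res2 <- map_and_call(ref, tg2)
  d2 <- res2$calls[res2$calls$type == "frameshift_deletion", ]
  expect_equal(d2$length, 19L)
  expect_equal(d2$frame_consequence, "shift+1")   # 19 mod 3 = 1
})
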