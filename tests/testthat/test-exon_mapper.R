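test_that("scoring scheme validates its invariants", {
  s <- scoring_scheme()
  expect_equal(s$match, 2L)
  expect_equal(s$word_size, 10L)
  expect_error(scoring_scheme(match = 0), "match")
  expect_error(scoring_scheme(gap_open = -1, gap_extend = -2))
  expect_error(scoring_scheme(word_size = 3))
})

test_that("aligner agrees with the exhaustive path-enumeration oracle", {
  set.seed(101)
  scheme <- scoring_scheme()
  for (i in 1:30) {
    p <- random_seq(sample(2:4, 1))
    s <- random_seq(sample(2:5, 1))
    a <- align_exon(p, s, scheme)
    expect_equal(a$score, enum_semiglobal_score(p, s, scheme),
                 info = paste(p, s))
  }
})

test_that("aligner agrees with the substring-global DP oracle on 500 pairs", {
  set.seed(202)
  scheme <- scoring_scheme()
  mism <- 0L
  for (i in 1:500) {
    p <- random_seq(sample(3:9, 1))
    s <- random_seq(sample(3:12, 1))
    a <- align_exon(p, s, scheme)
    o <- oracle_semiglobal_score(p, s, scheme)
    if (a$score != o) mism <- mism + 1L
  }
  expect_equal(mism, 0L)
})

test_that("N scores zero and never counts toward identity", {
  scheme <- scoring_scheme()
  a <- align_exon("ACGTACGTACGT", "ACGTNCGTACGT", scheme)
  # N column contributes 0: 11 matches * 2 + 0
  expect_equal(a$score, 22L)
  expect_equal(a$identity, 11 / 12)
  # an N-only window aligns with zero substitution score
  b <- align_exon("ACGT", "NNNN", scheme)
  expect_equal(b$score, 0L)
  expect_equal(b$identity, 0)
})

test_that("identical sequences give perfect gap-free alignments", {
  set.seed(7)
  x <- random_seq(60)
  a <- align_exon(x, paste0("TTT", x, "GGG"), scoring_scheme())
  expect_equal(a$score, 120L)
  expect_equal(a$identity, 1)
  expect_false(any(is.na(a$ref_idx)) || any(is.na(a$tgt_idx)))
  expect_equal(a$target_start, 3L)
  expect_equal(a$target_end, 63L)
})

test_that("seeding finds planted exons, ranks ties leftmost, rejects noise", {
  set.seed(11)
  exon <- random_seq(60)
  target <- paste0(random_seq(500), exon, random_seq(440))
  cand <- seed_candidates(exon, target)
  expect_gt(nrow(cand), 0)
  expect_true(cand$start[1] <= 500 && cand$end[1] >= 560)
  expect_equal(cand$seed_start[1], 500L)

  # exon present twice: two candidates, leftmost first on equal support
  t2 <- paste0(random_seq(200), exon, random_seq(300), exon,
               random_seq(100))
  c2 <- seed_candidates(exon, t2)
  expect_gte(nrow(c2), 2)
  expect_equal(c2$support[1], c2$support[2])
  expect_lt(c2$seed_start[1], c2$seed_start[2])

  # absent exon on random 10 kb target: chance k-mer collisions occur,
  # but never a supported cluster
  set.seed(12)
  sup <- unlist(lapply(1:10, function(i)
    seed_candidates(random_seq(60), random_seq(10000))$support))
  expect_true(length(sup) == 0 || max(sup) <= 2L)
})

test_that("alignments are deterministic and monotone in the match reward", {
  set.seed(23)
  for (i in 1:25) {
    p <- random_seq(sample(20:60, 1))
    s <- paste0(random_seq(30), random_seq(sample(20:60, 1)),
                random_seq(30))
    a1 <- align_exon(p, s, scoring_scheme())
    a2 <- align_exon(p, s, scoring_scheme())
    expect_identical(a1, a2)
    a3 <- align_exon(p, s, scoring_scheme(match = 3L))
    expect_gte(a3$score, a1$score)
  }
})

test_that("planted exons are recovered at their exact intervals", {
  set.seed(31)
  for (i in 1:100) {
    exon <- random_seq(sample(40:120, 1))
    left <- sample(100:1500, 1)
    target <- paste0(random_seq(left), exon, random_seq(300))
    cand <- seed_candidates(exon, target)
    w <- substr(target, cand$start[1] + 1, cand$end[1])
    a <- align_exon(exon, w, scoring_scheme(),
                    window_offset = cand$start[1])
    expect_equal(a$target_start, left)
    expect_equal(a$target_end, left + nchar(exon))
    expect_equal(a$identity, 1)
  }
})

test_that("long structural deletions come out as one chained gap run", {
  set.seed(47)
  exon <- random_seq(300)
  # remove an interior 120-nt block from the target copy
  mut <- paste0(substr(exon, 1, 100), substr(exon, 221, 300))
  target <- paste0(random_seq(400), mut, random_seq(400))
  ref <- list(model = gene_model("g", "c", "+",
                                 cbind(0L, 300L)),
              genome = genome(c(c = exon)))
  tg <- genome(c(c = target))
  mapping <- map_gene(ref$model, ref$genome, tg, "c")
  a <- mapping$alignments[[1]]
  expect_equal(a$status, "mapped")
  kind <- ifelse(is.na(a$tgt_idx), "D", ifelse(is.na(a$ref_idx), "I", "M"))
  r <- rle(kind)
  expect_equal(sum(r$values == "D"), 1)        # a single deletion run
  expect_equal(r$lengths[r$values == "D"], 120)
})

test_that("mapping a planted multi-exon gene is colinear and complete", {
  ref <- toy_gene(seed = 3L)
  res <- map_and_call(ref, ref$genome)
  st <- vapply(res$mapping$alignments, `[[`, character(1), "status")
  expect_true(all(st == "mapped"))
  expect_true(res$mapping$colinear)
  expect_equal(nrow(res$calls), 0L)
  # recovered intervals equal the annotated exons exactly
  for (i in seq_len(nrow(ref$model$exons))) {
    a <- res$mapping$alignments[[i]]
    expect_equal(c(a$target_start, a$target_end),
                 unname(ref$model$exons[i, ]))
  }
})

test_that("exons replaced by N runs are missing_in_gap, absent exons not", {
  ref <- toy_gene(seed = 13L)
  ex <- ref$model$exons
  # exon 2 replaced by 200 Ns
  gapped <- edit_locus(ref, ex[2, 1], ex[2, 2], strrep("N", 200))
  m1 <- map_gene(ref$model, ref$genome, gapped, ref$model$chrom)
  expect_equal(m1$alignments[[2]]$status, "missing_in_gap")
  # exon 2 deleted outright, flanks intact and N-free
  deleted <- edit_locus(ref, ex[2, 1] - 40L, ex[2, 2] + 40L, "")
  m2 <- map_gene(ref$model, ref$genome, deleted, ref$model$chrom)
  expect_equal(m2$alignments[[2]]$status, "missing_no_gap")
  expect_equal(m2$alignments[[1]]$status, "mapped")
  expect_equal(m2$alignments[[3]]$status, "mapped")
})
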