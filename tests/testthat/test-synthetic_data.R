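test_that("reference generation honours its construction guarantees", {
  ref <- generate_reference_gene(3L, c(99L, 120L, 84L), c(500L, 800L),
                                 seed = 1L, gene_id = "g")
  expect_equal(ref$model$cds_length, 303L)
  aa <- as.character(translate_cds(ref$cds))
  # exactly one stop, at the end
  expect_equal(which(strsplit(aa, "")[[1]] == "*"), 101L)
  expect_equal(substr(ref$cds, 1, 3), "ATG")
  # introns begin GT and end AG
  ex <- ref$model$exons
  g <- ref$genome[[ref$model$chrom]]
  for (i in 1:2) {
    expect_equal(substr(g, ex[i, 2] + 1, ex[i, 2] + 2), "GT")
    expect_equal(substr(g, ex[i + 1, 1] - 1, ex[i + 1, 1]), "AG")
  }
  # determinism: same seed, identical genome
  ref2 <- generate_reference_gene(3L, c(99L, 120L, 84L), c(500L, 800L),
                                  seed = 1L, gene_id = "g")
  expect_identical(unclass(ref$genome), unclass(ref2$genome))
  expect_error(generate_reference_gene(3L, c(100L, 120L, 84L),
                                       c(500L, 800L)),
               "multiple of 3")
})

test_that("descent on the tree shares branch events with all descendants", {
  ref <- toy_gene(seed = 61L)
  tree <- parse_newick("(((A,B)AB,C)ABC,D)R;")
  # rate 0, no specs: all leaves identical to the root
  sim0 <- evolve_on_tree(ref, tree, data.frame(
    branch = character(0), type = character(0), exon_index = integer(0),
    cds_pos = integer(0), length = integer(0), alt = character(0),
    gstart = integer(0), gend = integer(0)), rate = 0, seed = 2L)
  for (sp in tree$tip.label)
    expect_identical(sim0$genomes[[sp]][[ref$model$chrom]],
                     ref$genome[[ref$model$chrom]])

  # a deletion planted on the AB branch is inherited by A and B only
  specs <- data.frame(branch = "AB", type = "frameshift_deletion",
                      exon_index = 2L, cds_pos = 150L, length = 2L,
                      alt = NA_character_, gstart = NA_integer_,
                      gend = NA_integer_)
  sim <- evolve_on_tree(ref, tree, specs, rate = 0, seed = 2L)
  root <- ref$genome[[ref$model$chrom]]
  for (sp in c("A", "B"))
    expect_equal(nchar(sim$genomes[[sp]][[ref$model$chrom]]),
                 nchar(root) - 2L)
  for (sp in c("C", "D"))
    expect_identical(sim$genomes[[sp]][[ref$model$chrom]], root)
  expect_setequal(sim$truth$species_id, c("A", "B"))
  expect_true(all(sim$truth$observable))

  # overlapping point events on one lineage are rejected
  bad <- rbind(specs, data.frame(branch = "A",
                                 type = "frameshift_deletion",
                                 exon_index = 2L, cds_pos = 150L,
                                 length = 3L, alt = NA_character_,
                                 gstart = NA_integer_,
                                 gend = NA_integer_))
  expect_error(evolve_on_tree(ref, tree, bad, rate = 0, seed = 2L),
               "conflicting specs")
})

test_that("branch substitution counts follow the Poisson model", {
  ref <- toy_gene(seed = 67L)
  tree <- parse_newick("(A,B)R;")
  L <- nchar(ref$genome[[ref$model$chrom]])
  rate <- 10 / L                       # expect ~10 substitutions per branch
  empty <- data.frame(branch = character(0), type = character(0),
                      exon_index = integer(0), cds_pos = integer(0),
                      length = integer(0), alt = character(0),
                      gstart = integer(0), gend = integer(0))
  counts <- vapply(1:100, function(s) {
    sim <- evolve_on_tree(ref, tree, empty, rate = rate, seed = s)
    x <- strsplit(sim$genomes[["A"]][[ref$model$chrom]], "")[[1]]
    y <- strsplit(ref$genome[[ref$model$chrom]], "")[[1]]
    sum(x != y)
  }, numeric(1))
  # total across 100 seeds ~ Poisson(1000), test at the 99.9% envelope
  expect_gte(sum(counts), qpois(5e-4, 1000))
  expect_lte(sum(counts), qpois(1 - 5e-4, 1000))
})

test_that("read simulation matches its stated error and coverage model", {
  set.seed(9)
  hap <- random_seq(400)
  # zero error: every read is an exact substring in one orientation
  rs <- simulate_reads(hap, n_samples = 1, depth = 10, read_length = 80,
                       error_rate = 0, seed = 3L)[[1]]
  for (s in rs$reads$seq)
    expect_true(grepl(s, hap, fixed = TRUE) ||
                  grepl(revcomp(s), hap, fixed = TRUE))
  # coverage near the requested depth
  expect_equal(nrow(rs$reads), ceiling(10 * 400 / 80))
  # distinct samples are distinct read multisets; same seed reproduces
  two <- simulate_reads(hap, n_samples = 2, depth = 10, read_length = 80,
                        error_rate = 0.01, seed = 4L)
  expect_false(identical(sort(two[[1]]$reads$seq),
                         sort(two[[2]]$reads$seq)))
  again <- simulate_reads(hap, n_samples = 2, depth = 10,
                          read_length = 80, error_rate = 0.01, seed = 4L)
  expect_identical(two[[1]]$reads, again[[1]]$reads)
})

test_that("FASTQ round-trip preserves reads", {
  set.seed(10)
  rs <- read_set("s1", vapply(1:5, function(i) random_seq(50),
                              character(1)))
  f <- tempfile(fileext = ".fastq")
  write_reads_fastq(rs, f)
  back <- read_reads(f, sample_id = "s1")
  expect_identical(back$reads$seq, rs$reads$seq)
  expect_identical(back$reads$read_id, rs$reads$read_id)
  unlink(f)
})

test_that("the melatonin fixtures are reproducible and well-formed", {
  fx1 <- melatonin_fixture("Aanat", seed = 5L)
  fx2 <- melatonin_fixture("Aanat", seed = 5L)
  for (sp in fx1$species)
    expect_identical(fx1$genomes[[sp]][[fx1$chrom]],
                     fx2$genomes[[sp]][[fx2$chrom]])
  expect_setequal(names(fx1$sra_samples), fx1$tree$tip.label)
  expect_equal(unname(fx1$sra_samples[c("L_vexillifer", "S_chinensis")]),
               c(1L, 1L))
  # the sperm whale truth has the 12 + 6 nt in-frame deletions
  pc <- fx1$truth[fx1$truth$species_id == "P_catodon" &
                    fx1$truth$type == "inframe_deletion", ]
  expect_setequal(pc$length, c(12L, 6L))
  # scenario export writes standard text formats
  d <- tempfile()
  write_scenario(fx1, d)
  expect_true(file.exists(file.path(d, "reference.fasta")))
  expect_true(file.exists(file.path(d, "species_tree.nwk")))
  expect_true(file.exists(file.path(d, "truth.tsv")))
  tr <- parse_newick(readLines(file.path(d, "species_tree.nwk")))
  expect_setequal(tr$tip.label, fx1$species)
  unlink(d, recursive = TRUE)
})
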