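# brute-force Dollo oracle: the smallest clade containing every carrier
oracle_branch <- function(tree, carriers) {
  ntip <- ape::Ntip(tree)
  nodes <- c(seq_len(ntip), ntip + seq_len(tree$Nnode))
  tips_of <- function(n) {
    if (n <= ntip) tree$tip.label[n]
    else ape::extract.clade(tree, n)$tip.label
  }
  ok <- Filter(function(n) all(carriers %in% tips_of(n)), nodes)
  sizes <- vapply(ok, function(n) length(tips_of(n)), integer(1))
  ok[[which.min(sizes)]]
}

test_that("newick parsing keeps labels and rejects malformed input", {
  t1 <- parse_newick("((A,B),C);")
  expect_equal(sort(t1$tip.label), c("A", "B", "C"))
  expect_equal(ape::Ntip(t1), 3L)
  t2 <- parse_newick("((A,B)AB,C)R;")
  expect_true("AB" %in% t2$node.label)
  expect_setequal(clade_species(t2, "AB"), c("A", "B"))
  expect_error(parse_newick("((A,B,C);"), "malformed")
  expect_error(parse_newick("((A,B))A,C);"), "malformed")
  expect_error(clade_species(t2, "nope"), "unknown clade")
})

test_that("exact-key grouping separates lengths and flags indeterminates", {
  mk <- function(sp, type = "frameshift_deletion", cds = 100L, len = 1L,
                 alt = "-")
    data.frame(species_id = sp, gene_id = "g", type = type,
               exon_index = 1L, cds_pos = cds, length = len,
               ref_allele = "A", alt_allele = alt,
               frame_consequence = "none", fs_context = FALSE,
               target_start = NA_integer_, target_end = NA_integer_,
               note = "")
  calls <- rbind(
    do.call(rbind, lapply(paste0("sp", 1:10), mk)),
    mk("sp11", cds = 200L, len = 12L, type = "inframe_deletion"),
    mk("sp12", cds = 200L, len = 6L, type = "inframe_deletion"))
  g <- match_mutations(calls)
  expect_equal(nrow(g), 3L)
  big <- g[g$n_carriers == 10, ]
  expect_equal(length(big$carriers[[1]]), 10L)
  # same position, different lengths: two distinct groups
  expect_equal(sort(g$length[g$cds_pos == 200L]), c(6L, 12L))

  # species with the exon unmapped are indeterminate, not absent
  fake_mapping <- function(status) structure(
    list(species_id = "x", gene_id = "g",
         alignments = list(list(status = status))),
    class = "gene_mapping")
  maps <- list(sp1 = fake_mapping("mapped"),
               spX = fake_mapping("missing_in_gap"),
               spY = fake_mapping("mapped"))
  g2 <- match_mutations(mk("sp1"), mappings = maps)
  expect_true("spX" %in% g2$indeterminate[[1]])
  expect_false("spY" %in% g2$indeterminate[[1]])

  # flagged frameshift-context stops are never grouped
  fs <- mk("sp1", type = "premature_stop")
  fs$fs_context <- TRUE
  expect_equal(nrow(match_mutations(fs)), 0L)
})

test_that("branch assignment is the edge above the carriers' MRCA", {
  tree <- parse_newick("((A,B)AB,C)R;")
  # verified against exhaustive enumeration of edges
  r <- assign_to_branch(c("A", "B"), tree)
  expect_equal(r$node, oracle_branch(tree, c("A", "B")))
  expect_equal(r$branch_label, "AB")
  expect_equal(r$conflicts, character(0))
  # single carrier: terminal branch
  r2 <- assign_to_branch("C", tree)
  expect_equal(r2$branch_label, "C")
  expect_equal(r2$clade, "C")
  expect_error(assign_to_branch("Z", tree), "unknown species")
  # non-carrier descendants are conflicts unless indeterminate
  r3 <- assign_to_branch(c("A", "C"), tree)
  expect_equal(r3$branch_label, "R")
  expect_equal(r3$conflicts, "B")
  r4 <- assign_to_branch(c("A", "C"), tree, indeterminate = "B")
  expect_equal(r4$conflicts, character(0))
})

test_that("planted branches are recovered on 200 random trees", {
  set.seed(404)
  fails <- 0L
  for (i in 1:200) {
    n <- sample(5:12, 1)
    tree <- ape::rtree(n, rooted = TRUE)
    ntip <- ape::Ntip(tree)
    node <- sample(c(seq_len(ntip), ntip + seq_len(tree$Nnode)), 1)
    carriers <- if (node <= ntip) tree$tip.label[node]
                else ape::extract.clade(tree, node)$tip.label
    r <- assign_to_branch(carriers, tree)
    if (r$node != node) fails <- fails + 1L
    if (r$node != oracle_branch(tree, carriers)) fails <- fails + 1L
  }
  expect_equal(fails, 0L)
})

test_that("adding carriers only moves the assignment rootward", {
  set.seed(505)
  for (i in 1:25) {
    tree <- ape::rtree(8, rooted = TRUE)
    sp <- sample(tree$tip.label)
    prev_clade <- character(0)
    for (k in 2:8) {
      r <- assign_to_branch(sp[1:k], tree)
      expect_true(all(prev_clade %in% r$clade))
      prev_clade <- r$clade
    }
  }
})

test_that("indeterminate species never influence the MRCA", {
  tree <- parse_newick("(((A,B)AB,C)ABC,D)R;")
  r1 <- assign_to_branch(c("A", "B"), tree)
  r2 <- assign_to_branch(c("A", "B"), tree, indeterminate = c("C", "D"))
  expect_equal(r1$node, r2$node)
  expect_equal(r1$branch_label, "AB")
})
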