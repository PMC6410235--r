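# small in-code fixtures shared across test files

toy_gene <- function(exon_lengths = c(99L, 120L, 84L),
                     intron_lengths = c(200L, 250L), seed = 42L,
                     gene_id = "toy") {
  generate_reference_gene(length(exon_lengths), exon_lengths,
                          intron_lengths, seed = seed, gene_id = gene_id,
                          upstream_symbols = paste0("UP", 3:1),
                          downstream_symbols = paste0("DN", 1:3))
}

# apply root-coordinate edits (data.frame gstart, gend, repl) to a
# reference locus, yielding a target genome for mapping tests; independent
# re-implementation so caller tests do not lean on the simulator
edit_locus <- function(ref, gstart, gend, repl = "") {
  seq <- ref$genome[[ref$model$chrom]]
  o <- order(gstart, decreasing = TRUE)
  for (i in o) {
    seq <- paste0(substring(seq, 1, gstart[i]), repl[i],
                  substring(seq, gend[i] + 1, nchar(seq)))
  }
  genome(stats::setNames(seq, ref$model$chrom))
}

map_and_call <- function(ref, target_genome, species_id = "target",
                         scheme = scoring_scheme()) {
  mapping <- map_gene(ref$model, ref$genome, target_genome,
                      ref$model$chrom, scheme, species_id = species_id)
  calls <- call_mutations(mapping, ref$model, ref$genome, target_genome,
                          scheme, species_id = species_id)
  list(mapping = mapping, calls = calls)
}

# genomic position of a CDS coordinate in the toy (plus strand)
toy_g <- function(ref, cds_pos) cds_to_genomic(ref$model, cds_pos)

# minimal four-species scenario for pipeline-level tests
mini_scenario <- function(seed = 7L) {
  ref <- toy_gene(seed = seed, gene_id = "mini")
  tree <- parse_newick("(((A,B)AB,C)ABC,D)R;")
  specs <- rbind(
    data.frame(branch = "AB", type = "premature_stop", exon_index = 2L,
               cds_pos = 120L, length = 3L, alt = "TGA",
               gstart = NA_integer_, gend = NA_integer_),
    data.frame(branch = "A", type = "frameshift_deletion", exon_index = 3L,
               cds_pos = 240L, length = 2L, alt = NA_character_,
               gstart = NA_integer_, gend = NA_integer_))
  # a stop one substitution from its precursor, as in real pseudogenes
  seq <- ref$genome[[ref$model$chrom]]
  g <- cds_to_genomic(ref$model, 120L)
  substr(seq, g + 1, g + 3) <- "TGG"
  ref$genome <- genome(stats::setNames(seq, ref$model$chrom))
  substr(ref$cds, 121, 123) <- "TGG"
  sim <- evolve_on_tree(ref, tree, specs, rate = 0, seed = seed)
  structure(list(
    gene_id = "mini", model = ref$model, ref_genome = ref$genome,
    ref_annotation = ref$annotation, ref_cds = ref$cds, tree = tree,
    newick = "(((A,B)AB,C)ABC,D)R;", species = tree$tip.label,
    genomes = sim$genomes, annotations = sim$annotations,
    truth = sim$truth,
    sra_samples = stats::setNames(c(2L, 2L, 2L, 2L), tree$tip.label),
    critical_codons = integer(0), chrom = ref$model$chrom,
    seed = seed), class = "gene_loss_scenario")
}
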