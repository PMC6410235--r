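#' The built-in cetacean species tree
#'
#' Rooted topology used by [melatonin_fixture()]: eight toothed whales
#' (Odontoceti) and four baleen whales (Mysticeti) as sister clades, with
#' the hippopotamus and then the manatee as successive outgroups. Internal
#' nodes carry clade labels (`Cetacea`, `Odontoceti`, `Mysticeti`, ...)
#' so planted mutations and branch assignments can be addressed by name.
#' The within-clade topology is a documented fixture choice.
#'
#' @return newick string.
#' @export
fixture_newick <- function() {
  paste0(
    "(((",
    "(P_catodon,(L_vexillifer,(N_asiaeorientalis,(D_leucas,",
    "(S_chinensis,(L_obliquidens,(T_truncatus,O_orca)OrcaTursiops",
    ")Delphininae)Delphinidae))Delphinoidea)Delphinida)Odontoceti,",
    "(B_mysticetus,((B_acutorostrata,B_bonaerensis)Balaenoptera,",
    "E_robustus)Balaenopteroidea)Mysticeti",
    ")Cetacea,H_amphibius)Whippomorpha,T_manatus)Root;")
}

MELATONIN_GENES <- c("Aanat", "Asmt", "Mtnr1a", "Mtnr1b")

CETACEAN_SPECIES <- c("O_orca", "T_truncatus", "L_obliquidens",
                      "S_chinensis", "D_leucas", "L_vexillifer",
                      "N_asiaeorientalis", "P_catodon", "B_acutorostrata",
                      "B_bonaerensis", "E_robustus", "B_mysticetus")

# gene architectures: CDS exon lengths and intron lengths (nt); realistic
# orders of magnitude for the mammalian orthologues, exact values are
# recorded fixture choices
melatonin_architecture <- function(gene) {
  switch(gene,
    Aanat = list(
      exons = c(250L, 160L, 139L, 72L), introns = c(400L, 350L, 450L),
      upstream = c("ASPSCR1", "STRA13", "SLC16A3", "CSNK1D", "UBE2O"),
      downstream = c("RHBDF", "NPLOC4", "PDE6G", "GPS1", "DUS1L")),
    Asmt = list(
      exons = c(141L, 117L, 96L, 102L, 120L, 90L, 108L, 129L, 132L),
      introns = c(300L, 320L, 340L, 360L, 380L, 400L, 420L, 440L),
      upstream = c("GTPBP6", "PPP2R3B", "SHOX", "CRLF2", "P2RY8"),
      downstream = c("DHRSX", "ZBED1", "CD99", "XG", "GYG2")),
    Mtnr1a = list(
      exons = c(520L, 581L), introns = c(1200L),
      upstream = c("SORBS2", "PDLIM3", "CCDC110", "TRIML2", "FAT1"),
      downstream = c("F11", "KLKB1", "CYP4V2", "TLR3", "FAM149A")),
    Mtnr1b = list(
      exons = c(450L, 903L), introns = c(900L),
      upstream = c("FAT3", "MTMR2", "CEP57", "SESN3", "SLC36A4"),
      downstream = c("ANGPTL5", "ARHGAP42", "TMEM133", "PGR", "TRPC6")),
    stop("unknown gene: ", gene))
}

spec_row <- function(branch, type, exon_index = NA_integer_,
                     cds_pos = NA_integer_, length = NA_integer_,
                     alt = NA_character_, gstart = NA_integer_,
                     gend = NA_integer_) {
  data.frame(branch = branch, type = type,
             exon_index = as.integer(exon_index),
             cds_pos = as.integer(cds_pos), length = as.integer(length),
             alt = alt, gstart = as.integer(gstart),
             gend = as.integer(gend), stringsAsFactors = FALSE)
}

mask_row <- function(branch, gstart, gend) {
  data.frame(branch = branch, gstart = as.integer(gstart),
             gend = as.integer(gend), stringsAsFactors = FALSE)
}

# planted events + assembly gaps reproducing the published per-species
# mutation maps for each melatonin gene
melatonin_events <- function(gene, ref) {
  ex <- ref$model$exons
  ann <- ref$annotation
  grow <- ann[ann$gene_symbol == ref$model$gene_id, ]
  e1 <- ex[1, ]
  switch(gene,
    Aanat = list(
      specs = rbind(
        # shared exon-1 stop across Cetacea
        spec_row("Cetacea", "premature_stop", 1L, 120L, 3L, "TGA"),
        # toothed whales: start loss + exon-3 frameshift deletions
        spec_row("Odontoceti", "start_loss", 1L, 0L, 3L, "GTG"),
        spec_row("Odontoceti", "frameshift_deletion", 3L, 425L, 2L),
        spec_row("Odontoceti", "frameshift_deletion", 3L, 455L, 1L),
        # baleen whales: disruptive intron-2/exon-3 acceptor
        spec_row("Mysticeti", "splice_acceptor_noncanonical", 3L,
                 alt = "AA"),
        # sperm whale: 12-nt (exon 2) + 6-nt (exon 3) in-frame deletions
        spec_row("P_catodon", "inframe_deletion", 2L, 300L, 12L),
        spec_row("P_catodon", "inframe_deletion", 3L, 500L, 6L),
        # orca + bottlenose dolphin: premature stop truncating exon 3
        spec_row("OrcaTursiops", "premature_stop", 3L, 480L, 3L, "TGA"),
        # manatee: convergent start loss + exon-3 acceptor mutation
        spec_row("T_manatus", "start_loss", 1L, 0L, 3L, "ACG"),
        spec_row("T_manatus", "splice_acceptor_noncanonical", 3L,
                 alt = "CG")),
      masks = mask_row("P_catodon", e1[1] - 60L, e1[2] + 60L)),
    Asmt = list(
      specs = rbind(
        # shared 1-nt insertion in exon 1
        spec_row("Cetacea", "frameshift_insertion", 1L, 70L, 1L, "A"),
        # exon-5 erosion in the delphinoid clade (carries Gly187)
        spec_row("Delphinoidea", "exon_deletion", 5L),
        # toothed whales: non-canonical acceptor of exon 8
        spec_row("Odontoceti", "splice_acceptor_noncanonical", 8L,
                 alt = "AC"),
        spec_row("P_catodon", "frameshift_insertion", 4L, 400L, 1L, "T"),
        spec_row("L_obliquidens", "frameshift_deletion", 3L, 300L, 1L),
        # exon 9 absent in all cetaceans
        spec_row("Cetacea", "exon_deletion", 9L),
        # manatee: premature stop in exon 5
        spec_row("T_manatus", "premature_stop", 5L, 540L, 3L, "TGA")),
      masks = rbind(
        mask_row("L_obliquidens", e1[1] - 60L, e1[2] + 60L),
        mask_row("S_chinensis", e1[1] - 60L, e1[2] + 60L),
        mask_row("P_catodon", e1[1] - 60L, e1[2] + 60L),
        mask_row("B_mysticetus", e1[1] - 60L, e1[2] + 60L),
        mask_row("T_truncatus", ex[5, 1] - 200L, ex[5, 2] + 200L),
        mask_row("Balaenoptera", ex[5, 1] - 200L, ex[5, 2] + 200L),
        mask_row("B_mysticetus", ex[5, 1] - 200L, ex[5, 2] + 200L))),
    Mtnr1a = list(
      specs = rbind(
        # whole-locus deletion between FAT1 and F11 in the seven
        # non-sperm-whale toothed whales
        spec_row("Delphinida", "gene_deletion",
                 gstart = grow$start - 300L, gend = grow$end + 300L),
        # sperm whale: 19-nt frameshift deletion in exon 1
        spec_row("P_catodon", "frameshift_deletion", 1L, 200L, 19L),
        # baleen whales: heavy erosion of exon 1 (relic)
        spec_row("Mysticeti", "inframe_deletion", 1L, 100L, 330L),
        # manatee: 1-nt deletion in exon 2
        spec_row("T_manatus", "frameshift_deletion", 2L, 700L, 1L)),
      masks = rbind(
        # assembly gaps impairing the absence call in four toothed whales
        mask_row("O_orca", grow$start - 550L, grow$start - 350L),
        mask_row("T_truncatus", grow$start - 550L, grow$start - 350L),
        mask_row("S_chinensis", grow$start - 550L, grow$start - 350L),
        mask_row("L_vexillifer", grow$start - 550L, grow$start - 350L),
        # exon 2 unresolved in the sperm whale and baleen whales
        mask_row("P_catodon", ex[2, 1] - 100L, ex[2, 2] + 100L),
        mask_row("Mysticeti", ex[2, 1] - 100L, ex[2, 2] + 100L))),
    Mtnr1b = list(
      specs = rbind(
        # conserved exon-1 stop in orca and humpbacked dolphin
        spec_row("O_orca", "premature_stop", 1L, 90L, 3L, "TGA"),
        spec_row("S_chinensis", "premature_stop", 1L, 90L, 3L, "TGA"),
        # start loss across the four delphinids
        spec_row("Delphinidae", "start_loss", 1L, 0L, 3L, "ACG"),
        # 1-nt exon-1 insertion in the rorqual + grey whale clade
        spec_row("Balaenopteroidea", "frameshift_insertion", 1L, 150L,
                 1L, "G"),
        # trans-species 1-nt deletion in exon 2 (cetacean root)
        spec_row("Cetacea", "frameshift_deletion", 2L, 500L, 1L),
        # grey whale: 282-nt in-frame deletion in exon 2
        spec_row("E_robustus", "inframe_deletion", 2L, 600L, 282L),
        # Pacific white-sided dolphin: exon 2 cleanly deleted
        spec_row("L_obliquidens", "exon_deletion", 2L),
        # manatee: exon-2 stop + frameshift set
        spec_row("T_manatus", "premature_stop", 2L, 480L, 3L, "TAA"),
        spec_row("T_manatus", "frameshift_insertion", 2L, 540L, 1L, "A"),
        spec_row("T_manatus", "frameshift_deletion", 2L, 570L, 1L)),
      masks = rbind(
        mask_row("B_bonaerensis", e1[1] - 100L, e1[2] + 100L),
        mask_row("O_orca", ex[2, 1] - 100L, ex[2, 2] + 100L),
        mask_row("T_truncatus", ex[2, 1] - 100L, ex[2, 2] + 100L))),
    stop("unknown gene: ", gene))
}

# premature stops arise by single substitutions in nature; force the
# reference codon at each planted stop site to a sense codon one
# substitution away from the planted stop
plant_stop_precursors <- function(ref, specs) {
  precursor <- c(TGA = "TGG", TAA = "TCA", TAG = "TAC")
  rows <- which(specs$type == "premature_stop")
  for (i in rows) {
    p <- specs$cds_pos[i]
    codon <- precursor[[specs$alt[i]]]
    g <- cds_to_genomic(ref$model, p)
    seq <- ref$genome[[ref$model$chrom]]
    substr(seq, g + 1L, g + 3L) <- codon
    ref$genome <- genome(stats::setNames(seq, ref$model$chrom))
    substr(ref$cds, p + 1L, p + 3L) <- codon
  }
  ref
}

#' Ready-made gene-loss scenario for one melatonin gene
#'
#' Builds a complete, seeded simulation of one melatonin pathway gene
#' (`Aanat`, `Asmt`, `Mtnr1a` or `Mtnr1b`) across 12 cetaceans with the
#' hippopotamus and manatee as outgroups: a reference locus, per-species
#' genomes carrying the published per-species mutation maps planted on the
#' branches where they are shared by descent, assembly gaps as N runs,
#' per-species annotation tables and sequencing-sample counts (two
#' independent projects per species; one for *L. vexillifer* and
#' *S. chinensis*).
#'
#' @param gene one of `"Aanat"`, `"Asmt"`, `"Mtnr1a"`, `"Mtnr1b"`.
#' @param seed integer seed fixing every random stream.
#' @param substitution_rate per-site, per-branch neutral substitution rate
#'   (default 0: the mutation maps are exact replicas; raise it to overlay
#'   background divergence).
#' @return a `gene_loss_scenario`: list with `gene_id`, `model`,
#'   `ref_genome`, `ref_annotation`, `ref_cds`, `tree`, `newick`,
#'   `species`, `genomes`, `annotations`, `truth`, `sra_samples`,
#'   `critical_codons`, `chrom` and `seed`.
#' @export
melatonin_fixture <- function(gene = MELATONIN_GENES, seed = 1L,
                              substitution_rate = 0) {
  gene <- match.arg(gene)
  arch <- melatonin_architecture(gene)
  ref <- generate_reference_gene(
    length(arch$exons), arch$exons, arch$introns,
    seed = make_seed(seed, match(gene, MELATONIN_GENES)),
    gene_id = gene, upstream_symbols = arch$upstream,
    downstream_symbols = arch$downstream)
  tree <- parse_newick(fixture_newick())
  ev <- melatonin_events(gene, ref)
  ref <- plant_stop_precursors(ref, ev$specs)
  sim <- evolve_on_tree(ref, tree, ev$specs, ev$masks,
                        rate = substitution_rate,
                        seed = make_seed(seed, 100L))
  sra <- stats::setNames(rep(2L, length(tree$tip.label)), tree$tip.label)
  sra[c("L_vexillifer", "S_chinensis")] <- 1L
  structure(list(
    gene_id = gene, model = ref$model, ref_genome = ref$genome,
    ref_annotation = ref$annotation, ref_cds = ref$cds,
    tree = tree, newick = fixture_newick(),
    species = tree$tip.label,
    genomes = sim$genomes, annotations = sim$annotations,
    truth = sim$truth, sra_samples = sra,
    critical_codons = if (gene == "Asmt") 187L else integer(0),
    chrom = ref$model$chrom, seed = as.integer(seed)
  ), class = "gene_loss_scenario")
}

#' @export
print.gene_loss_scenario <- function(x, ...) {
  cat(sprintf(
    "<gene_loss_scenario> %s: %d species, %d planted event record(s)\n",
    x$gene_id, length(x$species),
    if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

#' Write a scenario to disk as standard formats
#'
#' FASTA genomes, GFF3 reference annotation, newick tree, BED-like TSV
#' annotation tables and the TSV truth table, under one directory.
#'
#' @param scenario a [melatonin_fixture()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(scenario$ref_genome,
                     file.path(dir, "reference.fasta"))
  write_gene_model_gff3(scenario$model, file.path(dir, "reference.gff3"))
  writeLines(scenario$newick, file.path(dir, "species_tree.nwk"))
  write_annotation_table(scenario$ref_annotation,
                         file.path(dir, "reference_annotation.tsv"))
  for (sp in scenario$species) {
    write_genome_fasta(scenario$genomes[[sp]],
                       file.path(dir, paste0(sp, ".fasta")))
    write_annotation_table(scenario$annotations[[sp]],
                           file.path(dir, paste0(sp, "_annotation.tsv")))
  }
  if (!is.null(scenario$truth))
    utils::write.table(scenario$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
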