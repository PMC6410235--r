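---
title: "Inferring gene loss from genome assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene loss from genome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inference problem

A gene is *lost* when its locus is gone, and *pseudogenized* when the locus
persists but the open reading frame (ORF) is disrupted. Establishing either
from genome assemblies alone is delicate: an exon can be genuinely deleted
or simply fall into an assembly gap; an apparent frameshift can be a real
mutation or a sequencing error; and a mutation observed in several species
can mark a single ancestral event or repeated artifacts. `genloss`
implements a complete, testable version of the comparative workflow used in
studies of gene loss in mammals — the worked example throughout is the
erosion of the melatonin synthesis (*Aanat*, *Asmt*) and signalling
(*Mtnr1a*, *Mtnr1b*) genes in cetaceans — with each line of evidence kept
explicit:

1. **Exon mapping** — each reference exon is located and aligned
   independently in the target genome.
2. **Mutation calling** — ORF-disrupting events are read off the
   alignments: premature stop codons, frameshift and in-frame indels,
   start-codon loss, non-canonical splice sites, whole-exon deletions.
3. **Read validation** — candidate mutations are checked against raw
   sequencing reads, requiring support from independent sequencing
   projects.
4. **Cross-species matching and branch placement** — equivalent mutations
   are grouped across species and placed on the branch of a rooted species
   tree where they arose, under Dollo parsimony.
5. **Synteny** — where a gene is not found at all, the flanking-gene
   context decides between *lost* (complete, gap-free locus without the
   gene) and *inconclusive* (gaps or remnants).
6. **Status classification** — the evidence is combined into one verdict
   per species and gene: `intact`, `pseudogene`, `likely_pseudogene`,
   `lost` or `inconclusive`.

# Exon mapping

## Seeding and alignment

Candidate placements come from exact shared k-mers (default `word_size`
10, the value blastn-style retrieval uses for diverged queries), clustered
by alignment diagonal within a 16-column band. Each cluster is expanded
into a window sized by the *unseeded* query remainder on each side plus a
30-nt slack — enough to place the rest of the exon, little room to drift.

Each exon is then aligned semi-globally (global in the exon, free end-gaps
in the window) under the Gotoh three-state affine-gap recurrence,
implemented in C++ (`src/gotoh.cpp`). Scoring defaults are blastn-like:
match +2, mismatch −3, gap open −5, gap extend −2; a gap of length L costs
`open + (L−1)·extend`. Determinism is part of the contract: traceback
prefers diagonal over up over left, gap extension over re-opening, and the
leftmost optimal endpoint, so identical inputs give byte-identical
alignments.

**N handling.** Assembly gaps must neither create nor mask mutations, so
any column involving N scores 0 (neither match nor mismatch) and never
counts toward identity.

## Long structural indels: seed-anchored chaining

With blastn-like scores, *extending* a gap costs 2 per column while
*drifting through unrelated sequence* costs only ~1.75 per column in
expectation — which is why blastn reports a long deletion as two separate
local hits rather than one gapped alignment. A single semi-global pass
therefore shreds deletions longer than a few dozen bases into spurious
micro-indels. When collinear seed clusters imply a diagonal jump of at
least 30 nt, `map_gene()` instead aligns the exon piecewise: each seed
block and each inter-block segment is aligned under hard end constraints,
and the concatenated columns yield the structural event as one clean gap
run. This reproduces, in code, what manual curation of split blast hits
does by eye, and is what recovers a 282-nt deletion as a single in-frame
event.

## Terminal noise trimming

The exon-global recurrence must spend every exon base; when an exon end has
no true homolog in the window, the optimal path strings it through
unrelated sequence at roughly LCS density (~65% identity — above any
reasonable acceptance threshold). A terminal segment scoring below −15 over
at least 15 columns is therefore trimmed: its exon bases are re-emitted as
a terminal deletion run and its window bases returned to the free overhang.
Genuine diverged exon ends score positive and are never touched. The
thresholds are deliberately coarse — a couple of edge mismatches never
trigger trimming.

## Acceptance and missing statuses

An exon is `mapped` when alignment identity (matched columns / total
columns) reaches `min_identity`, default 0.60 — tolerant of
cetacean–cow-scale divergence, while rejecting spurious windows. Below
that, the placement counts as `low_identity` (a *remnant*) only when
backed by a solid seed cluster covering at least 5% of the exon's k-mers
(never fewer than 3 shared k-mers); one chance 10-mer collision in
unrelated sequence is not a remnant. Exons with no acceptable placement are
`missing_in_gap` when ≥30% of the interval projected from the nearest
mapped flanking exons is N, otherwise `missing_no_gap`. Overlapping
placements keep the higher-scoring exon and remap the other among its
remaining candidates.

# Mutation calling

* **Indels.** Each maximal gap run in a mapped exon alignment is one
  event: target-side gaps are deletions, reference-side gaps insertions,
  classified by length mod 3. Every indel is left-normalized VCF-style
  against the reference CDS, so the same event gets identical coordinates
  in every species regardless of where the aligner happened to place the
  gap — the property that makes exact-key cross-species matching valid.
  `frame_consequence` labels a shifting event by its own length mod 3
  (`shift+1`, `shift+2`); the signed running total over the CDS decides
  `restored` (e.g. a 2-nt and then a 1-nt deletion).
* **Premature stops.** Target codons are read on the reference codon grid,
  only where all three codon bases are aligned without gaps or internal
  insertions and the cumulative frame at the codon start is intact or
  restored. Stops downstream of an uncompensated frameshift are reported
  with an `fs_context` flag (first stop per shifted run) — consequences of
  the frameshift, never independent events, and excluded from grouping and
  status logic.
* **Start codon.** `start_loss` when the three target bases aligned to the
  reference ATG are not ATG; gaps count as loss; an unmapped start exon is
  an indeterminate start, not a call.
* **Splice sites.** Canonical is GT/AG only. For each inferred intron
  between consecutive mapped exons the two donor and two acceptor bases
  are inspected; a GC donor is still called non-canonical but annotated
  `GC-AG minor`; N at the site yields no call.
* **Exon loss.** A missing exon with mapped flanks becomes `exon_deletion`
  only when the intervening target interval has no N run (≥10 nt) and no
  residual exon seeds; with N runs, or at a gene terminus where assembly
  truncation cannot be excluded, it is `exon_missing_gap`.

# Read validation

Assembly-derived mutations are confirmed against raw reads the way
SRA-based validation is done manually: each read is aligned (both
orientations) to a reference-allele and a mutant-allele haplotype of the
locus; reads under 95% identity are discarded; a surviving read supports
the allele of its higher-scoring haplotype (ties ignored) and only counts
if it spans the event plus ≥10 nt on each side. A mutation is `confirmed`
with spanning mutant reads in at least 2 distinct samples ("sequencing
projects"), `unconfirmed` otherwise (a single available sample is noted as
such), `insufficient_data` with no read sets. Validation never changes a
verdict — mutations present in an assembly are reported even where
confirmation was impossible — it only sets the `validated` flag.

# Cross-species matching and Dollo placement

Groups are formed by exact key: (gene, type, exon, normalized CDS
position, length, alt allele). Species whose mapping has no usable exon at
the event position are *indeterminate* for that group — absence of
evidence, not evidence of absence. An optional ±1-codon tolerance for
premature stops exists but is off by default.

A shared mutation is placed on the edge above the most recent common
ancestor of its carriers — the Dollo (single origin, no reversal)
assumption, matching how shared-presence arguments are actually made.
Non-carrier, non-indeterminate descendants of that ancestor are reported
as conflicts (possible independent origin or missed call) rather than
silently absorbed; the built-in scenarios exercise this deliberately with
an exon-1 stop shared by two non-sister dolphins.

# Synteny

The reference block collects the five nearest protein-coding genes on each
side of the target (non-coding entries are skipped and do not count). In a
query species the interval between the two *direct* neighbours is
inspected: `present` with any mapped exon; `remnant` with only
sub-threshold placements or solid residual seeds; otherwise
`absent_gapped` when the interval carries an N run of ≥10 nt (missing
sequence — no conclusion), and `absent_complete` when it is gap-free and
traceless. Only `absent_complete` can support a `lost` verdict.

# Status classification

Decision order, per species × gene:

1. no mapped exon — synteny decides: `absent_complete` → `lost`,
   otherwise `inconclusive`;
2. any hard disrupting call (premature stop, frameshift, non-canonical
   splice, start loss, exon deletion) → `pseudogene`;
3. only in-frame indels, but removing ≥4 codons in total or a flagged
   critical residue (e.g. the active-site glycine, codon 187, of ASMT) →
   `likely_pseudogene` — encoding the judgement that substantial in-frame
   loss "strongly suggests" inactivation without overclaiming for small
   in-frame events;
4. every exon mapped and zero calls → `intact`;
5. otherwise `inconclusive`.

# The simulator and the built-in scenarios

`generate_reference_gene()` builds a synthetic locus: a multi-exon gene of
random sense codons (ATG start, single terminal stop), canonical GT/AG
introns, five protein-coding neighbour genes per side plus non-coding
features, all annotated. `evolve_on_tree()` copies the root sequence down
a rooted tree, drawing `Poisson(rate × length)` substitutions per branch
and then applying that branch's planted mutation specs, so planted events
are shared by descent; assembly gaps are painted as N runs per species;
every coordinate is a root coordinate, and each leaf's truth table records
which planted events the pipeline can in principle observe (events in
masked, deleted or heavily eroded exons, deleted loci, or terminal exons
without anchors are marked unobservable, with the reason).

`melatonin_fixture()` instantiates the four published cetacean mutation
maps on a 14-taxon tree (eight toothed whales, four baleen whales,
hippopotamus and manatee as outgroups; internal nodes carry clade labels).
Fixture choices worth knowing:

* **Substitution rate defaults to 0** for these named scenarios: the
  published per-species maps depict the disruptive events themselves, not
  background divergence, so the replicas are exact. `evolve_on_tree()`
  takes any rate, and the recovery properties are also exercised at
  nonzero rates in the test suite.
* Planted premature stops sit one substitution from their reference codon
  (TGG→TGA and the like), as real nonsense mutations do.
* Exon and intron lengths are realistic in order of magnitude; exact
  values are recorded constants. The *Mtnr1b* second exon is 903 nt so
  that its 282-nt deletion leaves the exon mappable above the 0.60
  identity threshold.
* Sequencing-sample counts are two per species, one for *L. vexillifer*
  (explicitly single-resource) and one for *S. chinensis* (its shared
  exon-2 deletion is reported as the one not SRA-confirmed); that is what
  makes the shared *Aanat* exon-1 stop confirmable in exactly 9 of its 11
  carriers.
* The non-canonical *Asmt* splice site of Odontoceti is planted at the
  acceptor of exon 8: with exon 9 absent in all cetaceans, a donor behind
  exon 8 could never be inspected.
* Terminal-exon deletions (exon 9 of *Asmt*; the *L. obliquidens Mtnr1b*
  exon 2) are reported by the caller as `exon_missing_gap` — the
  conservative terminal rule refuses to exclude assembly truncation — and
  their truth rows are marked unobservable as deletions.

What the simulator does *not* emulate: realistic indel length spectra, GC
content and repeats, quality-score error profiles, paralogous gene
families, rearrangements beyond a single locus. Passing tests demonstrate
that the *logic* of the pipeline is sound under its stated assumptions,
not that real assemblies are free of the artifacts that manual curation
deals with in practice.

# Problem sizes and numerical choices

The test suite runs entirely on synthetic data built at test time: 14
species × 4 genes for the scenario tests; 500 random pairs (length ≤ 12)
against an independently implemented substring-global oracle plus 30 tiny
pairs against full path enumeration for the aligner; planted indel lengths
1–30 exhaustively; 200 random (tree, branch) draws for Dollo placement; 50
seeded replicates at 0.5% read error, 20× depth and 2 samples for
validation. All randomness flows from explicit integer seeds through named
sub-streams, so every run is reproducible bit for bit.

Tie-breaking is specified everywhere rather than left to chance: leftmost
placement on equal seed support, diagonal > up > left in traceback,
extension over re-opening within a gap run, and alphabetical stability in
grouping. Degenerate inputs (empty read sets, absent neighbours, exons at
contig edges, all-N windows) are all defined states, not errors, except
where the input itself is malformed (CDS length not a multiple of 3,
overlapping planted events on one lineage).

# Limitations

* Exons are mapped independently; there is no spliced-alignment model with
  intron-length priors, and paralogy is resolved only by best score with
  runners-up reported, not by orthology inference.
* Identity-based acceptance uses a single global threshold; extremely
  short exons (<20 nt) would seed poorly at word size 10.
* Dollo placement reports conflicts but does not probabilistically weigh
  independent origins against missed calls.
* The read validator aligns against two local haplotypes; it is not a
  general-purpose read mapper and does not model mapping quality.
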