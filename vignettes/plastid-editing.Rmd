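---
title: "Calling and comparing plastid RNA editing from aligned RNA-seq reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing plastid RNA editing from aligned RNA-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastedit)
```

## The problem

In plant organelles, post-transcriptional RNA editing converts individual
cytidines to uridines (and, rarely, uridines to cytidines). Against a
plastid genome reference, an editing event is visible in RNA-seq as a
reference-C position where a fraction of aligned reads carry T (on the
reverse strand: reference G with A-bearing reads). `plastedit` turns
per-tissue aligned reads (SAM) plus a reference (FASTA) and gene models
(GFF3) into a table of editing sites with per-tissue efficiencies,
feature and codon consequences, differential-editing calls between
tissues, and RPKM expression estimates — and ships a deterministic
synthetic-plastome simulator so every stage can be validated against a
known truth table without any sequencing data.

## The calling model

For each reference position the pileup records depth and counts of each
read base in reference plus-strand space (SAM already stores read
sequences in that orientation). Each reference base admits exactly one
editing interpretation:

| reference base | read base | transcript strand | call |
|---|---|---|---|
| C | T | + | C-to-U |
| T | C | + | U-to-C |
| G | A | − | C-to-U |
| A | G | − | U-to-C |

Inside an annotated stranded feature only the orientation matching the
feature strand is evaluated; intergenic positions are reported with
`transcript_strand = "unassigned"` using the orientation implied by the
reference base. A consequence of the table above is that a single pileup
column can never yield two competing interpretations, so no tie-breaking
between orientations is ever needed.

A site is called when all three low-frequency variant thresholds hold:

* depth ≥ `min_coverage` (default 10),
* edited-read count ≥ `min_count` (default 2),
* edited fraction ≥ `min_frequency` (default 5%).

The **editing efficiency** of a site is simply `edited_count / depth`.
Sites inside, or within 1 bp of, a homopolymer run of
`homopolymer_min_run` (default 6) identical bases are flagged and
excluded from all downstream summaries: sequencing slippage in such runs
mimics editing, and slippage errors concentrate at run borders, which is
why the 1 bp border is included in the mask.

Efficiencies are binned into five classes — full (> 90%), high partial
(60–90%], medium partial (40–60%], low partial (20–40%] and poor partial
[5–20%]. The published ranges share their endpoints, so the bins are
resolved lower-exclusive/upper-inclusive (0.90 is *high*, 0.91 is
*full*), with the poor bin closed at 0.05 so that every called site has
a class.

Before the pileup, alignments are filtered by two mapping-quality style
fractions: aligned length / read length ≥ 0.98 and matching bases /
aligned length ≥ 0.98. "Similarity" is defined here over the aligned
part of the read (matches / aligned length), since the term is
mapper-specific and not otherwise pinned down. No base-quality or
mapping-quality cutoffs are applied by default.

## Annotation

Sites are assigned to the unique overlapping feature (CDS, tRNA, rRNA,
intron), or to the intergenic spacer (IGS). For CDS sites the offset
within the spliced CDS is computed by walking exons in transcript
orientation, giving the conventional `<gene>-<offset>` site label; other
sites are labelled by genomic position (IGS sites additionally carry
their flanking gene names). The codon consequence translates the
reference and edited codons under the standard genetic code:

* `start_created` — the edit falls in codon 1 of a CDS whose annotated
  initiation codon is not ATG and turns it into ATG (ACG→AUG). An
  internal ACG→AUG is ordinary nonsynonymous; start creation is a
  property of the initiation codon only.
* `stop_created` — the edited codon is a stop and the reference codon is
  not (e.g. CAA→UAA).
* otherwise `synonymous` / `nonsynonymous` by amino-acid identity. Every
  third-codon-position C-to-U edit is synonymous under the standard code
  (NNC and NNU always encode the same residue); the test suite asserts
  this over all 16 contexts.

Hydropathy change is reported on the Kyte–Doolittle scale (edited minus
reference residue; 0 for start/stop cases). The scale choice is a
package decision — "hydrophobicity increase" is the quantity of
interest, and Kyte–Doolittle is the field default.

Each edit is annotated independently against the reference CDS. For
codons carrying two edits, `codon_consequence()` also accepts both
positions at once and annotates the jointly edited codon (e.g. a UCC
serine codon edited at positions 2 and 3 becomes UUU, Ser→Phe); note
that the second-position edit alone already gives Ser→Phe while the
third-position edit alone is synonymous, so per-site and joint
bookkeeping genuinely differ.

`neighbor_context()` profiles the bases immediately 5′ and 3′ of each
site in transcript orientation (reported in the RNA alphabet),
separately for protein-coding and non-coding sites — the classic check
for the pyrimidine_A ("U_A") neighbourhood bias of plant editing sites.
`extract_window()` returns oriented edited/unedited windows (e.g. the
−30/+10 cis-element region, or 50 nt flanks for folding analyses, which
are themselves out of scope here).

## Differential editing and expression

`merge_tissues()` takes the union of called sites and looks up the raw
efficiency of every site in every tissue directly from the pileup, so a
sub-threshold 3% efficiency is recorded as 3%, not as "absent". A site
is *common* when called in both tissues and *tissue-specific* when
called in one tissue while the other has adequate coverage
(≥ `min_coverage`) but fails the calling thresholds; with inadequate
coverage the status is *unknown* rather than specific. The differential
statistic is the raw percentage-point difference of efficiencies
(first tissue minus second); a site is differential when both tissues
have adequate coverage and |delta| ≥ 0.20. Deltas are differences of
efficiencies, never of classes, and a delta of exactly 0 is never
counted as differential at any threshold.

`compute_rpkm()` counts a read for a gene when its alignment midpoint
falls in the gene's exons (midpoint assignment avoids double counting at
gene boundaries; the exon model excludes introns), with the library size
equal to all retained mapped reads, and reports reads per kilobase of
exon model per million mapped reads plus the between-tissue fold change.
Ratios with a zero denominator are flagged undefined rather than
reported as infinite.

`summarize_edits()` assembles the per-tissue / common / total accounting
table over all categories and the derived percentages. In the
codon-position substitution shares, start- and stop-creating edits count
as nonsynonymous; in the category table they are separate rows. The
two-tissue identities (per-tissue counts minus common equals the union,
category rows summing to their totals) are asserted as properties over
random simulations in the test suite.

## The synthetic-data generator

`sim_config()` fixes the simulation scenario; its defaults are the
validation conditions used throughout the tests: a 20 kb plastome-like
genome (GC 37%) carrying 12 genes on both strands (two intron-containing
CDS, two tRNAs; every CDS in frame, started by ATG — or ACG for the
designated start-creation test gene — free of internal stops, and one
CDS carrying a CCC-CCC codon pair so a ≥6 bp homopolymer run exists
inside a gene), 100 planted edits with per-tissue efficiencies uniform
on [0.10, 0.95] (8% of them U-to-C, echoing the strong C-to-U bias of
plastid editing), 100 bp single-end reads at 200-fold coverage, and a
uniform substitution error rate of 0.002 per base. The planted set
always contains, unless disabled, one tissue-specific site (efficiency 0
in the second tissue), one pair differing by 30 percentage points, and
one site inside a homopolymer run (whose masking the tests verify).
Reads overlapping a planted site carry the edited base independently per
read with probability equal to the tissue's true efficiency, giving the
Binomial(depth, efficiency) structure the efficiency estimator assumes.

Everything is deterministic in the seed, down to byte-identical FASTA /
GFF3 / SAM / TSV outputs. What the simulator does *not* model: indels,
paired-end or spliced reads, base-quality variation, coverage biases, or
the duplicated inverted repeat of real plastomes — so passing tests
demonstrate correctness of the counting and classification machinery,
not robustness to mapping artefacts of real libraries.

Reads are emitted pre-aligned (SAM with correct coordinates, `NM` tags
and `@SQ` header) because read mapping itself is outside the package's
scope; the genome is treated as linear for read placement (no
origin-spanning reads), which is adequate at this scale.

## Numerical and design notes

* **Benchmark problem sizes.** The recovery benchmark uses the default
  20 kb / 100-edit / 200-fold scenario; the differential benchmark
  plants 160 sites per delta level (deltas 0, 0.1, 0.25, 0.5 against a
  0.30 baseline) at 800-fold coverage on a 12 kb genome, where the
  per-site miss probability for a 0.25 delta against the 0.20 threshold
  is about 2%, so 160 sites give the sensitivity estimate a ~1%
  standard error.
* **Filtering planted-edit benchmarks.** The recovery benchmarks build
  the pileup from the simulated alignments directly, without the
  similarity filter. At planted densities of several edits per kilobase
  — far above natural plastome density, where a 100 bp read overlaps
  ~0.1 edits — each edit on a read counts as a mismatch against the DNA
  reference, so a 0.98 similarity cutoff preferentially discards edited
  reads and biases efficiencies downward. This interaction is a real
  property of similarity filtering worth knowing about; at natural
  densities it is negligible. The filter has its own dedicated tests
  (exact threshold arithmetic, and retention matching the closed-form
  binomial tail under uniform errors).
* **Rounding.** Printed percentages follow fixed conventions:
  whole percents for codon-position and substitution shares, one
  decimal for efficiency-class shares, two decimals for the
  edits-per-nucleotide rate. Counts are exact integers.
* **Degenerate inputs.** Empty pileups, gene-free genomes, zero planted
  edits, and empty call sets all flow through and summarise to zeros;
  infeasible gene packing and insufficient eligible positions raise
  configuration errors naming the problem.
* **Statistical testing.** No per-site significance test is attempted:
  the design has no biological replicates, so the 5% frequency floor
  and the 20-percentage-point differential rule are the operative
  definitions, as in the study design this package follows.

## A complete run

```{r, eval = FALSE}
library(plastedit)

cfg <- sim_config(seed = 1)
res <- run_pipeline(cfg, "demo_out")
print(res$summary)

# recovery of the planted truth
rec <- read.delim(res$paths$recovery)
mean(rec$called[!rec$in_homopolymer & rec$true_efficiency >= 0.2])
```

With real data, replace the configuration by file paths:

```{r, eval = FALSE}
res <- run_pipeline(list(genome = "cpDNA.fasta",
                         features = "cpDNA.gff3",
                         sam = c(leaf = "leaf.sam", flower = "flower.sam")),
                    "out")
```
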