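---
title: "Identifying and characterising lncRNAs with lncloc: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and characterising lncRNAs with lncloc: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncloc)
```

## The problem

Long noncoding RNAs (lncRNAs) are transcripts of at least 200 nt with no
protein-coding capacity. In non-model organisms they are discovered by
assembling RNA-seq reads into transcript models and then eliminating
everything that looks protein-coding. `lncloc` implements the downstream
half of that workflow for any organism with a genome and a protein-coding
gene set: it consumes an assembled transcript GTF (the assembly itself —
read mapping, junction pooling, transcript reconstruction — is out of
scope) and produces classified, named lncRNA candidates together with
expression and co-expression analyses.

## The filter cascade

Candidates are reduced in seven ordered steps, each recorded in a
telescoping report (input − removed = surviving at every step):

1. **Size**: spliced length ≥ 200 nt *and* ≥ 2 exons. Multi-exon evidence
   guards against mono-exonic assembly artefacts.
2. **ORF**: transcripts whose longest open reading frame is ≥ 300 nt are
   removed.
3.–7. **Evidence lists**: protein homology hits (e.g. BLASTX against
   SWISS-PROT at e < 0.001), putative UTR fragments of known mRNAs,
   coding-potential calls (e.g. CPC score > −1), conserved protein domains
   (Pfam/HMMER), and structural non-coding RNAs (tRNA/rRNA/sno/snRNA from
   Rfam/Infernal). These tools and their databases are external and
   version-dependent, so `lncloc` takes their *output* as plain
   transcript-ID lists; a helper parses tabular BLAST output (outfmt 6)
   at a chosen e-value cutoff. IDs not present in the input are collected
   as "stale evidence" and warned about rather than failing the run.

The final survivor set is order-independent (each rule is a set
intersection); only the per-step counts depend on the order.

### ORF definition

ORF finders differ in what they count. `lncloc::longest_orf` uses the most
conservative reading of "open reading frame": ATG-initiated,
stop-terminated (TAA/TAG/TGA), stop codon *included* in the length,
scanned over all six frames (both strands). ORFs truncated by the sequence
end do not count, and any codon containing `N` matches neither start nor
stop, so ambiguous sequence can only shorten an ORF, never extend one.
Forward-only scanning is available (`both_strands = FALSE`) for
strand-aware applications.

## Location classification

Each candidate receives exactly one of seven classes relative to the
reference annotation:

| class | rule |
|---|---|
| `JUNCTION_SHARED` | same strand, ≥ 1 intron identical (both boundaries) to a reference intron |
| `EXONIC_SENSE` | same strand, ≥ 1 bp exon–exon overlap |
| `EXONIC_ANTISENSE` | opposite strand, ≥ 1 bp exon–exon overlap |
| `INTRONIC_SENSE` | entire span inside one reference intron, same strand |
| `INTRONIC_ANTISENSE` | exons overlap a reference intron on the opposite strand, none of that gene's exons |
| `INTERGENIC` | no overlap with any gene span |
| `UNCLASSIFIED` | residual: unknown strand over a gene, or overlap patterns matching no rule |

Several rules can fire at once; they are resolved by a precedence ladder —
junction sharing is the strongest structural evidence, exonic beats
intronic, sense beats antisense:

`JUNCTION_SHARED > EXONIC_SENSE > EXONIC_ANTISENSE > INTRONIC_SENSE > INTRONIC_ANTISENSE`

The order is a package decision (annotation-comparison tools imply roughly
this ranking through their class codes but none states a formal
tie-break); it is an argument of `classify_transcripts()` and recorded in
the output. "Overlap" means ≥ 1 bp — the smallest unambiguous threshold.
The partner gene is the gene satisfying the winning rule, ties broken by
largest exonic overlap and then smallest `gene_id` for determinism.

### Naming

`assign_names()` follows gene-nomenclature practice for lncRNAs: intergenic
loci are numbered `<prefix>LINC1, 2, ...` by genomic position;
gene-associated loci take the partner gene ID plus `-IT` (sense intronic),
`-AS` (antisense), or `-OT` (sense exonic / shared junction); residual loci
become `<prefix>LNC-unc<n>`. Whether an intron-antisense overlap should be
`-AS` or `-IT` is genuinely ambiguous in the nomenclature; `-AS`
(antisense semantics) is the default and the alternative is a flag. When
two loci map to the same base name the second is suffixed numerically
(`-OT`, `-OT2`, ...), and isoforms within a multi-transcript locus get
`-RA`, `-RB`, ... ordered by position then ID.

## Loci and structural summaries

A *locus* is a connected component of transcripts under "same chromosome,
same strand, ≥ 1 bp exonic overlap" (transitive closure) — the operational
behaviour of assembler locus grouping. Unstranded transcripts only group
with each other. `structure_summary()` reports the exon-count histogram,
mean/median spliced length, mean exon and intron lengths, and the
alternative-splicing fraction (loci with ≥ 2 isoforms / loci). Exon and
intron means are computed **per interval** by default — every exon weighs
equally, matching how pooled length distributions are usually drawn — with
a per-transcript mode (`per_transcript = TRUE`) for the alternative
convention, since published summaries rarely say which was used.

## Expression analysis

All expression input is an FPKM matrix (TSV; first column IDs, header of
sample names). Missing cells are imputed as 0 with a logged count.

**Specific expression.** A transcript is specifically expressed in sample
*s* iff FPKM(s) > 3, FPKM < 1 in every other sample, and FPKM(s) ≥ 10 ×
the *maximum* over other samples. The fold rule could also be read against
the mean of the other samples; the maximum is stricter and is the default
(`compare = "mean"` gives the other reading). With the expressed threshold
above the silent threshold, at most one sample can be specific per
transcript.

**Differential expression.** `call_differential()` runs a Welch two-sample
t-test per transcript on `log2(FPKM + 1)` (variance stabilisation;
standard for FPKM), with Benjamini–Hochberg correction across tested
transcripts; a call requires p < 0.01 and q < 0.05. Replicates are
required: sequencing studies without biological replicates historically
relied on a model-based caller's internal dispersion assumptions, and
re-implementing those is not honest statistics — with single-replicate
groups the function returns the fold-change ranking only, with a warning.
Degenerate rows (zero pooled variance) get p = 1 when the group means are
equal and p = 0 otherwise.

**Clustering.** `cluster_expression()` performs average-linkage (UPGMA)
agglomeration on the distance 1 − Pearson r between rows. Rows are sorted
by ID before clustering so ties resolve deterministically; a constant row
has undefined correlation, which is treated as r = 0 (distance 1) and
reported.

## Neighbour co-expression

`nearest_genes()` assigns each lncRNA the reference gene minimising the
span-to-span gap on its chromosome, strand-ignored (distance 0 when spans
overlap; ties to the smallest gene ID), binned as overlap / < 5 kb /
< 10 kb / ≥ 10 kb with half-open boundaries (a gap of exactly 5000 falls
in the < 10 kb bin).

`coexpression_test()` compares the Pearson correlations of
(lncRNA, neighbour) expression pairs against `n_random` uniformly sampled
(lncRNA, non-neighbour gene) pairs, using a Welch two-sample t-test on the
two r distributions. The null never draws a lncRNA's own neighbour(s) or
the lncRNA itself, so true pairs cannot contaminate it. Pairs with
|r| > 0.8 are flagged as strongly correlated. Everything downstream of the
seed is deterministic: the same seed gives bit-identical results.

## The fixture generator

`generate_fixtures()` builds a complete synthetic study with known ground
truth so that every stage is testable without downloads: a toy genome,
protein-coding gene models, lncRNAs planted per location class, transcripts
planted to fail each filter rule, coding-evidence lists, and an FPKM matrix
with planted sample-specific rows and lncRNA–neighbour correlation.

Defaults emulate the structural scales reported for insect transcriptomes:
coding exons averaging 250 nt with 2.6 kb introns, lncRNA exons averaging
363 nt (lognormal lengths), an exon-count distribution in which most
lncRNAs have two exons, ~20 % of lncRNA loci carrying a second isoform,
and twelve expression samples. Expression noise is lognormal with a log2
standard deviation of 0.5 per sample; planted neighbour pairs share a
latent factor giving correlation ρ = 0.5 on the log scale.

Two design points matter for the ORF rule. Background sequence carries the
motif `CTAGCTAGCTAG` every 60 nt: `CTAG` is its own reverse complement and
the repeat places a TAG stop in all three codon phases, so every one of
the six frames meets a stop inside each motif and no spurious ORF can
exceed ~130 nt — comfortably below the 300 nt threshold even across splice
junctions. Planted ORFs are ATG + random non-stop codons + TAA cassettes
written into a single exon behind a pinning stop codon, and verified with
the package's own scanner at generation time (the cassette is redrawn in
the rare case a shifted frame beats the planted frame).

For the differential-expression simulations (`simulate_diff_matrix`) the
replicate noise default is σ = 0.1 on the log2 scale (~7 % CV, the
technical-replicate regime). This is a power-driven choice: with 3 vs 3
replicates the Welch degrees of freedom are only 2–4, and the BH q < 0.05
cutoff over 2000 transcripts with 50 true shifts requires per-row p below
~1.25 × 10⁻³, which an 8-fold shift reaches reliably only when σ ≲ 0.15
(measured recall ≈ 0.48 at σ = 0.3, ≈ 0.91 at σ = 0.15, ≈ 0.99 at
σ = 0.1). Larger biological variability is perfectly realistic too — it
simply leaves a 3-replicate design underpowered at those cutoffs, which is
worth knowing when planning a real experiment.

### What the generator does not emulate

Passing the truth-recovery suite shows the *logic* of each stage is
correct; it does not validate behaviour on real data. The generator makes
no attempt at realistic nucleotide composition (beyond stop-motif
seeding), sequencing noise in assembly (fragmented or merged transcripts,
retained introns), annotation errors in the reference gene set, multiple
isoforms per coding gene, overlapping coding genes, or heavy-tailed FPKM
distributions with dropout. Results on real assemblies will inherit
whatever artefacts the upstream assembler produced.

## Numerical and edge-case conventions

- Internal coordinates are 0-based half-open; GTF/GFF3 I/O converts
  to/from 1-based inclusive. Length is always `end − start`.
- Percentages are rounded half away from zero to 2 decimals
  (`round_half_up`), so tabulated percentages match hand arithmetic
  rather than banker's rounding.
- Strand "." is rejected in the reference annotation (the classifier
  needs it) but accepted with a warning for assembled transcripts, which
  are then excluded from strand-specific classes.
- A duplicate `transcript_id` spanning two chromosomes is an error, never
  a silent merge.
- A transcript on a chromosome absent from the annotation classifies as
  intergenic, with a warning; a chromosome with no genes yields an
  infinite neighbour distance, flagged.
- Evidence IDs absent from the input are warned about ("stale"), not
  fatal.

## Problem sizes used in validation

The shipped test-suite and acceptance script regenerate everything from
code at these sizes: 30 planted lncRNAs per class against 120 coding genes
on 4 Mb of genome for classifier recovery; 1000 random 1 kb sequences for
the ORF scanner cross-check; a 100-transcript fixture for the filter
cascade; a 1000 × 6 matrix with 50 planted specific rows and 30 decoys;
20 × 2000 transcripts for differential-caller calibration and recall;
100 seeds (power) plus 200 replicates (calibration) for the co-expression
test; and 50-element instances for the locus-grouping and UPGMA
brute-force comparisons.

## Known limitations

- The seven-class scheme needs transcript strand; unstranded assemblies
  degrade to intergenic/unclassified calls.
- The UTR-fragment filter step has no reproducible published algorithm;
  it is expressible only through an evidence list.
- `call_differential` tests exactly two groups per call; multi-group
  designs require multiple calls (with the multiple-testing implications
  left to the analyst).
- The co-expression null samples random pairs with replacement and
  excludes only annotated neighbours; cryptic paralogy or shared
  regulation in the "random" pool would make the test conservative.
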