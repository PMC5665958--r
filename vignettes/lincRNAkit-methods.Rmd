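---
title: "lincRNAkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincRNAkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(lincRNAkit))
```

# Scope

`lincRNAkit` implements a desk-scale version of a common comparative
genomics workflow: define a catalogue of long intergenic noncoding RNAs
(lincRNAs) from assembled transcript models, score their tissue
specificity from a multi-tissue expression matrix, and characterise their
epigenomic context (DNA methylation, transcription-factor binding,
sequence composition) around transcription start sites (TSSs), including
the relation between differentially methylated regions (DMRs) and
lincRNA loci. A seeded generator produces miniature datasets with known
ground truth so that every stage can be validated end to end without any
external data.

# The data model

All coordinates follow Bioconductor conventions internally: 1-based,
closed `GRanges` intervals. File formats keep their native conventions
(GTF 1-based closed; bedGraph and BED 0-based half-open; cytosine
reports 1-based positions). Conversions happen only in the readers and
writers in `R/io.R`.

* `TranscriptSet` — exon structures (a named `GRangesList`) plus
  per-transcript metadata (`transcript_id`, `gene_id`, `biotype`,
  evidence `source`). Validity enforces sorted, non-overlapping exons on
  a single chromosome and strand per transcript.
* `MethylationCalls` — width-1 cytosine records with methylated (`m`)
  and unmethylated (`u`) read counts, unique per (chromosome, position,
  strand).
* `MetaProfile` — a binned TSS-centred profile: `2 * flank / binWidth`
  values orientated 5'→3', with the bin geometry stored alongside.
* `FilterConfig` / `SimulationConfig` — parameter bundles with validity
  checks.

# The lincRNA definition cascade

A candidate transcript is called a lincRNA iff it passes all six
filters. Boundary semantics are part of the contract and are unit-tested
explicitly:

| filter | rule (defaults) | boundary |
|---|---|---|
| structure | ≥ 2 exons and exonic length > 200 nt | 201 passes, 200 fails |
| exon coverage | covered fraction ≥ 0.8 | 0.80 passes, 0.79 fails |
| junction support | every intron ≥ 3 reads | 3 passes, 2 fails |
| intergenic | ≥ 500 bp from any coding/housekeeping locus, strand-ignored | 500 passes, 499 fails |
| coding potential | CPC-style score < −1 | −1.01 passes, −1.0 fails |
| housekeeping | no BLASTN hit with evalue ≤ 1e−10 **and** identity ≥ 80 | both conditions required |

Transcripts whose evidence source is `annotation` (curated gene models
rather than RNA-seq assemblies) skip the two RNA-seq evidence filters.
The cascade short-circuits for speed but records an audit table with one
verdict (`pass` / `fail` / `not_evaluated`) per filter per transcript;
the surviving set is invariant to the filter order because the filters
are independent predicates (property-tested). Survivors are clustered
into loci by single-linkage over strand-aware ≥ 1 bp exonic overlap.

# Tissue specificity

For gene $g$ with mean-over-replicates FPKM vector $x$ across $T$
tissues, the expression density is $p = x / \sum_t x_t$. With Shannon
entropy $H$ in bits, the Jensen–Shannon divergence
$\mathrm{JSD}(p,q) = H\!\left(\tfrac{p+q}{2}\right) -
\tfrac{H(p)+H(q)}{2} \in [0,1]$, and the specificity score against
tissue $t$ is $1 - \sqrt{\mathrm{JSD}(p, e_t)}$ with $e_t$ the unit
vector. The reported JS score is the maximum over tissues; genes with JS
score > 0.5 are called tissue-specific (strict inequality). A gene
expressed in exactly one tissue scores exactly 1 there; all-zero genes
are flagged not-evaluable rather than scored. Argmax ties break to the
lowest tissue index for determinism.

```{r js}
fpkm <- c(0, 0, 12, 0, 0, 0, 0, 0, 0, 0, 0)
specificityScore(expressionDensity(fpkm), 3)
```

# TSS metaprofiles

All four profile operations share one window convention: 100 bins of
100 bp covering TSS ± 5 kb, orientated 5'→3'. In 0-based half-open
coordinates a plus-strand window is `[tss − 5000, tss + 5000)`; a
minus-strand window is the mirror `[tss − 4999, tss + 5001)` with bins
counted right-to-left. This makes bin 51 start exactly at the TSS on
both strands and makes profiles exactly invariant under reflecting the
genome and flipping strands — a property the test suite asserts to
1e−12 against naive per-base reimplementations.

* **Methylation**: per transcript and bin, $M = m/(m+u)$ over the summed
  calls in the bin, with the convention $M = 0$ when $m = 0$ (which also
  covers bins without cytosines); bins are averaged over all
  transcripts. An alternative `average = "covered"` mode averages only
  over transcripts with calls in the bin.
* **Binding**: mean per-base read depth per bin, positions absent from
  the coverage track counting as depth 0.
* **GC content**: $(\#G + \#C)/(\#A+\#C+\#G+\#T)$ per 100-bp window; N
  bases are excluded from both counts and all-N windows from the bin
  mean.
* **CpG observed/expected**: $\#\mathrm{CpG} \cdot L / (\#C \cdot \#G)$
  with $L$ the number of non-N bases, defined as 0 when $\#C$ or $\#G$
  is 0. Reference values: a window of `CGCG` scores 2, `CCGG` scores 1.

Gene-level methylation uses the same $M = m/(m+u)$, $M=0$ if $m=0$
convention over all calls in the locus span, both strands pooled.

# DMR calling and overlap

`callDmrsNaive()` is a deliberately simple stand-in for beta-binomial
dispersion-shrinkage DMR callers (such as DSS), whose statistical model
is out of scope here; externally produced DMR sets can be supplied via
`readDmrBed()`. Replicates are pooled per group by summing counts; at
every position covered in both groups a two-sided two-proportion z-test
with pooled variance is computed; significant CpGs (p < 0.01) with a
consistent sign of the difference merge into regions when consecutive
significant CpGs are ≤ 100 bp apart; regions are kept if they span
≥ 50 bp and contain ≥ 3 significant CpGs. These region rules mirror the
documented defaults of DSS's `callDMR`. `overlapDmrsWithGenes()` reports
every (locus, DMR) pair with ≥ 1 bp overlap, strand-ignored.

# The synthetic-data generator

The generator emulates the *structure* of the study data, not raw reads:
no FASTQ, alignment or bisulfite-conversion artefacts are simulated. The
default configuration is the desk-scale study condition and is **not**
tuned to the test suite:

* genome: 2 chromosomes × 5 Mb, uniform base composition (GC 0.42);
* genes: 300 protein-coding, 150 lincRNA, 20 housekeeping, plus 12
  decoys of each of five classes, each violating exactly one filter
  (single-exon, < 200 nt, < 500 bp from a coding gene, coding-potential
  positive, housekeeping-like);
* expression: 11 tissues × 2 replicates; per-gene lognormal baseline
  (lincRNA mean lower than coding) with small per-tissue and
  per-replicate lognormal noise; a biotype-dependent fraction of genes
  (lincRNA 0.5 > coding 0.15) has one tissue multiplied by a dominance
  fold of 50;
* methylation: CpGs every ~50 bp (geometric spacing), ~30× Poisson
  depth, binomial sampling; true levels are body/intergenic plateaus
  (coding 0.62 < intergenic 0.75 < lincRNA 0.80) minus a triangular dip
  centred on the nearest TSS, deeper for coding (0.42) than for lincRNA
  (0.40) genes — so lincRNAs are more methylated than coding genes both
  over gene bodies and at TSSs, and both profiles are V-shaped;
* binding: Poisson depth around a triangular peak (height 20, half-width
  1 kb) over background 2, piecewise constant at 50-bp steps;
* DMRs: 3 intervals of 400 bp planted inside lincRNA loci, group 2
  levels lowered by 0.5.

Triangular (not Gaussian) shapes were chosen so dip/peak expectations
are exactly computable in tests. Every output is byte-identical across
runs with the same configuration; all randomness flows from the single
seed through R's Mersenne–Twister stream in a fixed order.

```{r sim}
cfg <- simulationConfig(seed = 11,
  genome = list(nChroms = 1L, chromLength = 3e5),
  genes = list(nCoding = 10L, nLincRNA = 5L, nHousekeeping = 2L,
               nDecoySingleExon = 1L, nDecoyShort = 1L,
               nDecoyNearGene = 1L, nDecoyCpc = 1L,
               nDecoyHousekeeping = 1L),
  dmr = list(nPlanted = 1L))
sim <- simulateDataset(cfg, outDir = NULL, writeGenome = FALSE)
table(sim$truth$transcripts$class)
res <- runFilterCascade(sim$candidates, sim$evidence,
                        hkHits = sim$hkHits, annotation = sim$annotation)
res$funnel
```

# Numerical and determinism choices

* Entropies use base-2 logarithms with the convention
  $0 \log 0 = 0$, so JSD is bounded by 1 and the single-tissue score is
  exactly 1 (no tolerance needed).
* Probability vectors are validated to sum to 1 within 1e−9.
* $\mathrm{JSD}$ values are clamped at 0 before the square root to
  absorb negative round-off.
* File writers fix floating-point output at 6 significant digits so
  identical inputs give byte-identical outputs; full precision is kept
  in memory.
* Rank-sum tests use the normal approximation (`exact = FALSE`) so
  p-values are deterministic in the presence of ties.

# Decisions on underdetermined points

Where the workflow description leaves room, this package fixes the
following interpretations (each is documented at the function level):

* "longer than 200 nt" is implemented as exonic length ≥ 201 (strict
  inequality at 200).
* Junction support is per intron: every intron needs ≥ 3 reads.
* The intergenic distance is strand-agnostic and measured between locus
  spans (gap = bases strictly between; adjacent intervals have gap 0).
* The housekeeping exclusion requires the evalue and identity conditions
  jointly.
* Minus-strand windows mirror plus-strand windows exactly (see above)
  rather than sharing left edges.
* Gene methylation and bin methylation define $M = 0$ when $m = 0$,
  which also covers empty regions.
* Replicate expression values are averaged (mean FPKM) before forming
  densities.

# Problem sizes and limitations

The default simulation (~470 genes, ~200k CpGs × 4 call sets, 11 × 2
expression samples) runs the full pipeline in well under two minutes on
one CPU; the test suite's largest instance (520 genes per biotype)
finishes in about a minute. The package is not designed for
genome-scale inputs: profile extraction is linear in transcripts ×
window size, the naive DMR caller holds all shared CpGs in memory, and
no parallelism is used. The DMR caller ignores biological
overdispersion and should not be used for real inference; the generator
does not model read-level artefacts, isoform complexity (one transcript
per gene), or non-uniform genome composition (so sequence-composition
profiles from simulated genomes are flat apart from sampling noise).
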