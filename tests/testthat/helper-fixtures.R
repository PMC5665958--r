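## Shared fixture builders and brute-force oracles.

## Quick TranscriptSet from a list of specs:
##   list(chrom=, starts=, widths=, strand=, gene=, biotype=, source=)
makeTx <- function(specs, ids = sprintf("t%d", seq_along(specs))) {
  grl <- GenomicRanges::GRangesList(lapply(specs, function(s)
    GenomicRanges::GRanges(
      s$chrom %||% "chr1",
      IRanges::IRanges(s$starts, width = s$widths),
      strand = s$strand %||% "+")))
  names(grl) <- ids
  TranscriptSet(grl,
    gene_id = vapply(specs, function(s) s$gene %||% NA_character_,
                     character(1)),
    biotype = vapply(specs, function(s) s$biotype %||% "other",
                     character(1)),
    source = vapply(specs, function(s) s$source %||% "rnaseq",
                    character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Small simulation config (single chromosome) used across test files.
smallSimConfig <- function(seed = 11L, ...) {
  simulationConfig(seed = seed,
    genome = list(nChroms = 1L, chromLength = 1200000),
    genes = list(nCoding = 30L, nLincRNA = 15L, nHousekeeping = 3L,
                 nDecoySingleExon = 2L, nDecoyShort = 2L,
                 nDecoyNearGene = 2L, nDecoyCpc = 2L,
                 nDecoyHousekeeping = 2L),
    dmr = list(nPlanted = 2L), ...)
}

## Evidence DataFrame for candidates that should all pass the cascade.
passingEvidence <- function(x) {
  n <- length(x)
  S4Vectors::DataFrame(
    transcript_id = names(x),
    exon_coverage = rep(0.95, n),
    junction_reads = IRanges::IntegerList(lapply(
      pmax(exonCounts(x) - 1L, 0L), function(k) rep(10L, k))),
    cpc_score = rep(-2.5, n),
    source = rep("rnaseq", n))
}

## Brute-force per-base TSS window extraction shared by profile oracles:
## returns, for one transcript, the 2*flank genomic 0-based positions of
## its window ordered 5' -> 3'.
bruteWindowPos <- function(tss1, strand, flank = 5000L) {
  tss0 <- tss1 - 1L
  if (strand == "+") seq(tss0 - flank, tss0 + flank - 1L)
  else seq(tss0 + flank, tss0 - flank + 1L)
}

## The true methylation-level surface used by the generator, re-derived
## naively for spot checks (single position, ignoring clamping edge cases).
expectIdenticalFiles <- function(f1, f2) {
  testthat::expect_identical(readBin(f1, "raw", file.size(f1) + 10),
                             readBin(f2, "raw", file.size(f2) + 10))
}
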