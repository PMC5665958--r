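#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths
NULL

#' Set of spliced transcript models
#'
#' A \code{TranscriptSet} holds a collection of transcript models: for each
#' transcript, its ordered exons (a \linkS4class{GRangesList} element, all
#' exons on one strand of one chromosome) plus per-transcript metadata
#' (transcript id, gene id, biotype, evidence source).
#'
#' @slot exons A \linkS4class{GRangesList}, one element per transcript,
#'   named by transcript id. Exons within an element are sorted by start,
#'   pairwise non-overlapping, and share seqname and strand.
#' @slot txData A \linkS4class{DataFrame} with columns \code{transcript_id},
#'   \code{gene_id}, \code{biotype} (one of \code{coding}, \code{lincRNA},
#'   \code{housekeeping}, \code{other}) and \code{source} (\code{rnaseq} or
#'   \code{annotation}), one row per transcript, in the same order as
#'   \code{exons}.
#'
#' @seealso [TranscriptSet()] for construction, [readGtf()],
#'   [txSpans()], [tssOf()], [lociOf()]
#' @export
setClass("TranscriptSet",
  representation(exons = "GRangesList", txData = "DataFrame"))

.validTranscriptSet <- function(object) {
  msg <- NULL
  td <- object@txData
  need <- c("transcript_id", "gene_id", "biotype", "source")
  if (!all(need %in% colnames(td)))
    msg <- c(msg, paste("txData must have columns",
                        paste(need, collapse = ", ")))
  else {
    if (length(object@exons) != nrow(td))
      msg <- c(msg, "length(exons) must equal nrow(txData)")
    if (!identical(names(object@exons), as.character(td$transcript_id)))
      msg <- c(msg, "names(exons) must equal txData$transcript_id")
    if (anyDuplicated(td$transcript_id))
      msg <- c(msg, "transcript ids must be unique")
    bad <- !td$biotype %in% c("coding", "lincRNA", "housekeeping", "other")
    if (any(bad))
      msg <- c(msg, "biotype must be coding/lincRNA/housekeeping/other")
  }
  if (length(object@exons) > 0L) {
    u <- unlist(object@exons, use.names = FALSE)
    if (any(width(u) < 1L))
      msg <- c(msg, "all exons must have width >= 1")
    nchr <- elementNROWS(unique(seqnames(object@exons)))
    nstr <- elementNROWS(unique(strand(object@exons)))
    if (any(nchr > 1L) || any(nstr > 1L))
      msg <- c(msg, "exons of a transcript must share chromosome and strand")
    if (!all(unlist(lapply(start(object@exons), function(s)
        !is.unsorted(s, strictly = TRUE)))))
      msg <- c(msg, "exons must be sorted by start")
    ok <- vapply(seq_along(object@exons), function(i) {
      e <- object@exons[[i]]
      length(e) < 2L || all(start(e)[-1L] > end(e)[-length(e)])
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "exons of a transcript must be pairwise non-overlapping")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("TranscriptSet", .validTranscriptSet)

#' Construct a TranscriptSet
#'
#' @param exons A \linkS4class{GRangesList} of exons, one element per
#'   transcript. Elements are sorted by exon start on construction.
#' @param gene_id Character vector of gene ids, recycled to the number of
#'   transcripts. Defaults to the transcript ids.
#' @param biotype Character vector of biotypes (\code{coding},
#'   \code{lincRNA}, \code{housekeeping}, \code{other}).
#' @param source Character vector: \code{rnaseq} for assembly-derived
#'   transcripts (subject to exon-coverage and junction filters) or
#'   \code{annotation} for RefSeq/UniGene-style models that skip them.
#' @return A \linkS4class{TranscriptSet}.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   t1 = GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(101, 301), c(200, 500)), strand = "+"))
#' TranscriptSet(ex, gene_id = "g1", biotype = "other")
#' @export
TranscriptSet <- function(exons, gene_id = names(exons),
                          biotype = "other", source = "rnaseq") {
  if (!is(exons, "GRangesList"))
    exons <- as(exons, "GRangesList")
  if (is.null(names(exons)))
    stop("'exons' must be named by transcript id")
  exons <- endoapply(exons, function(e) e[order(start(e))])
  n <- length(exons)
  td <- DataFrame(
    transcript_id = names(exons),
    gene_id = rep(as.character(gene_id), length.out = n),
    biotype = rep(as.character(biotype), length.out = n),
    source = rep(as.character(source), length.out = n))
  new("TranscriptSet", exons = exons, txData = td)
}

#' @describeIn TranscriptSet Number of transcripts.
#' @param x,object A \code{TranscriptSet}.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @describeIn TranscriptSet Transcript ids.
#' @export
setMethod("names", "TranscriptSet", function(x) names(x@exons))

#' Subset a TranscriptSet
#'
#' @param x A \code{TranscriptSet}.
#' @param i Index vector (integer, logical or transcript id).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x))
  initialize(x, exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

setMethod("show", "TranscriptSet", function(object) {
  bt <- table(factor(object@txData$biotype,
                     c("coding", "lincRNA", "housekeeping", "other")))
  cat("TranscriptSet with", length(object), "transcripts (",
      paste(names(bt), bt, sep = ":", collapse = " "), ")\n")
  if (length(object) > 0L)
    cat("  chromosomes:",
        paste(seqlevels(object@exons), collapse = ", "), "\n")
})

#' Per-cytosine bisulfite methylation calls
#'
#' Stores one record per genomic cytosine with the number of methylated
#' (\code{m}) and unmethylated (\code{u}) base calls observed in aligned
#' bisulfite reads.
#'
#' @slot calls A width-1 \linkS4class{GRanges} with integer metadata
#'   columns \code{m} and \code{u}; positions are unique per
#'   (chromosome, position, strand).
#' @seealso [MethylationCalls()], [readMethylationCalls()],
#'   [geneMethylationLevel()], [tssMethylationProfile()]
#' @export
setClass("MethylationCalls", representation(calls = "GRanges"))

.validMethylationCalls <- function(object) {
  gr <- object@calls
  msg <- NULL
  if (!all(c("m", "u") %in% colnames(mcols(gr))))
    return("calls must have metadata columns 'm' and 'u'")
  if (length(gr) > 0L) {
    if (any(width(gr) != 1L))
      msg <- c(msg, "all call positions must have width 1")
    if (any(gr$m < 0L) || any(gr$u < 0L))
      msg <- c(msg, "m and u counts must be non-negative")
    key <- paste(seqnames(gr), start(gr), strand(gr))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, pos, strand) records")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("MethylationCalls", .validMethylationCalls)

#' Construct a MethylationCalls object
#'
#' @param chrom Character vector of chromosome names, or a width-1
#'   \linkS4class{GRanges} with \code{m}/\code{u} metadata columns (in which
#'   case the other arguments are ignored).
#' @param pos Integer vector of 0-based cytosine positions.
#' @param strand Strand of each cytosine (\code{+}, \code{-} or \code{*}).
#' @param m,u Integer vectors of methylated / unmethylated call counts.
#' @return A \linkS4class{MethylationCalls} object.
#' @examples
#' MethylationCalls("chr1", pos = c(1000L, 1050L), strand = "+",
#'                  m = c(3L, 0L), u = c(1L, 7L))
#' @export
MethylationCalls <- function(chrom, pos = NULL, strand = "+",
                             m = integer(), u = integer()) {
  if (is(chrom, "GRanges")) {
    gr <- chrom
  } else {
    pos <- as.integer(pos)
    gr <- GRanges(chrom, IRanges(start = pos + 1L,
                                 width = rep(1L, length(pos))),
                  strand = if (length(pos)) strand else character())
    gr$m <- as.integer(m)
    gr$u <- as.integer(u)
  }
  gr <- sort(gr, ignore.strand = TRUE)
  new("MethylationCalls", calls = gr)
}

#' @describeIn MethylationCalls Number of cytosine records.
#' @param x,object A \code{MethylationCalls} object.
#' @export
setMethod("length", "MethylationCalls", function(x) length(x@calls))

setMethod("show", "MethylationCalls", function(object) {
  gr <- object@calls
  cat("MethylationCalls with", length(gr), "cytosines\n")
  if (length(gr) > 0L) {
    M <- sum(gr$m) / (sum(gr$m) + sum(gr$u))
    cat(sprintf("  overall level: %.3f (m=%d, u=%d)\n",
                M, sum(gr$m), sum(gr$u)))
  }
})

#' Extract the underlying call GRanges
#' @param x A \code{MethylationCalls} object.
#' @return A width-1 \linkS4class{GRanges} with \code{m} and \code{u}
#'   metadata columns (0-based positions are \code{start(x) - 1}).
#' @export
methCalls <- function(x) {
  stopifnot(is(x, "MethylationCalls"))
  x@calls
}

#' TSS-centred metaprofile
#'
#' A binned summary of a genomic signal over the 10 kb window centred on
#' transcription start sites: 100 bins of 100 bp covering TSS - 5 kb to
#' TSS + 5 kb, ordered 5' to 3' relative to transcription (bin 1 is the
#' most-upstream bin, bin 51 begins at the TSS base).
#'
#' @slot values Numeric vector of exactly 100 per-bin values.
#' @slot kind One of \code{methylation}, \code{binding}, \code{gc},
#'   \code{cpg_oe}.
#' @slot nTranscripts Number of transcripts averaged.
#' @slot binWidth Bin width in bp (100).
#' @slot flank Flank on each side of the TSS in bp (5000).
#' @seealso [tssMethylationProfile()], [tssBindingProfile()],
#'   [gcContentProfile()], [cpgOeProfile()]
#' @export
setClass("MetaProfile",
  representation(values = "numeric", kind = "character",
                 nTranscripts = "integer", binWidth = "integer",
                 flank = "integer"),
  prototype(binWidth = 100L, flank = 5000L))

.validMetaProfile <- function(object) {
  msg <- NULL
  if (length(object@values) != 2L * object@flank / object@binWidth)
    msg <- c(msg, "values must have flank*2/binWidth bins")
  if (!object@kind %in% c("methylation", "binding", "gc", "cpg_oe"))
    msg <- c(msg, "kind must be methylation/binding/gc/cpg_oe")
  if (object@kind == "methylation" &&
      any(object@values < 0 | object@values > 1, na.rm = TRUE))
    msg <- c(msg, "methylation bin values must lie in [0,1]")
  if (object@kind != "methylation" && any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "bin values must be non-negative")
  if (is.null(msg)) TRUE else msg
}
setValidity("MetaProfile", .validMetaProfile)

MetaProfile <- function(values, kind, nTranscripts,
                        binWidth = 100L, flank = 5000L) {
  new("MetaProfile", values = as.numeric(values), kind = kind,
      nTranscripts = as.integer(nTranscripts),
      binWidth = as.integer(binWidth), flank = as.integer(flank))
}

setMethod("show", "MetaProfile", function(object) {
  cat(sprintf(
    "MetaProfile (%s): %d bins of %d bp over TSS +/- %d bp, n = %d\n",
    object@kind, length(object@values), object@binWidth, object@flank,
    object@nTranscripts))
  v <- object@values
  cat(sprintf("  range [%.4g, %.4g], centre bins (50,51): %.4g, %.4g\n",
              min(v), max(v), v[50], v[51]))
})

#' Per-bin values of a MetaProfile
#' @param x A \linkS4class{MetaProfile}.
#' @return Numeric vector of 100 per-bin values, 5' to 3'.
#' @export
profileValues <- function(x) {
  stopifnot(is(x, "MetaProfile"))
  x@values
}

#' Number of transcripts contributing to a MetaProfile
#' @param x A \linkS4class{MetaProfile}.
#' @return Integer count of transcripts averaged.
#' @export
nTranscripts <- function(x) {
  stopifnot(is(x, "MetaProfile"))
  x@nTranscripts
}

#' Bin start offsets of a MetaProfile
#' @param x A \linkS4class{MetaProfile}.
#' @return Integer vector of bin start offsets in bp relative to the TSS
#'   (bin 51 starts at offset 0).
#' @export
profileOffsets <- function(x) {
  stopifnot(is(x, "MetaProfile"))
  seq(-x@flank, x@flank - x@binWidth, by = x@binWidth)
}

#' Filter thresholds of the lincRNA definition cascade
#'
#' Bundles the thresholds of the transcript filters. Boundary semantics
#' follow the wording of the definitions: exon coverage and junction reads
#' are "at least" (>=), transcript length is "more than" (strict >, encoded
#' as \code{minLength = 201} with a >= test), the intergenic gap is "at
#' least" (>=) and the coding-potential score must be strictly less than
#' \code{maxCpcScore}.
#'
#' @slot minExonCoverage Minimum fraction of exonic bases covered by reads
#'   (default 0.8).
#' @slot minJunctionReads Minimum reads supporting every splice junction
#'   (default 3).
#' @slot minExons Minimum exon count (default 2).
#' @slot minLength Minimum exonic transcript length in nt (default 201,
#'   i.e. strictly more than 200).
#' @slot minIntergenicGap Minimum gap in bp to the nearest protein-coding or
#'   housekeeping locus (default 500).
#' @slot maxCpcScore Transcripts pass iff CPC score < this (default -1).
#' @slot hkMaxEvalue,hkMinIdentity A housekeeping BLASTN hit disqualifies a
#'   transcript iff evalue <= \code{hkMaxEvalue} and percent identity >=
#'   \code{hkMinIdentity} (defaults 1e-10 and 80).
#' @export
setClass("FilterConfig",
  representation(minExonCoverage = "numeric", minJunctionReads = "integer",
                 minExons = "integer", minLength = "integer",
                 minIntergenicGap = "integer", maxCpcScore = "numeric",
                 hkMaxEvalue = "numeric", hkMinIdentity = "numeric"))

setValidity("FilterConfig", function(object) {
  msg <- NULL
  if (object@minExonCoverage < 0 || object@minExonCoverage > 1)
    msg <- c(msg, "minExonCoverage must lie in [0,1]")
  for (s in c("minJunctionReads", "minExons", "minLength",
              "minIntergenicGap", "hkMaxEvalue", "hkMinIdentity"))
    if (slot(object, s) < 0)
      msg <- c(msg, paste(s, "must be non-negative"))
  if (is.null(msg)) TRUE else msg
})

#' @describeIn FilterConfig Constructor with the default thresholds.
#' @param minExonCoverage,minJunctionReads,minExons,minLength See slots.
#' @param minIntergenicGap,maxCpcScore,hkMaxEvalue,hkMinIdentity See slots.
#' @return A \code{FilterConfig}.
#' @examples
#' FilterConfig()
#' FilterConfig(minIntergenicGap = 1000L)
#' @export
FilterConfig <- function(minExonCoverage = 0.8, minJunctionReads = 3L,
                         minExons = 2L, minLength = 201L,
                         minIntergenicGap = 500L, maxCpcScore = -1,
                         hkMaxEvalue = 1e-10, hkMinIdentity = 80) {
  new("FilterConfig",
      minExonCoverage = minExonCoverage,
      minJunctionReads = as.integer(minJunctionReads),
      minExons = as.integer(minExons),
      minLength = as.integer(minLength),
      minIntergenicGap = as.integer(minIntergenicGap),
      maxCpcScore = maxCpcScore,
      hkMaxEvalue = hkMaxEvalue,
      hkMinIdentity = hkMinIdentity)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:\n")
  cat(sprintf("  exon coverage >= %.2f; junction reads >= %d (per intron)\n",
              object@minExonCoverage, object@minJunctionReads))
  cat(sprintf("  exons >= %d; length >= %d nt; intergenic gap >= %d bp\n",
              object@minExons, object@minLength, object@minIntergenicGap))
  cat(sprintf("  CPC score < %g; housekeeping hit: evalue <= %g & id >= %g\n",
              object@maxCpcScore, object@hkMaxEvalue, object@hkMinIdentity))
})
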