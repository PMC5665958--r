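#' Exonic spans of transcripts
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @return A \linkS4class{GRanges} with one range per transcript covering
#'   first exon start to last exon end, carrying \code{transcript_id},
#'   \code{gene_id} and \code{biotype}.
#' @export
txSpans <- function(x) {
  stopifnot(is(x, "TranscriptSet"))
  if (length(x) == 0L)
    return(GRanges(transcript_id = character(), gene_id = character(),
                   biotype = character()))
  sp <- unlist(range(x@exons), use.names = FALSE)
  sp$transcript_id <- x@txData$transcript_id
  sp$gene_id <- x@txData$gene_id
  sp$biotype <- x@txData$biotype
  names(sp) <- x@txData$transcript_id
  sp
}

#' Exonic lengths of transcripts
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @return Named integer vector: sum of exon widths per transcript.
#' @export
txLengths <- function(x) {
  stopifnot(is(x, "TranscriptSet"))
  setNames(as.integer(sum(width(x@exons))), names(x))
}

#' Exon counts of transcripts
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @return Named integer vector of exon counts.
#' @export
exonCounts <- function(x) {
  stopifnot(is(x, "TranscriptSet"))
  setNames(elementNROWS(x@exons), names(x))
}

#' Intron lengths of transcripts
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @return An \linkS4class{IntegerList}, one element per transcript, with
#'   the gap between consecutive exons (empty for single-exon models).
#' @export
intronLengths <- function(x) {
  stopifnot(is(x, "TranscriptSet"))
  setNames(IntegerList(lapply(seq_along(x@exons), function(i) {
    e <- x@exons[[i]]
    if (length(e) < 2L) integer() else
      start(e)[-1L] - end(e)[-length(e)] - 1L
  })), names(x))
}

#' Transcription start sites
#'
#' The TSS is the first transcribed base: the span start for plus-strand
#' transcripts, the span end for minus-strand transcripts.
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @return A width-1 \linkS4class{GRanges} of TSS bases, one per
#'   transcript, named by transcript id. (The 0-based TSS position is
#'   \code{start - 1}.)
#' @export
tssOf <- function(x) {
  stopifnot(is(x, "TranscriptSet"))
  sp <- txSpans(x)
  st <- as.character(strand(sp))
  if (any(st == "*"))
    stop("TSS is undefined for unstranded transcripts: ",
         paste(head(names(sp)[st == "*"]), collapse = ", "))
  pos <- ifelse(st == "+", start(sp), end(sp))
  GRanges(seqnames(sp), IRanges(pos, width = 1L), strand = st,
          transcript_id = sp$transcript_id)
}

#' Gene loci of a TranscriptSet
#'
#' One range per gene id, covering the union span of the gene's
#' transcripts. All transcripts of a gene must share chromosome and strand.
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @return A \linkS4class{GRanges} with \code{gene_id}, \code{biotype} and
#'   \code{n_transcripts} columns, sorted by (chrom, start, gene_id).
#' @export
lociOf <- function(x) {
  stopifnot(is(x, "TranscriptSet"))
  if (length(x) == 0L)
    return(GRanges(gene_id = character(), biotype = character(),
                   n_transcripts = integer()))
  sp <- txSpans(x)
  f <- factor(sp$gene_id, levels = unique(sp$gene_id))
  byGene <- split(sp, f)
  sameChrom <- all(elementNROWS(unique(seqnames(byGene))) == 1L)
  sameStrand <- all(elementNROWS(unique(strand(byGene))) == 1L)
  if (!sameChrom || !sameStrand)
    stop("all transcripts of a gene must share chromosome and strand")
  span <- unlist(range(byGene), use.names = FALSE)
  span$gene_id <- levels(f)
  bt <- vapply(split(sp$biotype, f), function(b) b[[1]], character(1))
  span$biotype <- unname(bt)
  span$n_transcripts <- unname(elementNROWS(byGene))
  o <- order(as.character(seqnames(span)), start(span), span$gene_id)
  span[o]
}

#' Gap between genomic intervals
#'
#' Number of bases strictly between two intervals on the same chromosome:
#' 0 for directly adjacent intervals, \code{-1} when the intervals overlap
#' (the distinct overlap flag). Strand is ignored.
#'
#' @param a,b \linkS4class{GRanges} of equal length (or length 1,
#'   recycled), pairwise on the same chromosome.
#' @return Integer vector of gaps, \code{-1} flagging overlap.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(601, 700))
#' gapDistance(a, b)  # 500
#' @export
gapDistance <- function(a, b) {
  if (length(a) == 1L) a <- rep(a, length(b))
  if (length(b) == 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  if (any(as.character(seqnames(a)) != as.character(seqnames(b))))
    stop("gapDistance requires intervals on the same chromosome")
  d <- distance(a, b, ignore.strand = TRUE)
  ov <- start(a) <= end(b) & start(b) <= end(a)
  d[ov] <- -1L
  as.integer(d)
}

#' Cluster transcripts into loci by exonic overlap
#'
#' Single-linkage clustering: two transcripts belong to the same locus iff
#' they are connected by a chain of transcript pairs sharing at least one
#' exonic base on the same strand of the same chromosome (transcripts that
#' overlap only across introns are not merged). Locus ids are assigned
#' deterministically by leftmost span coordinate (chrom, start, transcript
#' id).
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @param prefix Prefix for the generated locus ids.
#' @return A \linkS4class{TranscriptSet} identical to \code{x} except that
#'   \code{gene_id} holds the assigned locus id; use [lociOf()] for the
#'   locus spans.
#' @export
clusterTranscriptsIntoLoci <- function(x, prefix = "LOC") {
  stopifnot(is(x, "TranscriptSet"))
  n <- length(x)
  if (n == 0L) return(x)
  hits <- findOverlaps(x@exons, x@exons)   # strand-aware, >=1 bp exon overlap
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  qh <- queryHits(hits); sh <- subjectHits(hits)
  for (k in seq_along(qh)) {
    ri <- findRoot(qh[k]); rj <- findRoot(sh[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  comp <- vapply(seq_len(n), findRoot, integer(1))
  sp <- txSpans(x)
  first <- tapply(seq_len(n), comp, function(ix) {
    ix[order(as.character(seqnames(sp))[ix], start(sp)[ix], names(x)[ix])][1]
  })
  o <- order(as.character(seqnames(sp))[first], start(sp)[first],
             names(x)[first])
  locusId <- setNames(sprintf("%s%06d", prefix, seq_along(o)),
                      names(first)[o])
  td <- x@txData
  td$gene_id <- unname(locusId[as.character(comp)])
  initialize(x, txData = td)
}
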