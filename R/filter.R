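#' @importFrom stats setNames wilcox.test ks.test pnorm rbinom
#'   rgeom rlnorm rnorm rpois runif rbeta
NULL

.VERDICTS <- c("pass", "fail", "not_evaluated")

#' Exon-coverage filter
#'
#' A transcript passes when the fraction of its exonic bases covered by
#' RNA-seq reads is at least \code{minExonCoverage} (boundary inclusive:
#' coverage 0.80 passes at the default threshold).
#'
#' @param coverage Numeric vector of exon-coverage fractions in [0,1];
#'   \code{NA} yields \code{not_evaluated}.
#' @param config A \linkS4class{FilterConfig}.
#' @return Character vector of verdicts (\code{pass}, \code{fail},
#'   \code{not_evaluated}).
#' @export
filterExonCoverage <- function(coverage, config = FilterConfig()) {
  ok <- !is.na(coverage)
  if (any(coverage[ok] < 0 | coverage[ok] > 1))
    stop("exon coverage fractions must lie in [0,1]")
  out <- rep("not_evaluated", length(coverage))
  out[ok] <- ifelse(coverage[ok] >= config@minExonCoverage, "pass", "fail")
  out
}

#' Splice-junction support filter
#'
#' A transcript passes when every one of its introns is supported by at
#' least \code{minJunctionReads} reads (3 by default; per-intron, the
#' stricter reading of junction support). Single-exon transcripts pass
#' vacuously and are rejected by the structure filter instead.
#'
#' @param junctionReads An \linkS4class{IntegerList} (or list of integer
#'   vectors), one element per transcript with one count per intron;
#'   \code{NULL} elements yield \code{not_evaluated}.
#' @param config A \linkS4class{FilterConfig}.
#' @param nExons Optional integer vector of exon counts; when supplied,
#'   count lists whose length differs from \code{nExons - 1} raise an
#'   error.
#' @return Character vector of verdicts.
#' @export
filterJunctionSupport <- function(junctionReads, config = FilterConfig(),
                                  nExons = NULL) {
  jr <- as.list(junctionReads)
  if (!is.null(nExons)) {
    stopifnot(length(nExons) == length(jr))
    len <- lengths(jr)
    evaluated <- !vapply(jr, is.null, logical(1))
    bad <- evaluated & len != pmax(nExons - 1L, 0L)
    if (any(bad))
      stop("junction count list length must equal exon count - 1 ",
           "(transcripts: ", paste(head(which(bad)), collapse = ", "), ")")
  }
  vapply(jr, function(counts) {
    if (is.null(counts)) return("not_evaluated")
    if (length(counts) == 0L) return("pass")
    if (anyNA(counts)) return("not_evaluated")
    if (all(counts >= config@minJunctionReads)) "pass" else "fail"
  }, character(1))
}

#' Transcript-structure filter
#'
#' A transcript passes when it is multi-exonic (at least
#' \code{minExons} exons) and its exonic length exceeds 200 nt
#' (\code{>= minLength} with the default \code{minLength = 201}).
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @param config A \linkS4class{FilterConfig}.
#' @return Character vector of verdicts, one per transcript.
#' @export
filterStructure <- function(x, config = FilterConfig()) {
  ifelse(exonCounts(x) >= config@minExons &
           txLengths(x) >= config@minLength, "pass", "fail")
}

#' Intergenic-position filter
#'
#' A transcript passes when its span neither overlaps nor lies within
#' \code{minIntergenicGap} bases of any protein-coding or housekeeping
#' locus span, regardless of strand (gap 500 passes at the default;
#' 499 or overlap fails).
#'
#' @param x A \linkS4class{TranscriptSet} of candidates.
#' @param annotation A \linkS4class{GRanges} of annotated loci (or a
#'   \linkS4class{TranscriptSet}, converted via [lociOf()]) with a
#'   \code{biotype} column (e.g. from [lociOf()]); only \code{coding} and
#'   \code{housekeeping} loci are considered.
#' @param config A \linkS4class{FilterConfig}.
#' @return Character vector of verdicts, one per transcript.
#' @export
classifyIntergenic <- function(x, annotation, config = FilterConfig()) {
  if (is(annotation, "TranscriptSet")) annotation <- lociOf(annotation)
  stopifnot(is(x, "TranscriptSet"), is(annotation, "GRanges"))
  ann <- annotation
  if (!is.null(ann$biotype))
    ann <- ann[ann$biotype %in% c("coding", "housekeeping")]
  sp <- txSpans(x)
  out <- rep("pass", length(sp))
  if (length(ann) == 0L || length(sp) == 0L)
    return(out)
  ov <- countOverlaps(sp, ann, ignore.strand = TRUE) > 0L
  out[ov] <- "fail"
  hit <- distanceToNearest(sp, ann, ignore.strand = TRUE)
  near <- queryHits(hit)[mcols(hit)$distance < config@minIntergenicGap]
  out[near] <- "fail"
  out
}

#' Coding-potential filter
#'
#' A transcript passes when its CPC-style coding-potential score is
#' strictly less than \code{maxCpcScore} (default -1: a score of exactly
#' -1.0 fails).
#'
#' @param cpcScore Numeric vector of scores; \code{NA} yields
#'   \code{not_evaluated}.
#' @param config A \linkS4class{FilterConfig}.
#' @return Character vector of verdicts.
#' @export
filterCodingPotential <- function(cpcScore, config = FilterConfig()) {
  out <- rep("not_evaluated", length(cpcScore))
  ok <- !is.na(cpcScore)
  out[ok] <- ifelse(cpcScore[ok] < config@maxCpcScore, "pass", "fail")
  out
}

#' Housekeeping-RNA exclusion filter
#'
#' A transcript fails iff it has at least one BLASTN hit against the
#' housekeeping-RNA databases with evalue <= \code{hkMaxEvalue} and percent
#' identity >= \code{hkMinIdentity}. Transcripts with no hits pass.
#'
#' @param transcriptIds Character vector of transcript ids to evaluate.
#' @param hits data.frame of hits with columns \code{transcript_id},
#'   \code{evalue}, \code{percent_identity} (possibly zero rows).
#' @param config A \linkS4class{FilterConfig}.
#' @return Character vector of verdicts, one per transcript id.
#' @export
filterHousekeeping <- function(transcriptIds, hits,
                               config = FilterConfig()) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(rep("pass", length(transcriptIds)))
  sig <- hits$evalue <= config@hkMaxEvalue &
    hits$percent_identity >= config@hkMinIdentity
  bad <- unique(hits$transcript_id[sig])
  ifelse(transcriptIds %in% bad, "fail", "pass")
}

.FILTER_ORDER <- c("structure", "exon_coverage", "junction_support",
                   "intergenic", "coding_potential", "housekeeping")

#' Run the full lincRNA definition cascade
#'
#' Applies the six transcript filters in a fixed order (structure, exon
#' coverage, junction support, intergenic position, coding potential,
#' housekeeping exclusion), short-circuiting on the first failure but
#' recording every evaluated verdict in an audit table. Transcripts whose
#' evidence source is \code{annotation} (RefSeq/UniGene-style) skip the two
#' RNA-seq-only filters (exon coverage and junction support). Survivors are
#' clustered into loci by strand-aware exonic overlap.
#'
#' @param x A \linkS4class{TranscriptSet} of candidate transcripts.
#' @param evidence A \linkS4class{DataFrame} as returned by
#'   [readEvidence()]; every \code{rnaseq} transcript must have a row.
#' @param hkHits data.frame of housekeeping BLASTN hits (see
#'   [filterHousekeeping()]); \code{NULL} for none.
#' @param annotation A \linkS4class{GRanges} of annotated loci (or a
#'   \linkS4class{TranscriptSet}, converted via [lociOf()]) with a
#'   \code{biotype} column.
#' @param config A \linkS4class{FilterConfig}.
#' @param order Character vector permuting \code{.FILTER_ORDER}; the
#'   surviving set is invariant to the order (the filters are independent
#'   predicates), only the audit's not-evaluated pattern changes.
#' @param shortCircuit Evaluate filters after the first failure? Default
#'   \code{TRUE} (later verdicts are recorded as \code{not_evaluated}).
#' @return A list with elements \code{lincRNA} (a
#'   \linkS4class{TranscriptSet} of survivors with locus-assigned gene ids
#'   and biotype \code{lincRNA}), \code{loci} (a \linkS4class{GRanges} from
#'   [lociOf()]), \code{audit} (data.frame with one verdict column per
#'   filter and \code{final_class}), and \code{funnel} (named integer
#'   vector of survivor counts after each stage).
#' @examples
#' ## see the package vignette for an end-to-end example on simulated data
#' @export
runFilterCascade <- function(x, evidence, hkHits = NULL, annotation,
                             config = FilterConfig(),
                             order = .FILTER_ORDER, shortCircuit = TRUE) {
  stopifnot(is(x, "TranscriptSet"),
            setequal(order, .FILTER_ORDER))
  n <- length(x)
  ids <- names(x)
  ei <- match(ids, evidence$transcript_id)
  src <- ifelse(is.na(ei), "annotation", as.character(evidence$source[ei]))
  missingEv <- is.na(ei) & x@txData$source == "rnaseq"
  if (any(missingEv))
    stop("rnaseq transcripts lack evidence rows: ",
         paste(head(ids[missingEv]), collapse = ", "))

  cov <- rep(NA_real_, n)
  cpc <- rep(NA_real_, n)
  jr <- vector("list", n)
  has <- !is.na(ei)
  cov[has] <- evidence$exon_coverage[ei[has]]
  cpc[has] <- evidence$cpc_score[ei[has]]
  jr[has] <- as.list(evidence$junction_reads[ei[has]])

  evaluators <- list(
    structure = function(idx) filterStructure(x[idx], config),
    exon_coverage = function(idx) filterExonCoverage(cov[idx], config),
    junction_support = function(idx)
      filterJunctionSupport(jr[idx], config, nExons = exonCounts(x[idx])),
    intergenic = function(idx) classifyIntergenic(x[idx], annotation, config),
    coding_potential = function(idx) filterCodingPotential(cpc[idx], config),
    housekeeping = function(idx) filterHousekeeping(ids[idx], hkHits, config))

  verdicts <- matrix("not_evaluated", n, length(.FILTER_ORDER),
                     dimnames = list(ids, .FILTER_ORDER))
  alive <- rep(TRUE, n)
  funnel <- integer(0)
  annotationDerived <- src == "annotation"
  for (f in order) {
    idx <- if (shortCircuit) which(alive) else seq_len(n)
    if (f %in% c("exon_coverage", "junction_support")) {
      idx <- idx[!annotationDerived[idx]]   # annotation path skips these
    }
    if (length(idx) > 0L)
      verdicts[idx, f] <- evaluators[[f]](idx)
    alive <- alive & verdicts[, f] != "fail"
    funnel[f] <- sum(alive)
  }
  finalClass <- ifelse(
    alive & apply(verdicts, 1L, function(v)
      all(v[v != "not_evaluated"] == "pass")),
    "lincRNA", "rejected")

  surv <- x[which(finalClass == "lincRNA")]
  surv@txData$biotype <- rep("lincRNA", length(surv))
  surv <- clusterTranscriptsIntoLoci(surv)
  audit <- data.frame(transcript_id = ids, verdicts,
                      final_class = finalClass, row.names = NULL,
                      check.names = FALSE)
  list(lincRNA = surv, loci = lociOf(surv), audit = audit,
       funnel = funnel[order])
}

#' Interval statistics of lincRNA and coding loci
#'
#' Computes (a) the gap from each lincRNA locus to its nearest coding locus,
#' (b) the gap from each coding locus to its nearest other coding locus,
#' and (c) all intron lengths of coding transcripts; reports the median of
#' each and two-sided rank-sum (Mann-Whitney) p-values comparing (a) with
#' (b) and (a) with (c).
#'
#' @param lincLoci \linkS4class{GRanges} of lincRNA loci (>= 2).
#' @param codingLoci \linkS4class{GRanges} of coding loci (>= 2).
#' @param codingTx Optional \linkS4class{TranscriptSet} of coding
#'   transcripts for the intron-length sample; when absent, the intron
#'   comparison is skipped.
#' @return A list with vectors \code{linc_gaps}, \code{coding_gaps},
#'   \code{intron_lengths}, their medians (\code{median_linc_gap},
#'   \code{median_coding_gap}, \code{median_intron_length}) and p-values
#'   \code{p_gap} (a vs b), \code{p_intron} (a vs c).
#' @export
intervalStatistics <- function(lincLoci, codingLoci, codingTx = NULL) {
  if (length(lincLoci) < 2L || length(codingLoci) < 2L)
    stop("need at least two loci per set")
  nearGap <- function(query, subject) {
    hit <- distanceToNearest(query, subject, ignore.strand = TRUE,
                             select = "all")
    as.numeric(tapply(mcols(hit)$distance, queryHits(hit), min))
  }
  ## nearest-other gap within one set: distanceToNearest(x, x) would
  ## return every range as its own (distance-0) nearest hit, so combine
  ## strictly-upstream/-downstream neighbours with overlaps of others
  nearOtherGap <- function(x) {
    x <- unstrand(x)
    d <- rep(NA_real_, length(x))
    ov <- findOverlaps(x, x, ignore.strand = TRUE)
    d[unique(queryHits(ov)[queryHits(ov) != subjectHits(ov)])] <- 0
    for (fun in c(precede, follow)) {
      nb <- fun(x, x, ignore.strand = TRUE)
      ok <- !is.na(nb)
      dd <- rep(NA_real_, length(x))
      dd[ok] <- distance(x[ok], x[nb[ok]], ignore.strand = TRUE)
      d <- pmin(d, dd, na.rm = TRUE)
    }
    d[!is.na(d)]
  }
  a <- nearGap(lincLoci, codingLoci)
  b <- nearOtherGap(codingLoci)
  res <- list(linc_gaps = a, coding_gaps = b,
              median_linc_gap = median(a), median_coding_gap = median(b),
              p_gap = wilcox.test(a, b, exact = FALSE)$p.value)
  if (!is.null(codingTx)) {
    keep <- codingTx@txData$biotype == "coding"
    il <- as.numeric(unlist(intronLengths(codingTx[which(keep)])))
    res$intron_lengths <- il
    res$median_intron_length <- if (length(il)) median(il) else NA_real_
    res$p_intron <- if (length(il) >= 2L) wilcox.test(a, il, exact = FALSE)$p.value
                    else NA_real_
  }
  res
}

#' Per-transcript exonic length distribution
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @return data.frame with \code{transcript_id}, \code{biotype} and
#'   \code{length} (exonic nt).
#' @export
transcriptLengthDistribution <- function(x) {
  stopifnot(is(x, "TranscriptSet"))
  if (length(x) > 0L && any(elementNROWS(x@exons) == 0L))
    stop("transcripts with no exons are invalid")
  data.frame(transcript_id = names(x),
             biotype = x@txData$biotype,
             length = unname(txLengths(x)),
             row.names = NULL)
}
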