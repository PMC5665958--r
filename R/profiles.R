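#' @importFrom Biostrings letterFrequency dinucleotideFrequency
#'   reverseComplement subseq DNAString
NULL

## 0-based half-open windows of flank bp either side of each TSS, plus the
## per-call bin arithmetic. Plus strand: [tss-flank, tss+flank), bin i =
## [tss-flank+(i-1)w, tss-flank+iw). Minus strand: the strand mirror
## [tss-flank+1, tss+flank+1) with bins counted right-to-left so that bin 1
## is always the most 5'/upstream bin and bin flank/w + 1 starts at the TSS.
.tssWindows <- function(x, flank = 5000L) {
  tss <- tssOf(x)
  pos0 <- start(tss) - 1L
  st <- as.character(strand(tss))
  winStart0 <- ifelse(st == "+", pos0 - flank, pos0 - flank + 1L)
  data.frame(transcript_id = tss$transcript_id,
             chrom = as.character(seqnames(tss)),
             tss0 = pos0, strand = st,
             winStart0 = winStart0, winEnd0 = winStart0 + 2L * flank)
}

.binIndex <- function(pos0, tss0, strand, flank = 5000L, binWidth = 100L) {
  ifelse(strand == "+",
         (pos0 - (tss0 - flank)) %/% binWidth + 1L,
         ((tss0 + flank) - pos0) %/% binWidth + 1L)
}

#' Gene-level methylation
#'
#' For each locus, sums methylated (m) and unmethylated (u) base calls over
#' all cytosine records (both strands) within the locus span and computes
#' the methylation level M = m / (m + u), with M = 0 when m = 0 (which
#' also covers loci with no calls).
#'
#' @param loci A \linkS4class{GRanges} of gene loci with \code{gene_id}
#'   (e.g. from [lociOf()]).
#' @param calls A \linkS4class{MethylationCalls} object.
#' @return data.frame with \code{gene_id}, \code{m}, \code{u},
#'   \code{level}.
#' @examples
#' calls <- MethylationCalls("chr1", pos = c(10L, 20L), m = c(0L, 0L),
#'                           u = c(3L, 4L))
#' gene <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
#'                                gene_id = "g1")
#' geneMethylationLevel(gene, calls)$level  # 0
#' @export
geneMethylationLevel <- function(loci, calls) {
  stopifnot(is(loci, "GRanges"), is(calls, "MethylationCalls"))
  gr <- calls@calls
  hits <- findOverlaps(gr, loci, ignore.strand = TRUE)
  m <- u <- integer(length(loci))
  if (length(hits) > 0L) {
    ms <- tapply(gr$m[queryHits(hits)], subjectHits(hits), sum)
    us <- tapply(gr$u[queryHits(hits)], subjectHits(hits), sum)
    ix <- as.integer(names(ms))
    m[ix] <- as.integer(ms); u[ix] <- as.integer(us)
  }
  level <- ifelse(m == 0, 0, m / (m + u))
  data.frame(gene_id = loci$gene_id, m = m, u = u, level = level,
             row.names = NULL)
}

#' Compare two methylation-level distributions
#'
#' Two-sample, two-sided Kolmogorov-Smirnov test of lincRNA vs coding
#' gene-level methylation.
#'
#' @param lincLevels,codingLevels Numeric vectors of per-gene methylation
#'   levels (>= 2 values each).
#' @return list with \code{statistic} (D) and \code{p.value}.
#' @export
compareMethylationDistributions <- function(lincLevels, codingLevels) {
  if (length(lincLevels) < 2L || length(codingLevels) < 2L)
    stop("need at least two values per sample")
  kt <- suppressWarnings(ks.test(lincLevels, codingLevels,
                                 alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' TSS-centred methylation metaprofile
#'
#' The 10 kb window around each transcript's TSS is split into 100 bins of
#' 100 bp oriented 5' to 3' (minus-strand windows are mirrored). Per
#' transcript t and bin i, M_ti = m_ti / (m_ti + u_ti) from the summed
#' calls in the bin, with M_ti = 0 when m_ti = 0 (which also covers bins
#' without cytosines); the profile value V_i is the mean of M_ti over all
#' n transcripts. The alternative mode \code{average = "covered"} averages
#' each bin over the transcripts with at least one call in that bin.
#'
#' @param x A stranded \linkS4class{TranscriptSet} (non-empty).
#' @param calls A \linkS4class{MethylationCalls} object.
#' @param flank,binWidth Window geometry (defaults 5000 and 100 bp).
#' @param average \code{"all"} (default; empty bins contribute 0) or
#'   \code{"covered"}.
#' @return A \linkS4class{MetaProfile} of kind \code{methylation}.
#' @export
tssMethylationProfile <- function(x, calls, flank = 5000L, binWidth = 100L,
                                  average = c("all", "covered")) {
  average <- match.arg(average)
  stopifnot(is(x, "TranscriptSet"), is(calls, "MethylationCalls"))
  if (length(x) == 0L) stop("empty transcript set")
  nbin <- as.integer(2L * flank / binWidth)
  w <- .tssWindows(x, flank)
  wgr <- GRanges(w$chrom, IRanges(w$winStart0 + 1L, w$winEnd0))
  gr <- calls@calls
  hits <- findOverlaps(gr, wgr, ignore.strand = TRUE)
  n <- length(x)
  M <- matrix(0, n, nbin)
  covered <- matrix(FALSE, n, nbin)
  if (length(hits) > 0L) {
    t <- subjectHits(hits)
    pos0 <- start(gr)[queryHits(hits)] - 1L
    bin <- .binIndex(pos0, w$tss0[t], w$strand[t], flank, binWidth)
    key <- (bin - 1L) * n + t    # column-major linear index into M
    ms <- tapply(gr$m[queryHits(hits)], key, sum)
    us <- tapply(gr$u[queryHits(hits)], key, sum)
    k <- as.integer(names(ms))
    mv <- as.numeric(ms); uv <- as.numeric(us)
    M[k] <- ifelse(mv == 0, 0, mv / (mv + uv))
    covered[k] <- TRUE
  }
  V <- if (average == "all") colMeans(M)
       else ifelse(colSums(covered) > 0, colSums(M) / colSums(covered), 0)
  MetaProfile(V, "methylation", n, binWidth, flank)
}

#' TSS-centred binding-intensity metaprofile
#'
#' Per transcript t and 100-bp sub-region i, the binding intensity I_ti is
#' the mean per-base read depth over the sub-region's bases (positions
#' absent from the track, including off-chromosome positions, count depth
#' 0); the profile value B_i is the mean of I_ti over transcripts.
#' Minus-strand windows are mirrored as in [tssMethylationProfile()].
#'
#' @param x A stranded \linkS4class{TranscriptSet} (non-empty).
#' @param track An \linkS4class{RleList} of per-base depths (from
#'   [readCoverageBedGraph()] or \code{GenomicRanges::coverage}).
#' @param flank,binWidth Window geometry (defaults 5000 and 100 bp).
#' @return A \linkS4class{MetaProfile} of kind \code{binding}.
#' @export
tssBindingProfile <- function(x, track, flank = 5000L, binWidth = 100L) {
  stopifnot(is(x, "TranscriptSet"))
  if (length(x) == 0L) stop("empty transcript set")
  nbin <- as.integer(2L * flank / binWidth)
  w <- .tssWindows(x, flank)
  acc <- matrix(0, length(x), nbin)
  for (i in seq_len(nrow(w))) {
    d <- trackDepth(track, w$chrom[i], w$winStart0[i], w$winEnd0[i])
    if (w$strand[i] == "-") d <- rev(d)
    acc[i, ] <- colMeans(matrix(d, nrow = binWidth))
  }
  MetaProfile(colMeans(acc), "binding", length(x), binWidth, flank)
}

.windowSeqs <- function(x, genome, flank, binWidth) {
  w <- .tssWindows(x, flank)
  L <- 2L * flank
  seqs <- character(nrow(w))
  for (i in seq_len(nrow(w))) {
    chrSeq <- genome[[w$chrom[i]]]
    lo <- w$winStart0[i] + 1L; hi <- w$winEnd0[i]
    clampLo <- max(lo, 1L); clampHi <- min(hi, length(chrSeq))
    body <- if (clampHi >= clampLo)
      as.character(subseq(chrSeq, clampLo, clampHi)) else ""
    padL <- strrep("N", max(0L, clampLo - lo))
    padR <- strrep("N", max(0L, hi - clampHi))
    s <- paste0(padL, body, padR)
    if (w$strand[i] == "-")
      s <- as.character(reverseComplement(DNAString(s)))
    seqs[i] <- s
  }
  ## split each window into binWidth-sized sub-windows
  starts <- seq(1L, L, by = binWidth)
  DNAStringSet(unlist(lapply(seqs, function(s)
    substring(s, starts, starts + binWidth - 1L)), use.names = FALSE))
}

#' TSS-centred GC-content metaprofile
#'
#' GC content (#G + #C) / (#A + #C + #G + #T) in consecutive 100-bp
#' windows over TSS +/- 5 kb, averaged per bin across transcripts. N bases
#' are excluded from numerator and denominator; windows that are entirely N
#' (including regions off the chromosome end) are excluded from that bin's
#' mean.
#'
#' @param x A stranded \linkS4class{TranscriptSet} (non-empty).
#' @param genome A \linkS4class{DNAStringSet} named by chromosome.
#' @param flank,binWidth Window geometry (defaults 5000 and 100 bp;
#'   windows are non-overlapping, step = width).
#' @return A \linkS4class{MetaProfile} of kind \code{gc}.
#' @export
gcContentProfile <- function(x, genome, flank = 5000L, binWidth = 100L) {
  stopifnot(is(x, "TranscriptSet"))
  if (length(x) == 0L) stop("empty transcript set")
  nbin <- as.integer(2L * flank / binWidth)
  subs <- .windowSeqs(x, genome, flank, binWidth)
  freq <- letterFrequency(subs, c("A", "C", "G", "T"))
  gc <- freq[, "G"] + freq[, "C"]
  tot <- rowSums(freq)
  val <- ifelse(tot > 0, gc / tot, NA_real_)
  vm <- matrix(val, ncol = nbin, byrow = TRUE)
  V <- apply(vm, 2L, function(col)
    if (all(is.na(col))) 0 else mean(col, na.rm = TRUE))
  MetaProfile(V, "gc", length(x), binWidth, flank)
}

#' TSS-centred CpG observed/expected metaprofile
#'
#' Per 100-bp window, o/e = (#CpG dinucleotides * L) / (#C * #G) where L
#' is the number of non-N bases in the window; defined 0 when #C or #G is
#' 0. Averaged per bin across transcripts; all-N windows are excluded from
#' the bin mean.
#'
#' @inheritParams gcContentProfile
#' @return A \linkS4class{MetaProfile} of kind \code{cpg_oe}.
#' @examples
#' ## "CGCG": 2 CpG, 2 C, 2 G, L = 4 -> o/e = 2
#' @export
cpgOeProfile <- function(x, genome, flank = 5000L, binWidth = 100L) {
  stopifnot(is(x, "TranscriptSet"))
  if (length(x) == 0L) stop("empty transcript set")
  nbin <- as.integer(2L * flank / binWidth)
  subs <- .windowSeqs(x, genome, flank, binWidth)
  freq <- letterFrequency(subs, c("A", "C", "G", "T"))
  cpg <- dinucleotideFrequency(subs)[, "CG"]
  L <- rowSums(freq)
  cg <- freq[, "C"] * freq[, "G"]
  val <- ifelse(L == 0, NA_real_, ifelse(cg == 0, 0, cpg * L / cg))
  vm <- matrix(val, ncol = nbin, byrow = TRUE)
  V <- apply(vm, 2L, function(col)
    if (all(is.na(col))) 0 else mean(col, na.rm = TRUE))
  MetaProfile(V, "cpg_oe", length(x), binWidth, flank)
}
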