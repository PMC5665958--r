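#' Overlap DMRs with gene loci
#'
#' Reports every (gene locus, DMR) pair with at least 1 bp of overlap
#' between the DMR interval and the locus span; strand is ignored.
#'
#' @param dmrs An unstranded \linkS4class{GRanges} of DMRs with a
#'   \code{dmr_id} column (one is generated when absent).
#' @param loci A \linkS4class{GRanges} of gene loci with \code{gene_id}.
#' @return data.frame with \code{gene_id}, \code{dmr_id} and
#'   \code{overlap_bp}, ordered by (gene, DMR).
#' @export
overlapDmrsWithGenes <- function(dmrs, loci) {
  stopifnot(is(dmrs, "GRanges"), is(loci, "GRanges"))
  if (is.null(dmrs$dmr_id))
    dmrs$dmr_id <- sprintf("dmr%04d", seq_along(dmrs))
  hits <- findOverlaps(loci, dmrs, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(gene_id = character(), dmr_id = character(),
                      overlap_bp = integer()))
  ov <- width(pintersect(loci[queryHits(hits)], dmrs[subjectHits(hits)],
                         ignore.strand = TRUE))
  out <- data.frame(gene_id = loci$gene_id[queryHits(hits)],
                    dmr_id = dmrs$dmr_id[subjectHits(hits)],
                    overlap_bp = as.integer(ov))
  out[order(out$gene_id, out$dmr_id), , drop = FALSE]
}

.poolCalls <- function(callSets) {
  if (is(callSets, "MethylationCalls")) callSets <- list(callSets)
  grs <- lapply(callSets, function(cs) {
    stopifnot(is(cs, "MethylationCalls"))
    cs@calls
  })
  all <- do.call(c, lapply(grs, function(g) {
    strand(g) <- "*"; g
  }))
  key <- paste(seqnames(all), start(all))
  m <- tapply(all$m, key, sum)
  u <- tapply(all$u, key, sum)
  first <- !duplicated(key)
  gr <- granges(all[first])
  ord <- key[first]
  gr$m <- as.integer(m[ord]); gr$u <- as.integer(u[ord])
  sort(gr, ignore.strand = TRUE)
}

#' Naive differential-methylation caller
#'
#' A deliberately simple two-group DMR caller (a documented stand-in for
#' beta-binomial dispersion-shrinkage callers such as DSS, whose model is
#' out of scope here; externally produced DMR sets can be fed to
#' [overlapDmrsWithGenes()] via [readDmrBed()]). Replicate call sets are
#' pooled within each group; at every cytosine position covered in both
#' groups a two-sided two-proportion z-test (pooled variance) is computed;
#' significant CpGs (p < \code{pThreshold}) with a consistent sign of the
#' methylation difference are merged into regions when consecutive
#' significant CpGs are at most \code{mergeGap} bp apart; regions are kept
#' when they span at least \code{minLen} bp and contain at least
#' \code{minCpg} significant CpGs (the documented region defaults of DSS
#' callDMR).
#'
#' @param group1,group2 A \linkS4class{MethylationCalls} object or a list
#'   of them (replicates).
#' @param pThreshold Per-CpG significance threshold (default 0.01).
#' @param mergeGap Maximum distance between consecutive significant CpGs
#'   within one region (default 100 bp).
#' @param minLen Minimum region span in bp (default 50).
#' @param minCpg Minimum number of significant CpGs per region (default 3).
#' @return An unstranded \linkS4class{GRanges} of DMRs with columns
#'   \code{dmr_id}, \code{n_cpg}, \code{mean_level_group1},
#'   \code{mean_level_group2} and \code{score} (summed z statistics);
#'   empty (with a warning) when the groups share no positions.
#' @export
callDmrsNaive <- function(group1, group2, pThreshold = 0.01,
                          mergeGap = 100L, minLen = 50L, minCpg = 3L) {
  g1 <- .poolCalls(group1)
  g2 <- .poolCalls(group2)
  k1 <- paste(seqnames(g1), start(g1))
  k2 <- paste(seqnames(g2), start(g2))
  shared <- intersect(k1, k2)
  empty <- GRanges(dmr_id = character(), n_cpg = integer(),
                   mean_level_group1 = numeric(),
                   mean_level_group2 = numeric(), score = numeric())
  if (length(shared) == 0L) {
    warning("groups share no cytosine positions; no DMRs callable")
    return(empty)
  }
  a <- g1[match(shared, k1)]
  b <- g2[match(shared, k2)]
  o <- order(as.character(seqnames(a)), start(a))
  a <- a[o]; b <- b[o]
  n1 <- a$m + a$u; n2 <- b$m + b$u
  ok <- n1 > 0L & n2 > 0L
  a <- a[ok]; b <- b[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  p1 <- a$m / n1; p2 <- b$m / n2
  pp <- (a$m + b$m) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  p <- 2 * pnorm(-abs(z))
  sig <- p < pThreshold
  if (!any(sig)) return(empty)

  s <- which(sig)
  chrom <- as.character(seqnames(a))[s]
  pos <- start(a)[s]
  sgn <- sign(p1 - p2)[s]
  newRegion <- c(TRUE, chrom[-1] != chrom[-length(s)] |
                   pos[-1] - pos[-length(s)] > mergeGap |
                   sgn[-1] != sgn[-length(s)])
  region <- cumsum(newRegion)
  keep <- tapply(seq_along(s), region, function(ix) {
    length(ix) >= minCpg && (pos[max(ix)] - pos[min(ix)] + 1L) >= minLen
  })
  regIds <- as.integer(names(keep))[keep]
  if (length(regIds) == 0L) return(empty)
  out <- lapply(regIds, function(r) {
    ix <- which(region == r)
    gix <- s[ix]
    GRanges(chrom[ix[1]], IRanges(pos[min(ix)], pos[max(ix)]),
            n_cpg = length(ix),
            mean_level_group1 = mean(p1[gix]),
            mean_level_group2 = mean(p2[gix]),
            score = sum(z[gix]))
  })
  res <- sort(do.call(c, out), ignore.strand = TRUE)
  res$dmr_id <- sprintf("dmr%04d", seq_along(res))
  res[, c("dmr_id", "n_cpg", "mean_level_group1",
          "mean_level_group2", "score")]
}
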