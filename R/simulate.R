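#' Default tissue panel
#'
#' The eleven-organ panel used for tissue-specificity scoring.
#' @return Character vector of 11 tissue labels.
#' @export
defaultTissues <- function() {
  c("adrenal_gland", "brain", "heart", "kidney", "liver", "lung",
    "muscle", "spleen", "thymus", "testes", "uterus")
}

#' Configuration of the synthetic-data generator
#'
#' Bundles every parameter of the miniature-dataset simulator. The
#' defaults describe the desk-scale study conditions: a 2 x 5 Mb genome,
#' 300 protein-coding, 150 lincRNA and 20 housekeeping genes, 11 tissues
#' with 2 replicates, CpGs every ~50 bp at ~30x depth, lincRNAs shorter,
#' lower-expressed, more tissue-specific and more TSS-methylated than
#' coding genes, an inverted-V TF-binding peak at TSSs, and 3 DMRs planted
#' inside lincRNA loci. The generator is fully deterministic given
#' \code{seed}.
#'
#' @slot seed Integer RNG seed.
#' @slot genome list: \code{nChroms}, \code{chromLength} (bp), \code{gc}
#'   (base composition).
#' @slot genes list: gene counts (\code{nCoding}, \code{nLincRNA},
#'   \code{nHousekeeping}), decoy counts per class
#'   (\code{nDecoySingleExon}, \code{nDecoyShort}, \code{nDecoyNearGene},
#'   \code{nDecoyCpc}, \code{nDecoyHousekeeping}), and the inter-gene gap
#'   scales \code{gapScaleCoding}/\code{gapScaleLinc} (the gamma-mean bp
#'   added to the 600 bp floor; lincRNA gaps are drawn larger, matching
#'   the wider intergenic spacing of lincRNA loci).
#' @slot expression list: \code{tissues}, \code{replicates},
#'   \code{meanLog} per biotype (lincRNA lower), \code{sdLogGene},
#'   \code{sdLogTissue}, \code{sdLogRep}, \code{fracSpecific} per biotype
#'   (lincRNA higher), \code{dominanceFold}.
#' @slot evidenceNoise list: \code{fracFailing} (fraction of true lincRNAs
#'   given failing evidence; 0 = noise-free), \code{fracInsignificantHits}
#'   (fraction of true lincRNAs given a non-significant housekeeping hit).
#' @slot methylation list: \code{cpgSpacing}, \code{meanDepth},
#'   \code{levelIntergenic}, \code{levelCodingBody}, \code{levelLincBody},
#'   \code{dipDepthCoding}, \code{dipDepthLinc} (shallower: lincRNA TSSs
#'   stay more methylated), \code{dipHalfWidth}, \code{replicates} per
#'   group.
#' @slot binding list: \code{background}, \code{peakHeight},
#'   \code{peakHalfWidth}, \code{step} (bp resolution of the track),
#'   \code{flank}.
#' @slot dmr list: \code{nPlanted}, \code{effect} (level drop in group 2),
#'   \code{width} (bp).
#' @seealso [simulateDataset()]
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", genome = "list", genes = "list",
                 expression = "list", evidenceNoise = "list",
                 methylation = "list", binding = "list", dmr = "list"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  g <- object@genes
  for (f in grep("^n", names(g), value = TRUE))
    if (g[[f]] < 0) msg <- c(msg, paste(f, "must be >= 0"))
  en <- object@evidenceNoise
  if (en$fracFailing < 0 || en$fracFailing > 1)
    msg <- c(msg, "fracFailing must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SimulationConfig Constructor; any element of the list slots
#'   can be overridden by name.
#' @param seed Integer RNG seed.
#' @param genome,genes,expression,evidenceNoise,methylation,binding,dmr
#'   Named lists overriding individual defaults of the matching slot.
#' @return A \code{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 7, genes = list(nCoding = 50))
#' @export
simulationConfig <- function(seed = 1L, genome = list(), genes = list(),
                             expression = list(), evidenceNoise = list(),
                             methylation = list(), binding = list(),
                             dmr = list()) {
  upd <- function(def, user) {
    bad <- setdiff(names(user), names(def))
    if (length(bad))
      stop("unknown config fields: ", paste(bad, collapse = ", "))
    def[names(user)] <- user
    def
  }
  new("SimulationConfig",
    seed = as.integer(seed),
    genome = upd(list(nChroms = 2L, chromLength = 5e6, gc = 0.42), genome),
    genes = upd(list(nCoding = 300L, nLincRNA = 150L, nHousekeeping = 20L,
                     nDecoySingleExon = 12L, nDecoyShort = 12L,
                     nDecoyNearGene = 12L, nDecoyCpc = 12L,
                     nDecoyHousekeeping = 12L,
                     gapScaleCoding = 1500, gapScaleLinc = 3000), genes),
    expression = upd(list(tissues = defaultTissues(), replicates = 2L,
                          meanLog = c(coding = log(8), lincRNA = log(2)),
                          sdLogGene = 1.0, sdLogTissue = 0.25,
                          sdLogRep = 0.15,
                          fracSpecific = c(coding = 0.15, lincRNA = 0.5),
                          dominanceFold = 50), expression),
    evidenceNoise = upd(list(fracFailing = 0,
                             fracInsignificantHits = 0.1), evidenceNoise),
    methylation = upd(list(cpgSpacing = 50, meanDepth = 30,
                           levelIntergenic = 0.75, levelCodingBody = 0.62,
                           levelLincBody = 0.80, dipDepthCoding = 0.42,
                           dipDepthLinc = 0.40, dipHalfWidth = 2000,
                           replicates = 2L), methylation),
    binding = upd(list(background = 2, peakHeight = 20,
                       peakHalfWidth = 1000, step = 50L, flank = 6000L),
                  binding),
    dmr = upd(list(nPlanted = 3L, effect = 0.5, width = 400L), dmr))
}

setMethod("show", "SimulationConfig", function(object) {
  g <- object@genome; gg <- object@genes
  cat(sprintf(
    "SimulationConfig (seed %d): %d x %.1f Mb genome; %d coding, %d lincRNA, %d housekeeping genes\n",
    object@seed, g$nChroms, g$chromLength / 1e6, gg$nCoding, gg$nLincRNA,
    gg$nHousekeeping))
  cat(sprintf("  %d tissues x %d reps; %d planted DMRs\n",
              length(object@expression$tissues),
              object@expression$replicates, object@dmr$nPlanted))
})

## -- gene structure sampling ------------------------------------------------

.sampleStructure <- function(class) {
  switch(class,
    coding = list(
      exonLens = pmax(60L, as.integer(round(rlnorm(sample(4:10, 1),
                                                   log(180), 0.5)))),
      intronScale = c(log(1100), 0.7)),
    housekeeping = list(
      exonLens = as.integer(round(runif(1, 80, 300))),
      intronScale = NULL),
    decoy_single_exon = list(
      exonLens = as.integer(round(runif(1, 500, 2000))),
      intronScale = NULL),
    decoy_short = list(
      exonLens = as.integer(round(runif(2, 60, 100))),
      intronScale = c(log(400), 0.4)),
    ## lincRNA-like structures (true lincRNAs and the remaining decoys)
    list(
      exonLens = pmax(120L, as.integer(round(rlnorm(sample(2:4, 1),
                                                    log(280), 0.5)))),
      intronScale = c(log(800), 0.6)))
}

.buildExons <- function(startPos, struct) {
  nEx <- length(struct$exonLens)
  introns <- if (nEx > 1L)
    pmax(80L, as.integer(round(rlnorm(nEx - 1L, struct$intronScale[1],
                                      struct$intronScale[2]))))
  else integer()
  starts <- startPos + cumsum(c(0L, struct$exonLens[-nEx] + introns))
  IRanges(starts, width = struct$exonLens)
}

#' Simulate a gene annotation with planted candidate transcripts
#'
#' Lays out non-overlapping single-transcript genes along the configured
#' chromosomes: protein-coding and housekeeping genes (the reference
#' annotation), true lincRNAs, and five decoy classes that each violate
#' exactly one lincRNA filter (single-exon, too short, too close to a
#' coding gene, coding-potential-positive, housekeeping-like). Gaps around
#' lincRNA-like genes are drawn wider than gaps between coding genes;
#' near-gene decoys are placed 100-400 bp downstream of a coding gene.
#'
#' Uses the current RNG state; call \code{set.seed} first (or use
#' [simulateDataset()], which seeds everything).
#'
#' @param cfg A \linkS4class{SimulationConfig}.
#' @return list with \code{annotation} (a \linkS4class{TranscriptSet} of
#'   coding + housekeeping genes), \code{candidates} (a
#'   \linkS4class{TranscriptSet} of true lincRNAs and decoys, biotype
#'   \code{other}) and \code{truth} (data.frame \code{transcript_id},
#'   \code{class}).
#' @export
simulateAnnotation <- function(cfg) {
  g <- cfg@genes
  classes <- c(rep("coding", g$nCoding),
               rep("housekeeping", g$nHousekeeping),
               rep("lincRNA", g$nLincRNA),
               rep("decoy_single_exon", g$nDecoySingleExon),
               rep("decoy_short", g$nDecoyShort),
               rep("decoy_cpc", g$nDecoyCpc),
               rep("decoy_housekeeping", g$nDecoyHousekeeping))
  classes <- sample(classes)
  nearGene <- rep("decoy_near_gene", g$nDecoyNearGene)
  ## insert near-gene decoys immediately after randomly chosen coding genes
  codingPos <- which(classes == "coding")
  if (length(nearGene) > 0L && length(codingPos) == 0L)
    stop("near-gene decoys require at least one coding gene")
  insertAfter <- sort(sample(codingPos, length(nearGene), replace = FALSE))
  out <- as.list(classes)
  for (k in rev(seq_along(insertAfter)))
    out <- append(out, list("decoy_near_gene"), after = insertAfter[k])
  classes <- unlist(out)

  nChrom <- cfg@genome$nChroms
  chromLen <- cfg@genome$chromLength
  chromOf <- rep(seq_len(nChrom), length.out = length(classes))
  ## keep near-gene decoys on the same chromosome as their coding anchor
  for (i in which(classes == "decoy_near_gene"))
    chromOf[i] <- chromOf[i - 1L]

  lincLike <- function(cl) cl %in% c("lincRNA", "decoy_single_exon",
                                     "decoy_short", "decoy_cpc",
                                     "decoy_housekeeping")
  recs <- vector("list", length(classes))
  cursor <- rep(1L, nChrom)
  for (i in seq_along(classes)) {
    cl <- classes[i]; chr <- chromOf[i]
    gap <- if (cl == "decoy_near_gene") {
      as.integer(round(runif(1, 100, 400)))
    } else {
      scale <- if (lincLike(cl) ||
                   (i > 1L && chromOf[i - 1L] == chr &&
                    lincLike(classes[i - 1L])))
        g$gapScaleLinc else g$gapScaleCoding
      600L + as.integer(round(rgamma(1, shape = 2, scale = scale / 2)))
    }
    startPos <- cursor[chr] + gap
    ex <- .buildExons(startPos, .sampleStructure(cl))
    if (max(end(ex)) > chromLen - 1000L)
      stop("cannot fit genes into the configured genome (overcrowding); ",
           "increase chromLength or reduce gene counts")
    recs[[i]] <- list(chrom = paste0("chr", chr), exons = ex,
                      strand = sample(c("+", "-"), 1), class = cl)
    cursor[chr] <- max(end(ex))
  }
  ids <- sprintf("T%06d", seq_along(recs))
  grl <- GRangesList(lapply(seq_along(recs), function(i)
    GRanges(recs[[i]]$chrom, recs[[i]]$exons,
            strand = recs[[i]]$strand)))
  names(grl) <- ids
  class <- vapply(recs, `[[`, character(1), "class")
  biotype <- ifelse(class %in% c("coding", "housekeeping"), class, "other")
  geneIds <- sprintf("G%06d", seq_along(recs))
  all <- TranscriptSet(grl, gene_id = geneIds, biotype = biotype,
                       source = "rnaseq")
  isAnn <- class %in% c("coding", "housekeeping")
  truth <- data.frame(transcript_id = ids, gene_id = geneIds,
                      class = class, row.names = NULL)
  list(annotation = all[which(isAnn)],
       candidates = all[which(!isAnn)],
       truth = truth)
}

#' Simulate transcript evidence and housekeeping hits for candidates
#'
#' True lincRNAs receive passing evidence (coverage 0.85-1, every junction
#' 13-23 reads, CPC around -2.5); each decoy class receives evidence
#' failing exactly its target filter. A configurable fraction of true
#' lincRNAs is corrupted to failing values (default 0: noise-free), and a
#' fraction receives a non-significant housekeeping hit (which must not
#' disqualify them).
#'
#' @param cfg A \linkS4class{SimulationConfig}.
#' @param candidates The candidate \linkS4class{TranscriptSet} from
#'   [simulateAnnotation()].
#' @param truth Its truth table.
#' @return list with \code{evidence} (a \linkS4class{DataFrame} in
#'   [readEvidence()] layout) and \code{hkHits} (data.frame).
#' @export
simulateEvidence <- function(cfg, candidates, truth) {
  ids <- names(candidates)
  cls <- truth$class[match(ids, truth$transcript_id)]
  nEx <- exonCounts(candidates)
  n <- length(ids)
  coverage <- runif(n, 0.85, 1)
  cpc <- pmin(rnorm(n, -2.5, 0.4), -1.2)
  jr <- lapply(seq_len(n), function(i)
    as.integer(3L + rpois(max(nEx[i] - 1L, 0L), 10)))
  coverage[cls == "decoy_short"] <- runif(sum(cls == "decoy_short"), .85, 1)
  cpc[cls == "decoy_cpc"] <- rnorm(sum(cls == "decoy_cpc"), 2, 0.5)

  fracBad <- cfg@evidenceNoise$fracFailing
  if (fracBad > 0) {
    lincIx <- which(cls == "lincRNA")
    bad <- sample(lincIx, round(fracBad * length(lincIx)))
    coverage[bad] <- runif(length(bad), 0.3, 0.79)
  }
  ev <- DataFrame(transcript_id = ids, exon_coverage = coverage,
                  junction_reads = IntegerList(jr), cpc_score = cpc,
                  source = rep("rnaseq", n))
  hkIx <- which(cls == "decoy_housekeeping")
  hits <- data.frame(
    transcript_id = ids[hkIx],
    evalue = 10^runif(length(hkIx), -40, -15),
    percent_identity = runif(length(hkIx), 85, 99))
  weak <- which(cls == "lincRNA")
  weak <- sample(weak, round(cfg@evidenceNoise$fracInsignificantHits *
                               length(weak)))
  if (length(weak))
    hits <- rbind(hits, data.frame(
      transcript_id = ids[weak],
      evalue = 10^runif(length(weak), -6, -2),
      percent_identity = runif(length(weak), 60, 75)))
  list(evidence = ev, hkHits = hits)
}

#' Simulate a tissue expression matrix with planted specific genes
#'
#' Per gene, a lognormal baseline (lincRNA mean lower than coding); a
#' biotype-dependent fraction of genes is made tissue-specific by
#' multiplying one uniformly chosen tissue by the dominance fold.
#' Per-tissue and per-replicate lognormal noise is applied.
#'
#' @param cfg A \linkS4class{SimulationConfig}.
#' @param geneIds Character vector of gene ids.
#' @param biotype Matching vector with values \code{coding} or
#'   \code{lincRNA} (others are treated as coding-like baseline).
#' @return list with \code{se} (a \linkS4class{SummarizedExperiment},
#'   assay \code{fpkm}, columns \code{tissue.repN}) and \code{truth}
#'   (data.frame \code{gene_id}, \code{specific_tissue}, \code{NA} for
#'   non-planted genes).
#' @export
simulateExpressionMatrix <- function(cfg, geneIds, biotype) {
  e <- cfg@expression
  tissues <- e$tissues
  Tn <- length(tissues); R <- e$replicates
  n <- length(geneIds)
  ml <- ifelse(biotype == "lincRNA", e$meanLog["lincRNA"],
               e$meanLog["coding"])
  base <- rlnorm(n, ml, e$sdLogGene)
  frac <- ifelse(biotype == "lincRNA", e$fracSpecific["lincRNA"],
                 e$fracSpecific["coding"])
  specific <- runif(n) < frac
  specTissue <- ifelse(specific, sample(Tn, n, replace = TRUE), NA)
  perTissue <- base * matrix(rlnorm(n * Tn, 0, e$sdLogTissue), n, Tn)
  fold <- cbind(seq_len(n), specTissue)
  perTissue[fold[!is.na(specTissue), , drop = FALSE]] <-
    perTissue[fold[!is.na(specTissue), , drop = FALSE]] * e$dominanceFold
  m <- matrix(0, n, Tn * R)
  cols <- character(Tn * R)
  for (t in seq_len(Tn)) for (r in seq_len(R)) {
    j <- (t - 1L) * R + r
    m[, j] <- perTissue[, t] * rlnorm(n, 0, e$sdLogRep)
    cols[j] <- paste0(tissues[t], ".rep", r)
  }
  dimnames(m) <- list(geneIds, cols)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = m),
    colData = DataFrame(tissue = rep(tissues, each = R),
                        row.names = cols))
  list(se = se,
       truth = data.frame(gene_id = geneIds,
                          specific_tissue = ifelse(is.na(specTissue), NA,
                                                   tissues[specTissue]),
                          row.names = NULL))
}

## true methylation level at given CpG positions (GRanges, width 1)
.trueMethLevels <- function(cfg, cpg, annTx) {
  me <- cfg@methylation
  lvl <- rep(me$levelIntergenic, length(cpg))
  loci <- lociOf(annTx)
  for (bt in c("coding", "lincRNA")) {
    body <- loci[loci$biotype == bt]
    hit <- overlapsAny(cpg, body, ignore.strand = TRUE)
    lvl[hit] <- if (bt == "coding") me$levelCodingBody else me$levelLincBody
  }
  tss <- tssOf(annTx)
  bt <- annTx@txData$biotype
  keep <- bt %in% c("coding", "lincRNA")
  tss <- tss[keep]; bt <- bt[keep]
  win <- suppressWarnings(resize(tss, 2L * me$dipHalfWidth + 1L,
                                 fix = "center", ignore.strand = TRUE))
  hits <- findOverlaps(cpg, win, ignore.strand = TRUE)
  if (length(hits) > 0L) {
    d <- abs(start(cpg)[queryHits(hits)] - start(tss)[subjectHits(hits)])
    depth <- ifelse(bt[subjectHits(hits)] == "coding",
                    me$dipDepthCoding, me$dipDepthLinc)
    red <- depth * pmax(0, 1 - d / me$dipHalfWidth)   # triangular dip
    redMax <- tapply(red, queryHits(hits), max)
    ix <- as.integer(names(redMax))
    lvl[ix] <- lvl[ix] - as.numeric(redMax)
  }
  pmin(pmax(lvl, 0.02), 0.98)
}

#' Simulate bisulfite methylation call sets for two strain groups
#'
#' CpG positions are placed with geometric spacing along each chromosome.
#' Every CpG's true level is a biotype-dependent body/intergenic level
#' minus a triangular dip centred on the nearest TSS (deeper for coding
#' genes, so lincRNA TSSs stay more methylated). Group 2's level is
#' lowered by the configured effect inside DMR intervals planted within
#' the first \code{nPlanted} lincRNA loci. Observed (m, u) counts are
#' binomial draws at Poisson-distributed depth, per replicate.
#'
#' Uses the current RNG state (see [simulateDataset()]).
#'
#' @param cfg A \linkS4class{SimulationConfig}.
#' @param annTx A \linkS4class{TranscriptSet} of coding + lincRNA (and
#'   housekeeping) transcripts with final biotypes.
#' @param groups Number of groups to simulate (1 or 2; 1 skips DMRs).
#' @return list with \code{group1}/\code{group2} (lists of
#'   \linkS4class{MethylationCalls}, one per replicate), \code{dmrs}
#'   (planted \linkS4class{GRanges}, empty when \code{groups = 1}) and
#'   \code{cpg} (the CpG position \linkS4class{GRanges} with true levels).
#' @export
simulateMethylationCalls <- function(cfg, annTx, groups = 2L) {
  me <- cfg@methylation
  nChrom <- cfg@genome$nChroms
  chromLen <- cfg@genome$chromLength
  cpgList <- lapply(seq_len(nChrom), function(chr) {
    expected <- ceiling(chromLen / me$cpgSpacing * 1.2)
    gaps <- rgeom(expected, 1 / me$cpgSpacing) + 1L
    pos <- cumsum(gaps)
    pos[pos < chromLen - 1L]
  })
  allPos <- unlist(cpgList)
  cpg <- GRanges(rep(paste0("chr", seq_len(nChrom)), lengths(cpgList)),
                 IRanges(allPos + 1L, width = rep(1L, length(allPos))),
                 strand = "+")
  lvl1 <- .trueMethLevels(cfg, cpg, annTx)

  dmrs <- GRanges()
  lvl2 <- lvl1
  if (groups >= 2L && cfg@dmr$nPlanted > 0L) {
    loci <- lociOf(annTx)
    linc <- loci[loci$biotype == "lincRNA"]
    if (length(linc) < cfg@dmr$nPlanted)
      stop("not enough lincRNA loci to plant DMRs")
    host <- linc[seq_len(cfg@dmr$nPlanted)]
    width <- pmin(cfg@dmr$width, width(host))
    dmrs <- GRanges(seqnames(host),
                    IRanges(start(host) +
                              pmax((width(host) - width) %/% 2L, 0L),
                            width = width))
    strand(dmrs) <- "*"
    dmrs$dmr_id <- sprintf("planted%02d", seq_along(dmrs))
    dmrs$host_gene <- host$gene_id
    inDmr <- overlapsAny(cpg, dmrs, ignore.strand = TRUE)
    lvl2[inDmr] <- pmax(lvl1[inDmr] - cfg@dmr$effect, 0.02)
  }
  drawGroup <- function(lvl) {
    lapply(seq_len(me$replicates), function(r) {
      depth <- rpois(length(cpg), me$meanDepth) + 1L
      m <- rbinom(length(cpg), depth, lvl)
      gr <- cpg
      gr$m <- m; gr$u <- depth - m
      MethylationCalls(gr)
    })
  }
  res <- list(group1 = drawGroup(lvl1))
  if (groups >= 2L) res$group2 <- drawGroup(lvl2)
  cpg$true_level_group1 <- lvl1
  cpg$true_level_group2 <- lvl2
  res$dmrs <- dmrs
  res$cpg <- cpg
  res
}

#' Simulate a TF-binding coverage track
#'
#' Within the flanking window of every coding or lincRNA TSS the per-base
#' read depth is Poisson with mean background + a triangular (inverted-V)
#' peak of the configured height and half-width centred on the TSS; the
#' track is piecewise constant at the configured step resolution and zero
#' outside the windows.
#'
#' @param cfg A \linkS4class{SimulationConfig}.
#' @param annTx A \linkS4class{TranscriptSet} with final biotypes.
#' @return An \linkS4class{RleList} of per-base depths.
#' @export
simulateBindingTrack <- function(cfg, annTx) {
  b <- cfg@binding
  bt <- annTx@txData$biotype
  keep <- bt %in% c("coding", "lincRNA")
  tss <- tssOf(annTx[which(keep)])
  step <- b$step
  nStep <- as.integer(2L * b$flank / step)
  pieces <- lapply(seq_along(tss), function(i) {
    tss0 <- start(tss)[i] - 1L
    s0 <- tss0 - b$flank + as.integer((seq_len(nStep) - 1L) * step)
    mid <- s0 + step / 2
    mu <- b$background +
      b$peakHeight * pmax(0, 1 - abs(mid - tss0) / b$peakHalfWidth)
    depth <- rpois(nStep, mu)
    keepIx <- s0 >= 0L & depth > 0L
    GRanges(seqnames(tss)[i],
            IRanges(s0[keepIx] + 1L, width = step),
            score = depth[keepIx])
  })
  gr <- do.call(c, pieces)
  coverage(gr, weight = "score")
}

#' Generate a complete miniature dataset with ground truth
#'
#' Seeds the RNG from the config and produces the full file bundle of the
#' analysis: reference annotation GTF (coding + housekeeping), candidate
#' transcript GTF (true lincRNAs + decoys), evidence and housekeeping-hit
#' tables, expression matrix with per-tissue replicates, genome FASTA,
#' cytosine reports for two groups x replicates, a TF-binding bedGraph and
#' the planted-DMR BED, plus truth tables for every planted signal. The
#' output is byte-identical for identical configs.
#'
#' @param cfg A \linkS4class{SimulationConfig}.
#' @param outDir Output directory (created if needed). \code{NULL} skips
#'   all file writing and returns objects only.
#' @param writeGenome Write the genome FASTA? (It is the largest file and
#'   only the sequence-composition profiles need it.)
#' @return Invisibly, a list with the in-memory objects:
#'   \code{annotation}, \code{candidates}, \code{evidence}, \code{hkHits},
#'   \code{expression} (SummarizedExperiment), \code{methylation} (see
#'   [simulateMethylationCalls()]), \code{binding} (RleList),
#'   \code{genome} (DNAStringSet or NULL), and \code{truth} (list with
#'   \code{transcripts}, \code{specific}, \code{dmrs}).
#' @examples
#' cfg <- simulationConfig(seed = 11,
#'   genome = list(nChroms = 1L, chromLength = 3e5),
#'   genes = list(nCoding = 10L, nLincRNA = 5L, nHousekeeping = 2L,
#'                nDecoySingleExon = 1L, nDecoyShort = 1L,
#'                nDecoyNearGene = 1L, nDecoyCpc = 1L,
#'                nDecoyHousekeeping = 1L),
#'   dmr = list(nPlanted = 2L))
#' sim <- simulateDataset(cfg, outDir = NULL, writeGenome = FALSE)
#' table(sim$truth$transcripts$class)
#' @export
simulateDataset <- function(cfg, outDir = NULL, writeGenome = TRUE) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg@seed, kind = "Mersenne-Twister")

  ann <- simulateAnnotation(cfg)
  ev <- simulateEvidence(cfg, ann$candidates, ann$truth)

  ## biotype-resolved set of real genes (for methylation/binding truth)
  lincIds <- ann$truth$transcript_id[ann$truth$class == "lincRNA"]
  realTx <- c(names(ann$annotation), lincIds)
  allTx <- .concatTranscriptSets(ann$annotation, ann$candidates)
  realSet <- allTx[realTx]
  realSet@txData$biotype[realSet@txData$transcript_id %in% lincIds] <-
    "lincRNA"

  loci <- lociOf(realSet)
  exprSim <- simulateExpressionMatrix(
    cfg, loci$gene_id,
    ifelse(loci$biotype == "lincRNA", "lincRNA", "coding"))
  methSim <- simulateMethylationCalls(cfg, realSet, groups = 2L)
  bindTrack <- simulateBindingTrack(cfg, realSet)

  genome <- NULL
  if (writeGenome) {
    gc <- cfg@genome$gc
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    genome <- DNAStringSet(vapply(seq_len(cfg@genome$nChroms), function(i)
      paste(sample(names(p), cfg@genome$chromLength, replace = TRUE,
                   prob = p), collapse = ""), character(1)))
    names(genome) <- paste0("chr", seq_len(cfg@genome$nChroms))
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeGtf(ann$annotation, file.path(outDir, "annotation.gtf"))
    writeGtf(ann$candidates, file.path(outDir, "candidates.gtf"))
    writeEvidence(ev$evidence, file.path(outDir, "evidence.tsv"))
    write.table(ev$hkHits, file.path(outDir, "housekeeping_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeExpressionMatrix(exprSim$se, file.path(outDir, "expression.tsv"))
    for (grp in c("group1", "group2"))
      for (r in seq_along(methSim[[grp]]))
        writeMethylationCalls(
          methSim[[grp]][[r]],
          file.path(outDir, sprintf("methylation_%s_rep%d.tsv", grp, r)))
    writeCoverageBedGraph(bindTrack, file.path(outDir, "binding.bedgraph"))
    writeDmrBed(methSim$dmrs, file.path(outDir, "dmrs_true.bed"))
    write.table(ann$truth, file.path(outDir, "truth_transcripts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(exprSim$truth, file.path(outDir, "truth_specific.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(genome))
      Biostrings::writeXStringSet(genome, file.path(outDir, "genome.fa"))
  }
  invisible(list(annotation = ann$annotation, candidates = ann$candidates,
                 evidence = ev$evidence, hkHits = ev$hkHits,
                 expression = exprSim$se, methylation = methSim,
                 binding = bindTrack, genome = genome,
                 truth = list(transcripts = ann$truth,
                              specific = exprSim$truth,
                              dmrs = methSim$dmrs)))
}

.concatTranscriptSets <- function(a, b) {
  ex <- c(a@exons, b@exons)
  TranscriptSet(ex,
                gene_id = c(a@txData$gene_id, b@txData$gene_id),
                biotype = c(a@txData$biotype, b@txData$biotype),
                source = c(a@txData$source, b@txData$source))
}
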