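profileFixture <- function(seed = 5, flank = 500L, binWidth = 50L) {
  set.seed(seed)
  x <- makeTx(list(
    list(starts = 2000, widths = 400, strand = "+"),
    list(starts = 2500, widths = 300, strand = "-"),
    list(starts = c(300, 900), widths = c(100, 200), strand = "-"),
    list(chrom = "chr2", starts = 700, widths = 900, strand = "+")))
  pos <- sort(sample(0:4000, 160))
  chrom <- rep(c("chr1", "chr2"), c(110, 50))
  m <- rpois(160, 4); u <- rpois(160, 3)
  calls <- MethylationCalls(chrom, pos = pos,
                            strand = sample(c("+", "-"), 160, TRUE),
                            m = m, u = u)
  steps <- GenomicRanges::GRanges(
    rep(c("chr1", "chr2"), c(40, 20)),
    IRanges::IRanges(c(seq(1, 3901, by = 100), seq(1, 1901, by = 100)),
                     width = 100),
    score = rpois(60, 5))
  track <- GenomicRanges::coverage(steps, weight = "score")
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 4200, TRUE), collapse = ""),
    chr2 = paste(sample(c("A", "C", "G", "T", "N"), 2400, TRUE,
                        prob = c(.24, .24, .24, .24, .04)),
                 collapse = "")))
  list(x = x, calls = calls, track = track, genome = genome,
       flank = flank, binWidth = binWidth)
}

test_that("gene methylation level follows M = m/(m+u) with M = 0 at m = 0", {
  calls <- MethylationCalls(rep("chr1", 4), pos = c(10L, 20L, 30L, 500L),
                            strand = c("+", "-", "+", "+"),
                            m = c(2L, 3L, 0L, 50L), u = c(1L, 0L, 4L, 0L))
  loci <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 400, 900), c(100, 600, 1000)),
    gene_id = c("g1", "g2", "g3"))
  res <- geneMethylationLevel(loci, calls)
  expect_equal(res$level[1], 5 / 10)       # both strands summed
  expect_equal(res$level[2], 1)
  expect_equal(res$level[3], 0)            # no calls -> m = 0 -> level 0
  ## m = 0 with positive u is 0, not NaN
  calls0 <- MethylationCalls("chr1", pos = 10L, m = 0L, u = 7L)
  expect_equal(geneMethylationLevel(loci[1], calls0)$level, 0)
})

test_that("methylation metaprofile matches the per-base oracle", {
  f <- profileFixture()
  for (avg in c("all", "covered")) {
    got <- tssMethylationProfile(f$x, f$calls, f$flank, f$binWidth,
                                 average = avg)
    exp <- bruteMethProfile(f$x, f$calls, f$flank, f$binWidth, avg)
    expect_equal(profileValues(got), exp, tolerance = 1e-12)
  }
  got <- tssMethylationProfile(f$x, f$calls, f$flank, f$binWidth)
  expect_s4_class(got, "MetaProfile")
  expect_equal(nTranscripts(got), 4L)
  expect_equal(length(profileValues(got)), 2L * 500L / 50L)
})

test_that("binding metaprofile matches the per-base oracle", {
  f <- profileFixture()
  got <- tssBindingProfile(f$x, f$track, f$flank, f$binWidth)
  exp <- bruteBindingProfile(f$x, f$track, f$flank, f$binWidth)
  expect_equal(profileValues(got), exp, tolerance = 1e-12)
})

test_that("a constant track yields a constant binding profile", {
  x <- makeTx(list(list(starts = 6000, widths = 500),
                   list(starts = 8000, widths = 500, strand = "-")))
  track <- GenomicRanges::coverage(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 20000), score = 4),
    weight = "score")
  got <- tssBindingProfile(x, track)
  expect_equal(profileValues(got), rep(4, 100))
})

test_that("sequence metaprofiles match the per-base oracle", {
  f <- profileFixture()
  gotGc <- gcContentProfile(f$x, f$genome, f$flank, f$binWidth)
  expGc <- bruteSeqProfile(f$x, f$genome, f$flank, f$binWidth, "gc")
  expect_equal(profileValues(gotGc), expGc, tolerance = 1e-12)
  gotOe <- cpgOeProfile(f$x, f$genome, f$flank, f$binWidth)
  expOe <- bruteSeqProfile(f$x, f$genome, f$flank, f$binWidth, "cpg")
  expect_equal(profileValues(gotOe), expOe, tolerance = 1e-12)
})

test_that("CpG o/e reference values: CGCG -> 2, CCGG -> 1", {
  ## genome tiled so every 4-bp window is the motif; flank 200, bin 4
  mk <- function(motif) Biostrings::DNAStringSet(c(
    chr1 = paste(rep(motif, 200), collapse = "")))
  x <- makeTx(list(list(starts = 401, widths = 300)))
  oeCgcg <- cpgOeProfile(x, mk("CGCG"), flank = 200L, binWidth = 4L)
  expect_equal(profileValues(oeCgcg), rep(2, 100))
  oeCcgg <- cpgOeProfile(x, mk("CCGG"), flank = 200L, binWidth = 4L)
  expect_equal(profileValues(oeCcgg), rep(1, 100))
  gc <- gcContentProfile(x, mk("ATCG"), flank = 200L, binWidth = 4L)
  expect_equal(profileValues(gc), rep(0.5, 100))
})

test_that("profiles are invariant under genome reflection + strand flip", {
  ## reflect all coordinates through L and flip strand: the 5'->3'
  ## oriented profile must be identical.
  f <- profileFixture()
  L <- 10000L
  reflectTx <- function(x) {
    grl <- GenomicRanges::GRangesList(lapply(as.list(x@exons), function(g) {
      st <- BiocGenerics::start(g); en <- BiocGenerics::end(g)
      GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(g),
        IRanges::IRanges(L - en + 1L, L - st + 1L),
        strand = ifelse(as.character(BiocGenerics::strand(g)) == "+",
                        "-", "+"))
    }))
    names(grl) <- names(x)
    TranscriptSet(grl, gene_id = x@txData$gene_id,
                  biotype = x@txData$biotype, source = x@txData$source)
  }
  gr <- methCalls(f$calls)
  reflCalls <- MethylationCalls(
    as.character(GenomeInfoDb::seqnames(gr)),
    pos = L - BiocGenerics::start(gr),   # 0-based reflected position
    strand = as.character(BiocGenerics::strand(gr)),
    m = gr$m, u = gr$u)
  p1 <- profileValues(tssMethylationProfile(f$x, f$calls, f$flank,
                                            f$binWidth))
  p2 <- profileValues(tssMethylationProfile(reflectTx(f$x), reflCalls,
                                            f$flank, f$binWidth))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("default geometry is exactly 100 bins of 100 bp over +/- 5 kb", {
  x <- makeTx(list(list(starts = 50000, widths = 500)))
  calls <- MethylationCalls("chr1", pos = 50100L, m = 3L, u = 1L)
  prof <- tssMethylationProfile(x, calls)
  expect_equal(length(profileValues(prof)), 100L)
  off <- profileOffsets(prof)
  expect_equal(off, seq(-5000L, 4900L, by = 100L))
  expect_equal(diff(off), rep(100L, 99))
  ## bin 51 starts at the TSS
  expect_equal(off[51], 0L)
})

test_that("KS comparison separates shifted distributions", {
  set.seed(2)
  a <- rbeta(200, 8, 2)    # high methylation
  b <- rbeta(200, 5, 5)    # intermediate
  res <- compareMethylationDistributions(a, b)
  expect_lt(res$p.value, 1e-6)
  same <- compareMethylationDistributions(a, a)
  expect_equal(same$statistic, 0)
  expect_error(compareMethylationDistributions(1, c(0.5, 0.6)),
               "two values")
})
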