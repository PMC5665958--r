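test_that("TranscriptSet validity rejects malformed input", {
  expect_error(makeTx(list(
    list(starts = 1, widths = 100), list(starts = 200, widths = 100)),
    ids = c("a", "a")), "unique|duplicate")
  ## overlapping exons within a transcript
  expect_error(makeTx(list(list(starts = c(1, 50), widths = c(100, 100)))),
               "overlap")
  ## exons on two chromosomes
  grl <- GenomicRanges::GRangesList(x = GenomicRanges::GRanges(
    c("chr1", "chr2"), IRanges::IRanges(c(1, 1), width = 10),
    strand = "+"))
  expect_error(TranscriptSet(grl, gene_id = "g", biotype = "other",
                             source = "rnaseq"), "chromosome|seqname")
  ## bad biotype
  expect_error(makeTx(list(list(starts = 1, widths = 300,
                                biotype = "nonsense"))), "biotype")
})

test_that("TranscriptSet subsetting and accessors are consistent", {
  x <- makeTx(list(
    list(starts = c(1, 201), widths = c(100, 100), gene = "g1"),
    list(starts = c(1000, 1500), widths = c(50, 250), gene = "g2",
         strand = "-"),
    list(starts = 5000, widths = 400, gene = "g3")))
  expect_equal(length(x), 3L)
  expect_equal(names(x), c("t1", "t2", "t3"))
  expect_equal(unname(txLengths(x)), c(200L, 300L, 400L))
  expect_equal(unname(exonCounts(x)), c(2L, 2L, 1L))
  expect_equal(as.integer(intronLengths(x)[[1]]), 100L)
  expect_equal(names(x[c(3, 1)]), c("t3", "t1"))
  expect_equal(names(x["t2"]), "t2")
  expect_equal(names(x[c(TRUE, FALSE, TRUE)]), c("t1", "t3"))
})

test_that("tssOf honours strand and rejects unstranded transcripts", {
  x <- makeTx(list(
    list(starts = c(101, 301), widths = c(50, 100)),
    list(starts = c(101, 301), widths = c(50, 100), strand = "-")))
  tss <- tssOf(x)
  expect_equal(BiocGenerics::start(tss), c(101L, 400L))
  expect_true(all(BiocGenerics::width(tss) == 1L))
  expect_error(tssOf(makeTx(list(list(starts = 1, widths = 10,
                                      strand = "*")))), "strand")
})

test_that("gapDistance counts strictly-between bases", {
  gr <- function(s, e, chrom = "chr1")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
  expect_equal(gapDistance(gr(1, 100), gr(101, 200)), 0L)   # adjacent
  expect_equal(gapDistance(gr(1, 100), gr(102, 200)), 1L)
  expect_equal(gapDistance(gr(1, 100), gr(601, 700)), 500L)
  expect_equal(gapDistance(gr(1, 100), gr(50, 200)), -1L)   # overlap
  expect_error(gapDistance(gr(1, 100), gr(1, 100, "chr2")),
               "chromosome")
})

test_that("GTF round-trips exactly", {
  x <- makeTx(list(
    list(starts = c(11, 211), widths = c(100, 120), gene = "gA",
         biotype = "coding"),
    list(starts = c(1001, 1301), widths = c(80, 220), gene = "gB",
         strand = "-", biotype = "other")))
  f <- tempfile(fileext = ".gtf")
  writeGtf(x, f)
  y <- readGtf(f)
  expect_equal(names(y), names(x))
  expect_identical(lapply(as.list(y@exons), BiocGenerics::start),
                   lapply(as.list(x@exons), BiocGenerics::start))
  expect_identical(lapply(as.list(y@exons), BiocGenerics::end),
                   lapply(as.list(x@exons), BiocGenerics::end))
  expect_equal(y@txData$gene_id, x@txData$gene_id)
  expect_equal(y@txData$biotype, x@txData$biotype)
  expect_equal(as.character(BiocGenerics::strand(txSpans(y))),
               as.character(BiocGenerics::strand(txSpans(x))))
})

test_that("methylation calls round-trip, including gzip", {
  mc <- MethylationCalls(c("chr1", "chr1", "chr2"),
                         pos = c(9L, 99L, 9L),
                         strand = c("+", "-", "+"),
                         m = c(3L, 0L, 7L), u = c(1L, 5L, 0L))
  for (ext in c(".tsv", ".tsv.gz")) {
    f <- tempfile(fileext = ext)
    writeMethylationCalls(mc, f)
    back <- readMethylationCalls(f)
    expect_identical(methCalls(back)$m, methCalls(mc)$m)
    expect_identical(methCalls(back)$u, methCalls(mc)$u)
    expect_equal(BiocGenerics::start(methCalls(back)),
                 BiocGenerics::start(methCalls(mc)))
  }
  ## negative counts rejected
  f <- tempfile()
  writeLines("chr1\t10\t+\t-1\t5", f)
  expect_error(readMethylationCalls(f), "non-negative")
  ## empty file gives an empty call set
  f2 <- tempfile(); file.create(f2)
  expect_equal(length(readMethylationCalls(f2)), 0L)
})

test_that("bedGraph coverage equals a per-base expansion oracle", {
  f <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t10\t3", "chr1\t10\t15\t7", "chr1\t100\t110\t2"),
             f)
  track <- readCoverageBedGraph(f)
  oracle <- numeric(120)
  oracle[1:10] <- 3; oracle[11:15] <- 7; oracle[101:110] <- 2
  len <- length(track[["chr1"]])
  expect_equal(as.numeric(track[["chr1"]]), oracle[seq_len(len)])
  expect_equal(trackDepth(track, "chr1", 5L, 20L), oracle[6:20])
  ## positions beyond the track (and unknown chromosomes) have depth 0
  expect_equal(trackDepth(track, "chr1", 200L, 205L), rep(0, 5))
  expect_equal(trackDepth(track, "chrX", 0L, 3L), rep(0, 3))
  ## overlapping intervals are rejected
  f2 <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t10\t3", "chr1\t5\t15\t7"), f2)
  expect_error(readCoverageBedGraph(f2), "overlap")
})

test_that("coverage track round-trips through the bedGraph writer", {
  f <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t3\t10\t4", "chr1\t50\t60\t1"), f)
  track <- readCoverageBedGraph(f)
  f2 <- tempfile(fileext = ".bedgraph")
  writeCoverageBedGraph(track, f2)
  expect_equal(as.numeric(readCoverageBedGraph(f2)[["chr1"]]),
               as.numeric(track[["chr1"]]))
})

test_that("evidence tables round-trip with per-intron junction lists", {
  ev <- S4Vectors::DataFrame(
    transcript_id = c("t1", "t2", "t3"),
    exon_coverage = c(0.8, 0.79, 1),
    junction_reads = IRanges::IntegerList(c(3L, 4L), integer(), 7L),
    cpc_score = c(-1.01, -1, 2.5),
    source = c("rnaseq", "rnaseq", "annotation"))
  f <- tempfile(fileext = ".tsv")
  writeEvidence(ev, f)
  back <- readEvidence(f)
  expect_equal(back$transcript_id, ev$transcript_id)
  expect_equal(back$exon_coverage, ev$exon_coverage)
  expect_identical(as.list(back$junction_reads),
                   as.list(ev$junction_reads))
  expect_equal(back$cpc_score, ev$cpc_score)
  expect_equal(back$source, ev$source)
})

test_that("expression matrices round-trip and parse tissue names", {
  m <- matrix(c(1, 0, 5.5, 2, 0, 3), nrow = 2,
              dimnames = list(c("g1", "g2"),
                              c("liver.rep1", "liver.rep2", "brain.rep1")))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = m),
    colData = S4Vectors::DataFrame(
      tissue = c("liver", "liver", "brain"),
      row.names = colnames(m)))
  f <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(se, f)
  back <- readExpressionMatrix(f)
  expect_equal(SummarizedExperiment::assay(back, "fpkm"), m)
  expect_equal(
    as.character(SummarizedExperiment::colData(back)$tissue),
    c("liver", "liver", "brain"))
  ## negative FPKM rejected
  f2 <- tempfile()
  writeLines(c("gene_id\tliver.rep1", "g1\t-2"), f2)
  expect_error(readExpressionMatrix(f2), "negative|non-negative")
})

test_that("locus clustering matches a brute-force oracle", {
  bruteCluster <- function(x) {
    n <- length(x)
    ex <- as.list(x@exons)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      hits <- GenomicRanges::findOverlaps(ex[[i]], ex[[j]])   # strand-aware
      adj[i, j] <- length(hits) > 0L
    }
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    comp
  }
  set.seed(42)
  for (rep in 1:5) {
    specs <- lapply(1:30, function(i) {
      s <- sample(1:3000, 1)
      list(chrom = sample(c("chr1", "chr2"), 1),
           starts = s, widths = sample(50:400, 1),
           strand = sample(c("+", "-"), 1))
    })
    x <- makeTx(specs, ids = sprintf("t%02d", 1:30))
    got <- clusterTranscriptsIntoLoci(x)
    expected <- bruteCluster(x)
    ## same partition: locus ids agree iff brute-force components agree
    gid <- got@txData$gene_id[match(names(x), names(got))]
    expect_equal(outer(gid, gid, "=="), outer(expected, expected, "=="),
                 ignore_attr = TRUE)
  }
})

test_that("lociOf unions transcript spans per gene", {
  x <- makeTx(list(
    list(starts = c(101, 501), widths = c(100, 100), gene = "g1",
         biotype = "coding"),
    list(starts = 301, widths = 600, gene = "g1", biotype = "coding"),
    list(starts = 5001, widths = 300, gene = "g2", biotype = "other")))
  loci <- lociOf(x)
  expect_equal(length(loci), 2L)
  g1 <- loci[loci$gene_id == "g1"]
  expect_equal(BiocGenerics::start(g1), 101L)
  expect_equal(BiocGenerics::end(g1), 900L)
  expect_equal(g1$n_transcripts, 2L)
})

test_that("profile TSV writer emits 6-significant-digit values", {
  prof <- MetaProfile(rep(1 / 3, 100), "binding", 5L)
  f <- tempfile(fileext = ".tsv")
  writeProfileTsv(prof, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 100L)
  expect_equal(df$offset_bp[1], -5000L)
  expect_equal(df$offset_bp[100], 4900L)
  expect_equal(df$value[1], signif(1 / 3, 6))
})
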