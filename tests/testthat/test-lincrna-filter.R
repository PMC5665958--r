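test_that("exon-coverage boundary: 0.80 passes, 0.79 fails", {
  expect_equal(filterExonCoverage(c(0.80, 0.79, NA)),
               c("pass", "fail", "not_evaluated"))
  expect_error(filterExonCoverage(1.2), "\\[0,1\\]")
})

test_that("junction-support boundary: 3 passes, 2 fails, per intron", {
  expect_equal(
    filterJunctionSupport(list(c(3L, 3L), c(3L, 2L), integer(), NULL)),
    c("pass", "fail", "pass", "not_evaluated"))
  ## per-intron semantics: one weak intron fails the transcript
  expect_equal(filterJunctionSupport(list(c(100L, 2L, 100L))), "fail")
  ## count list length must be exon count - 1
  expect_error(
    filterJunctionSupport(list(c(3L, 3L)), nExons = 4L),
    "exon count")
})

test_that("structure boundary: length 201 passes, 200 fails; >= 2 exons", {
  x <- makeTx(list(
    list(starts = c(1, 201), widths = c(100, 101)),    # 201 nt, 2 exons
    list(starts = c(1, 201), widths = c(100, 100)),    # 200 nt
    list(starts = 1, widths = 1000)))                  # single exon
  expect_equal(unname(filterStructure(x)), c("pass", "fail", "fail"))
})

test_that("intergenic boundary: gap 500 passes, 499 fails, overlap fails", {
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
                                strand = "-", gene_id = "c1",
                                biotype = "coding")
  x <- makeTx(list(
    list(starts = 1501, widths = 300),    # gap 500 (bases 1001..1500)
    list(starts = 1500, widths = 300),    # gap 499
    list(starts = 900, widths = 300)))    # overlap
  expect_equal(classifyIntergenic(x, ann), c("pass", "fail", "fail"))
  ## strand is ignored: the annotation above is on "-", candidates on "+"
  ## non-coding annotation biotypes are not considered
  ann2 <- ann; ann2$biotype <- "other"
  expect_equal(classifyIntergenic(x, ann2), rep("pass", 3))
})

test_that("coding-potential boundary: -1.0 fails, -1.01 passes", {
  expect_equal(filterCodingPotential(c(-1.01, -1, 0, NA)),
               c("pass", "fail", "fail", "not_evaluated"))
})

test_that("housekeeping exclusion needs both evalue and identity", {
  hits <- data.frame(
    transcript_id = c("a", "b", "c", "d"),
    evalue = c(1e-10, 1e-9, 1e-30, 1e-30),
    percent_identity = c(80, 95, 79.9, 80))
  got <- filterHousekeeping(c("a", "b", "c", "d", "e"), hits)
  ## a: boundary significant (<= 1e-10 and >= 80); b: evalue too weak;
  ## c: identity too low; d: significant; e: no hits
  expect_equal(got, c("fail", "pass", "pass", "fail", "pass"))
  expect_equal(filterHousekeeping("x", NULL), "pass")
})

cascadeFixture <- function() {
  ann <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 50000), width = 2000),
    strand = "+", gene_id = c("c1", "c2"),
    biotype = c("coding", "housekeeping"))
  x <- makeTx(list(
    list(starts = c(10001, 10501), widths = c(200, 300)),  # good lincRNA
    list(starts = c(20001, 20501), widths = c(200, 300)),  # bad coverage
    list(starts = 2400, widths = 900),                     # single exon
    list(starts = c(30001, 30501), widths = c(200, 300)),  # hk hit
    list(starts = c(40001, 40501), widths = c(200, 300),
         source = "annotation")),                          # annotated lincRNA
    ids = c("good", "lowcov", "single", "hk", "anno"))
  ev <- S4Vectors::DataFrame(
    transcript_id = c("good", "lowcov", "single", "hk"),
    exon_coverage = c(0.9, 0.5, 0.9, 0.9),
    junction_reads = IRanges::IntegerList(5L, 5L, integer(), 5L),
    cpc_score = c(-2, -2, -2, -2),
    source = rep("rnaseq", 4))
  hk <- data.frame(transcript_id = "hk", evalue = 1e-30,
                   percent_identity = 95)
  list(x = x, ev = ev, hk = hk, ann = ann)
}

test_that("cascade classifies, audits and short-circuits", {
  f <- cascadeFixture()
  res <- runFilterCascade(f$x, f$ev, hkHits = f$hk, annotation = f$ann)
  expect_setequal(names(res$lincRNA), c("good", "anno"))
  a <- res$audit
  expect_equal(sort(a$transcript_id), sort(names(f$x)))
  rownames(a) <- a$transcript_id
  expect_equal(a["good", "final_class"], "lincRNA")
  expect_equal(a["lowcov", "exon_coverage"], "fail")
  ## short-circuit: filters after the first failure are not evaluated
  expect_equal(a["lowcov", "housekeeping"], "not_evaluated")
  expect_equal(a["single", "structure"], "fail")
  expect_equal(a["hk", "housekeeping"], "fail")
  ## annotation-source transcripts skip the two RNA-seq evidence filters
  expect_equal(a["anno", "exon_coverage"], "not_evaluated")
  expect_equal(a["anno", "junction_support"], "not_evaluated")
  expect_equal(a["anno", "final_class"], "lincRNA")
  ## funnel is monotonically non-increasing and starts from the full set
  expect_true(all(diff(res$funnel) <= 0))
  expect_equal(unname(res$funnel[length(res$funnel)]), 2L)
})

test_that("surviving set is invariant to filter order", {
  f <- cascadeFixture()
  ref <- sort(names(runFilterCascade(f$x, f$ev, hkHits = f$hk,
                                     annotation = f$ann)$lincRNA))
  set.seed(1)
  for (i in 1:5) {
    ord <- sample(c("structure", "exon_coverage", "junction_support",
                    "intergenic", "coding_potential", "housekeeping"))
    got <- runFilterCascade(f$x, f$ev, hkHits = f$hk, annotation = f$ann,
                            order = ord)
    expect_equal(sort(names(got$lincRNA)), ref)
  }
  ## disabling short-circuit evaluates everything but keeps the same set
  full <- runFilterCascade(f$x, f$ev, hkHits = f$hk, annotation = f$ann,
                           shortCircuit = FALSE)
  expect_equal(sort(names(full$lincRNA)), ref)
  expect_false(any(full$audit$housekeeping == "not_evaluated"))
})

test_that("cascade errors on rnaseq transcripts without evidence", {
  f <- cascadeFixture()
  expect_error(
    runFilterCascade(f$x, f$ev[f$ev$transcript_id != "good", ],
                     hkHits = f$hk, annotation = f$ann),
    "evidence")
})

test_that("interval statistics match a hand-computed toy layout", {
  ## coding loci: [1,1000], [3001,4000], [10001,11000] on chr1
  coding <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 3001, 10001), width = 1000),
    gene_id = c("c1", "c2", "c3"))
  ## linc loci: [1501,1600] (gaps 500/1400), [20001,20100] (gap 9000)
  linc <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1501, 20001), width = 100),
    gene_id = c("l1", "l2"))
  st <- intervalStatistics(linc, coding)
  expect_equal(sort(st$linc_gaps), c(500, 9000))
  ## coding-coding nearest-other gaps: c1->c2 2000, c2->c1 2000, c3->c2 6000
  expect_equal(sort(st$coding_gaps), c(2000, 2000, 6000))
  expect_equal(st$median_linc_gap, 4750)
  expect_equal(st$median_coding_gap, 2000)
  expect_true(st$p_gap > 0 && st$p_gap <= 1)
})

test_that("nearest-other gaps handle overlap and adjacency", {
  coding <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 500, 2001, 10001), width = 600),
    gene_id = sprintf("c%d", 1:4))
  linc <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(30001, 40001), width = 100),
    gene_id = c("l1", "l2"))
  st <- intervalStatistics(linc, coding)
  ## c1 overlaps c2 -> 0; c2-c3 gap 901; c3 min(901, 7400); c4 7400
  expect_equal(sort(st$coding_gaps), c(0, 0, 901, 7400))
})

test_that("length distribution reports exonic lengths by biotype", {
  x <- makeTx(list(
    list(starts = c(1, 1001), widths = c(500, 700), biotype = "coding"),
    list(starts = 5001, widths = 300, biotype = "other")))
  d <- transcriptLengthDistribution(x)
  expect_equal(d$length, c(1200L, 300L))
  expect_equal(d$biotype, c("coding", "other"))
})
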