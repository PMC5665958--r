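## Naive per-base brute-force oracles shared by the profile and
## acceptance tests.

bruteMethProfile <- function(x, calls, flank = 5000L, binWidth = 100L,
                             average = "all") {
  gr <- methCalls(calls)
  tss <- tssOf(x)
  nbin <- 2L * flank %/% binWidth
  n <- length(x)
  M <- matrix(0, n, nbin)
  cov <- matrix(FALSE, n, nbin)
  for (t in seq_len(n)) {
    posSeq <- bruteWindowPos(BiocGenerics::start(tss)[t],
                             as.character(BiocGenerics::strand(tss))[t],
                             flank)
    chrom <- as.character(GenomeInfoDb::seqnames(tss))[t]
    for (i in seq_len(nbin)) {
      basePos0 <- posSeq[((i - 1L) * binWidth + 1L):(i * binWidth)]
      sel <- as.character(GenomeInfoDb::seqnames(gr)) == chrom &
        (BiocGenerics::start(gr) - 1L) %in% basePos0
      if (any(sel)) {
        m <- sum(gr$m[sel]); u <- sum(gr$u[sel])
        M[t, i] <- if (m == 0) 0 else m / (m + u)
        cov[t, i] <- TRUE
      }
    }
  }
  if (average == "all") colMeans(M)
  else ifelse(colSums(cov) > 0, colSums(M) / colSums(cov), 0)
}

bruteBindingProfile <- function(x, track, flank = 5000L, binWidth = 100L) {
  tss <- tssOf(x)
  nbin <- 2L * flank %/% binWidth
  acc <- matrix(0, length(x), nbin)
  for (t in seq_along(tss)) {
    posSeq <- bruteWindowPos(BiocGenerics::start(tss)[t],
                             as.character(BiocGenerics::strand(tss))[t],
                             flank)
    chrom <- as.character(GenomeInfoDb::seqnames(tss))[t]
    rl <- if (chrom %in% names(track)) as.numeric(track[[chrom]])
          else numeric()
    depth <- vapply(posSeq, function(p0) {
      if (p0 >= 0 && p0 < length(rl)) rl[p0 + 1L] else 0
    }, numeric(1))
    acc[t, ] <- vapply(seq_len(nbin), function(i)
      mean(depth[((i - 1L) * binWidth + 1L):(i * binWidth)]), numeric(1))
  }
  colMeans(acc)
}

bruteSeqProfile <- function(x, genome, flank, binWidth, what = "gc") {
  tss <- tssOf(x)
  nbin <- 2L * flank %/% binWidth
  vals <- matrix(NA_real_, length(x), nbin)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  for (t in seq_along(tss)) {
    posSeq <- bruteWindowPos(BiocGenerics::start(tss)[t],
                             as.character(BiocGenerics::strand(tss))[t],
                             flank)
    chrom <- as.character(GenomeInfoDb::seqnames(tss))[t]
    chrSeq <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    minus <- as.character(BiocGenerics::strand(tss))[t] == "-"
    base <- vapply(posSeq, function(p0) {
      if (p0 >= 0 && p0 < length(chrSeq)) chrSeq[p0 + 1L] else "N"
    }, character(1))
    if (minus) base <- unname(comp[base])
    for (i in seq_len(nbin)) {
      w <- base[((i - 1L) * binWidth + 1L):(i * binWidth)]
      L <- sum(w != "N")
      if (L == 0) next
      if (what == "gc") {
        vals[t, i] <- sum(w %in% c("G", "C")) / L
      } else {
        cpg <- sum(w[-length(w)] == "C" & w[-1] == "G")
        cg <- sum(w == "C") * sum(w == "G")
        vals[t, i] <- if (cg == 0) 0 else cpg * L / cg
      }
    }
  }
  apply(vals, 2L, function(col)
    if (all(is.na(col))) 0 else mean(col, na.rm = TRUE))
}

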