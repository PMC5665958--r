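#' Normalise an expression vector to a density
#'
#' @param x Non-negative numeric vector of FPKM values over tissues with at
#'   least one positive entry.
#' @return \code{x / sum(x)}, a probability vector.
#' @examples
#' expressionDensity(c(2, 2, 0, 0))
#' @export
expressionDensity <- function(x) {
  if (any(x < 0)) stop("expression values must be non-negative")
  s <- sum(x)
  if (s == 0) stop("all-zero expression vector has no density")
  x / s
}

.entropyBits <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))   # 0 * log 0 = 0
}

#' Jensen-Shannon divergence (bits)
#'
#' JSD(p, q) = H((p+q)/2) - (H(p) + H(q))/2 with Shannon entropy in bits,
#' so the value lies in [0, 1]: 0 iff p = q, 1 for distributions with
#' disjoint support.
#'
#' @param p,q Probability vectors of equal length (each summing to 1 within
#'   1e-9).
#' @return The divergence, a number in [0, 1].
#' @examples
#' jsDivergence(c(1, 0), c(0, 1))  # 1
#' @export
jsDivergence <- function(p, q) {
  if (length(p) != length(q))
    stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0))
    stop("probability vectors must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("probability vectors must sum to 1")
  .entropyBits((p + q) / 2) - (.entropyBits(p) + .entropyBits(q)) / 2
}

#' Tissue-specificity score for one tissue
#'
#' \code{1 - sqrt(JSD(p, e_t))} where \code{e_t} is the unit vector for
#' tissue \code{t}: the similarity between a gene's expression density
#' across all tissues and idealised expression in that single tissue. A
#' gene expressed in only one tissue scores exactly 1 there and 0
#' elsewhere.
#'
#' @param p Expression density (from [expressionDensity()]).
#' @param t Tissue index (1-based) or vector of indices.
#' @return Numeric score(s) in [0, 1].
#' @export
specificityScore <- function(p, t = seq_along(p)) {
  vapply(t, function(ti) {
    e <- numeric(length(p)); e[ti] <- 1
    1 - sqrt(jsDivergence(p, e))
  }, numeric(1))
}

#' Score genes for maximal tissue specificity
#'
#' For each gene, replicate samples of a tissue are averaged (mean FPKM),
#' the expression density is formed, and the specificity score is computed
#' against every tissue. The maximal score (the JS score) and its tissue
#' are reported; genes exceeding \code{threshold} are called
#' tissue-specific. All-zero genes are flagged not-evaluable rather than
#' scored. Ties in the argmax break to the lowest tissue index.
#'
#' @param E A \linkS4class{SummarizedExperiment} with assay \code{fpkm} and
#'   a \code{tissue} column in \code{colData}, or a numeric matrix
#'   (genes x samples) with gene-id rownames.
#' @param tissue Character vector assigning each column to a tissue;
#'   defaults to \code{colData(E)$tissue} or, for a matrix, its column
#'   names.
#' @param threshold Specificity call threshold (JS score strictly greater;
#'   default 0.5).
#' @return A data.frame with one row per gene: \code{gene_id},
#'   \code{js_score}, \code{best_tissue}, \code{is_specific},
#'   \code{evaluable}, plus the per-tissue score matrix as attribute
#'   \code{"per_tissue"}.
#' @export
scoreGenes <- function(E, tissue = NULL, threshold = 0.5) {
  if (is(E, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(E, "fpkm")
    if (is.null(tissue))
      tissue <- as.character(SummarizedExperiment::colData(E)$tissue)
  } else {
    m <- as.matrix(E)
    if (is.null(tissue)) tissue <- colnames(m)
  }
  if (is.null(tissue) || length(tissue) != ncol(m))
    stop("'tissue' must assign every sample column to a tissue")
  if (any(m < 0)) stop("FPKM values must be non-negative")
  tf <- factor(tissue, levels = unique(tissue))
  ## replicate averaging: mean FPKM per tissue
  agg <- sapply(levels(tf), function(tl)
    rowMeans(m[, tf == tl, drop = FALSE]))
  if (!is.matrix(agg))
    agg <- matrix(agg, nrow = nrow(m),
                  dimnames = list(rownames(m), levels(tf)))
  rownames(agg) <- rownames(m)
  Tn <- ncol(agg)
  total <- rowSums(agg)
  evaluable <- total > 0
  scores <- matrix(NA_real_, nrow(agg), Tn,
                   dimnames = list(rownames(agg), colnames(agg)))
  if (any(evaluable)) {
    p <- agg[evaluable, , drop = FALSE] / total[evaluable]
    ## vectorised over genes: JSD(p, e_t) per tissue
    Hp <- apply(p, 1L, .entropyBits)
    for (t in seq_len(Tn)) {
      mix <- p / 2
      mix[, t] <- mix[, t] + 0.5
      Hmix <- apply(mix, 1L, .entropyBits)
      scores[evaluable, t] <- 1 - sqrt(pmax(Hmix - Hp / 2, 0))
    }
  }
  best <- apply(scores, 1L, function(s)
    if (all(is.na(s))) NA_integer_ else which.max(s))  # lowest index on ties
  js <- vapply(seq_len(nrow(scores)), function(i)
    if (is.na(best[i])) NA_real_ else scores[i, best[i]], numeric(1))
  res <- data.frame(
    gene_id = rownames(agg),
    js_score = js,
    best_tissue = ifelse(is.na(best), NA_character_, colnames(agg)[best]),
    is_specific = !is.na(js) & js > threshold,
    evaluable = evaluable,
    row.names = NULL)
  attr(res, "per_tissue") <- scores
  res
}

#' Nearest protein-coding neighbour of each lincRNA locus
#'
#' For every lincRNA locus, finds the coding locus with minimal gap on the
#' same chromosome (strand ignored); ties break to the leftmost coding
#' locus. LincRNAs on chromosomes without coding loci get an \code{NA}
#' neighbour.
#'
#' @param lincLoci \linkS4class{GRanges} of lincRNA loci with
#'   \code{gene_id}.
#' @param codingLoci \linkS4class{GRanges} of coding loci with
#'   \code{gene_id}.
#' @return data.frame with \code{lincRNA_gene_id}, \code{coding_gene_id}
#'   (\code{NA} when absent) and \code{gap} (bp; \code{NA} when absent).
#' @export
nearestCodingNeighbors <- function(lincLoci, codingLoci) {
  stopifnot(is(lincLoci, "GRanges"), is(codingLoci, "GRanges"))
  out <- data.frame(lincRNA_gene_id = lincLoci$gene_id,
                    coding_gene_id = NA_character_,
                    gap = NA_integer_)
  if (length(codingLoci) == 0L || length(lincLoci) == 0L)
    return(out)
  hit <- distanceToNearest(lincLoci, codingLoci, ignore.strand = TRUE,
                           select = "all")
  if (length(hit) == 0L) return(out)
  df <- data.frame(q = queryHits(hit), s = subjectHits(hit),
                   d = mcols(hit)$distance)
  df$sStart <- start(codingLoci)[df$s]
  df <- df[order(df$q, df$d, df$sStart, df$s), ]
  df <- df[!duplicated(df$q), ]
  out$coding_gene_id[df$q] <- codingLoci$gene_id[df$s]
  out$gap[df$q] <- as.integer(df$d)
  out
}
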