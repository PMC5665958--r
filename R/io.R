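#' @importFrom rtracklayer import export
#' @importFrom utils read.table write.table
#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
NULL

#' Read transcript models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (1-based closed coordinates) into a
#' \linkS4class{TranscriptSet} (internal coordinates are the usual
#' GRanges 1-based closed form; 0-based half-open positions used in text
#' formats are converted at the boundary). Only \code{exon} feature lines
#' are used. The gene biotype is taken from a \code{gene_biotype} (or
#' \code{biotype}) attribute when present and mapped onto
#' \code{coding}/\code{lincRNA}/\code{housekeeping}/\code{other};
#' unannotated transcripts get \code{other}.
#'
#' @param path Path to a GTF file (gzip-transparent).
#' @param source Evidence source recorded for all transcripts
#'   (\code{rnaseq} or \code{annotation}).
#' @return A \linkS4class{TranscriptSet}.
#' @seealso [writeGtf()], [lociOf()]
#' @export
readGtf <- function(path, source = "rnaseq") {
  if (!file.exists(path))
    stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    return(TranscriptSet(GRangesList()))
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("GTF exon lines must carry a transcript_id attribute")
  bt <- if (!is.null(gr$gene_biotype)) gr$gene_biotype
        else if (!is.null(gr$biotype)) gr$biotype
        else rep(NA_character_, length(gr))
  bt <- .normalizeBiotype(bt)
  key <- gr$transcript_id
  o <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[o]; key <- key[o]; bt <- bt[o]
  firsts <- !duplicated(key)
  txid <- key[firsts]
  gid <- if (!is.null(gr$gene_id)) gr$gene_id[firsts] else txid
  gid[is.na(gid)] <- txid[is.na(gid)]
  exons <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr))
  grl <- split(exons, factor(key, levels = txid))
  TranscriptSet(grl, gene_id = gid, biotype = bt[firsts], source = source)
}

.normalizeBiotype <- function(bt) {
  out <- rep("other", length(bt))
  out[bt %in% c("protein_coding", "coding")] <- "coding"
  out[bt %in% c("lincRNA", "lncRNA")] <- "lincRNA"
  out[bt %in% c("housekeeping", "tRNA", "snRNA", "snoRNA",
                "rRNA", "Mt_tRNA", "Mt_rRNA")] <- "housekeeping"
  out
}

#' Write a TranscriptSet to a GTF file
#'
#' Emits one \code{exon} line per exon with \code{gene_id},
#' \code{transcript_id} and \code{gene_biotype} attributes, 1-based closed
#' coordinates. \code{readGtf(writeGtf(x))} reproduces coordinates exactly.
#'
#' @param x A \linkS4class{TranscriptSet}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(x, path) {
  stopifnot(is(x, "TranscriptSet"))
  gr <- unlist(x@exons, use.names = FALSE)
  n <- elementNROWS(x@exons)
  mcols(gr) <- DataFrame(
    type = rep("exon", length(gr)),
    source = factor(rep("lincRNAkit", length(gr))),
    gene_id = rep(x@txData$gene_id, n),
    transcript_id = rep(x@txData$transcript_id, n),
    gene_biotype = rep(x@txData$biotype, n))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a Bismark-style cytosine report
#'
#' Expects a headerless TSV with columns chromosome, 1-based position,
#' strand, count methylated, count unmethylated (additional context columns
#' are ignored). Positions are converted to the internal representation;
#' counts are preserved exactly.
#'
#' @param path Path to the report (gzip-transparent).
#' @return A \linkS4class{MethylationCalls} object.
#' @seealso [writeMethylationCalls()]
#' @export
readMethylationCalls <- function(path) {
  if (!file.exists(path))
    stop("cytosine report not found: ", path)
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop("malformed cytosine report '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (is.null(df) || nrow(df) == 0L)
    return(MethylationCalls(character(), integer(), "+",
                            integer(), integer()))
  if (ncol(df) < 5L)
    stop("cytosine report must have >= 5 columns ",
         "(chrom, pos, strand, count_m, count_u)")
  m <- as.integer(df[[4]]); u <- as.integer(df[[5]])
  if (anyNA(m) || anyNA(u) || any(m < 0L) || any(u < 0L))
    stop("methylation counts must be non-negative integers")
  MethylationCalls(as.character(df[[1]]), pos = as.integer(df[[2]]) - 1L,
                   strand = as.character(df[[3]]), m = m, u = u)
}

#' Write methylation calls as a cytosine report
#'
#' @param x A \linkS4class{MethylationCalls} object.
#' @param path Output path (\code{.gz} suffix compresses).
#' @return \code{path}, invisibly.
#' @export
writeMethylationCalls <- function(x, path) {
  stopifnot(is(x, "MethylationCalls"))
  gr <- x@calls
  df <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   strand = as.character(strand(gr)), m = gr$m, u = gr$u)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-base coverage track from a bedGraph file
#'
#' bedGraph intervals are 0-based half-open; overlapping intervals within a
#' chromosome are rejected. The result is a run-length encoded per-base
#' depth vector per chromosome; positions absent from the file have depth 0.
#'
#' @param path Path to a bedGraph file (gzip-transparent).
#' @return A named \linkS4class{RleList} of per-base depths.
#' @seealso [trackDepth()], [tssBindingProfile()]
#' @export
readCoverageBedGraph <- function(path) {
  if (!file.exists(path))
    stop("bedGraph file not found: ", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0L)
    return(RleList(compress = FALSE))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L)
    return(RleList(compress = FALSE))
  if (any(gr$score < 0))
    stop("coverage depths must be non-negative")
  hits <- findOverlaps(gr, gr, ignore.strand = TRUE)
  if (any(queryHits(hits) != subjectHits(hits)))
    stop("overlapping intervals in bedGraph: ", path)
  coverage(gr, weight = "score")
}

#' Per-base depth of a coverage track over a region
#'
#' @param track An \linkS4class{RleList} as returned by
#'   [readCoverageBedGraph()].
#' @param chrom Chromosome name.
#' @param start0 0-based inclusive start of the query.
#' @param end0 0-based exclusive end.
#' @return Numeric vector of length \code{end0 - start0}; positions outside
#'   the track (including unknown chromosomes and negative coordinates)
#'   report depth 0.
#' @export
trackDepth <- function(track, chrom, start0, end0) {
  stopifnot(end0 >= start0)
  n <- end0 - start0
  out <- numeric(n)
  if (!chrom %in% names(track))
    return(out)
  r <- track[[chrom]]
  lo <- max(start0 + 1L, 1L)       # 1-based inclusive
  hi <- min(end0, length(r))
  if (hi >= lo)
    out[(lo - start0):(hi - start0)] <- as.numeric(r[lo:hi])
  out
}

#' Write a coverage track as bedGraph
#'
#' @param track An \linkS4class{RleList} of per-base depths.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCoverageBedGraph <- function(track, path) {
  gr <- as(track, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a transcript evidence table
#'
#' TSV with header columns \code{transcript_id}, \code{exon_coverage},
#' \code{junction_reads} (comma-joined integers, one per intron; empty for
#' single-exon models), \code{cpc_score} and optionally \code{source}.
#' Missing values (\code{NA} or empty) yield not-evaluated verdicts in the
#' corresponding filters.
#'
#' @param path Path to the TSV (gzip-transparent).
#' @return A \linkS4class{DataFrame} with columns \code{transcript_id},
#'   \code{exon_coverage}, \code{junction_reads} (an IntegerList),
#'   \code{cpc_score}, \code{source}.
#' @export
readEvidence <- function(path) {
  if (!file.exists(path))
    stop("evidence table not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("transcript_id", "exon_coverage", "junction_reads", "cpc_score")
  if (!all(need %in% colnames(df)))
    stop("evidence table must have columns ",
         paste(need, collapse = ", "))
  jr <- lapply(df$junction_reads, function(s) {
    if (is.na(s) || !nzchar(s)) integer() else
      as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  })
  DataFrame(transcript_id = df$transcript_id,
            exon_coverage = as.numeric(df$exon_coverage),
            junction_reads = IntegerList(jr),
            cpc_score = as.numeric(df$cpc_score),
            source = if ("source" %in% colnames(df)) df$source
                     else rep("rnaseq", nrow(df)))
}

#' Write a transcript evidence table
#'
#' @param ev A \linkS4class{DataFrame} as returned by [readEvidence()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeEvidence <- function(ev, path) {
  df <- data.frame(
    transcript_id = ev$transcript_id,
    exon_coverage = ev$exon_coverage,
    junction_reads = vapply(as.list(ev$junction_reads),
                            paste, character(1), collapse = ","),
    cpc_score = ev$cpc_score,
    source = ev$source)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read housekeeping-RNA BLASTN hits
#'
#' Accepts either a headered TSV with columns \code{transcript_id},
#' \code{evalue}, \code{percent_identity}, or a headerless BLAST
#' outfmt-6 table (12 columns; fields 1, 3 and 11 are query id, percent
#' identity and evalue).
#'
#' @param path Path to the hit table (gzip-transparent).
#' @return A data.frame with columns \code{transcript_id}, \code{evalue},
#'   \code{percent_identity} (zero rows if the file is empty).
#' @export
readHousekeepingHits <- function(path) {
  if (!file.exists(path))
    stop("housekeeping hit table not found: ", path)
  empty <- data.frame(transcript_id = character(),
                      evalue = numeric(), percent_identity = numeric())
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L || !nzchar(first))
    return(empty)
  hasHeader <- grepl("transcript_id", first, fixed = TRUE)
  df <- read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE)
  if (hasHeader) {
    data.frame(transcript_id = df$transcript_id,
               evalue = as.numeric(df$evalue),
               percent_identity = as.numeric(df$percent_identity))
  } else {
    if (ncol(df) < 11L)
      stop("headerless housekeeping hit table must be BLAST outfmt 6")
    data.frame(transcript_id = df[[1]],
               evalue = as.numeric(df[[11]]),
               percent_identity = as.numeric(df[[3]]))
  }
}

#' Read an expression matrix from TSV
#'
#' Genes as rows (first column \code{gene_id}), samples as the remaining
#' columns. Column names of the form \code{tissue.repN} (or
#' \code{tissue_repN}) are parsed into tissue labels for replicate
#' averaging.
#'
#' @param path Path to the TSV (gzip-transparent).
#' @return A \linkS4class{SummarizedExperiment} with assay \code{fpkm}
#'   and a \code{tissue} column in \code{colData}.
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path))
    stop("expression table not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0))
    stop("FPKM values must be non-negative")
  tissue <- sub("[._]rep[0-9]+$", "", colnames(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpkm = m),
    colData = DataFrame(tissue = tissue, row.names = colnames(m)))
}

#' Write an expression matrix to TSV
#'
#' @param se A \linkS4class{SummarizedExperiment} with assay \code{fpkm},
#'   or a plain numeric matrix with gene ids as rownames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(se, path) {
  m <- if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "fpkm") else se
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read DMR intervals from a BED-like TSV
#'
#' Columns: chrom, start (0-based), end (exclusive), then optionally
#' \code{n_cpg}, \code{mean_level_group1}, \code{mean_level_group2},
#' \code{score}. A header line starting with \code{chrom} is permitted.
#'
#' @param path Path to the file (gzip-transparent).
#' @return An unstranded \linkS4class{GRanges} with a \code{dmr_id} column
#'   plus any extra columns present.
#' @export
readDmrBed <- function(path) {
  if (!file.exists(path))
    stop("DMR file not found: ", path)
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (length(first) == 0L || !nzchar(first))
    return(GRanges(dmr_id = character()))
  hasHeader <- grepl("^chrom", first)
  df <- read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE)
  cn <- c("chrom", "start", "end", "n_cpg",
          "mean_level_group1", "mean_level_group2", "score")
  if (!hasHeader)
    colnames(df) <- cn[seq_len(ncol(df))]
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  gr$dmr_id <- if ("dmr_id" %in% colnames(df)) df$dmr_id else
    sprintf("dmr%04d", seq_len(nrow(df)))
  for (col in c("n_cpg", "mean_level_group1", "mean_level_group2", "score"))
    if (col %in% colnames(df)) mcols(gr)[[col]] <- df[[col]]
  gr
}

#' Write DMR intervals to a BED-like TSV
#'
#' @param dmrs A \linkS4class{GRanges} of DMRs (e.g. from
#'   [callDmrsNaive()]).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDmrBed <- function(dmrs, path) {
  df <- data.frame(chrom = as.character(seqnames(dmrs)),
                   start = start(dmrs) - 1L, end = end(dmrs))
  for (col in c("n_cpg", "mean_level_group1", "mean_level_group2", "score"))
    if (col %in% colnames(mcols(dmrs)))
      df[[col]] <- signif(as.numeric(mcols(dmrs)[[col]]), 6)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a MetaProfile to TSV
#'
#' Columns: \code{bin_index}, \code{offset_bp} (bin start relative to the
#' TSS), \code{value} (6 significant digits), \code{n}.
#'
#' @param profile A \linkS4class{MetaProfile}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeProfileTsv <- function(profile, path) {
  df <- data.frame(bin_index = seq_along(profileValues(profile)),
                   offset_bp = profileOffsets(profile),
                   value = signif(profileValues(profile), 6),
                   n = nTranscripts(profile))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
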