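#' Read a genome FASTA
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the first word of each
#'   FASTA header.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read spliced alignments from a SAM file
#'
#' Loads mapped records of a SAM file into the flat alignment table consumed
#' by [extract_junctions()] and [count_junction_reads()]. Mismatch counts are
#' taken from the `NM` tag (0 when absent). A read is flagged unique when its
#' `NH` tag is 1 (or absent) and the record is not secondary.
#'
#' @param path Path to a SAM (or BAM) file with a valid header.
#' @return A data.frame with columns `read_id`, `chrom`, `pos` (1-based
#'   leftmost mapped position), `cigar`, `mismatch_count`, `is_unique`.
#' @export
read_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "flag"),
    tag = c("NM", "NH"), flag = flag)
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  nm <- x$tag$NM
  nh <- x$tag$NH
  n <- length(x$qname)
  if (is.null(nm)) nm <- integer(n)
  if (is.null(nh)) nh <- rep(1L, n)
  nm[is.na(nm)] <- 0L
  nh[is.na(nh)] <- 1L
  secondary <- bitwAnd(x$flag, 256L) > 0L
  data.frame(
    read_id = x$qname,
    chrom = as.character(x$rname),
    pos = x$pos,
    cigar = x$cigar,
    mismatch_count = as.integer(nm),
    is_unique = nh == 1L & !secondary,
    stringsAsFactors = FALSE)
}

#' Read a gene annotation (GTF/GFF3)
#'
#' Imports `exon`, `start_codon` and `stop_codon` features and organises them
#' by gene. Annotated introns are derived from consecutive exons of each
#' transcript.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return An object of class `gene_annotation`: a list with data.frames
#'   `exons` (`gene_id`, `transcript_id`, `chrom`, `start`, `end`, `strand`),
#'   `start_codons`, `stop_codons` (same columns minus `transcript_id`),
#'   `genes` (`gene_id`, `chrom`, `strand`) and `introns` (annotated introns:
#'   `chrom`, `intron_start`, `intron_end`, `strand`, `gene_id`).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (is.null(df$gene_id)) stop("annotation lacks gene_id attributes")
  if (is.null(df$transcript_id)) df$transcript_id <- df$gene_id
  df$type <- as.character(df$type)
  take <- function(what, tx = TRUE) {
    y <- df[df$type == what,
            c("gene_id", "transcript_id", "seqnames", "start", "end", "strand")]
    names(y)[3] <- "chrom"
    y$chrom <- as.character(y$chrom)
    y$strand <- as.character(y$strand)
    rownames(y) <- NULL
    if (!tx) y$transcript_id <- NULL
    y
  }
  ann <- list(
    exons = take("exon"),
    start_codons = take("start_codon", tx = FALSE),
    stop_codons = take("stop_codon", tx = FALSE))
  ann$genes <- unique(ann$exons[, c("gene_id", "chrom", "strand")])
  rownames(ann$genes) <- NULL
  ann$introns <- derive_annotated_introns(ann$exons)
  class(ann) <- "gene_annotation"
  ann
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$introns), "annotated introns\n")
  invisible(x)
}

# Introns implied by consecutive exons of each transcript.
derive_annotated_introns <- function(exons) {
  ord <- order(exons$transcript_id, exons$start)
  ex <- exons[ord, ]
  same_tx <- ex$transcript_id[-1] == ex$transcript_id[-nrow(ex)]
  i <- which(c(same_tx, FALSE))
  out <- data.frame(
    chrom = ex$chrom[i],
    intron_start = ex$end[i] + 1L,
    intron_end = ex$start[i + 1L] - 1L,
    strand = ex$strand[i],
    gene_id = ex$gene_id[i],
    stringsAsFactors = FALSE)
  out <- out[out$intron_end >= out$intron_start, , drop = FALSE]
  unique(out)
}

#' Write / read an intron table
#'
#' The intron table is a TSV whose first line is a comment documenting the
#' coordinate convention (1-based, inclusive; `intron_start` = first intronic
#' base). [read_intron_table()] is the exact inverse of
#' [write_intron_table()].
#'
#' @param introns A data.frame as produced by [detect_introns()] or
#'   [quantify_introns()].
#' @param path Output (input) file path.
#' @return `write_intron_table()` returns `path` invisibly;
#'   `read_intron_table()` returns the data.frame.
#' @export
write_intron_table <- function(introns, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# splicedrift intron table; coordinates 1-based inclusive;",
                   "intron_start = first intronic base"), con)
  write.table(introns, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intron_table
#' @export
read_intron_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read SNP positions from a VCF
#'
#' Only chromosome and position are used; indels (REF or ALT longer than one
#' base) are ignored, and multi-allelic records count once.
#'
#' @param path Path to a VCF file.
#' @return A data.frame with columns `chrom` and `pos` (unique positions).
#' @export
read_snp_positions <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alt1 <- vapply(strsplit(fix$ALT, ","), function(a) max(nchar(a)), 1)
  keep <- nchar(fix$REF) == 1L & alt1 == 1L
  unique(data.frame(chrom = fix$CHROM[keep],
                    pos = as.integer(fix$POS[keep]),
                    stringsAsFactors = FALSE))
}

#' Write synthetic alignments as SAM
#'
#' @param aln Alignment table in the [read_sam()] schema.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, seqlengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  if (nrow(aln)) {
    writeLines(sprintf(
      "%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*\tNM:i:%d\tNH:i:%d",
      aln$read_id, aln$chrom, aln$pos, aln$cigar, aln$mismatch_count,
      ifelse(aln$is_unique, 1L, 2L)), con)
  }
  invisible(path)
}

#' Write SNPs as a minimal VCF
#'
#' @param snps Data.frame with `chrom`, `pos` and optionally `ref`, `alt`.
#' @param seqlengths Named integer vector of contig lengths.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, seqlengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(sprintf("##contig=<ID=%s,length=%d>", names(seqlengths),
                     as.integer(seqlengths)), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(snps)) {
    ref <- if (is.null(snps$ref)) rep("A", nrow(snps)) else snps$ref
    alt <- if (is.null(snps$alt)) rep("T", nrow(snps)) else snps$alt
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       snps$chrom, snps$pos, ref, alt), con)
  }
  invisible(path)
}

#' Write an annotation table as GTF
#'
#' @param features Data.frame with `chrom`, `start`, `end`, `strand`, `type`,
#'   `gene_id`, `transcript_id`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$source <- "splicedrift"
  S4Vectors::mcols(gr)$gene_id <- features$gene_id
  S4Vectors::mcols(gr)$transcript_id <- features$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
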