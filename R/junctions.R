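#' Extract splice-junction evidence from spliced alignments
#'
#' Scans CIGAR strings for `N` operations (skipped reference, i.e. candidate
#' introns) and emits one evidence record per `N` op of every retained read.
#' A read contributes nothing if it is not uniquely mapped or if its mismatch
#' ratio (`mismatch_count` / aligned M bases) exceeds `max_mismatch_ratio`;
#' an individual junction is dropped if either anchor (the number of M-op
#' bases aligned between the junction and the read end or the neighbouring
#' `N` op on that side) is shorter than `min_anchor`, or if the intron is
#' longer than `max_intron_len`.
#'
#' @param alignments Alignment table in the [read_sam()] schema (`read_id`,
#'   `chrom`, `pos`, `cigar`, `mismatch_count`, `is_unique`).
#' @param min_anchor Minimum anchor length in bp on each side (8 for intron
#'   detection, 5 for quantification).
#' @param max_intron_len Maximum intron length in bp.
#' @param max_mismatch_ratio Maximum per-read mismatch ratio.
#' @return A data.frame of junction evidence: `chrom`, `intron_start` (first
#'   intronic base, 1-based), `intron_end` (last intronic base),
#'   `left_anchor`, `right_anchor`, `read_id`.
#' @examples
#' aln <- data.frame(read_id = "r1", chrom = "chr1", pos = 101,
#'                   cigar = "50M100N50M", mismatch_count = 0,
#'                   is_unique = TRUE)
#' extract_junctions(aln)  # intron 151..250, anchors 50/50
#' @export
extract_junctions <- function(alignments, min_anchor = 8L,
                              max_intron_len = 2000000L,
                              max_mismatch_ratio = 0.02) {
  stopifnot(min_anchor >= 1L, max_intron_len >= 1L)
  empty <- data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), left_anchor = integer(),
                      right_anchor = integer(), read_id = character(),
                      stringsAsFactors = FALSE)
  aln <- as.data.frame(alignments)
  if (!nrow(aln)) return(empty)
  ok_cigar <- grepl("^([0-9]+[MIDNS])+$", aln$cigar)
  if (any(!ok_cigar)) {
    warning(sum(!ok_cigar),
            " alignment(s) with malformed or unsupported CIGAR dropped")
    aln <- aln[ok_cigar, , drop = FALSE]
  }
  aln <- aln[aln$is_unique & grepl("N", aln$cigar, fixed = TRUE), ,
             drop = FALSE]
  if (!nrow(aln)) return(empty)

  ops_l <- GenomicAlignments::explodeCigarOps(aln$cigar)
  len_l <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)
  nop <- lengths(ops_l)
  read_idx <- rep.int(seq_len(nrow(aln)), nop)
  op <- unlist(ops_l, use.names = FALSE)
  len <- unlist(len_l, use.names = FALSE)
  if (any(len <= 0L)) {
    bad <- unique(read_idx[len <= 0L])
    warning(length(bad), " alignment(s) with non-positive CIGAR length dropped")
    keep <- !(read_idx %in% bad)
    op <- op[keep]; len <- len[keep]; read_idx <- read_idx[keep]
  }
  if (!length(op)) return(empty)

  mlen <- ifelse(op == "M", len, 0L)
  msum_read <- rowsum(mlen, read_idx)
  aligned_length <- msum_read[, 1L]
  ridx <- as.integer(rownames(msum_read))
  keep_read <- aligned_length > 0L &
    aln$mismatch_count[ridx] / pmax(aligned_length, 1L) <= max_mismatch_ratio
  good_reads <- ridx[keep_read]
  sel <- read_idx %in% good_reads
  op <- op[sel]; len <- len[sel]; read_idx <- read_idx[sel]
  mlen <- mlen[sel]
  if (!length(op)) return(empty)

  is_n <- op == "N"
  # segment = index of the inter-N stretch an op belongs to (0-based); an N op
  # separates segment j-1 (its left anchor) from segment j (its right anchor)
  n_before <- stats::ave(as.integer(is_n), read_idx, FUN = cumsum)
  seg <- n_before - as.integer(is_n)
  K <- max(seg) + 2L
  gid <- as.numeric(read_idx) * K + seg
  msum <- rowsum(mlen, gid)
  mlook <- setNames(msum[, 1L], rownames(msum))
  key <- function(r, s) as.character(as.numeric(r) * K + s)

  rlen <- ifelse(op %in% c("M", "D", "N"), len, 0L)
  ref_before <- stats::ave(rlen, read_idx, FUN = cumsum) - rlen

  nsel <- which(is_n)
  left <- mlook[key(read_idx[nsel], seg[nsel])]
  right <- mlook[key(read_idx[nsel], seg[nsel] + 1L)]
  left[is.na(left)] <- 0L
  right[is.na(right)] <- 0L
  intron_start <- aln$pos[read_idx[nsel]] + ref_before[nsel]
  out <- data.frame(
    chrom = aln$chrom[read_idx[nsel]],
    intron_start = as.integer(intron_start),
    intron_end = as.integer(intron_start + len[nsel] - 1L),
    left_anchor = as.integer(left),
    right_anchor = as.integer(right),
    read_id = aln$read_id[read_idx[nsel]],
    stringsAsFactors = FALSE)
  out <- out[out$left_anchor >= min_anchor & out$right_anchor >= min_anchor &
               (out$intron_end - out$intron_start + 1L) <= max_intron_len, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Accepted splice signals: dinucleotide pairs on the forward genome and the
# strand/signal they imply.
.signal_table <- data.frame(
  din5 = c("GT", "GC", "AT", "CT", "CT", "GT"),
  din3 = c("AG", "AG", "AC", "AC", "GC", "AT"),
  strand = c("+", "+", "+", "-", "-", "-"),
  signal = c("GT-AG", "GC-AG", "AT-AC", "GT-AG", "GC-AG", "AT-AC"),
  stringsAsFactors = FALSE)

#' Validate splice signals and infer intron strand
#'
#' Keeps junctions whose first two and last two intronic bases match one of
#' the accepted splice signals (GT-AG, GC-AG, AT-AC) on either strand, and
#' infers the strand from the signal: forward bases `GT..AG` / `GC..AG` /
#' `AT..AC` imply `+`; their reverse complements (`CT..AC`, `CT..GC`,
#' `GT..AT`) imply `-`.
#'
#' @param junctions Data.frame with `chrom`, `intron_start`, `intron_end`
#'   (junction evidence or a unique-intron table).
#' @param genome A named [Biostrings::DNAStringSet].
#' @return The accepted rows of `junctions` with `strand` and `signal`
#'   columns added; non-matching junctions are dropped.
#' @export
validate_splice_signal <- function(junctions, genome) {
  jx <- as.data.frame(junctions)
  if (!nrow(jx)) {
    jx$strand <- character()
    jx$signal <- character()
    return(jx)
  }
  missing_chrom <- setdiff(unique(jx$chrom), names(genome))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  din5 <- character(nrow(jx))
  din3 <- character(nrow(jx))
  for (ch in unique(jx$chrom)) {
    i <- which(jx$chrom == ch)
    chseq <- as.character(genome[[ch]])
    L <- nchar(chseq)
    if (any(jx$intron_start[i] < 1L | jx$intron_end[i] > L |
              jx$intron_start[i] > jx$intron_end[i]))
      stop("junction coordinates outside chromosome ", ch)
    din5[i] <- substring(chseq, jx$intron_start[i], jx$intron_start[i] + 1L)
    din3[i] <- substring(chseq, jx$intron_end[i] - 1L, jx$intron_end[i])
  }
  m <- match(paste(din5, din3), paste(.signal_table$din5, .signal_table$din3))
  keep <- !is.na(m)
  out <- jx[keep, , drop = FALSE]
  out$strand <- .signal_table$strand[m[keep]]
  out$signal <- .signal_table$signal[m[keep]]
  rownames(out) <- NULL
  out
}

#' Assign introns to annotated genes
#'
#' An intron is assigned to a gene if either intron boundary falls within
#' `tolerance_bp` of any annotated exon start/end coordinate of that gene
#' (union over isoforms). The candidate gene set is the union over both
#' boundaries; introns matched by more than one gene are flagged ambiguous
#' (and excluded from downstream analyses), introns matched by none are
#' unassigned.
#'
#' @param introns Data.frame with `chrom`, `intron_start`, `intron_end`.
#' @param annotation A `gene_annotation` from [read_annotation()].
#' @param tolerance_bp Matching tolerance in bp (default 1).
#' @return `introns` with columns `gene_id` (NA unless uniquely assigned) and
#'   `gene_status` (`assigned`, `ambiguous`, `unassigned`).
#' @export
assign_to_gene <- function(introns, annotation, tolerance_bp = 1L) {
  introns <- as.data.frame(introns)
  introns$gene_id <- NA_character_
  introns$gene_status <- rep("unassigned", nrow(introns))
  if (!nrow(introns)) return(introns)
  ex <- annotation$exons
  coords <- unique(data.frame(
    chrom = c(ex$chrom, ex$chrom),
    pos = c(ex$start, ex$end),
    gene_id = c(ex$gene_id, ex$gene_id),
    stringsAsFactors = FALSE))
  for (ch in unique(introns$chrom)) {
    ci <- which(introns$chrom == ch)
    cc <- coords[coords$chrom == ch, , drop = FALSE]
    if (!nrow(cc)) next
    subj <- IRanges::IRanges(cc$pos - tolerance_bp, cc$pos + tolerance_bp)
    qry <- IRanges::IRanges(c(introns$intron_start[ci], introns$intron_end[ci]),
                            width = 1L)
    hits <- IRanges::findOverlaps(qry, subj)
    if (!length(hits)) next
    intron_of <- rep(ci, 2L)[S4Vectors::queryHits(hits)]
    gene_of <- cc$gene_id[S4Vectors::subjectHits(hits)]
    sets <- split(gene_of, intron_of)
    ng <- vapply(sets, function(g) length(unique(g)), 1L)
    idx <- as.integer(names(sets))
    introns$gene_status[idx] <- ifelse(ng == 1L, "assigned", "ambiguous")
    one <- ng == 1L
    introns$gene_id[idx[one]] <-
      vapply(sets[one], function(g) g[[1L]], "")
  }
  introns
}

#' Flag introns that match the annotation exactly
#'
#' An intron is "annotated" iff both boundaries coincide exactly with an
#' intron derived from the annotated exon structure (same chromosome and
#' strand).
#'
#' @param introns Data.frame with `chrom`, `intron_start`, `intron_end`,
#'   `strand`.
#' @param annotation A `gene_annotation`.
#' @return `introns` with a logical `annotated` column added.
#' @export
mark_annotated <- function(introns, annotation) {
  introns <- as.data.frame(introns)
  ai <- annotation$introns
  key <- function(d) paste(d$chrom, d$intron_start, d$intron_end, d$strand)
  introns$annotated <- key(introns) %in% key(ai)
  introns
}

#' Restrict introns to the CDS span of their gene
#'
#' For each gene the extreme coding coordinates are taken across all
#' annotated isoforms, orientation-aware: the transcription-wise first start
#' codon and last stop codon. Introns whose both boundaries lie between
#' these coordinates are flagged `in_cds_span`; an intron straddling or
#' outside them is not. Genes lacking start or stop codons have all their
#' introns flagged out-of-span with a warning.
#'
#' @param introns Data.frame with `chrom`, `intron_start`, `intron_end`,
#'   `gene_id`.
#' @param annotation A `gene_annotation`.
#' @param drop If `TRUE` (default) return only in-span introns, else return
#'   all rows with the `in_cds_span` flag.
#' @return The (optionally filtered) intron table with an `in_cds_span`
#'   column.
#' @export
restrict_to_cds_span <- function(introns, annotation, drop = TRUE) {
  introns <- as.data.frame(introns)
  introns$in_cds_span <- rep(FALSE, nrow(introns))
  if (!nrow(introns)) return(introns)
  genes <- unique(introns$gene_id)
  genes <- genes[!is.na(genes)]
  missing_codons <- character()
  for (g in genes) {
    sc <- annotation$start_codons[annotation$start_codons$gene_id == g, ,
                                  drop = FALSE]
    tc <- annotation$stop_codons[annotation$stop_codons$gene_id == g, ,
                                 drop = FALSE]
    i <- which(introns$gene_id == g)
    if (!nrow(sc) || !nrow(tc)) {
      missing_codons <- c(missing_codons, g)
      next
    }
    strand <- annotation$genes$strand[match(g, annotation$genes$gene_id)]
    if (identical(strand, "-")) {
      lo <- min(tc$start)
      hi <- max(sc$end)
    } else {
      lo <- min(sc$start)
      hi <- max(tc$end)
    }
    introns$in_cds_span[i] <- introns$intron_start[i] >= lo &
      introns$intron_end[i] <= hi
  }
  if (length(missing_codons))
    warning("gene(s) without annotated start/stop codons, introns flagged ",
            "out of CDS span: ", paste(missing_codons, collapse = ", "))
  if (drop) introns[introns$in_cds_span, , drop = FALSE] else introns
}

#' Detect and annotate introns from spliced alignments
#'
#' Full junction-extraction pipeline: extract junction evidence with the
#' detection anchor, collapse to unique introns, validate splice signals and
#' infer strands, assign introns to genes (ambiguous and unassigned introns
#' are excluded), flag annotated introns and restrict to CDS spans.
#'
#' @param alignments Alignment table from [read_sam()].
#' @param genome A named [Biostrings::DNAStringSet].
#' @param annotation A `gene_annotation` from [read_annotation()].
#' @param min_anchor_detect Detection anchor length in bp (default 8).
#' @param max_intron_len,max_mismatch_ratio Passed to [extract_junctions()].
#' @param cds_only If `TRUE` (default), keep only introns inside their
#'   gene's CDS span.
#' @return An intron table: `chrom`, `intron_start`, `intron_end`, `strand`,
#'   `signal`, `gene_id`, `annotated`, `in_cds_span`, `n_detect` (number of
#'   supporting reads at the detection anchor). Coordinates are 1-based
#'   inclusive.
#' @export
detect_introns <- function(alignments, genome, annotation,
                           min_anchor_detect = 8L, max_intron_len = 2000000L,
                           max_mismatch_ratio = 0.02, cds_only = TRUE) {
  ev <- extract_junctions(alignments, min_anchor = min_anchor_detect,
                          max_intron_len = max_intron_len,
                          max_mismatch_ratio = max_mismatch_ratio)
  key <- paste(ev$chrom, ev$intron_start, ev$intron_end)
  cnt <- table(key)
  uq <- ev[!duplicated(key), c("chrom", "intron_start", "intron_end"),
           drop = FALSE]
  uq$n_detect <- as.integer(cnt[paste(uq$chrom, uq$intron_start,
                                      uq$intron_end)])
  uq <- validate_splice_signal(uq, genome)
  uq <- assign_to_gene(uq, annotation)
  uq <- uq[uq$gene_status == "assigned", , drop = FALSE]
  uq$gene_status <- NULL
  uq <- mark_annotated(uq, annotation)
  uq <- restrict_to_cds_span(uq, annotation, drop = cds_only)
  uq <- uq[, c("chrom", "intron_start", "intron_end", "strand", "signal",
               "gene_id", "annotated", "in_cds_span", "n_detect")]
  rownames(uq) <- NULL
  uq
}
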