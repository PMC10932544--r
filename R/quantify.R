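#' Count spliced, alternative and unspliced reads per intron
#'
#' For each focal intron computes the junction-read counts of Fig.-2 type
#' AS quantification:
#' * `Ns` — spliced reads excising exactly the focal intron (both boundaries
#'   match, anchors >= `quant_anchor`);
#' * `Na` — spliced reads sharing exactly one boundary with the focal intron;
#' * `Nu` — unspliced reads, co-linear with the genome (no `N` op), whose
#'   aligned span covers at least `retention_overlap` bp on each side of an
#'   exon-intron boundary, summed over the two boundaries.
#'
#' Reads failing the uniqueness or mismatch-ratio filters are excluded from
#' all three counts.
#'
#' @param introns Intron table with `chrom`, `intron_start`, `intron_end`.
#' @param alignments Alignment table from [read_sam()].
#' @param quant_anchor Quantification anchor length in bp (default 5).
#' @param retention_overlap Minimum aligned bp on each side of a boundary
#'   for a retention read (default 10).
#' @param max_intron_len,max_mismatch_ratio Passed to [extract_junctions()].
#' @return `introns` with integer columns `Ns`, `Na`, `Nu` added.
#' @export
count_junction_reads <- function(introns, alignments, quant_anchor = 5L,
                                 retention_overlap = 10L,
                                 max_intron_len = 2000000L,
                                 max_mismatch_ratio = 0.02) {
  introns <- as.data.frame(introns)
  ev <- extract_junctions(alignments, min_anchor = quant_anchor,
                          max_intron_len = max_intron_len,
                          max_mismatch_ratio = max_mismatch_ratio)
  jkey <- paste(ev$chrom, ev$intron_start, ev$intron_end)
  jcnt <- table(jkey)
  dcnt <- table(paste(ev$chrom, ev$intron_start))
  acnt <- table(paste(ev$chrom, ev$intron_end))
  k <- paste(introns$chrom, introns$intron_start, introns$intron_end)
  ns <- as.integer(jcnt[k])
  ns[is.na(ns)] <- 0L
  dtot <- as.integer(dcnt[paste(introns$chrom, introns$intron_start)])
  atot <- as.integer(acnt[paste(introns$chrom, introns$intron_end)])
  dtot[is.na(dtot)] <- 0L
  atot[is.na(atot)] <- 0L
  introns$Ns <- ns
  introns$Na <- dtot + atot - 2L * ns

  # retention: unspliced (N-free) reads passing the same read-level filters
  aln <- as.data.frame(alignments)
  aln <- aln[grepl("^([0-9]+[MIDS])+$", aln$cigar) & aln$is_unique, ,
             drop = FALSE]
  introns$Nu <- 0L
  if (nrow(aln)) {
    # M-only aligned length for the mismatch ratio
    mono <- vapply(GenomicAlignments::explodeCigarOpLengths(aln$cigar,
                                                            ops = "M"),
                   sum, integer(1))
    keep <- mono > 0L & aln$mismatch_count / pmax(mono, 1L) <= max_mismatch_ratio
    aln <- aln[keep, , drop = FALSE]
  }
  if (nrow(aln)) {
    rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
    for (ch in unique(introns$chrom)) {
      ci <- which(introns$chrom == ch)
      ai <- which(aln$chrom == ch)
      if (!length(ai)) next
      spans <- IRanges::IRanges(aln$pos[ai], width = rw[ai])
      s <- introns$intron_start[ci]
      e <- introns$intron_end[ci]
      donor_win <- IRanges::IRanges(s - retention_overlap,
                                    s + retention_overlap - 1L)
      accept_win <- IRanges::IRanges(e - retention_overlap + 1L,
                                     e + retention_overlap)
      introns$Nu[ci] <-
        IRanges::countOverlaps(donor_win, spans, type = "within") +
        IRanges::countOverlaps(accept_win, spans, type = "within")
    }
  }
  introns
}

#' Compute RAS and RANS splicing ratios
#'
#' `RAS = Ns / (Ns + Na)` measures the relative abundance of the focal
#' intron against spliced variants sharing one boundary; `RANS = Ns /
#' (Ns + Nu/2)` measures it against unspliced (retention) reads. `Nu` is
#' halved because retention is quantified at both boundaries. Each ratio is
#' only defined when its denominator reaches `min_denominator` reads
#' (`Nu/2` enters as an exact real value); undefined ratios are `NA`.
#'
#' @param counts Data.frame with `Ns`, `Na`, `Nu` (e.g. from
#'   [count_junction_reads()]).
#' @param min_denominator Minimum denominator read count (default 10).
#' @return `counts` with numeric columns `RAS` and `RANS` added.
#' @export
compute_ratios <- function(counts, min_denominator = 10) {
  counts <- as.data.frame(counts)
  stopifnot(all(counts$Ns >= 0), all(counts$Na >= 0), all(counts$Nu >= 0))
  denom_ras <- counts$Ns + counts$Na
  denom_rans <- counts$Ns + counts$Nu / 2
  counts$RAS <- ifelse(denom_ras >= min_denominator,
                       counts$Ns / denom_ras, NA_real_)
  counts$RANS <- ifelse(denom_rans >= min_denominator,
                        counts$Ns / denom_rans, NA_real_)
  counts
}

#' Classify introns as major, minor or unclassified
#'
#' Major-isoform introns have both ratios defined and `RAS > 0.5` and
#' `RANS > 0.5`; minor-isoform introns have at least one defined ratio
#' `<= 0.5`; all remaining introns (e.g. both ratios undefined, or one
#' undefined and the other `> 0.5`) are unclassified.
#'
#' @param ratios Data.frame with `RAS` and `RANS` columns (NA = undefined).
#' @return `ratios` with a character column `class` added
#'   (`"major"`/`"minor"`/`"unclassified"`).
#' @export
classify_introns <- function(ratios) {
  ratios <- as.data.frame(ratios)
  ras <- ratios$RAS
  rans <- ratios$RANS
  minor <- (!is.na(ras) & ras <= 0.5) | (!is.na(rans) & rans <= 0.5)
  major <- !is.na(ras) & !is.na(rans) & ras > 0.5 & rans > 0.5
  cls <- rep("unclassified", nrow(ratios))
  cls[minor] <- "minor"
  cls[major] <- "major"
  ratios$class <- cls
  ratios
}

#' Quantify introns: counts, ratios and classification
#'
#' Convenience pipeline combining [count_junction_reads()],
#' [compute_ratios()] and [classify_introns()].
#'
#' @inheritParams count_junction_reads
#' @param min_denominator Passed to [compute_ratios()].
#' @return The intron table with `Ns`, `Na`, `Nu`, `RAS`, `RANS`, `class`.
#' @export
quantify_introns <- function(introns, alignments, quant_anchor = 5L,
                             retention_overlap = 10L, min_denominator = 10,
                             max_intron_len = 2000000L,
                             max_mismatch_ratio = 0.02) {
  q <- count_junction_reads(introns, alignments, quant_anchor,
                            retention_overlap, max_intron_len,
                            max_mismatch_ratio)
  classify_introns(compute_ratios(q, min_denominator))
}

#' Link minor-isoform introns to major-isoform introns
#'
#' A minor-isoform intron is linked to a major-isoform intron when the two
#' share exactly one boundary coordinate on the same chromosome and strand.
#' A minor intron shared between two major introns is linked to each
#' independently. The non-shared boundary defines the link's `offset`
#' (absolute bp distance to the corresponding major boundary) and `location`
#' (`"intronic"` if it lies inside the major intron, `"exonic"` otherwise);
#' `shared_side` names the shared splice site strand-aware (`"donor"` =
#' 5' site).
#'
#' @param quant Classified intron table from [quantify_introns()] (needs
#'   `chrom`, `intron_start`, `intron_end`, `strand`, `class`, `Ns`).
#' @return A link table with one row per (major, minor) pair: major and
#'   minor coordinates, `gene_id` (if present), `Nim` (spliced-read count of
#'   the minor intron), `shared_side`, `offset`, `location`.
#' @export
link_minor_variants <- function(quant) {
  quant <- as.data.frame(quant)
  quant$.row <- seq_len(nrow(quant))
  maj <- quant[quant$class == "major", , drop = FALSE]
  mnr <- quant[quant$class == "minor", , drop = FALSE]
  empty <- data.frame(
    major_row = integer(), minor_row = integer(), chrom = character(),
    strand = character(), major_start = integer(), major_end = integer(),
    minor_start = integer(), minor_end = integer(), gene_id = character(),
    Nim = integer(), shared_side = character(), offset = integer(),
    location = character(), stringsAsFactors = FALSE)
  if (!nrow(maj) || !nrow(mnr)) return(empty)
  gid <- function(d) if (is.null(d$gene_id)) NA_character_ else d$gene_id
  mk <- function(M, m, shared_start) {
    if (!nrow(M)) return(empty)
    off <- if (shared_start) abs(m$intron_end - M$intron_end) else
      abs(m$intron_start - M$intron_start)
    free <- if (shared_start) m$intron_end else m$intron_start
    loc <- ifelse(free >= M$intron_start & free <= M$intron_end,
                  "intronic", "exonic")
    side <- if (shared_start) ifelse(M$strand == "-", "acceptor", "donor")
    else ifelse(M$strand == "-", "donor", "acceptor")
    data.frame(
      major_row = M$.row, minor_row = m$.row, chrom = M$chrom,
      strand = M$strand, major_start = M$intron_start,
      major_end = M$intron_end, minor_start = m$intron_start,
      minor_end = m$intron_end, gene_id = gid(M), Nim = m$Ns,
      shared_side = side, offset = as.integer(off), location = loc,
      stringsAsFactors = FALSE)
  }
  join <- function(shared_start) {
    bcol <- if (shared_start) "intron_start" else "intron_end"
    other <- if (shared_start) "intron_end" else "intron_start"
    key_m <- paste(maj$chrom, maj$strand, maj[[bcol]])
    key_n <- paste(mnr$chrom, mnr$strand, mnr[[bcol]])
    hit <- match(key_n, key_m)
    ok <- which(!is.na(hit))
    if (!length(ok)) return(empty)
    M <- maj[hit[ok], , drop = FALSE]
    m <- mnr[ok, , drop = FALSE]
    keep <- m[[other]] != M[[other]]
    mk(M[keep, , drop = FALSE], m[keep, , drop = FALSE], shared_start)
  }
  out <- rbind(join(TRUE), join(FALSE))
  rownames(out) <- NULL
  out
}

#' Per-major-intron AS rate and minor-variant MIRA
#'
#' For each major-isoform intron, `NM` is its own spliced-read count, `Nm`
#' the summed spliced-read counts of its linked minor-isoform introns,
#' `AS = Nm / (NM + Nm)` its AS rate, and each minor variant's
#' `MIRA = Nim / (NM + Nm)`; the MIRAs of a major intron sum exactly to its
#' AS.
#'
#' @param quant Classified intron table from [quantify_introns()].
#' @param links Optional precomputed link table from
#'   [link_minor_variants()].
#' @return A list with `majors` (the major-intron rows plus `NM`, `Nm`,
#'   `AS`; `AS` is `NA` when `NM + Nm = 0`) and `links` (the link table plus
#'   `MIRA`).
#' @export
quantify_major_introns <- function(quant, links = NULL) {
  quant <- as.data.frame(quant)
  quant$.row <- seq_len(nrow(quant))
  if (is.null(links)) links <- link_minor_variants(quant)
  majors <- quant[quant$class == "major", , drop = FALSE]
  nm <- rowsum(links$Nim, links$major_row)
  majors$NM <- majors$Ns
  majors$Nm <- 0L
  m <- match(majors$.row, as.integer(rownames(nm)))
  majors$Nm[!is.na(m)] <- as.integer(nm[m[!is.na(m)], 1L])
  tot <- majors$NM + majors$Nm
  majors$AS <- ifelse(tot > 0L, majors$Nm / tot, NA_real_)
  links$MIRA <- links$Nim /
    (majors$NM + majors$Nm)[match(links$major_row, majors$.row)]
  names(majors)[names(majors) == ".row"] <- "major_id"
  list(majors = majors, links = links)
}

#' Per-gene AS rate
#'
#' Pools the (NM, Nm) counts of a gene's major-isoform introns into a single
#' per-intron rate `pooled_rate = sum(Nm) / sum(NM + Nm)` and, assuming
#' independent AS events at each of the gene's `Ni` major introns, reports
#' the probability of at least one AS event:
#' `ASg = 1 - (1 - pooled_rate)^Ni`.
#'
#' @param majors Major-intron table with `gene_id`, `NM`, `Nm` (from
#'   [quantify_major_introns()]).
#' @return A data.frame with one row per gene: `gene_id`, `pooled_rate`,
#'   `Ni`, `p0`, `ASg`. Genes with zero total reads get `NA` rates.
#' @export
per_gene_as_rate <- function(majors) {
  majors <- as.data.frame(majors)
  stopifnot(!is.null(majors$gene_id))
  g <- factor(majors$gene_id)
  nm <- tapply(majors$Nm, g, sum)
  tot <- tapply(majors$NM + majors$Nm, g, sum)
  ni <- as.integer(table(g))
  pooled <- ifelse(tot > 0, nm / tot, NA_real_)
  p0 <- (1 - pooled)^ni
  data.frame(gene_id = levels(g), pooled_rate = as.numeric(pooled),
             Ni = ni, p0 = as.numeric(p0), ASg = 1 - as.numeric(p0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sequencing depth of a sample
#'
#' The sample depth is the median per-base read coverage across a reference
#' gene set (single-copy orthologues in cross-species work).
#'
#' @param coverage Numeric vector of per-base coverages.
#' @return The median coverage.
#' @export
sample_depth <- function(coverage) {
  if (!length(coverage)) stop("empty coverage vector")
  median(coverage)
}

#' Depth-weighted mean expression
#'
#' Averages per-sample expression values (e.g. FPKM) weighted by each
#' sample's sequencing depth.
#'
#' @param fpkm Numeric vector of per-sample expression values.
#' @param depths Numeric vector of per-sample depths (same length,
#'   non-negative, not all zero).
#' @return The weighted mean expression.
#' @export
weighted_expression <- function(fpkm, depths) {
  stopifnot(length(fpkm) == length(depths), all(depths >= 0))
  if (sum(depths) <= 0) stop("all sample depths are zero")
  sum(fpkm * depths) / sum(depths)
}
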