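# Genomic positions of a splice-site dinucleotide, strand-aware.
# side = "donor" (5' site, first two intronic bases in transcription sense)
# or "acceptor" (3' site, last two intronic bases).
.dinuc_positions <- function(start, end, strand, side) {
  fivep <- (side == "donor") == (strand != "-")
  p1 <- ifelse(fivep, start, end - 1L)
  data.frame(pos1 = as.integer(p1), pos2 = as.integer(p1 + 1L))
}

#' Enumerate splice-site dinucleotides of minor-major links
#'
#' For each minor-major link, emits the dinucleotide of the minor intron's
#' non-shared boundary (categorised `minor_exonic` or `minor_intronic` by
#' where that boundary falls relative to the major intron) and the
#' corresponding major-intron dinucleotide on the same side (`major_donor`
#' or `major_acceptor`). Each locus carries the link's abundance class
#' (`abundant`: MIRA > `threshold`; `rare` otherwise).
#'
#' @param links Link table from [quantify_major_introns()] (needs minor and
#'   major coordinates, `shared_side`, `location`, `MIRA`, `strand`).
#' @param threshold MIRA threshold for the abundant/rare split (default
#'   0.05).
#' @return A data.frame of loci: `chrom`, `pos1`, `pos2` (adjacent 1-based
#'   positions), `category`, `sv_class`.
#' @export
enumerate_splice_sites <- function(links, threshold = 0.05) {
  links <- as.data.frame(links)
  empty <- data.frame(chrom = character(), pos1 = integer(),
                      pos2 = integer(), category = character(),
                      sv_class = character(), stringsAsFactors = FALSE)
  if (!nrow(links)) return(empty)
  free_side <- ifelse(links$shared_side == "donor", "acceptor", "donor")
  sv <- split_abundant_rare(links$MIRA, threshold)
  minor <- .dinuc_positions(links$minor_start, links$minor_end,
                            links$strand, free_side)
  major <- .dinuc_positions(links$major_start, links$major_end,
                            links$strand, free_side)
  rbind(
    data.frame(chrom = links$chrom, minor,
               category = paste0("minor_", links$location),
               sv_class = sv, stringsAsFactors = FALSE),
    data.frame(chrom = links$chrom, major,
               category = paste0("major_", free_side),
               sv_class = sv, stringsAsFactors = FALSE))
}

#' Find control dinucleotides near major splice sites
#'
#' For each link, searches the reference sequence for neutral dinucleotides
#' matched to the splice-site consensus but placed where they cannot be
#' functional splice sites: `AG` dinucleotides near the major intron's
#' donor site (in the upstream exon and in the intron) and `GT`
#' dinucleotides near its acceptor site (in the downstream exon and in the
#' intron) — the cross-placement avoids scoring unidentified minor splice
#' sites. Candidates are sought at 20-60 bp (inclusive) from the major
#' splice site in transcription coordinates; the candidate nearest the
#' splice site wins, and none is emitted for a flank without a candidate.
#' Candidates overlapping positions in `exclude` (e.g. all detected splice
#' dinucleotides) are skipped.
#'
#' @param links Link table (needs `chrom`, `strand`, `major_start`,
#'   `major_end`, `MIRA`).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param window Integer vector `c(min, max)` distance in bp (default
#'   `c(20, 60)`).
#' @param threshold MIRA threshold for the abundance class.
#' @param exclude Optional data.frame of positions to avoid (`chrom`,
#'   `pos`), e.g. from [splice_dinucleotide_positions()].
#' @return A data.frame of control loci in the [enumerate_splice_sites()]
#'   schema, with categories `control_exonic_AG`, `control_intronic_AG`,
#'   `control_exonic_GT`, `control_intronic_GT`.
#' @export
find_control_dinucleotides <- function(links, genome, window = c(20L, 60L),
                                       threshold = 0.05, exclude = NULL) {
  links <- as.data.frame(links)
  sv <- if (nrow(links)) split_abundant_rare(links$MIRA, threshold)
  else character()
  ks <- seq.int(window[1L], window[2L])
  excl_key <- if (is.null(exclude)) character() else
    paste(exclude$chrom, exclude$pos)
  seqs <- lapply(setNames(nm = unique(links$chrom)),
                 function(ch) as.character(genome[[ch]]))
  out <- vector("list", 4L * nrow(links))
  oi <- 0L
  for (i in seq_len(nrow(links))) {
    ch <- links$chrom[i]
    chseq <- seqs[[ch]]
    L <- nchar(chseq)
    minus <- links$strand[i] == "-"
    s <- links$major_start[i]
    e <- links$major_end[i]
    # transcription-sense search patterns on the forward genome
    pat_ag <- if (minus) "CT" else "AG"
    pat_gt <- if (minus) "AC" else "GT"
    # first (transcription-wise) base of a candidate at offset k, per flank
    flanks <- list(
      control_intronic_AG = list(pat = pat_ag,
                                 p1 = if (minus) e - ks - 1L else s + ks),
      control_exonic_AG = list(pat = pat_ag,
                               p1 = if (minus) e + ks - 1L else s - ks),
      control_intronic_GT = list(pat = pat_gt,
                                 p1 = if (minus) s + ks else e - ks - 1L),
      control_exonic_GT = list(pat = pat_gt,
                               p1 = if (minus) s - ks else e + ks - 1L))
    for (cat in names(flanks)) {
      p1 <- flanks[[cat]]$p1
      ok <- p1 >= 1L & p1 + 1L <= L
      p1 <- p1[ok]
      if (!length(p1)) next
      hit <- substring(chseq, p1, p1 + 1L) == flanks[[cat]]$pat
      if (length(excl_key)) {
        hit <- hit & !(paste(ch, p1) %in% excl_key) &
          !(paste(ch, p1 + 1L) %in% excl_key)
      }
      if (!any(hit)) next
      p <- p1[which(hit)[1L]]  # offsets are ordered nearest-first
      oi <- oi + 1L
      out[[oi]] <- data.frame(chrom = ch, pos1 = p, pos2 = p + 1L,
                              category = cat, sv_class = sv[i],
                              stringsAsFactors = FALSE)
    }
  }
  if (!oi) {
    return(data.frame(chrom = character(), pos1 = integer(),
                      pos2 = integer(), category = character(),
                      sv_class = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[seq_len(oi)])
  rownames(res) <- NULL
  res
}

#' All splice-site dinucleotide positions of an intron table
#'
#' Utility for building the exclusion set of
#' [find_control_dinucleotides()]: the donor and acceptor dinucleotide
#' positions of every intron.
#'
#' @param introns Intron table with `chrom`, `intron_start`, `intron_end`.
#' @return A data.frame with `chrom` and `pos`.
#' @export
splice_dinucleotide_positions <- function(introns) {
  introns <- as.data.frame(introns)
  data.frame(
    chrom = rep(introns$chrom, 4L),
    pos = c(introns$intron_start, introns$intron_start + 1L,
            introns$intron_end - 1L, introns$intron_end))
}

#' Flag loci subject to CpG hypermutability
#'
#' A dinucleotide locus is CpG-affected when any of its bases participates
#' in a CG dinucleotide in the reference, considering one flanking base on
#' each side (i.e. `CG` occurs within the 4-mer context). With
#' `strict = TRUE` only loci whose own dinucleotide is `CG` are flagged.
#' Flanks beyond contig edges are treated as absent.
#'
#' @param loci Locus table (`chrom`, `pos1`, `pos2`).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param strict Use the strict "dinucleotide is CG" rule (default FALSE).
#' @return `loci` with a logical `cpg_affected` column added.
#' @export
is_cpg_affected <- function(loci, genome, strict = FALSE) {
  loci <- as.data.frame(loci)
  loci$cpg_affected <- rep(FALSE, nrow(loci))
  for (ch in unique(loci$chrom)) {
    i <- which(loci$chrom == ch)
    chseq <- as.character(genome[[ch]])
    L <- nchar(chseq)
    if (strict) {
      loci$cpg_affected[i] <-
        substring(chseq, loci$pos1[i], loci$pos2[i]) == "CG"
    } else {
      ctx <- substring(chseq, pmax(loci$pos1[i] - 1L, 1L),
                       pmin(loci$pos2[i] + 1L, L))
      loci$cpg_affected[i] <- grepl("CG", ctx, fixed = TRUE)
    }
  }
  loci
}

#' SNP density per splice-site stratum
#'
#' Treats each base of each locus as a site; a site is polymorphic iff a
#' SNP is recorded at its position. Reports, per stratum, the number of
#' sites, the number of polymorphic sites, their proportion and its 95%
#' Wilson score confidence interval (proportion test without continuity
#' correction).
#'
#' @param loci Locus table from [enumerate_splice_sites()] /
#'   [find_control_dinucleotides()] (optionally with `cpg_affected`).
#' @param snps SNP table with `chrom` and `pos` (e.g. from
#'   [read_snp_positions()]).
#' @param by Stratifying columns (defaults to `category`, `sv_class` and,
#'   when present, `cpg_affected`).
#' @return A data.frame with the stratifying columns plus `n_sites`,
#'   `n_polymorphic`, `proportion`, `ci_low`, `ci_high`.
#' @export
snp_density <- function(loci, snps,
                        by = intersect(c("category", "sv_class",
                                         "cpg_affected"), names(loci))) {
  loci <- as.data.frame(loci)
  snp_key <- unique(paste(snps$chrom, snps$pos))
  poly <- (paste(loci$chrom, loci$pos1) %in% snp_key) +
    (paste(loci$chrom, loci$pos2) %in% snp_key)
  strata <- interaction(loci[by], drop = TRUE, sep = "\r")
  n_sites <- 2L * as.integer(table(strata))
  n_poly <- as.integer(tapply(poly, strata, sum))
  keys <- do.call(rbind, strsplit(levels(strata), "\r", fixed = TRUE))
  out <- as.data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  if ("cpg_affected" %in% by)
    out$cpg_affected <- as.logical(out$cpg_affected)
  out$n_sites <- n_sites
  out$n_polymorphic <- n_poly
  out$proportion <- n_poly / n_sites
  ci <- t(vapply(seq_along(n_sites), function(i) {
    if (n_sites[i] == 0L) return(c(NA_real_, NA_real_))
    as.numeric(suppressWarnings(
      prop.test(n_poly[i], n_sites[i], correct = FALSE))$conf.int)
  }, numeric(2L)))
  out$ci_low <- ci[, 1L]
  out$ci_high <- ci[, 2L]
  out
}
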