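test_that("CIGAR walk locates introns and anchors, including multi-N reads", {
  aln <- aln_row(pos = 101, cigar = "50M100N50M")
  jx <- extract_junctions(aln, min_anchor = 8)
  expect_equal(nrow(jx), 1L)
  expect_equal(jx$intron_start, 151L)
  expect_equal(jx$intron_end, 250L)
  expect_equal(jx$left_anchor, 50L)
  expect_equal(jx$right_anchor, 50L)

  # two junctions per read; internal anchors bounded by neighbouring N ops
  aln2 <- aln_row(pos = 1, cigar = "20M50N30M60N10M")
  jx2 <- extract_junctions(aln2, min_anchor = 8)
  expect_equal(jx2$intron_start, c(21L, 101L))
  expect_equal(jx2$intron_end, c(70L, 160L))
  expect_equal(jx2$left_anchor, c(20L, 30L))
  expect_equal(jx2$right_anchor, c(30L, 10L))

  # I consumes no reference and no anchor M; D consumes reference only
  jx3 <- extract_junctions(aln_row(pos = 1, cigar = "10M2I5M3D100N20M"),
                           min_anchor = 8)
  expect_equal(jx3$intron_start, 19L)  # 10M + 3D before the junction
  expect_equal(jx3$left_anchor, 15L)   # M bases only
  # soft clips contribute neither anchor nor reference
  jx4 <- extract_junctions(aln_row(pos = 1, cigar = "5S10M100N10M3S"),
                           min_anchor = 8)
  expect_equal(jx4$intron_start, 11L)
  expect_equal(c(jx4$left_anchor, jx4$right_anchor), c(10L, 10L))
})

test_that("detection vs quantification anchors, mismatch, length and uniqueness filters", {
  short <- aln_row(cigar = "5M100N95M")
  expect_equal(nrow(extract_junctions(short, min_anchor = 8)), 0L)
  expect_equal(nrow(extract_junctions(short, min_anchor = 5)), 1L)

  mm <- aln_row(cigar = "50M100N50M", mismatch_count = 3)  # ratio 0.03
  expect_equal(nrow(extract_junctions(mm)), 0L)
  mm$mismatch_count <- 2L  # ratio 0.02, at the threshold
  expect_equal(nrow(extract_junctions(mm)), 1L)

  long <- aln_row(cigar = "50M2000001N50M")
  expect_equal(nrow(extract_junctions(long)), 0L)
  expect_equal(nrow(extract_junctions(aln_row(cigar = "50M2000000N50M"))),
               1L)

  multi <- aln_row(cigar = "50M100N50M", is_unique = FALSE)
  expect_equal(nrow(extract_junctions(multi)), 0L)
})

test_that("malformed CIGARs are rejected with a warning, not an error", {
  aln <- rbind(aln_row("ok", cigar = "50M100N50M"),
               aln_row("bad1", cigar = "50M100N50"),
               aln_row("bad2", cigar = "50M100X50M"))
  expect_warning(jx <- extract_junctions(aln), "CIGAR")
  expect_equal(jx$read_id, "ok")
})

test_that("vectorized extraction equals a brute-force per-read walk", {
  aln <- random_reads(100, seed = 421)
  for (anchor in c(5L, 8L, 20L)) {
    got <- extract_junctions(aln, min_anchor = anchor)
    want <- naive_extract_junctions(aln, min_anchor = anchor)
    o1 <- do.call(order, got[c("read_id", "intron_start")])
    o2 <- do.call(order, want[c("read_id", "intron_start")])
    expect_equal(got[o1, ], want[o2, ], ignore_attr = TRUE)
  }
})

test_that("raising the anchor threshold never adds junctions", {
  aln <- random_reads(150, seed = 77)
  counts <- vapply(1:30, function(a)
    nrow(extract_junctions(aln, min_anchor = a)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("splice signals determine acceptance and strand", {
  g <- toy_genome(chr1 = paste0(strrep("A", 10),
                                "GT", strrep("C", 16), "AG",  # 11..30: GT-AG +
                                "CT", strrep("C", 16), "AC",  # 31..50: GT-AG -
                                "GG", strrep("C", 16), "AG",  # 51..70: invalid
                                "GC", strrep("C", 16), "AG",  # 71..90: GC-AG +
                                "AT", strrep("C", 16), "AC")) # 91..110: AT-AC +
  jx <- data.frame(chrom = "chr1",
                   intron_start = c(11L, 31L, 51L, 71L, 91L),
                   intron_end = c(30L, 50L, 70L, 90L, 110L))
  v <- validate_splice_signal(jx, g)
  expect_equal(v$intron_start, c(11L, 31L, 71L, 91L))
  expect_equal(v$strand, c("+", "-", "+", "+"))
  expect_equal(v$signal, c("GT-AG", "GT-AG", "GC-AG", "AT-AC"))

  expect_error(validate_splice_signal(
    data.frame(chrom = "chr1", intron_start = 105L, intron_end = 120L), g),
    "outside")
  expect_error(validate_splice_signal(
    data.frame(chrom = "chrX", intron_start = 1L, intron_end = 10L), g),
    "absent")
})

toy_annotation <- function() {
  ex <- data.frame(
    gene_id = c("A", "A", "B"),
    transcript_id = c("A.1", "A.1", "B.1"),
    chrom = "chr1",
    start = c(100L, 301L, 295L),
    end = c(200L, 400L, 360L),
    strand = "+", stringsAsFactors = FALSE)
  ann <- list(
    exons = ex,
    start_codons = data.frame(gene_id = "A", chrom = "chr1", start = 100L,
                              end = 102L, strand = "+",
                              stringsAsFactors = FALSE),
    stop_codons = data.frame(gene_id = "A", chrom = "chr1", start = 398L,
                             end = 400L, strand = "+",
                             stringsAsFactors = FALSE))
  ann$genes <- unique(ex[, c("gene_id", "chrom", "strand")])
  ann$introns <- splicedrift:::derive_annotated_introns(ex)
  class(ann) <- "gene_annotation"
  ann
}

test_that("gene assignment uses 1-bp tolerance and flags ambiguity", {
  ann <- toy_annotation()
  introns <- data.frame(
    chrom = "chr1",
    intron_start = c(201L,  # exactly exon A end + 1 -> A
                     300L,  # within 1 bp of A exon start 301 and B exon...
                     600L), # far from everything
    intron_end = c(300L,    # within 1bp of exon A start 301
                   360L,    # matches B exon end and within 1 of A
                   700L))
  a <- assign_to_gene(introns, ann)
  expect_equal(a$gene_status, c("assigned", "ambiguous", "unassigned"))
  expect_equal(a$gene_id, c("A", NA, NA))
})

test_that("annotated status requires both boundaries to match exactly", {
  ann <- toy_annotation()
  introns <- data.frame(chrom = "chr1",
                        intron_start = c(201L, 201L),
                        intron_end = c(300L, 299L),
                        strand = "+")
  m <- mark_annotated(introns, ann)
  expect_equal(m$annotated, c(TRUE, FALSE))
})

test_that("CDS-span restriction is orientation-aware and strict on straddles", {
  ann <- toy_annotation()
  introns <- data.frame(
    chrom = "chr1",
    intron_start = c(201L, 50L, 95L, 399L),
    intron_end = c(300L, 90L, 150L, 450L),
    gene_id = "A", stringsAsFactors = FALSE)
  r <- restrict_to_cds_span(introns, ann, drop = FALSE)
  # inside; fully upstream; straddling the start codon; straddling the stop
  expect_equal(r$in_cds_span, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(nrow(restrict_to_cds_span(introns, ann)), 1L)

  # minus-strand gene: span runs from min stop-codon to max start-codon coord
  ann$genes$strand <- "-"
  ann$exons$strand <- "-"
  ann$start_codons$start <- 398L
  ann$start_codons$end <- 400L
  ann$stop_codons$start <- 100L
  ann$stop_codons$end <- 102L
  r2 <- restrict_to_cds_span(introns, ann, drop = FALSE)
  expect_equal(r2$in_cds_span, c(TRUE, FALSE, FALSE, FALSE))

  # gene without codons: all flagged out, with a warning
  ann$start_codons <- ann$start_codons[0, ]
  expect_warning(r3 <- restrict_to_cds_span(introns, ann, drop = FALSE),
                 "start/stop")
  expect_false(any(r3$in_cds_span))
})

test_that("intron tables survive a write/read round trip", {
  sim <- generate_annotation(synthetic_config(n_genes = 4L), seed = 11)
  rd <- simulate_reads(sim, depth = 60, seed = 12)
  introns <- detect_introns(rd$alignments, sim$genome, sim$annotation)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intron_table(introns, path)
  back <- read_intron_table(path)
  expect_equal(back, introns, ignore_attr = TRUE)
})
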