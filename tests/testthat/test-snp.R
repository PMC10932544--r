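# one fully specified plus-strand link: major intron 101..200, minor intron
# 101..194 (acceptor 6 bp inside the major intron)
toy_link <- function(mira = 0.02, strand = "+") {
  data.frame(major_row = 1L, minor_row = 2L, chrom = "chr1",
             strand = strand, major_start = 101L, major_end = 200L,
             minor_start = 101L, minor_end = 194L, gene_id = "g1",
             Nim = 5L, shared_side = if (strand == "+") "donor" else
               "acceptor",
             offset = 6L, location = "intronic", MIRA = mira,
             stringsAsFactors = FALSE)
}

test_that("splice-site enumeration emits minor and matching major dinucleotides", {
  loci <- enumerate_splice_sites(toy_link())
  minor <- loci[loci$category == "minor_intronic", ]
  major <- loci[loci$category == "major_acceptor", ]
  expect_equal(nrow(loci), 2L)
  # last two bases of the minor intron, and of the major intron
  expect_equal(c(minor$pos1, minor$pos2), c(193L, 194L))
  expect_equal(c(major$pos1, major$pos2), c(199L, 200L))
  expect_equal(unique(loci$sv_class), "rare")
  expect_equal(unique(enumerate_splice_sites(toy_link(0.07))$sv_class),
               "abundant")

  # minus strand: the non-shared side becomes the donor at the same coords
  loci2 <- enumerate_splice_sites(toy_link(strand = "-"))
  expect_setequal(loci2$category, c("minor_intronic", "major_donor"))
  expect_equal(sort(loci2$pos1), c(193L, 199L))
})

test_that("control dinucleotides respect pattern, window and cross-placement", {
  # major intron 101..200 on an A-background: plant AG at donor+25 (intronic),
  # AG at donor-30 (exonic), GT at acceptor-25 (intronic), GT at acceptor+40
  base <- rep("A", 300)
  base[126:127] <- c("A", "G")   # intronic AG, first base at 101+25
  base[71:72] <- c("A", "G")     # exonic AG, first base at 101-30
  base[174:175] <- c("G", "T")   # intronic GT, last base at 200-25
  base[239:240] <- c("G", "T")   # exonic GT, last base at 200+40
  g <- toy_genome(chr1 = paste(base, collapse = ""))
  ctrl <- find_control_dinucleotides(toy_link(), g)
  expect_setequal(ctrl$category,
                  c("control_intronic_AG", "control_exonic_AG",
                    "control_intronic_GT", "control_exonic_GT"))
  expect_equal(ctrl$pos1[ctrl$category == "control_intronic_AG"], 126L)
  expect_equal(ctrl$pos1[ctrl$category == "control_exonic_AG"], 71L)
  expect_equal(ctrl$pos1[ctrl$category == "control_intronic_GT"], 174L)
  expect_equal(ctrl$pos1[ctrl$category == "control_exonic_GT"], 239L)

  # candidates closer than 20 bp are outside the window
  base19 <- rep("A", 300)
  base19[120:121] <- c("A", "G")  # 19 bp from the donor
  g19 <- toy_genome(chr1 = paste(base19, collapse = ""))
  ctrl19 <- find_control_dinucleotides(toy_link(), g19)
  expect_false("control_intronic_AG" %in% ctrl19$category)

  # nearest candidate wins; excluded positions are skipped
  base2 <- rep("A", 300)
  base2[126:127] <- c("A", "G")
  base2[131:132] <- c("A", "G")
  g2 <- toy_genome(chr1 = paste(base2, collapse = ""))
  c2 <- find_control_dinucleotides(toy_link(), g2)
  expect_equal(c2$pos1[c2$category == "control_intronic_AG"], 126L)
  c3 <- find_control_dinucleotides(
    toy_link(), g2, exclude = data.frame(chrom = "chr1", pos = 126L))
  expect_equal(c3$pos1[c3$category == "control_intronic_AG"], 131L)
})

test_that("minus-strand controls use reverse-complement patterns", {
  # minus-strand major intron 101..200: donor at 200, acceptor at 101;
  # a transcription-sense AG 25 bp into the intron is a forward CT at
  # positions (174, 175)
  base <- rep("A", 300)
  base[174:175] <- c("C", "T")
  g <- toy_genome(chr1 = paste(base, collapse = ""))
  ctrl <- find_control_dinucleotides(toy_link(strand = "-"), g)
  expect_equal(ctrl$pos1[ctrl$category == "control_intronic_AG"], 174L)
})

test_that("CpG flagging inspects the dinucleotide and one flanking base", {
  g <- toy_genome(chr1 = "TCGTAATAGAAACGAA")
  loci <- data.frame(chrom = "chr1",
                     pos1 = c(3L, 8L, 13L, 15L),
                     pos2 = c(4L, 9L, 14L, 16L))
  # CGT context (C before GT) -> TRUE; TAGA -> FALSE; ACGA (dinuc CG) -> TRUE;
  # contig edge with missing flank -> FALSE
  f <- is_cpg_affected(loci, g)
  expect_equal(f$cpg_affected, c(TRUE, FALSE, TRUE, FALSE))
  s <- is_cpg_affected(loci, g, strict = TRUE)
  expect_equal(s$cpg_affected, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("SNP density counts per base with Wilson confidence intervals", {
  # 100 dinucleotides = 200 bases, 6 polymorphic
  loci <- data.frame(chrom = "chr1", pos1 = seq(1L, 991L, 10L),
                     pos2 = seq(2L, 992L, 10L), category = "major_donor",
                     sv_class = "rare")
  snps <- data.frame(chrom = "chr1", pos = seq(1L, 991L, 10L)[1:6])
  d <- snp_density(loci, snps)
  expect_equal(d$n_sites, 200L)
  expect_equal(d$n_polymorphic, 6L)
  expect_equal(d$proportion, 0.03)
  expect_equal(d$ci_low, 0.01382031, tolerance = 1e-6)
  expect_equal(d$ci_high, 0.06389429, tolerance = 1e-6)

  # one SNP on one base of one dinucleotide among 50 -> 1/100 bases
  loci50 <- loci[1:50, ]
  d50 <- snp_density(loci50, data.frame(chrom = "chr1", pos = 2L))
  expect_equal(d50$proportion, 0.01)

  # invariant to the order of loci and SNPs
  perm <- snp_density(loci[sample(nrow(loci)), ],
                      snps[sample(nrow(snps)), , drop = FALSE])
  expect_equal(perm, d)

  # zero polymorphic: CI lower bound 0
  dz <- snp_density(loci50, data.frame(chrom = character(),
                                       pos = integer()))
  expect_equal(dz$proportion, 0)
  expect_equal(dz$ci_low, 0)
})

test_that("controls never coincide with splice-site dinucleotides", {
  sim <- generate_annotation(synthetic_config(n_genes = 25L), seed = 31)
  rd <- simulate_reads(sim, depth = 150, seed = 32)
  introns <- detect_introns(rd$alignments, sim$genome, sim$annotation)
  q <- quantify_introns(introns, rd$alignments)
  mq <- quantify_major_introns(q)
  excl <- splice_dinucleotide_positions(q)
  ctrl <- find_control_dinucleotides(mq$links, sim$genome, exclude = excl)
  expect_gt(nrow(ctrl), 0)
  ctrl_pos <- c(paste(ctrl$chrom, ctrl$pos1), paste(ctrl$chrom, ctrl$pos2))
  expect_length(intersect(ctrl_pos, paste(excl$chrom, excl$pos)), 0)
})

test_that("planted SNP-density reduction at minor sites is recovered", {
  cfg <- synthetic_config(n_genes = 150L, snp_background = 0.05,
                          snp_factor_major = 1,
                          snp_factor_minor_abundant = 0.4,
                          snp_factor_minor_rare = 0.4)
  sim <- generate_annotation(cfg, seed = 41)
  snps <- simulate_snps(sim, seed = 42)
  tr <- sim$truth$introns
  # score the truth minor dinucleotides directly against matched controls
  shared_start <- tr$minor_start == tr$intron_start
  minor <- data.frame(chrom = tr$chrom,
                      pos1 = ifelse(shared_start, tr$minor_end - 1L,
                                    tr$minor_start),
                      category = "minor", sv_class = "all")
  minor$pos2 <- minor$pos1 + 1L
  links <- data.frame(chrom = tr$chrom, strand = tr$strand,
                      major_start = tr$intron_start,
                      major_end = tr$intron_end, MIRA = tr$as_rate)
  ctrl <- find_control_dinucleotides(
    links, sim$genome,
    exclude = rbind(splice_dinucleotide_positions(tr),
                    data.frame(chrom = minor$chrom,
                               pos = c(minor$pos1, minor$pos2))))
  ctrl$sv_class <- "all"
  dens <- snp_density(rbind(minor[, c("chrom", "pos1", "pos2", "category",
                                      "sv_class")],
                            ctrl[, c("chrom", "pos1", "pos2", "category",
                                     "sv_class")]),
                      snps, by = "category")
  p_minor <- dens$proportion[dens$category == "minor"]
  p_ctrl <- mean(dens$proportion[dens$category != "minor"])
  ratio <- p_minor / p_ctrl
  expect_gt(dens$n_sites[dens$category == "minor"], 1000)
  expect_lt(abs(ratio - 0.4), 0.25)
})
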